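# optodecast

Machine-learning calibration and chemical imaging for dual-analyte
luminescent optodes.

## The problem

Luminescent optodes image chemistry: a sensor foil's emission spectrum,
recorded per pixel by a hyperspectral camera (470–900 nm, 3 nm steps),
encodes analyte concentrations at every point of a 2D scene. A
*dual-analyte* optode stacks a pH-sensitive layer (an HPTS-type indicator
with distinct acid/base emission forms and an isosbestic point at 530 nm)
on top of an oxygen-sensitive layer (a Pt-benzoporphyrin phosphor at
~770 nm plus a reference dye at 500–600 nm). Each analyte alone follows a
textbook law —

- pH: Boltzmann sigmoid, base-form fraction
  *f* = 1 / (1 + 10^((pKa − pH)/s)),
- O₂: simplified Stern–Volmer quenching, *I* = *I*₀ / (1 + K_SV · pO₂)

— but the stacked layers reabsorb each other's emission (inner-filter
cross-talk, strongest at acidic pH under anoxia), so single-analyte fits
fail. `optodecast` replaces them with a supervised pipeline whose core is
a **three-layer gradient-boosted (XGBoost) cascade**: layer 1 predicts pH
from the raw 144-band spectrum; layer 2 predicts pO₂ from the spectrum
plus the predicted pH; layer 3 refines the pO₂ estimate from both previous
outputs. Predictions outside the sensor's dynamic range (pH 5–9, pKa ± 2)
are flagged invalid.

The package is aimed at people building or analyzing optical chemical
sensors: it provides the full workflow — a physics-based spectral
simulator for testing, ENVI cube and CSV table I/O, data preparation
(5×5-pixel RoI tiling, per-band IQR outlier cleaning, median aggregation,
dataset balancing to the median per-point count, seeded 80:20 splits),
model screening across nine regressor families, hyperparameter sweeps,
MAE/RMSE with k-fold cross-validation, and pixel-wise conversion of
hyperspectral cubes into pH / pO₂ chemical images.

## Worked example

Simulate a noisy calibration campaign, train the cascade, and image a
pH-gradient scene:

```r
library(optodecast)

tab <- generate_calibration_set(ph_points = seq(5, 9, 0.5),
                                po2_points = c(0, 20, 50, 100, 150, 195),
                                counts = 8, seed = 42)
tab
#> <calibration_table> 432 samples x 144 bands; pH 5-9, pO2 0-195 hPa

sp <- split_table(tab, ratio = 0.8, seed = 1)
model <- train_cascade(sp$train)
model
#> <cascade_model> 3 gradient-boosted layers (pH -> pO2 -> refined pO2),
#> 144 bands, 346 training rows, oof conditioning

pred <- predict_samples(model, table_spectra(sp$validation))
mae(pred$ph, sp$validation$ph)            # 0.059  pH units
mae(pred$po2_layer2, sp$validation$po2)   # 1.47   hPa (first pass)
mae(pred$po2_refined, sp$validation$po2)  # 1.20   hPa (after refinement)

scene <- generate_gradient_scene(40, 60,
  ph_field = matrix(rep(seq(5, 9, length.out = 60), each = 40), 40, 60),
  po2_field = 100, seed = 7)
img <- predict_image(model, scene$cube)
img
#> <chemical_image> 40 x 60 px, 98.8% valid; pH 4.95-9.05, pO2 99.0-111.0 hPa
mae(as.numeric(img$ph_map), as.numeric(scene$truth$ph_map))  # 0.124
export_maps(img, "maps")   # ph.csv/po2.csv (lossless), PNG previews, maps.json
```

The held-out pH error of ~0.06 and refined pO₂ error of ~1.2 hPa show the
cascade inverting the coupled spectra well inside the sensor's dynamic
range; the refinement layer's improvement over the first oxygen pass
(1.47 → 1.20 hPa) is the reason it exists. On the gradient scene the
per-pixel pH map tracks the ground-truth ramp to ~0.12 pH units with the
out-of-range pixels at the ramp edges flagged invalid.

A thin command-line wrapper over the same functions ships in
`inst/cli/optodecast.R` (subcommands `simulate`, `prepare`, `select`,
`hpo`, `train`, `evaluate`, `predict-image`, `run-all`), and
`run_pipeline()` drives the whole workflow from one seeded config.

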