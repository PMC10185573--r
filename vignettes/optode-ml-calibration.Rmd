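---
title: "Calibrating dual-analyte optodes with a gradient-boosted cascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating dual-analyte optodes with a gradient-boosted cascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The sensing problem

A dual-analyte optode stacks two luminescent sensing layers on one foil: a
pH-sensitive layer whose indicator (an HPTS derivative) shifts emission
between an acid form (~490 nm) and a base form (~548 nm), and an
oxygen-sensitive layer combining an analyte-insensitive reference dye
(Macrolex Fluorescence Yellow, 500--600 nm) with a Pt-benzoporphyrin
phosphor emitting near 770 nm whose intensity is collisionally quenched by
molecular oxygen. Read out with a hyperspectral camera (470--900 nm, 3 nm
steps), every image pixel carries a 144-band spectrum that encodes both
analytes at one spot.

If the layers were independent, two textbook calibration laws would
suffice:

* **pH**: a Boltzmann sigmoid in pH for the base-form fraction,
  $f = \left(1 + 10^{(pK_a - \mathrm{pH})/s}\right)^{-1}$, centered at the
  apparent $pK_a$;
* **oxygen**: the simplified Stern--Volmer law
  $I = I_0 / (1 + K_{SV}\,p\mathrm{O}_2)$ for the phosphor intensity.

They do not suffice here, because the layers couple optically: emission of
the acid form overlaps the absorption of the oxygen layer (reabsorption is
strongest under acidic, anoxic conditions), and the reference dye's
emission is partially reabsorbed by the base form at high pH. Single-analyte
fits then fail visibly, which is exactly the situation the package's
supervised-learning calibration addresses.

## The forward simulator

`spectral_model_params()` + `emit_spectrum()` implement a physics-based
forward model used for testing and demonstration: four Gaussian emission
bands combined as

$$S(\lambda) = (1-f)\,A_a\,[1 - c_a g(p\mathrm{O}_2)]\,G_a(\lambda)
  + f\,A_b\,G_b(\lambda)
  + A_r\,[1 - c_r f]\,G_r(\lambda)
  + \frac{I_0}{1 + K_{SV} p\mathrm{O}_2} G_{o}(\lambda),$$

with $f$ the Boltzmann fraction and $g(p\mathrm{O}_2) = (1 + K_{SV}
p\mathrm{O}_2)^{-1}$ the saturation of the oxygen layer's absorption (the
same law as the quenching, so reabsorption of the acid band is maximal
under anoxia). The two cross-talk coefficients $c_a$ (acid emission
reabsorbed by the oxygen layer) and $c_r$ (reference emission reabsorbed
by the base form) are the terms that make naive per-analyte calibration
fail; they are free parameters of the simulator, set large enough (0.3 and
0.15) that the failure is visible, since their true magnitudes are not
tabulated for the real sensor.

Default parameter choices, with reasoning:

| parameter | default | why |
|---|---|---|
| $pK_a$ | 7.0 | midpoint of the sensor's stated dynamic range pH 5--9 ($pK_a \pm 2$) |
| Boltzmann slope $s$ | 1.0 pH | the $\pm 2$ range then spans $f \approx 0.01$--$0.99$ |
| acid band | 490 nm, $\sigma$ 25 nm | short-wavelength acid emission of the indicator |
| base band | 548 nm, $\sigma$ 30 nm | long-wavelength base emission |
| reference band | 535 nm, $\sigma$ 28 nm, $A_r$ 0.8 | reference dye between 500 and 600 nm |
| O$_2$ band | 770 nm, $\sigma$ 20 nm, $I_0$ 1.2 | NIR phosphor emission |
| $A_a / A_b$ | fixed by the 530 nm tie | the pure acid and base curves must cross at the indicator's isosbestic point |
| $K_{SV}$ | 0.02 hPa$^{-1}$ | ~80% quenching at air saturation (195 hPa), typical of Pt-benzoporphyrins in polystyrene |
| noise sd | 0.02 a.u. | ~1% of peak signal, a realistic camera SNR |

The acid-band amplitude is derived, not chosen: $A_a = A_b\,
G_b(530)/G_a(530)$, which pins the acid/base crossing to the isosbestic
point at 530 nm. With cross-talk on, the crossing of full spectra shifts
by roughly one band (to ~527--530 nm depending on oxygen), which stays
within the two-band (±6 nm) tolerance the tests assert.

Oxygen is expressed as partial pressure in hPa throughout, with air
saturation at 195 hPa.

What the simulator deliberately does *not* model: radiative-transfer
accuracy of the layer stack, FRET/PET kinetics, excitation-side effects,
wavelength-correlated noise, temperature dependence, photobleaching, and
instrument artifacts (vignetting, stray light). Passing tests on synthetic
data therefore demonstrate that the pipeline's statistics and plumbing are
correct and that the cascade can invert this class of coupled spectra;
they do not certify accuracy on any particular real sensor batch.

## Data preparation

Real calibration images are reduced to a labeled table in four steps,
mirroring common optode-imaging practice:

1. **RoI tiling** (`tile_rois`): the homogeneous calibration region is cut
   into non-overlapping 5×5-pixel tiles (partial edge tiles discarded);
   each tile becomes one sample, so a single 1088×2048 frame yields up to
   88,753 samples.
2. **Outlier cleaning** (`iqr_clean`): per tile and per band, values
   outside the Tukey fence $[Q_1 - 1.5\,\mathrm{IQR},\; Q_3 +
   1.5\,\mathrm{IQR}]$ are dropped. The 1.5 factor is the conventional
   fence; the cleaning axis (per band within each RoI) is a documented
   choice, applied exactly once — the fence is computed from the original
   tile, never iterated.
3. **Median aggregation** (`roi_median_spectrum`): the tile collapses to
   its per-band median of surviving pixels.
4. **Balancing** (`balance_table`): calibration campaigns oversample some
   points (anoxic and air-saturated oxygen above all). Each
   over-represented point — identified by its label pair after rounding pH
   to 0.1 and pO$_2$ to 1 hPa — is reduced to the median per-point count by
   partitioning its rows, in stored order, into that many contiguous
   chunks and averaging each chunk per band. Averaging (rather than
   subsampling) preserves information while removing the count bias, and
   the stored-order partition makes the operation deterministic without a
   seed. An even number of groups can make the median count half-integral;
   it is rounded to the nearest integer.

`split_table` then draws a seeded random 80:20 train/validation partition.
Dimension reduction (PCA and relatives) is intentionally absent: outlier
removal plus median aggregation preserves band-level information the
regressors exploit.

## The three-layer cascade

The calibration model (`train_cascade`) is a stack of three XGBoost
regressors on the *absolute* spectra (not ratios against the reference
dye — in this design the absolute intensities carried slightly more usable
signal):

1. **Layer 1** — pH from the 144-band spectrum
   (250 trees, depth 9, `min_child_weight` 3, learning rate 0.05);
2. **Layer 2** — pO$_2$ from the spectrum ⊕ the *predicted* pH
   (250 trees, depth 7, `min_child_weight` 5, learning rate 0.05);
3. **Layer 3** — pO$_2$ again, from the spectrum ⊕ predicted pH ⊕ layer 2's
   pO$_2$ — a single stacked refinement pass with the layer-2
   configuration.

pH is predicted first because the coupled spectrum is more sensitive to
oxygen than to pH; giving the oxygen layers explicit conditional knowledge
of pH lets them separate quenching from reabsorption. "Iterative"
refinement is realized as exactly one extra pass: that reproduces the
three-layer structure while keeping training cost linear.

**Conditioning choice.** During training, the pH (and pO$_2$) values fed
to later layers are out-of-fold predictions from an internal 5-fold split:
each training row's conditioning feature comes from boosters that never
saw that row. Conditioning on in-sample predictions (or labels) would give
later layers an optimistically accurate feature that is unavailable at
inference. `conditioning = "label"` is provided for comparison with
label-conditioned variants of the scheme.

Degenerate inputs: a single-valued target trains a constant predictor with
a warning rather than failing. All boosters run single-threaded with fixed
seeds, so training and prediction are bit-reproducible.

**Dynamic range.** The pH sensing layer only responds within $pK_a \pm 2$,
i.e. pH 5--9. `predict_samples` flags predictions outside that interval as
invalid — they are reported but marked not physically meaningful — and
`predict_image` propagates the flag into the chemical image's validity
mask (NaN in numeric exports, a sentinel color in previews).

## Model screening and tuning

`model_selection` reproduces the nine-family comparison that motivated the
choice of gradient boosting: linear, lasso, ridge, logistic, random
forest, support-vector, k-nearest-neighbors, decision-tree and XGBoost
regression, each fitted per analyte on raw spectra and scored by training
and validation MAE/RMSE. Two quirks are intentional:

* "logistic regression" on a continuous target is ill-posed; it is
  implemented as a multinomial classifier on integer-rounded targets and
  scored as a regressor, kept only as a diagnostic baseline (it performs
  terribly, as expected);
* the decision tree is unconstrained (`cp = 0`, `minsplit = 2`), so it
  memorizes duplicate-free training data exactly — training error 0 with
  much worse validation error, the classic overfitting signature.

`hpo_sweep` tunes one booster by exhaustive grid enumeration or seeded
random search, selecting by validation MAE with ties broken by validation
RMSE and then evaluation order, and returns the full trace.

## Validation

`mae` and `rmse` follow their standard definitions; `kfold_cv` performs
k-fold cross-validation (default 10) with folds of size
$\lfloor N/k \rfloor$ or $\lceil N/k \rceil$, every row validated exactly
once and excluded from its fold's training set. Per-fold MAE/RMSE are
recorded for the three outputs (pH, first-pass pO$_2$, refined pO$_2$);
the aggregate is the unweighted mean over folds. The interesting
comparison is layer 3 against layer 2: the refinement pass should not
degrade — and typically improves — the oxygen error, since it can correct
reabsorption-driven outliers of the first pass.

## Problem sizes used in the shipped checks

The package's own verification runs entirely on simulated data, at sizes
chosen to exercise the method honestly on a single CPU:

* recovery grids: pH 4--11 in 0.5 steps × pO$_2$ 0--195 hPa in 15 hPa
  steps, 25 samples per point (5250 samples), once noiseless and once at
  the default noise;
* 10-fold CV: pH 5--9 in 0.5 steps × six oxygen points × 8 samples
  (432 samples) at default noise;
* model screening: pH 4--11 × six oxygen points × 8 samples
  (384 samples).

On the noiseless grid the held-out samples are exact duplicates of
training conditions, so near-zero error is the correct expectation — that
check validates the plumbing, not generalization. The noisy grid and the
cross-validated refinement are the substantive checks. Note that pH error
concentrates at the range extremes (pH ≲ 5 and ≳ 10) where the Boltzmann
response saturates and neighboring pH values become spectrally almost
indistinguishable; this mirrors the behavior of the real sensor, whose
dynamic range ends at $pK_a \pm 2$.

## Known limitations

* The balancing partition ("average larger groups of pixels") is one
  admissible deterministic reading of a loosely specified operation;
  different groupings yield slightly different balanced sets.
* The cascade's accuracy on real data depends on calibration coverage;
  the simulator cannot substitute for a real calibration campaign.
* Cross-validation on small tables has high fold-to-fold variance; the
  layer-3 vs layer-2 comparison is directional, not a fixed effect size.
* ENVI I/O supports the BSQ/float32 dialect the pipeline writes; exotic
  vendor variants (BIL/BIP interleaves, other dtypes) are rejected rather
  than guessed.
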