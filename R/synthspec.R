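#' Physical parameters of the dual-analyte optode forward model
#'
#' Collects every constant of the spectral simulator: the Boltzmann pH
#' response of the indicator (apparent pKa and slope), four Gaussian
#' emission bands (acid and base forms of the pH indicator, the
#' analyte-insensitive reference dye, and the NIR oxygen phosphor), the
#' simplified Stern--Volmer quenching constant, two inner-filter
#' (reabsorption) cross-talk coefficients coupling the two sensor layers,
#' and the additive per-band noise level.
#'
#' Defaults emulate a two-layer pH/O2 optode read out between 470 and
#' 900 nm: acid band at 490 nm, base band at 548 nm, reference dye at
#' 535 nm, oxygen phosphor at 770 nm. The acid-band amplitude is fixed so
#' that the pure acid and base emission curves intersect at 530 nm, the
#' isosbestic point of the pH indicator. `pKa = 7` puts the usable dynamic
#' range (pKa +/- 2) at pH 5--9. `K_SV = 0.02` per hPa quenches the
#' phosphor to ~20% of its unquenched intensity at air saturation
#' (195 hPa). Cross-talk: a fraction `crosstalk_acid` of the acid-form
#' emission is reabsorbed by the (unquenched) oxygen layer, strongest
#' under anoxia; a fraction `crosstalk_ref` of the reference emission is
#' reabsorbed by the base form of the pH indicator.
#'
#' @param pKa Apparent pKa of the pH indicator (pH units).
#' @param boltzmann_slope Slope of the base-10 sigmoid (pH units); != 0.
#' @param acid_band,base_band,ref_band Numeric `c(center, width, amplitude)`
#'   (nm, nm, a.u.) of the Gaussian emission bands. `acid_band` amplitude
#'   `NA` (default) means "derive from `base_band` so the curves cross at
#'   `isosbestic` nm".
#' @param o2_band Numeric `c(center, width, I0)` for the oxygen phosphor;
#'   `I0` is the unquenched amplitude.
#' @param K_SV Stern--Volmer quenching constant (1/hPa); >= 0.
#' @param crosstalk_acid,crosstalk_ref Reabsorption fractions in [0, 1].
#' @param noise_sd Additive Gaussian noise sd per band (a.u.).
#' @param isosbestic Wavelength (nm) at which acid and base bands are tied.
#' @return An object of class `spectral_model_params`.
#' @examples
#' p <- spectral_model_params()
#' p$acid_band[["amplitude"]] # ~3.0, ties the isosbestic point to 530 nm
#' @export
spectral_model_params <- function(pKa = 7.0,
                                  boltzmann_slope = 1.0,
                                  acid_band = c(490, 25, NA),
                                  base_band = c(548, 30, 1.0),
                                  ref_band = c(535, 28, 0.8),
                                  o2_band = c(770, 20, 1.2),
                                  K_SV = 0.02,
                                  crosstalk_acid = 0.3,
                                  crosstalk_ref = 0.15,
                                  noise_sd = 0.02,
                                  isosbestic = 530) {
  band <- function(x, nm) {
    stopifnot(length(x) == 3)
    x <- as.numeric(x)
    names(x) <- c("center", "width", "amplitude")
    x
  }
  acid_band <- band(acid_band); base_band <- band(base_band)
  ref_band <- band(ref_band); o2_band <- band(o2_band)
  if (is.na(acid_band[["amplitude"]])) {
    # A_acid * G_acid(iso) == A_base * G_base(iso)
    acid_band[["amplitude"]] <- base_band[["amplitude"]] *
      gauss_shape(isosbestic, base_band) / gauss_shape(isosbestic, acid_band)
  }
  p <- structure(list(pKa = pKa, boltzmann_slope = boltzmann_slope,
                      acid_band = acid_band, base_band = base_band,
                      ref_band = ref_band, o2_band = o2_band,
                      K_SV = K_SV,
                      crosstalk_acid = crosstalk_acid,
                      crosstalk_ref = crosstalk_ref,
                      noise_sd = noise_sd,
                      isosbestic = isosbestic),
                 class = "spectral_model_params")
  validate_params(p)
  p
}

validate_params <- function(p) {
  bands <- list(p$acid_band, p$base_band, p$ref_band, p$o2_band)
  if (any(vapply(bands, function(b) b[["width"]] <= 0, logical(1))))
    stop("all band widths must be > 0", call. = FALSE)
  if (any(vapply(bands, function(b) b[["amplitude"]] < 0, logical(1))))
    stop("all band amplitudes must be >= 0", call. = FALSE)
  if (p$K_SV < 0) stop("K_SV must be >= 0", call. = FALSE)
  if (p$boltzmann_slope == 0)
    stop("boltzmann_slope must be nonzero", call. = FALSE)
  for (ct in c("crosstalk_acid", "crosstalk_ref")) {
    if (p[[ct]] < 0 || p[[ct]] > 1)
      stop(ct, " must lie in [0, 1]", call. = FALSE)
  }
  if (p$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  invisible(p)
}

# Unit-amplitude Gaussian band profile on wavelengths `wl`.
gauss_shape <- function(wl, band) {
  exp(-(wl - band[["center"]])^2 / (2 * band[["width"]]^2))
}

#' Fraction of the pH indicator in its base form
#'
#' Base-10 Boltzmann sigmoid `f = 1 / (1 + 10^((pKa - ph) / slope))`:
#' the standard sigmoidal calibration model of a pH indicator centered at
#' its apparent pKa. `f = 0.5` at `ph = pKa`; limits are 0 (fully acidic)
#' and 1 (fully basic); monotone increasing in pH for positive slope.
#'
#' @param ph pH value(s).
#' @param pKa Apparent pKa (pH units).
#' @param slope Sigmoid slope (pH units); must be nonzero.
#' @return Base-form fraction(s) in [0, 1], vectorized over `ph`.
#' @examples
#' boltzmann_fraction(7, 7, 1)    # 0.5
#' boltzmann_fraction(8, 7, 1)    # 10/11
#' @export
boltzmann_fraction <- function(ph, pKa, slope) {
  if (!is.numeric(slope) || length(slope) != 1 || slope == 0)
    stop("boltzmann_fraction: `slope` must be a single nonzero number",
         call. = FALSE)
  stopifnot(is.numeric(ph), is.numeric(pKa))
  1 / (1 + 10^((pKa - ph) / slope))
}

#' Quenched phosphorescence intensity (simplified Stern--Volmer)
#'
#' `I = I0 / (1 + K_SV * pO2)`: emission intensity of an oxygen-quenched
#' phosphor as a function of oxygen partial pressure. At `po2 = 0` the
#' unquenched intensity `I0` is recovered; for `K_SV > 0` the intensity is
#' strictly decreasing in pO2.
#'
#' @param I0 Unquenched intensity (a.u.); >= 0.
#' @param K_SV Stern--Volmer constant (1/hPa); >= 0.
#' @param po2 Oxygen partial pressure(s) in hPa; >= 0.
#' @return Quenched intensity, vectorized over `po2`.
#' @examples
#' stern_volmer_intensity(1, 0.01, 100) # 0.5
#' @export
stern_volmer_intensity <- function(I0, K_SV, po2) {
  if (!is.numeric(I0) || any(I0 < 0))
    stop("stern_volmer_intensity: `I0` must be >= 0", call. = FALSE)
  if (!is.numeric(K_SV) || any(K_SV < 0))
    stop("stern_volmer_intensity: `K_SV` must be >= 0", call. = FALSE)
  if (!is.numeric(po2) || any(po2 < 0))
    stop("stern_volmer_intensity: `po2` must be >= 0", call. = FALSE)
  I0 / (1 + K_SV * po2)
}

#' Noiseless emission spectrum of the dual-analyte optode
#'
#' Forward model of the coupled two-layer sensor. With base-form fraction
#' `f = boltzmann_fraction(ph, pKa, slope)` and oxygen-layer absorption
#' saturation `g(po2) = 1 / (1 + K_SV * po2)` (the same saturation law as
#' the quenching), the spectrum on the band grid is the sum of
#' \itemize{
#'   \item acid form: `(1 - f) * A_acid * (1 - crosstalk_acid * g(po2)) *
#'     G_acid` --- short-wavelength emission, partially reabsorbed by the
#'     oxygen layer, most strongly under anoxia (inner-filter effect);
#'   \item base form: `f * A_base * G_base`;
#'   \item reference dye: `A_ref * (1 - crosstalk_ref * f) * G_ref` ---
#'     partially reabsorbed by the base form at high pH;
#'   \item oxygen phosphor: `stern_volmer_intensity(I0, K_SV, po2) * G_o2`.
#' }
#' where each `G` is a unit Gaussian band profile. The cross-talk terms
#' reproduce the qualitative failure of naive single-analyte Boltzmann /
#' Stern--Volmer calibration on such a sensor.
#'
#' @param ph pH (scalar).
#' @param po2 Oxygen partial pressure in hPa (scalar, >= 0).
#' @param params A [spectral_model_params()] object.
#' @param grid A [wavelength_grid()] (or numeric wavelength vector).
#' @return Numeric vector of intensities (a.u.), one per band; all >= 0.
#' @examples
#' s <- emit_spectrum(7, 100, spectral_model_params(), wavelength_grid())
#' @export
emit_spectrum <- function(ph, po2, params = spectral_model_params(),
                          grid = wavelength_grid()) {
  stopifnot(inherits(params, "spectral_model_params"),
            length(ph) == 1, length(po2) == 1, is.finite(ph))
  if (po2 < 0) stop("emit_spectrum: `po2` must be >= 0", call. = FALSE)
  wl <- grid_values(grid)
  f <- boltzmann_fraction(ph, params$pKa, params$boltzmann_slope)
  g <- 1 / (1 + params$K_SV * po2)
  acid <- (1 - f) * params$acid_band[["amplitude"]] *
    (1 - params$crosstalk_acid * g) * gauss_shape(wl, params$acid_band)
  base <- f * params$base_band[["amplitude"]] * gauss_shape(wl, params$base_band)
  ref <- params$ref_band[["amplitude"]] * (1 - params$crosstalk_ref * f) *
    gauss_shape(wl, params$ref_band)
  o2 <- stern_volmer_intensity(params$o2_band[["amplitude"]], params$K_SV, po2) *
    gauss_shape(wl, params$o2_band)
  acid + base + ref + o2
}

#' Simulate one calibration cube at a fixed (pH, pO2) condition
#'
#' Every pixel is the noiseless [emit_spectrum()] plus i.i.d. additive
#' Gaussian noise (sd `params$noise_sd`), clipped at zero. Stands in for a
#' single calibration image acquisition of a homogeneous optode.
#'
#' @param ph,po2 Calibration condition.
#' @param params,grid Forward-model parameters and band grid.
#' @param shape `c(H, W)` in pixels; both >= 5 (one RoI tile minimum).
#' @param seed Integer seed; the cube is bit-reproducible given the seed.
#' @return A [spectral_cube()] whose `metadata` records `ph`, `po2`, `seed`.
#' @export
generate_calibration_cube <- function(ph, po2,
                                      params = spectral_model_params(),
                                      grid = wavelength_grid(),
                                      shape = c(25, 25), seed = 1) {
  stopifnot(length(shape) == 2)
  h <- as.integer(shape[1]); w <- as.integer(shape[2])
  if (h < 5 || w < 5)
    stop("generate_calibration_cube: shape must be at least 5x5 (one RoI tile)",
         call. = FALSE)
  wl <- grid_values(grid)
  s <- emit_spectrum(ph, po2, params, wl)
  b <- length(wl)
  data <- array(rep(s, each = h * w), dim = c(h, w, b))
  if (params$noise_sd > 0) {
    noise <- withr::with_seed(seed,
      array(stats::rnorm(h * w * b, sd = params$noise_sd), dim = c(h, w, b)))
    data <- pmax(data + noise, 0)
  }
  spectral_cube(data, wl,
                metadata = list(ph = ph, po2 = po2, seed = seed))
}

#' Per-calibration-point sample budgets, balanced or imbalanced
#'
#' Lays out a calibration design over the cross product of pH and pO2
#' points. The `"imbalanced"` preset reproduces the skew of a real optode
#' calibration campaign, where anoxic (0 hPa) and air-saturated (195 hPa)
#' oxygen conditions dominate the dataset: those two oxygen points get 8x
#' and 6x the base budget, and the near-neutral pH points get 2x.
#'
#' @param ph_points,po2_points Calibration grid values.
#' @param base Per-point base sample count.
#' @param preset `"balanced"` (all points = `base`) or `"imbalanced"`.
#' @return Data frame with columns `ph`, `po2`, `count`.
#' @export
calibration_design <- function(ph_points = seq(4, 11, by = 1),
                               po2_points = c(0, 5, 10, 20, 50, 100, 150, 195),
                               base = 25,
                               preset = c("balanced", "imbalanced")) {
  preset <- match.arg(preset)
  d <- expand.grid(ph = ph_points, po2 = po2_points,
                   KEEP.OUT.ATTRS = FALSE)
  d$count <- rep.int(base, nrow(d))
  if (preset == "imbalanced") {
    d$count[d$po2 == 0] <- 8L * base
    d$count[d$po2 == max(po2_points)] <- 6L * base
    mid <- abs(d$ph - stats::median(ph_points)) <= 1
    d$count[mid] <- d$count[mid] * 2L
  }
  d
}

#' Simulate a labeled calibration table
#'
#' Draws `count` noisy spectra (rows) for every calibration point of a
#' design, emulating per-RoI samples extracted from calibration images.
#'
#' @param design Data frame `(ph, po2, count)`, e.g. from
#'   [calibration_design()]; or `NULL` to build one from `ph_points`,
#'   `po2_points` and `counts`.
#' @param ph_points,po2_points,counts Convenience alternative to `design`:
#'   the cross product of the point vectors, each with budget `counts`
#'   (scalar, recycled).
#' @param params,grid Forward model.
#' @param seed Integer seed; table is reproducible.
#' @return A [calibration_table()] with provenance `"sim:<i>"`.
#' @export
generate_calibration_set <- function(design = NULL,
                                     ph_points = NULL, po2_points = NULL,
                                     counts = 25,
                                     params = spectral_model_params(),
                                     grid = wavelength_grid(),
                                     seed = 1) {
  if (is.null(design)) {
    stopifnot(!is.null(ph_points), !is.null(po2_points))
    design <- expand.grid(ph = ph_points, po2 = po2_points,
                          KEEP.OUT.ATTRS = FALSE)
    design$count <- rep_len(counts, nrow(design))
  }
  stopifnot(all(c("ph", "po2", "count") %in% names(design)))
  if (sum(design$count) == 0) {
    warning("generate_calibration_set: zero total budget, empty table")
    return(calibration_table(matrix(numeric(0), 0, length(grid_values(grid))),
                             ph = numeric(0), po2 = numeric(0),
                             wavelengths = grid_values(grid)))
  }
  wl <- grid_values(grid)
  n <- sum(design$count)
  withr::with_seed(seed, {
    spectra <- matrix(NA_real_, n, length(wl))
    ph <- numeric(n); po2 <- numeric(n)
    at <- 0L
    for (i in seq_len(nrow(design))) {
      k <- design$count[i]
      if (k == 0) next
      s <- emit_spectrum(design$ph[i], design$po2[i], params, wl)
      block <- matrix(rep(s, each = k), k, length(wl)) +
        matrix(stats::rnorm(k * length(wl), sd = params$noise_sd),
               k, length(wl))
      spectra[at + seq_len(k), ] <- pmax(block, 0)
      ph[at + seq_len(k)] <- design$ph[i]
      po2[at + seq_len(k)] <- design$po2[i]
      at <- at + k
    }
    calibration_table(spectra, ph = ph, po2 = po2, wavelengths = wl,
                      provenance = paste0("sim:", seq_len(n)))
  })
}

#' Simulate a scene with spatial analyte gradients
#'
#' Builds a hyperspectral cube whose pixel (r, c) is the forward-model
#' spectrum at `ph_field[r, c]` and `po2_field[r, c]` plus noise, together
#' with the pixel-aligned ground-truth chemical image. Used to exercise
#' chemical-image prediction against known truth.
#'
#' @param height,width Scene size in pixels.
#' @param ph_field,po2_field Matrices `height x width`, or scalars
#'   (constant fields). `po2_field` must be >= 0 everywhere.
#' @param params,grid Forward model.
#' @param seed Integer seed.
#' @return `list(cube = spectral_cube, truth = chemical_image)`.
#' @export
generate_gradient_scene <- function(height, width,
                                    ph_field, po2_field,
                                    params = spectral_model_params(),
                                    grid = wavelength_grid(),
                                    seed = 1) {
  expand_field <- function(x, what) {
    if (length(x) == 1) x <- matrix(x, height, width)
    if (!is.matrix(x) || !all(dim(x) == c(height, width)))
      stop("generate_gradient_scene: `", what, "` must be a scalar or a ",
           height, "x", width, " matrix", call. = FALSE)
    x
  }
  ph_field <- expand_field(ph_field, "ph_field")
  po2_field <- expand_field(po2_field, "po2_field")
  if (any(!is.finite(ph_field))) stop("pH field must be finite", call. = FALSE)
  if (any(po2_field < 0)) stop("pO2 field must be >= 0", call. = FALSE)
  wl <- grid_values(grid)
  b <- length(wl)
  # spectra for the distinct (ph, po2) pairs only; scenes are often ramps
  key <- paste(ph_field, po2_field)
  uk <- !duplicated(key)
  spec_lut <- matrix(NA_real_, sum(uk), b)
  uph <- ph_field[uk]; upo2 <- po2_field[uk]
  for (i in seq_along(uph)) {
    spec_lut[i, ] <- emit_spectrum(uph[i], upo2[i], params, wl)
  }
  idx <- match(key, key[uk])
  flat <- spec_lut[idx, , drop = FALSE]          # (H*W) x B, column-major pixels
  if (params$noise_sd > 0) {
    flat <- withr::with_seed(seed, {
      pmax(flat + matrix(stats::rnorm(length(flat), sd = params$noise_sd),
                         nrow(flat), b), 0)
    })
  }
  data <- array(flat, dim = c(height, width, b))
  cube <- spectral_cube(data, wl, metadata = list(scene = "gradient", seed = seed))
  truth <- chemical_image(ph_map = ph_field, po2_map = po2_field,
                          valid_mask = ph_field >= 5 & ph_field <= 9,
                          provenance = "ground-truth")
  list(cube = cube, truth = truth)
}
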