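test_that("boltzmann fraction has sigmoid midpoint, limits and monotonicity", {
  expect_equal(boltzmann_fraction(7, 7, 1), 0.5)
  expect_equal(boltzmann_fraction(8, 7, 1), 10 / 11)
  expect_equal(boltzmann_fraction(-1e6, 7, 1), 0)
  expect_equal(boltzmann_fraction(1e6, 7, 1), 1)
  ph <- seq(0, 14, 0.25)
  expect_true(all(diff(boltzmann_fraction(ph, 7, 1)) > 0))
  expect_error(boltzmann_fraction(7, 7, 0), "nonzero")
})

test_that("stern-volmer quenching matches the closed form and rejects bad input", {
  expect_equal(stern_volmer_intensity(3.2, 0.01, 0), 3.2)
  expect_equal(stern_volmer_intensity(1, 0.01, 100), 0.5)
  expect_equal(stern_volmer_intensity(2, 0, 1e5), 2)
  po2 <- seq(0, 300, 10)
  expect_true(all(diff(stern_volmer_intensity(1, 0.02, po2)) < 0))
  expect_error(stern_volmer_intensity(-1, 0.01, 0), ">= 0")
  expect_error(stern_volmer_intensity(1, -0.01, 0), ">= 0")
  expect_error(stern_volmer_intensity(1, 0.01, -5), ">= 0")
})

test_that("default wavelength grid has 144 bands from 470 to 899 nm", {
  g <- wavelength_grid()
  expect_length(g$values, 144)
  expect_equal(g$values[1], 470)
  expect_equal(max(g$values), 899)
  expect_true(all(diff(g$values) == 3))
  expect_error(wavelength_grid(step = 0), "step")
})

test_that("emission spectra are nonnegative and O2-band intensity is strictly
          decreasing in pO2 at every pH", {
  p <- spectral_model_params()
  g <- wavelength_grid()
  i770 <- which(g$values == 770)
  for (ph in seq(4, 11, length.out = 10)) {
    v <- vapply(seq(0, 195, length.out = 10),
                function(o) {
                  s <- emit_spectrum(ph, o, p, g)
                  expect_true(all(s >= 0))
                  s[i770]
                }, numeric(1))
    expect_true(all(diff(v) < 0))
  }
})

test_that("O2 band peak is unquenched at anoxia and halves when K_SV*pO2 = 1", {
  g <- wavelength_grid()
  i770 <- which(g$values == 770)
  p <- spectral_model_params(o2_band = c(770, 20, 1.0), K_SV = 0.01)
  s0 <- emit_spectrum(7, 0, p, g)
  s100 <- emit_spectrum(7, 100, p, g)
  # other bands are negligible at 770 nm, so the ratio is the SV factor
  expect_equal(s100[i770] / s0[i770], 0.5, tolerance = 1e-9)
  # unquenched limit equals the pO2 -> 0 maximum
  expect_equal(s0[i770], max(vapply(c(0, 1, 10, 100),
    function(o) emit_spectrum(7, o, p, g)[i770], numeric(1))))
})

test_that("pH-dependent spectra share a common crossing near the 530 nm
          isosbestic point", {
  p <- spectral_model_params()
  g <- wavelength_grid()
  wl <- g$values
  ph_set <- 4:11
  spectra <- vapply(ph_set, function(ph) emit_spectrum(ph, 0, p, g),
                    numeric(length(wl)))
  ref <- spectra[, 1]
  for (j in 2:length(ph_set)) {
    d <- spectra[, j] - ref
    # consider only wavelengths where the signal is substantial, to skip
    # float-noise sign flips in the dark NIR tails
    live <- which(pmax(spectra[, j], ref) > 0.05 * max(spectra))
    sign_change <- live[which(diff(sign(d[live])) != 0)]
    expect_true(length(sign_change) >= 1)
    crossing <- wl[sign_change[1]]
    expect_lte(abs(crossing - 530), 6)
  }
})

test_that("with cross-talk off, band-integrated intensities match the
          Boltzmann / Stern-Volmer closed forms", {
  p <- spectral_model_params(crosstalk_acid = 0, crosstalk_ref = 0,
                             noise_sd = 0)
  # fine grid wide enough that each Gaussian band integrates to ~width*sqrt(2pi)
  g <- wavelength_grid(300, 1100, 0.5)
  wl <- g$values
  gauss_int <- function(center, width, amp) {
    sum(amp * exp(-(wl - center)^2 / (2 * width^2))) * 0.5
  }
  for (ph in c(5, 7, 9)) {
    for (po2 in c(0, 50, 195)) {
      s <- emit_spectrum(ph, po2, p, g)
      f <- boltzmann_fraction(ph, p$pKa, p$boltzmann_slope)
      expected <- (1 - f) * gauss_int(490, 25, p$acid_band[["amplitude"]]) +
        f * gauss_int(548, 30, 1.0) +
        gauss_int(535, 28, 0.8) +
        gauss_int(770, 20, stern_volmer_intensity(1.2, p$K_SV, po2))
      expect_equal(sum(s) * 0.5, expected, tolerance = 1e-9)
    }
  }
})

test_that("calibration cubes are reproducible, noise-free when asked, and
          carry the requested noise level", {
  g <- small_grid()
  p0 <- spectral_model_params(noise_sd = 0)
  cube <- generate_calibration_cube(6, 50, p0, g, shape = c(5, 6), seed = 4)
  s <- emit_spectrum(6, 50, p0, g)
  expect_true(all(apply(cube$data, c(1, 2), function(px) identical(px, s))))
  expect_equal(cube$metadata$ph, 6)

  p <- spectral_model_params(noise_sd = 0.05)
  c1 <- generate_calibration_cube(7, 0, p, g, shape = c(50, 50), seed = 9)
  c2 <- generate_calibration_cube(7, 0, p, g, shape = c(50, 50), seed = 9)
  expect_identical(c1$data, c2$data)
  # per-band empirical sd ~ noise_sd (bands with signal >> 0, no clipping)
  strong <- which(emit_spectrum(7, 0, p, g) > 0.5)
  sds <- apply(c1$data[, , strong], 3, stats::sd)
  expect_true(all(abs(sds - 0.05) / 0.05 < 0.1))
  expect_error(generate_calibration_cube(7, 0, p, g, shape = c(4, 9)), "5x5")
})

test_that("calibration set generation honors budgets, determinism and the
          imbalanced preset", {
  tab <- generate_calibration_set(ph_points = 7, po2_points = 0, counts = 10,
                                  grid = small_grid(), seed = 1)
  expect_equal(nrow(tab), 10)
  expect_true(all(tab$ph == 7) && all(tab$po2 == 0))

  tab2 <- generate_calibration_set(ph_points = 7, po2_points = 0, counts = 10,
                                   grid = small_grid(), seed = 1)
  expect_identical(as.data.frame(tab), as.data.frame(tab2))

  expect_warning(
    empty <- generate_calibration_set(
      design = data.frame(ph = 7, po2 = 0, count = 0), grid = small_grid()),
    "zero")
  expect_equal(nrow(empty), 0)

  d <- calibration_design(preset = "imbalanced")
  counts_anoxic <- d$count[d$po2 == 0]
  expect_true(all(counts_anoxic > median(d$count)))
  counts_airsat <- d$count[d$po2 == 195]
  expect_true(all(counts_airsat > median(d$count)))
})

test_that("gradient scenes align ground truth with the cube and reduce to the
          calibration cube for constant fields", {
  g <- small_grid()
  p <- spectral_model_params(noise_sd = 0.02)
  sc <- generate_gradient_scene(6, 8, ph_field = 7, po2_field = 50,
                                params = p, grid = g, seed = 5)
  cube <- generate_calibration_cube(7, 50, p, g, shape = c(6, 8), seed = 5)
  expect_identical(sc$cube$data, cube$data)

  ramp <- matrix(rep(seq(5, 9, length.out = 8), each = 6), 6, 8)
  sc2 <- generate_gradient_scene(6, 8, ramp, 50, params = p, grid = g, seed = 2)
  expect_identical(sc2$truth$ph_map, ramp)
  expect_identical(dim(sc2$cube$data)[1:2], dim(sc2$truth$ph_map))
  sc3 <- generate_gradient_scene(6, 8, ramp, 50, params = p, grid = g, seed = 2)
  expect_identical(sc3$cube$data, sc2$cube$data)
  expect_error(generate_gradient_scene(6, 8, matrix(7, 3, 3), 50,
                                       params = p, grid = g), "matrix")
})

test_that("parameter validation rejects nonphysical simulator settings", {
  expect_error(spectral_model_params(acid_band = c(490, -1, 1)), "width")
  expect_error(spectral_model_params(K_SV = -0.1), "K_SV")
  expect_error(spectral_model_params(crosstalk_acid = 1.5), "crosstalk_acid")
  expect_error(spectral_model_params(boltzmann_slope = 0), "nonzero")
  expect_error(spectral_model_params(noise_sd = -1), "noise_sd")
})
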