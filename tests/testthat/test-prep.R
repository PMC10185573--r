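test_that("tile grids discard partial edge tiles and count correctly", {
  expect_equal(nrow(tile_grid(1088, 2048, tile = 5)), 217 * 409)
  expect_equal(nrow(tile_grid(5, 5, tile = 5)), 1)
  expect_equal(nrow(tile_grid(9, 9, tile = 5)), 1)
  expect_equal(nrow(tile_grid(10, 14, tile = 5)), 2 * 2)
  expect_error(tile_grid(4, 9, tile = 5), "smaller than one")
  expect_error(tile_grid(20, 20, region = c(10, 10, 15, 5)), "exceeds")
})

test_that("RoI tiling is non-overlapping and covers the aligned sub-grid", {
  cube <- generate_calibration_cube(7, 0, spectral_model_params(noise_sd = 0),
                                    small_grid(), shape = c(12, 11), seed = 1)
  rois <- tile_rois(cube, tile = 5)
  expect_length(rois, 2 * 2)
  origins <- t(vapply(rois, function(r) r$origin, numeric(2)))
  expect_equal(nrow(unique(origins)), 4)
  expect_true(all(origins[, 1] %in% c(1, 6) & origins[, 2] %in% c(1, 6)))
  expect_equal(dim(rois[[1]]$spectra), c(25, length(small_grid()$values)))
})

test_that("IQR cleaning matches a brute-force Tukey fence on random vectors", {
  brute <- function(v, f = 1.5) {
    q1 <- as.numeric(quantile(v, 0.25)); q3 <- as.numeric(quantile(v, 0.75))
    v[v >= q1 - f * (q3 - q1) & v <= q3 + f * (q3 - q1)]
  }
  withr::with_seed(42, {
    for (i in 1:1000) {
      n <- sample(4:30, 1)
      v <- rnorm(n, sd = sample(c(0.1, 1, 10), 1))
      if (i %% 7 == 0) v[1] <- v[1] + 100   # plant an outlier
      expect_identical(iqr_clean(v), brute(v))
    }
  })
  expect_identical(iqr_clean(rep(2, 8)), rep(2, 8))     # IQR = 0, fence kept
  expect_identical(iqr_clean(c(1, 1, 1, 1, 100)), rep(1, 4))
  expect_warning(out <- iqr_clean(c(1, 2, 3)), "fewer than 4")
  expect_identical(out, c(1, 2, 3))
})

test_that("survivors always lie inside the fence of the original input", {
  withr::with_seed(7, {
    for (i in 1:200) {
      v <- rcauchy(sample(5:50, 1))   # heavy tails exercise the fence
      q <- quantile(v, c(0.25, 0.75), names = FALSE)
      s <- iqr_clean(v)
      expect_true(all(s >= q[1] - 1.5 * diff(q) & s <= q[2] + 1.5 * diff(q)))
      expect_true(all(s %in% v))
    }
  })
})

test_that("RoI median spectrum excludes outlier pixels before the median", {
  b <- 5
  base <- matrix(rep(seq_len(b), each = 25), 25, b)
  expect_equal(roi_median_spectrum(base), as.numeric(seq_len(b)))

  withr::with_seed(3, {
    noisy <- base + matrix(rnorm(25 * b, sd = 0.01), 25, b)
    spoiled <- noisy
    spoiled[13, 2] <- spoiled[13, 2] + 1   # +100 sigma at one band
    brute <- vapply(seq_len(b), function(j) {
      v <- spoiled[, j]
      q <- quantile(v, c(0.25, 0.75), names = FALSE)
      median(v[v >= q[1] - 1.5 * diff(q) & v <= q[2] + 1.5 * diff(q)])
    }, numeric(1))
    expect_equal(roi_median_spectrum(spoiled), brute)
    # the planted outlier must not survive into the median
    expect_lt(abs(roi_median_spectrum(spoiled)[2] - 2), 0.05)
  })

  # odd survivor count -> exact middle order statistic
  v <- matrix(c(1, 2, 3, 4, 5), 5, 1)
  expect_equal(roi_median_spectrum(v), 3)
})

test_that("extraction yields one cleaned-median row per RoI with labels", {
  p0 <- spectral_model_params(noise_sd = 0)
  g <- small_grid()
  cube <- generate_calibration_cube(6, 100, p0, g, shape = c(25, 25), seed = 1)
  tab <- extract_calibration_samples(cube, tile = 5)
  expect_equal(nrow(tab), 25)
  expect_true(all(tab$ph == 6) && all(tab$po2 == 100))
  s <- emit_spectrum(6, 100, p0, g)
  for (i in seq_len(nrow(tab))) {
    expect_equal(as.numeric(table_spectra(tab)[i, ]), s)
  }
  cube$metadata$ph <- NULL
  expect_error(extract_calibration_samples(cube), "labels")
})

test_that("balancing reduces over-represented points to the median count by
          contiguous-chunk averaging", {
  g <- small_grid()
  p0 <- spectral_model_params(noise_sd = 0)
  design <- data.frame(ph = c(7, 8, 9), po2 = c(0, 0, 0),
                       count = c(10, 10, 100))
  tab <- generate_calibration_set(design, params = p0, grid = g, seed = 1)
  out <- balance_table(tab)
  expect_equal(attr(out$report, "target"), 10)
  expect_equal(out$report$before, c(10, 10, 100))
  expect_equal(out$report$after, c(10, 10, 10))
  expect_equal(nrow(out$table), 30)
  # no group grew; labels preserved
  expect_true(all(out$report$after <= out$report$before))
  expect_setequal(unique(out$table$ph), c(7, 8, 9))

  # brute-force check of the chunk means for the reduced group
  big <- table_spectra(tab)[tab$ph == 9, , drop = FALSE]
  sizes <- rep(10, 10)          # 100 rows into 10 chunks of 10
  got <- table_spectra(out$table)[out$table$ph == 9, , drop = FALSE]
  at <- 0
  for (k in seq_along(sizes)) {
    expect_equal(as.numeric(got[k, ]),
                 unname(colMeans(big[at + seq_len(sizes[k]), , drop = FALSE])))
    at <- at + sizes[k]
  }

  # balanced input passes through unchanged
  design2 <- data.frame(ph = c(7, 8, 9), po2 = 0, count = 10)
  tab2 <- generate_calibration_set(design2, params = p0, grid = g, seed = 1)
  out2 <- balance_table(tab2)
  expect_equal(nrow(out2$table), nrow(tab2))
  expect_equal(table_spectra(out2$table), table_spectra(tab2))
  expect_error(balance_table(tab2[0, ]), "empty")
})

test_that("uneven groups are chunked into ceiling/floor sizes", {
  g <- small_grid()
  design <- data.frame(ph = c(5, 6, 7), po2 = 0, count = c(3, 3, 11))
  tab <- generate_calibration_set(design, grid = g, seed = 2,
                                  params = spectral_model_params(noise_sd = 0))
  out <- balance_table(tab)
  expect_equal(attr(out$report, "target"), 3)
  # 11 rows in 3 chunks: sizes 4, 4, 3
  big <- table_spectra(tab)[tab$ph == 7, , drop = FALSE]
  got <- table_spectra(out$table)[out$table$ph == 7, , drop = FALSE]
  expect_equal(nrow(got), 3)
  expect_equal(as.numeric(got[1, ]), unname(colMeans(big[1:4, , drop = FALSE])))
  expect_equal(as.numeric(got[2, ]), unname(colMeans(big[5:8, , drop = FALSE])))
  expect_equal(as.numeric(got[3, ]), unname(colMeans(big[9:11, , drop = FALSE])))
})

test_that("balancing tames the imbalanced preset to max/median <= 2", {
  tab <- generate_calibration_set(calibration_design(preset = "imbalanced",
                                                     base = 5),
                                  grid = small_grid(), seed = 4)
  out <- balance_table(tab)
  counts <- out$report$after
  expect_lte(max(counts) / median(counts), 2)
})

test_that("train/validation split is a seeded partition with round(ratio*N)
          training rows", {
  tab <- small_table(seed = 5, counts = 2)
  n <- nrow(tab)
  sp <- split_table(tab, ratio = 0.8, seed = 10)
  expect_equal(nrow(sp$train), round(0.8 * n))
  expect_equal(nrow(sp$train) + nrow(sp$validation), n)
  expect_length(intersect(sp$train$provenance, sp$validation$provenance), 0)
  expect_setequal(c(sp$train$provenance, sp$validation$provenance),
                  tab$provenance)
  sp2 <- split_table(tab, ratio = 0.8, seed = 10)
  expect_identical(as.data.frame(sp$train), as.data.frame(sp2$train))
  sp3 <- split_table(tab[1:4, ], ratio = 0.5, seed = 1)
  expect_equal(nrow(sp3$train), 2)
  expect_error(split_table(tab, ratio = 1.2), "between 0 and 1")
  expect_error(split_table(tab[1, ], 0.5), "at least 2")
})
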