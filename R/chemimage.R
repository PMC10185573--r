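#' Chemical image container
#'
#' The end product of the pipeline: pixel-wise maps of pH and oxygen
#' partial pressure plus a validity mask, all of identical shape. Pixels
#' outside the sensor's dynamic range are flagged in `valid_mask`; they
#' are never interpolated, and numeric export writes them as `NaN`.
#'
#' @param ph_map,po2_map Numeric `H x W` matrices (pH units / hPa).
#' @param valid_mask Logical `H x W` matrix.
#' @param provenance Free-form id of the model and cube that produced it.
#' @return Object of class `chemical_image`.
#' @export
chemical_image <- function(ph_map, po2_map, valid_mask,
                           provenance = NA_character_) {
  stopifnot(is.matrix(ph_map), is.matrix(po2_map),
            is.matrix(valid_mask) || is.logical(valid_mask))
  valid_mask <- matrix(as.logical(valid_mask), nrow(ph_map), ncol(ph_map))
  if (!identical(dim(ph_map), dim(po2_map)) ||
      !identical(dim(ph_map), dim(valid_mask)))
    stop("chemical_image: map shapes differ", call. = FALSE)
  structure(list(ph_map = ph_map, po2_map = po2_map,
                 valid_mask = valid_mask, provenance = provenance),
            class = "chemical_image")
}

#' @export
print.chemical_image <- function(x, ...) {
  cat(sprintf("<chemical_image> %d x %d px, %.1f%% valid; pH %.2f-%.2f, pO2 %.1f-%.1f hPa\n",
              nrow(x$ph_map), ncol(x$ph_map), 100 * mean(x$valid_mask),
              min(x$ph_map), max(x$ph_map), min(x$po2_map), max(x$po2_map)))
  invisible(x)
}

#' Convert a hyperspectral cube into a chemical image
#'
#' Applies the trained cascade to every pixel spectrum independently
#' (no spatial coupling or smoothing): the result at pixel (r, c) is
#' exactly [predict_samples()] applied to that pixel's spectrum, with the
#' pixels batched in row-major order. The validity mask applies the pH
#' 5--9 dynamic-range rule.
#'
#' @param model A [cascade_model()][train_cascade].
#' @param cube A [spectral_cube()] whose wavelength axis matches the
#'   model's.
#' @param ph_range Dynamic-range interval for the validity mask.
#' @param median_filter Optional odd window size for a per-map 2D median
#'   filter applied after prediction; `NULL` (default) disables it.
#' @return A [chemical_image()].
#' @export
predict_image <- function(model, cube, ph_range = c(5, 9),
                          median_filter = NULL) {
  stopifnot(inherits(model, "cascade_model"), inherits(cube, "spectral_cube"))
  if (!isTRUE(all.equal(model$wavelengths, cube$wavelengths)))
    stop("predict_image: wavelength axes differ.\n  model: ",
         paste(utils::head(model$wavelengths), collapse = ", "), " ... (",
         length(model$wavelengths), " bands)\n  cube:  ",
         paste(utils::head(cube$wavelengths), collapse = ", "), " ... (",
         length(cube$wavelengths), " bands)", call. = FALSE)
  d <- dim(cube$data)
  px <- cube_pixel_matrix(cube)              # row-major pixel order
  pred <- predict_samples(model, px, ph_range = ph_range)
  to_map <- function(v) matrix(v, d[1], d[2], byrow = TRUE)
  ph_map <- to_map(pred$ph)
  po2_map <- to_map(pred$po2_refined)
  if (!is.null(median_filter)) {
    ph_map <- median_filter_2d(ph_map, median_filter)
    po2_map <- median_filter_2d(po2_map, median_filter)
  }
  chemical_image(ph_map, po2_map,
                 valid_mask = to_map(pred$valid),
                 provenance = sprintf("cascade[%d bands] x cube[%dx%d]",
                                      length(model$wavelengths), d[1], d[2]))
}

# Simple k x k running median with edge replication; optional, off by
# default in predict_image.
median_filter_2d <- function(m, k) {
  stopifnot(k %% 2 == 1, k >= 1)
  if (k == 1) return(m)
  h <- nrow(m); w <- ncol(m); r <- (k - 1) / 2
  out <- m
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      out[i, j] <- stats::median(m[max(1, i - r):min(h, i + r),
                                   max(1, j - r):min(w, j + r)])
    }
  }
  out
}

#' Export a chemical image to disk
#'
#' Writes, per analyte: a lossless numeric array (`ph.csv`, `po2.csv`;
#' full-precision CSV, invalid pixels as `NaN`), an 8-bit false-color PNG
#' preview (`ph.png`, `po2.png`) rendered with a viridis-like ramp over
#' the requested color ranges, and a `maps.json` sidecar recording the
#' colorbar limits, image shape and the share of valid pixels. Invalid
#' pixels are rendered in a dedicated sentinel color (magenta), never
#' blended into the ramp.
#'
#' @param img A [chemical_image()].
#' @param outdir Output directory (created if needed).
#' @param ph_range,po2_range Colorbar limits, defaults pH 5--9 and
#'   0--195 hPa (anoxic to air-saturated).
#' @return Invisibly, the named vector of written paths.
#' @export
export_maps <- function(img, outdir, ph_range = c(5, 9),
                        po2_range = c(0, 195)) {
  stopifnot(inherits(img, "chemical_image"))
  ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir))
    stop("export_maps: cannot create output directory: ", outdir,
         call. = FALSE)
  write_map_csv <- function(m, path) {
    m[!img$valid_mask] <- NaN
    utils::write.table(format(m, digits = 17, trim = TRUE),
                       path, sep = ",", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
    path
  }
  paths <- c(
    ph_csv = write_map_csv(img$ph_map, file.path(outdir, "ph.csv")),
    po2_csv = write_map_csv(img$po2_map, file.path(outdir, "po2.csv")),
    ph_png = write_preview(img$ph_map, img$valid_mask, ph_range,
                           file.path(outdir, "ph.png")),
    po2_png = write_preview(img$po2_map, img$valid_mask, po2_range,
                            file.path(outdir, "po2.png")))
  meta <- list(shape = dim(img$ph_map),
               ph_range = ph_range, po2_range = po2_range,
               valid_fraction = mean(img$valid_mask),
               invalid_color = "#FF00FF",
               provenance = img$provenance)
  jsonlite::write_json(meta, file.path(outdir, "maps.json"),
                       auto_unbox = TRUE, digits = NA)
  paths["json"] <- file.path(outdir, "maps.json")
  invisible(paths)
}

#' Read back a numeric map written by [export_maps()]
#' @param path CSV path.
#' @return Numeric matrix (invalid pixels are `NaN`).
#' @export
read_map_csv <- function(path) {
  as.matrix(utils::read.table(path, sep = ",", header = FALSE,
                              colClasses = "numeric"))
}

# viridis-like 5-anchor ramp; magenta sentinel for invalid pixels
write_preview <- function(m, valid, range, path) {
  anchors <- t(grDevices::col2rgb(c("#440154", "#3B528B", "#21908C",
                                    "#5DC863", "#FDE725"))) / 255
  t01 <- pmin(pmax((m - range[1]) / (range[2] - range[1]), 0), 1)
  pos <- t01 * (nrow(anchors) - 1)
  lo <- floor(pos); frac <- pos - lo
  lo1 <- pmin(lo + 1, nrow(anchors)); hi1 <- pmin(lo + 2, nrow(anchors))
  rgb <- array(0, dim = c(nrow(m), ncol(m), 3))
  for (ch in 1:3) {
    v <- (1 - frac) * anchors[lo1, ch] + frac * anchors[hi1, ch]
    v <- matrix(v, nrow(m), ncol(m))
    sentinel <- c(1, 0, 1)[ch]
    v[!valid] <- sentinel
    rgb[, , ch] <- v
  }
  png::writePNG(rgb, path)
  path
}
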