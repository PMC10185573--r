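#' Tile-aligned RoI grid over a frame
#'
#' Pure geometry: origins of all non-overlapping `tile x tile` regions of
#' interest inside a (sub-)rectangle of the frame. Partial edge tiles are
#' discarded, so a `H x W` region yields `floor(H/tile) * floor(W/tile)`
#' tiles.
#'
#' @param height,width Frame size in pixels.
#' @param region Optional `c(row0, col0, nrow, ncol)` sub-rectangle
#'   (1-based origin); default is the full frame.
#' @param tile Tile side in pixels (default 5).
#' @return Data frame with 1-based columns `row`, `col` (tile origins).
#' @examples
#' nrow(tile_grid(1088, 2048)) # 88753
#' @export
tile_grid <- function(height, width, region = NULL, tile = 5) {
  stopifnot(tile >= 1)
  if (is.null(region)) region <- c(1, 1, height, width)
  stopifnot(length(region) == 4)
  r0 <- region[1]; c0 <- region[2]; rh <- region[3]; rw <- region[4]
  if (r0 < 1 || c0 < 1 || r0 + rh - 1 > height || c0 + rw - 1 > width)
    stop("tile_grid: region exceeds the frame", call. = FALSE)
  nr <- rh %/% tile; nc <- rw %/% tile
  if (nr < 1 || nc < 1)
    stop("tile_grid: region smaller than one ", tile, "x", tile, " tile",
         call. = FALSE)
  expand.grid(row = r0 + tile * (seq_len(nr) - 1),
              col = c0 + tile * (seq_len(nc) - 1),
              KEEP.OUT.ATTRS = FALSE)
}

#' Cut a cube into 5x5-pixel regions of interest
#'
#' Each RoI carries its member pixel spectra as a `(tile^2) x B` matrix.
#'
#' @param cube A [spectral_cube()].
#' @param region Optional `c(row0, col0, nrow, ncol)` sub-rectangle.
#' @param tile Tile side (default 5).
#' @return List of RoIs: `list(origin = c(row, col), size, spectra)`.
#' @export
tile_rois <- function(cube, region = NULL, tile = 5) {
  stopifnot(inherits(cube, "spectral_cube"))
  d <- dim(cube$data)
  grid <- tile_grid(d[1], d[2], region, tile)
  b <- d[3]
  lapply(seq_len(nrow(grid)), function(i) {
    r <- grid$row[i]; c <- grid$col[i]
    block <- cube$data[r:(r + tile - 1), c:(c + tile - 1), , drop = FALSE]
    list(origin = c(row = r, col = c), size = tile,
         spectra = matrix(block, tile * tile, b))
  })
}

#' Interquartile-range outlier removal (Tukey fence)
#'
#' Keeps values inside `[Q1 - factor*IQR, Q3 + factor*IQR]`, with
#' quartiles by linear interpolation between order statistics (R's default
#' quantile type 7). With fewer than 4 values the fence is meaningless and
#' the input passes through with a warning. Applied exactly once per RoI
#' per band during extraction; re-running on the survivors is not
#' guaranteed to be a no-op.
#'
#' @param values Numeric vector.
#' @param factor Fence multiplier (conventional Tukey value 1.5).
#' @return The surviving values, in input order.
#' @examples
#' iqr_clean(c(1, 1, 1, 1, 100)) # drops 100
#' @export
iqr_clean <- function(values, factor = 1.5) {
  stopifnot(is.numeric(values), factor >= 0)
  if (length(values) < 4) {
    warning("iqr_clean: fewer than 4 values, passing through unchanged")
    return(values)
  }
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  values[values >= q[1] - factor * iqr & values <= q[2] + factor * iqr]
}

#' Outlier-cleaned median spectrum of an RoI
#'
#' Per band: IQR-clean the member pixel intensities, then take their
#' median. The Tukey fence always contains the central half of the data,
#' so the survivor set cannot be empty; should it ever be (degenerate
#' input), the band falls back to the uncleaned median with a warning.
#'
#' @param roi One RoI from [tile_rois()] (list with a `spectra` matrix),
#'   or a bare pixel-by-band matrix.
#' @param factor IQR fence multiplier.
#' @return Numeric vector: the per-band cleaned median spectrum.
#' @export
roi_median_spectrum <- function(roi, factor = 1.5) {
  m <- if (is.list(roi) && !is.null(roi$spectra)) roi$spectra else as.matrix(roi)
  if (nrow(m) == 0) stop("roi_median_spectrum: empty RoI", call. = FALSE)
  apply(m, 2, function(v) {
    s <- suppressWarnings(iqr_clean(v, factor))
    if (length(s) == 0) {
      warning("roi_median_spectrum: all pixels removed at a band; ",
              "falling back to the uncleaned median")
      s <- v
    }
    stats::median(s)
  })
}

#' Extract a calibration table from labeled cubes
#'
#' The data-reduction step of the pipeline: each cube is tiled into
#' 5x5-pixel RoIs, each RoI is cleaned of outliers per band (IQR fence)
#' and collapsed to its median spectrum, giving one labeled sample per
#' RoI. Labels (`ph`, `po2`) are taken from each cube's `metadata` unless
#' supplied in `labels`.
#'
#' @param cubes A [spectral_cube()] or list of them.
#' @param labels Optional data frame with columns `ph`, `po2`, one row per
#'   cube; overrides cube metadata.
#' @param region,tile Passed to [tile_rois()].
#' @param iqr_factor Fence multiplier for [iqr_clean()].
#' @return A [calibration_table()] with one row per RoI; provenance
#'   `"cube<i>:r<row>c<col>"`.
#' @export
extract_calibration_samples <- function(cubes, labels = NULL,
                                        region = NULL, tile = 5,
                                        iqr_factor = 1.5) {
  if (inherits(cubes, "spectral_cube")) cubes <- list(cubes)
  stopifnot(length(cubes) >= 1)
  wl <- cubes[[1]]$wavelengths
  out_spec <- list(); out_ph <- list(); out_po2 <- list(); out_prov <- list()
  for (i in seq_along(cubes)) {
    cube <- cubes[[i]]
    if (!identical(cube$wavelengths, wl))
      stop("extract_calibration_samples: cubes have mismatched wavelength axes",
           call. = FALSE)
    if (!is.null(labels)) {
      ph <- labels$ph[i]; po2 <- labels$po2[i]
    } else {
      ph <- cube$metadata$ph; po2 <- cube$metadata$po2
    }
    if (is.null(ph) || is.null(po2) || !is.finite(ph) || !is.finite(po2))
      stop("extract_calibration_samples: cube ", i,
           " carries no (ph, po2) labels", call. = FALSE)
    rois <- tile_rois(cube, region, tile)
    specs <- t(vapply(rois, roi_median_spectrum, numeric(length(wl)),
                      factor = iqr_factor))
    out_spec[[i]] <- specs
    out_ph[[i]] <- rep(ph, length(rois))
    out_po2[[i]] <- rep(po2, length(rois))
    out_prov[[i]] <- vapply(rois, function(r)
      sprintf("cube%d:r%dc%d", i, r$origin[["row"]], r$origin[["col"]]),
      character(1))
  }
  calibration_table(do.call(rbind, out_spec),
                    ph = unlist(out_ph), po2 = unlist(out_po2),
                    wavelengths = wl, provenance = unlist(out_prov))
}

#' Balance a calibration table to the median per-point count
#'
#' Real optode calibration campaigns oversample some conditions (anoxic
#' and air-saturated points especially), which biases a regressor trained
#' on the raw table. Balancing reduces every over-represented calibration
#' point down to the median per-point count, not by discarding rows but by
#' averaging them: the rows of a group with `n > target` are partitioned,
#' in their stored order, into `target` contiguous chunks of size
#' `ceiling(n/target)` or `floor(n/target)`, and each chunk is replaced by
#' its per-band mean spectrum (labels preserved). Groups at or below the
#' target are untouched. The operation is deterministic; no seed.
#'
#' A calibration point is identified by its label pair after rounding pH
#' to 0.1 and pO2 to 1 hPa. If the number of groups is even the median
#' count can be half-integral; it is rounded to the nearest integer.
#'
#' @param table A [calibration_table()].
#' @return `list(table = balanced calibration_table, report = data.frame
#'   (ph, po2, before, after) with attribute "target")`.
#' @export
balance_table <- function(table) {
  stopifnot(inherits(table, "calibration_table"))
  if (nrow(table) == 0) stop("balance_table: empty table", call. = FALSE)
  key <- paste(round(table$ph, 1), round(table$po2, 0), sep = "|")
  groups <- split(seq_len(nrow(table)), key)
  # split() orders by key string; restore first-appearance order for stability
  groups <- groups[unique(key)]
  counts <- lengths(groups)
  target <- as.integer(round(stats::median(counts)))
  spectra <- table_spectra(table)
  wl <- table_wavelengths(table)
  new_spec <- list(); new_ph <- list(); new_po2 <- list(); new_prov <- list()
  report <- data.frame(ph = numeric(0), po2 = numeric(0),
                       before = integer(0), after = integer(0))
  for (gi in seq_along(groups)) {
    idx <- groups[[gi]]
    n <- length(idx)
    ph_g <- table$ph[idx[1]]; po2_g <- table$po2[idx[1]]
    if (n <= target) {
      new_spec[[gi]] <- spectra[idx, , drop = FALSE]
      new_ph[[gi]] <- table$ph[idx]
      new_po2[[gi]] <- table$po2[idx]
      new_prov[[gi]] <- table$provenance[idx]
      after <- n
    } else {
      # partition idx (stored order) into `target` near-equal contiguous chunks
      chunk <- rep(seq_len(target), each = n %/% target)
      extra <- n - length(chunk)
      if (extra > 0) chunk <- c(rep(seq_len(extra), each = 1), chunk)
      chunk <- sort(chunk)[seq_len(n)]
      agg <- rowsum(spectra[idx, , drop = FALSE], chunk, reorder = TRUE)
      sizes <- as.vector(table(chunk))
      agg <- agg / sizes
      new_spec[[gi]] <- agg
      new_ph[[gi]] <- rep(ph_g, target)
      new_po2[[gi]] <- rep(po2_g, target)
      new_prov[[gi]] <- sprintf("balanced:%s|%s:%d", ph_g, po2_g,
                                seq_len(target))
      after <- target
    }
    report <- rbind(report, data.frame(ph = ph_g, po2 = po2_g,
                                       before = n, after = after))
  }
  out <- calibration_table(do.call(rbind, new_spec),
                           ph = unlist(new_ph), po2 = unlist(new_po2),
                           wavelengths = wl, provenance = unlist(new_prov))
  attr(report, "target") <- target
  list(table = out, report = report)
}

#' Random train/validation split
#'
#' Splits the table into disjoint subsets whose union is the input;
#' `|train| = round(ratio * N)`. Reproducible for a fixed seed.
#'
#' @param table A [calibration_table()].
#' @param ratio Train fraction, strictly between 0 and 1 (default 0.8).
#' @param seed Integer seed.
#' @return `list(train = ..., validation = ...)`.
#' @export
split_table <- function(table, ratio = 0.8, seed = 1) {
  stopifnot(inherits(table, "calibration_table"))
  n <- nrow(table)
  if (n < 2) stop("split_table: need at least 2 rows", call. = FALSE)
  if (!is.numeric(ratio) || ratio <= 0 || ratio >= 1)
    stop("split_table: `ratio` must lie strictly between 0 and 1",
         call. = FALSE)
  n_train <- round(ratio * n)
  idx <- withr::with_seed(seed, sample.int(n, n_train))
  list(train = table[sort(idx), , drop = FALSE],
       validation = table[setdiff(seq_len(n), idx), , drop = FALSE])
}
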