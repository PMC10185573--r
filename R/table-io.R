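#' Labeled calibration table
#'
#' The structured dataset the supervised model trains on: one row per
#' sample (a full emission spectrum) plus its known calibration labels.
#' Stored as a data frame with columns `ph`, `po2`, `provenance`, then one
#' numeric column per band named by its wavelength in nm ("470", "473",
#' ...). The wavelength axis is kept as an attribute.
#'
#' @param spectra Numeric matrix, one row per sample, one column per band.
#' @param ph,po2 Numeric label vectors (`po2` in hPa, >= 0).
#' @param wavelengths Band centers (nm), one per spectrum column.
#' @param provenance Optional character vector identifying each row's
#'   source (RoI id, file, simulation index).
#' @return A data frame of class `calibration_table`.
#' @export
calibration_table <- function(spectra, ph, po2, wavelengths,
                              provenance = NULL) {
  spectra <- as.matrix(spectra)
  n <- nrow(spectra)
  stopifnot(length(ph) == n, length(po2) == n,
            ncol(spectra) == length(wavelengths))
  if (any(!is.finite(ph)) || any(!is.finite(po2)))
    stop("calibration_table: labels must be finite", call. = FALSE)
  if (any(po2 < 0))
    stop("calibration_table: po2 must be >= 0", call. = FALSE)
  if (is.null(provenance)) provenance <- rep(NA_character_, n)
  df <- data.frame(ph = as.numeric(ph), po2 = as.numeric(po2),
                   provenance = as.character(provenance),
                   stringsAsFactors = FALSE)
  sp <- as.data.frame(spectra)
  names(sp) <- format(wavelengths, trim = TRUE, scientific = FALSE)
  df <- cbind(df, sp)
  attr(df, "wavelengths") <- as.numeric(wavelengths)
  class(df) <- c("calibration_table", "data.frame")
  df
}

#' Spectra of a calibration table as a matrix
#' @param table A [calibration_table()].
#' @return Numeric matrix, rows = samples, columns = bands.
#' @export
table_spectra <- function(table) {
  wl <- table_wavelengths(table)
  cols <- format(wl, trim = TRUE, scientific = FALSE)
  as.matrix(as.data.frame(table)[, cols, drop = FALSE])
}

#' Wavelength axis of a calibration table
#' @param table A [calibration_table()].
#' @return Numeric vector (nm).
#' @export
table_wavelengths <- function(table) {
  wl <- attr(table, "wavelengths")
  if (is.null(wl)) {
    # reconstruct from numeric column names
    num <- suppressWarnings(as.numeric(names(table)))
    wl <- num[!is.na(num)]
  }
  wl
}

#' @export
print.calibration_table <- function(x, ...) {
  cat(sprintf("<calibration_table> %d samples x %d bands; pH %s, pO2 %s hPa\n",
              nrow(x), length(table_wavelengths(x)),
              paste(range(x$ph), collapse = "-"),
              paste(range(x$po2), collapse = "-")))
  invisible(x)
}

# keep class + wavelength attribute across [ subsetting of rows
#' @export
`[.calibration_table` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && (missing(j) || identical(ncol(out), ncol(x)))) {
    attr(out, "wavelengths") <- attr(x, "wavelengths")
    class(out) <- c("calibration_table", "data.frame")
  }
  out
}

#' Write / read a calibration table as CSV
#'
#' Plain comma-separated values with a mandatory header row; "." decimal.
#' Label columns `ph` and `po2` (plus optional `provenance`) come first,
#' then wavelength columns in ascending order, named by their numeric band
#' center in nm. `read_table` identifies the wavelength columns by their
#' numeric header names, canonicalizes column order, and refuses malformed
#' input (a missing label column or a non-numeric cell is an error, never
#' a silent coercion). Numeric values are written with 17 significant
#' digits, so round-trips are lossless for doubles.
#'
#' @param table A [calibration_table()].
#' @param path CSV file path.
#' @return `write_table` returns `path` invisibly; `read_table` returns a
#'   [calibration_table()].
#' @export
write_table <- function(table, path) {
  stopifnot(inherits(table, "calibration_table"))
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, logical(1))
  for (k in which(num)) df[[k]] <- format(df[[k]], digits = 17, trim = TRUE,
                                          scientific = TRUE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop("read_table: no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  for (lab in c("ph", "po2")) {
    if (!lab %in% names(df))
      stop("read_table: missing label column \"", lab, "\"", call. = FALSE)
  }
  num_names <- suppressWarnings(as.numeric(names(df)))
  wl_cols <- which(!is.na(num_names))
  if (length(wl_cols) == 0)
    stop("read_table: no wavelength columns (numeric header names) found",
         call. = FALSE)
  wl <- num_names[wl_cols]
  ord <- order(wl)
  wl_cols <- wl_cols[ord]; wl <- wl[ord]
  parse_num <- function(col, nm) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & df[[col]] != "NA")
    if (length(bad) > 0)
      stop("read_table: non-numeric value in column \"", nm,
           "\" at row ", bad[1], call. = FALSE)
    v
  }
  spectra <- vapply(seq_along(wl_cols),
                    function(i) parse_num(wl_cols[i],
                                          names(df)[wl_cols[i]]),
                    numeric(nrow(df)))
  if (nrow(df) == 1) spectra <- matrix(spectra, nrow = 1)
  prov <- if ("provenance" %in% names(df)) df$provenance else NULL
  calibration_table(spectra,
                    ph = parse_num(which(names(df) == "ph")[1], "ph"),
                    po2 = parse_num(which(names(df) == "po2")[1], "po2"),
                    wavelengths = wl, provenance = prov)
}
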