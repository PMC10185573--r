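#' Hyperspectral cube container
#'
#' A 3D intensity array `H x W x B` with an explicit wavelength axis and
#' free-form acquisition metadata. Pixel coordinates are `(row, col)`,
#' 1-based as usual in R; band `b` of pixel `(r, c)` is `data[r, c, b]`.
#'
#' @param data Numeric array `H x W x B`; all values finite.
#' @param wavelengths Strictly increasing numeric vector of length `B` (nm).
#' @param metadata Named list of acquisition key-values.
#' @return An object of class `spectral_cube`.
#' @export
spectral_cube <- function(data, wavelengths, metadata = list()) {
  if (!is.array(data) || length(dim(data)) != 3)
    stop("spectral_cube: `data` must be an H x W x B array", call. = FALSE)
  wavelengths <- as.numeric(wavelengths)
  if (dim(data)[3] != length(wavelengths))
    stop("spectral_cube: band count (", dim(data)[3],
         ") != wavelength count (", length(wavelengths), ")", call. = FALSE)
  if (any(diff(wavelengths) <= 0))
    stop("spectral_cube: wavelengths must be strictly increasing", call. = FALSE)
  if (!all(is.finite(data)))
    stop("spectral_cube: intensities must be finite", call. = FALSE)
  structure(list(data = data, wavelengths = wavelengths, metadata = metadata),
            class = "spectral_cube")
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<spectral_cube> %d x %d pixels, %d bands (%g-%g nm)\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' @export
dim.spectral_cube <- function(x) dim(x$data)

# Pixels as an (H*W) x B matrix in row-major pixel order:
# row k corresponds to pixel (r, c) with k = (r-1)*W + c.
cube_pixel_matrix <- function(cube) {
  d <- dim(cube$data)
  m <- matrix(aperm(cube$data, c(2, 1, 3)), d[1] * d[2], d[3])
  m
}

#' Write / read a hyperspectral cube as an ENVI header + binary pair
#'
#' The on-disk dialect is the de-facto hyperspectral exchange format:
#' a plain-text `.hdr` file describing geometry, plus a band-sequential
#' (BSQ) little-endian float32 binary. The wavelength list is mandatory
#' in the header. `read_cube(write_cube(x))` is lossless for data already
#' held in float32 range (the simulator's cubes are written after a
#' float32 round, so round-trips are bit-identical).
#'
#' @param cube A [spectral_cube()].
#' @param path Path of the binary file (conventionally `.raw`); the header
#'   is written next to it as `<path>.hdr`.
#' @return `write_cube` returns `path` invisibly; `read_cube` returns a
#'   [spectral_cube()].
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "spectral_cube"))
  d <- dim(cube$data)
  hdr <- c(
    "ENVI",
    "file type = ENVI Standard",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "data type = 4",
    "interleave = bsq",
    "byte order = 0",
    sprintf("wavelength units = nm"),
    sprintf("wavelength = { %s }",
            paste(format(cube$wavelengths, trim = TRUE), collapse = ", "))
  )
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(path, "wb")
  on.exit(close(con))
  # BSQ: band-major, within a band row-major is *not* ENVI; ENVI stores
  # each band as lines x samples, sample fastest. aperm to (col fastest).
  v <- as.numeric(aperm(cube$data, c(2, 1, 3)))  # sample, line, band order
  writeBin(v, con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  hdr_path <- paste0(path, ".hdr")
  if (!file.exists(hdr_path))
    stop("read_cube: missing ENVI header: ", hdr_path, call. = FALSE)
  if (!file.exists(path))
    stop("read_cube: missing binary file: ", path, call. = FALSE)
  lines <- readLines(hdr_path, warn = FALSE)
  txt <- paste(lines, collapse = "\n")
  get_num <- function(key) {
    m <- regmatches(txt, regexpr(paste0("(?mi)^", key, "\\s*=\\s*([0-9]+)"),
                                 txt, perl = TRUE))
    if (length(m) == 0)
      stop("read_cube: header field missing: ", key, call. = FALSE)
    as.integer(sub(".*=\\s*", "", m))
  }
  samples <- get_num("samples"); nlines <- get_num("lines")
  bands <- get_num("bands"); dtype <- get_num("data type")
  byte_order <- get_num("byte order")
  interleave <- regmatches(txt, regexpr("(?mi)^interleave\\s*=\\s*(\\w+)",
                                        txt, perl = TRUE))
  interleave <- tolower(sub(".*=\\s*", "", interleave))
  if (length(interleave) == 0 || interleave != "bsq")
    stop("read_cube: only BSQ interleave is supported", call. = FALSE)
  if (dtype != 4)
    stop("read_cube: only data type 4 (float32) is supported", call. = FALSE)
  wl_match <- regmatches(txt, regexpr("wavelength\\s*=\\s*\\{[^}]*\\}", txt,
                                      perl = TRUE))
  if (length(wl_match) == 0)
    stop("read_cube: header field missing: wavelength", call. = FALSE)
  wl <- as.numeric(strsplit(gsub(".*\\{|\\}", "", wl_match), ",")[[1]])
  if (length(wl) != bands)
    stop("read_cube: wavelength list length (", length(wl),
         ") != bands (", bands, ")", call. = FALSE)
  if (any(diff(wl) <= 0))
    stop("read_cube: wavelengths not strictly increasing", call. = FALSE)
  n <- samples * nlines * bands
  if (file.info(path)$size != 4 * n)
    stop("read_cube: binary size (", file.info(path)$size,
         " bytes) does not match header geometry (", 4 * n, " bytes)",
         call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n = n, size = 4,
               endian = if (byte_order == 0) "little" else "big")
  data <- aperm(array(v, dim = c(samples, nlines, bands)), c(2, 1, 3))
  spectral_cube(data, wl, metadata = list(source = path))
}

#' Round cube intensities to float32 precision
#'
#' Convenience used before [write_cube()] when bit-identical round-trips
#' are required: the on-disk container is float32.
#' @param cube A [spectral_cube()].
#' @return The cube with data squeezed through float32.
#' @export
as_float32 <- function(cube) {
  bytes <- writeBin(as.numeric(cube$data), raw(), size = 4, endian = "little")
  v <- readBin(bytes, "numeric", n = length(cube$data), size = 4,
               endian = "little")
  cube$data <- array(v, dim = dim(cube$data))
  cube
}
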