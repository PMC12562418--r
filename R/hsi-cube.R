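#' Hyperspectral cubes
#'
#' A `hyper_cube` wraps a rank-3 array (`rows x cols x bands`) of raw
#' detector counts or reflectance together with its wavelength grid.
#'
#' @param data rank-3 numeric array, `rows x cols x bands`.
#' @param wavelengths_nm strictly increasing vector, one value per band.
#' @param kind `"raw"` (detector counts) or `"reflectance"`.
#' @return A `hyper_cube` object.
#' @export
hyper_cube <- function(data, wavelengths_nm, kind = c("raw", "reflectance")) {
  kind <- match.arg(kind)
  if (length(dim(data)) != 3)
    abort("`data` must be a rank-3 array (rows x cols x bands)",
          class = "spectraseed_format_error")
  if (dim(data)[3] != length(wavelengths_nm))
    abort(sprintf("band count (%d) does not match wavelength count (%d)",
                  dim(data)[3], length(wavelengths_nm)),
          class = "spectraseed_format_error")
  if (any(diff(wavelengths_nm) <= 0))
    abort("`wavelengths_nm` must be strictly increasing",
          class = "spectraseed_format_error")
  if (kind == "reflectance" && !all(is.finite(data)))
    abort("reflectance cubes must be finite", class = "spectraseed_format_error")
  structure(list(data = data, wavelengths_nm = as.numeric(wavelengths_nm),
                 kind = kind), class = "hyper_cube")
}

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("# Hyperspectral cube (%s): %d x %d px, %d bands (%.1f-%.1f nm)\n",
              x$kind, d[1], d[2], d[3],
              min(x$wavelengths_nm), max(x$wavelengths_nm)))
  invisible(x)
}

# ENVI data type codes supported for I/O
envi_dtypes <- list(
  `2` = list(what = "integer", size = 2, signed = TRUE),
  `4` = list(what = "numeric", size = 4, signed = TRUE),
  `5` = list(what = "numeric", size = 8, signed = TRUE),
  `12` = list(what = "integer", size = 2, signed = FALSE))

#' Write / read hyperspectral cubes in an ENVI-style format
#'
#' The cube is stored as a flat binary raster at `path` plus a text header at
#' `<path>.hdr` carrying `samples` (columns), `lines` (rows), `bands`,
#' `data type` (ENVI codes 2 = int16, 4 = float32, 5 = float64,
#' 12 = uint16), `interleave` (`bil` or `bsq`) and the wavelength list.
#' Round-tripping is bit-identical for the supported types. Little-endian
#' byte order only.
#'
#' @param cube a [hyper_cube()].
#' @param path raster file path (header written next to it).
#' @param interleave `"bil"` (line-major: per line, per band, per sample) or
#'   `"bsq"` (band-sequential).
#' @param data_type ENVI data-type code.
#' @export
write_envi <- function(cube, path, interleave = c("bil", "bsq"), data_type = 4) {
  stopifnot(inherits(cube, "hyper_cube"))
  interleave <- match.arg(interleave)
  dt <- envi_dtypes[[as.character(data_type)]]
  if (is.null(dt))
    abort(sprintf("unsupported ENVI data type %s", data_type),
          class = "spectraseed_format_error")
  d <- dim(cube$data)
  # data array is (row, col, band); serialise with samples fastest
  vals <- if (interleave == "bsq") {
    aperm(cube$data, c(2, 1, 3))          # sample, line, band
  } else {
    aperm(cube$data, c(2, 3, 1))          # sample, band, line
  }
  v <- as.vector(vals)
  if (dt$what == "integer") v <- as.integer(round(v))
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(v, con, size = dt$size, endian = "little")
  hdr <- c(
    "ENVI",
    "description = { spectraseed exported cube }",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", as.integer(data_type)),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    sprintf("wavelength units = Nanometers"),
    sprintf("wavelength = { %s }",
            paste(format(cube$wavelengths_nm, trim = TRUE, digits = 10),
                  collapse = ", ")))
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

parse_envi_header <- function(hdr_path) {
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  get_key <- function(key) {
    m <- regmatches(txt, regexec(
      sprintf("(?mi)^[ \t]*%s[ \t]*=[ \t]*([^\n{]*)$", key), txt, perl = TRUE))[[1]]
    if (length(m) < 2) NULL else trimws(m[2])
  }
  get_block <- function(key) {
    m <- regmatches(txt, regexec(
      sprintf("(?si)%s[ \t]*=[ \t]*\\{(.*?)\\}", key), txt, perl = TRUE))[[1]]
    if (length(m) < 2) NULL else trimws(m[2])
  }
  need <- function(key, val) {
    if (is.null(val) || !nzchar(val))
      abort(sprintf("ENVI header is missing required field `%s`", key),
            class = "spectraseed_format_error")
    val
  }
  list(samples = as.integer(need("samples", get_key("samples"))),
       lines = as.integer(need("lines", get_key("lines"))),
       bands = as.integer(need("bands", get_key("bands"))),
       data_type = as.integer(need("data type", get_key("data type"))),
       interleave = tolower(need("interleave", get_key("interleave"))),
       wavelength = as.numeric(strsplit(need("wavelength", get_block("wavelength")),
                                        "[,\n]")[[1]]))
}

#' @rdname write_envi
#' @param kind cube kind to stamp on the result (`"raw"` or `"reflectance"`).
#' @export
read_envi <- function(path, kind = "raw") {
  hdr_path <- paste0(path, ".hdr")
  if (!file.exists(hdr_path))
    abort(sprintf("header file not found: %s", hdr_path),
          class = "spectraseed_format_error")
  h <- parse_envi_header(hdr_path)
  if (length(h$wavelength) != h$bands)
    abort(sprintf("header field `wavelength` lists %d values but `bands` = %d",
                  length(h$wavelength), h$bands),
          class = "spectraseed_format_error")
  if (!h$interleave %in% c("bil", "bsq"))
    abort(sprintf("unsupported `interleave` value: %s", h$interleave),
          class = "spectraseed_format_error")
  dt <- envi_dtypes[[as.character(h$data_type)]]
  if (is.null(dt))
    abort(sprintf("unsupported `data type` code: %d", h$data_type),
          class = "spectraseed_format_error")
  n <- h$samples * h$lines * h$bands
  con <- file(path, "rb"); on.exit(close(con))
  v <- readBin(con, what = dt$what, n = n, size = dt$size,
               signed = dt$signed, endian = "little")
  if (length(v) != n)
    abort("raster file shorter than header dimensions imply",
          class = "spectraseed_format_error")
  arr <- if (h$interleave == "bsq") {
    aperm(array(v, c(h$samples, h$lines, h$bands)), c(2, 1, 3))
  } else {
    aperm(array(v, c(h$samples, h$bands, h$lines)), c(3, 1, 2))
  }
  storage.mode(arr) <- "double"
  hyper_cube(arr, h$wavelength, kind = kind)
}

# reduce a reference to a per-pixel matrix (mean over extra dims)
reduce_reference <- function(x, rows, cols, name) {
  if (is.matrix(x)) m <- x
  else if (length(dim(x)) == 3) m <- apply(x, c(1, 2), mean)
  else abort(sprintf("`%s` must be a matrix or rank-3 array", name),
             class = "spectraseed_format_error")
  if (!all(dim(m) == c(rows, cols)))
    abort(sprintf("`%s` does not match the cube's spatial dimensions", name),
          class = "spectraseed_format_error")
  m
}

#' Black/white reflectance calibration
#'
#' Converts raw detector counts to reflectance with the standard black/white
#' correction `I_c = (I_raw - I_dark) / (I_white - I_dark)`, applied per
#' pixel and band. References given as multi-frame stacks are first reduced
#' to per-pixel means. Reflectance is clipped to `[0, clip_max]`
#' (specular pixels can legitimately exceed 1); the number of clipped values
#' is reported so calibration faults are not silently hidden.
#'
#' @param raw a raw-kind [hyper_cube()].
#' @param white,dark white and dark reference frames: matrices matching the
#'   cube's spatial dimensions, or rank-3 stacks reduced by averaging.
#' @param clip_max upper reflectance clip (default 1.5).
#' @return A reflectance-kind [hyper_cube()].
#' @export
calibrate <- function(raw, white, dark, clip_max = 1.5) {
  stopifnot(inherits(raw, "hyper_cube"))
  if (raw$kind != "raw")
    abort("`raw` must be a raw-kind cube", class = "spectraseed_config_error")
  d <- dim(raw$data)
  w <- reduce_reference(white, d[1], d[2], "white")
  k <- reduce_reference(dark, d[1], d[2], "dark")
  span <- w - k
  bad <- sum(span <= 0)
  if (bad > 0)
    abort(sprintf("white - dark is non-positive at %d pixel(s); calibration undefined",
                  bad), class = "spectraseed_calibration_error")
  out <- array(0, d)
  for (b in seq_len(d[3])) out[, , b] <- (raw$data[, , b] - k) / span
  n_clip <- sum(out < 0 | out > clip_max)
  if (n_clip > 0)
    inform(sprintf("calibrate: clipped %d of %d values to [0, %g]",
                   n_clip, length(out), clip_max))
  out <- pmin(pmax(out, 0), clip_max)
  hyper_cube(out, raw$wavelengths_nm, kind = "reflectance")
}
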