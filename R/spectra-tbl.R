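#' Spectra tables
#'
#' A spectra table is the package's tabular container for per-seed mean
#' reflectance spectra: a tibble with one row per seed, a `sample_id` column,
#' an integer `class` column (variety label, `0..n_classes-1`, `NA` when
#' unknown), and one `wl_<nm>` column per wavelength. Because the wavelength
#' grid is encoded in the column names, spectra tables survive ordinary
#' dplyr manipulation (filtering, joining, slicing) without losing their
#' spectral axis.
#'
#' @param x numeric matrix, one row per seed, one column per band.
#' @param wavelengths_nm strictly increasing wavelength grid, one value per
#'   column of `x`.
#' @param labels integer class labels (`0`-based) or `NA`.
#' @param sample_ids optional character ids; generated when missing.
#' @return A tibble of class `spectra_tbl`.
#' @export
spectra_tbl <- function(x, wavelengths_nm, labels = NA_integer_, sample_ids = NULL) {
  x <- as.matrix(x)
  if (ncol(x) != length(wavelengths_nm))
    abort("`wavelengths_nm` length must match the number of spectral columns",
          class = "spectraseed_format_error")
  if (any(diff(wavelengths_nm) <= 0))
    abort("`wavelengths_nm` must be strictly increasing",
          class = "spectraseed_format_error")
  if (anyNA(x)) abort("spectra must not contain missing values",
                      class = "spectraseed_format_error")
  n <- nrow(x)
  if (is.null(sample_ids)) sample_ids <- sprintf("seed_%04d", seq_len(n))
  labels <- rep_len(as.integer(labels), n)
  colnames(x) <- wl_names(wavelengths_nm)
  out <- tibble::tibble(sample_id = as.character(sample_ids), class = labels)
  out <- dplyr::bind_cols(out, tibble::as_tibble(x))
  class(out) <- c("spectra_tbl", class(out))
  out
}

wl_names <- function(wavelengths_nm) sprintf("wl_%.10g", wavelengths_nm)

#' @rdname spectra_tbl
#' @param data a spectra table (or any data frame with `wl_*` columns).
#' @export
spectra_matrix <- function(data) {
  cols <- grep("^wl_", names(data), value = TRUE)
  if (length(cols) == 0)
    abort("no `wl_*` spectral columns found", class = "spectraseed_format_error")
  m <- as.matrix(as.data.frame(data)[cols])
  storage.mode(m) <- "double"
  m
}

#' @rdname spectra_tbl
#' @export
spectra_wavelengths <- function(data) {
  cols <- grep("^wl_", names(data), value = TRUE)
  as.numeric(sub("^wl_", "", cols))
}

#' @rdname spectra_tbl
#' @export
spectra_labels <- function(data) {
  if (!"class" %in% names(data))
    abort("no `class` column found", class = "spectraseed_format_error")
  as.integer(data[["class"]])
}

#' Read / write spectra tables as delimited text
#'
#' One row per seed: `sample_id`, `class`, then one reflectance value per
#' band. The wavelength grid travels in the header line as `wl_<nm>` names.
#'
#' @param data a spectra table.
#' @param path file path.
#' @param sep field separator.
#' @export
write_spectra <- function(data, path, sep = "\t") {
  utils::write.table(as.data.frame(data), path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_spectra
#' @export
read_spectra <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  wl <- as.numeric(sub("^wl_", "", grep("^wl_", names(df), value = TRUE)))
  spectra_tbl(as.matrix(df[grep("^wl_", names(df))]), wl,
              labels = df[["class"]], sample_ids = df[["sample_id"]])
}

#' @export
print.spectra_tbl <- function(x, ...) {
  wl <- spectra_wavelengths(x)
  cat(sprintf("# Spectra table: %d seeds x %d bands (%.1f-%.1f nm), %d labelled classes\n",
              nrow(x), length(wl), min(wl), max(wl),
              length(unique(stats::na.omit(x$class)))))
  NextMethod()
}

#' Plot spectra coloured by class
#'
#' @param object a spectra table.
#' @param max_per_class spectra drawn per class (thinned for legibility).
#' @param ... unused.
#' @method autoplot spectra_tbl
#' @export
autoplot.spectra_tbl <- function(object, max_per_class = 10, ...) {
  wl <- spectra_wavelengths(object)
  df <- object |>
    dplyr::group_by(.data$class) |>
    dplyr::slice_head(n = max_per_class) |>
    dplyr::ungroup() |>
    tidyr::pivot_longer(dplyr::starts_with("wl_"),
                        names_to = "wavelength", values_to = "reflectance") |>
    dplyr::mutate(wavelength = as.numeric(sub("^wl_", "", .data$wavelength)))
  ggplot2::ggplot(df, ggplot2::aes(.data$wavelength, .data$reflectance,
                                   group = .data$sample_id,
                                   colour = factor(.data$class))) +
    ggplot2::geom_line(alpha = 0.6, linewidth = 0.3) +
    ggplot2::labs(x = "wavelength (nm)", y = "reflectance", colour = "class") +
    ggplot2::theme_minimal()
}
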