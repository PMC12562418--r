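#' Savitzky-Golay smoothing of spectra
#'
#' Convolves every spectrum with the Savitzky-Golay least-squares kernel for
#' the given window and polynomial order. Edges are handled by the boundary
#' polynomial fit (the first/last rows of the Savitzky-Golay projection
#' matrix), the standard convention and the one [signal::sgolayfilt()]
#' implements. The default three-point, degree-1 kernel is the
#' `(1/3, 1/3, 1/3)` moving average: with a three-point window, degree 2
#' reproduces the input exactly (a quadratic through three points is exact),
#' so degree 1 is the only choice that actually smooths.
#'
#' @param data a spectra table.
#' @param window odd window length `>= 3`.
#' @param polyorder polynomial degree `< window`.
#' @return The smoothed spectra table; wavelengths unchanged.
#' @export
sg_smooth <- function(data, window = 3, polyorder = 1) {
  window <- check_count(window, "window", min = 3)
  polyorder <- check_count(polyorder, "polyorder", min = 0)
  if (window %% 2 == 0)
    abort("`window` must be odd", class = "spectraseed_config_error")
  if (polyorder >= window)
    abort("`polyorder` must be < `window`", class = "spectraseed_config_error")
  x <- spectra_matrix(data)
  b <- ncol(x)
  if (window > b)
    abort("`window` exceeds the number of bands",
          class = "spectraseed_config_error")
  sm <- sg_matrix(window, polyorder, b)
  out <- x %*% t(sm)
  res <- data
  res[grep("^wl_", names(res), value = TRUE)] <- out
  res
}

# full B x B smoothing operator: central SG kernel in the interior, boundary
# polynomial-fit rows at the edges
sg_matrix <- function(window, polyorder, n_bands) {
  fm <- unclass(signal::sgolay(p = polyorder, n = window))  # window x window
  h <- (window - 1) / 2
  m <- matrix(0, n_bands, n_bands)
  for (i in seq_len(h)) m[i, 1:window] <- fm[i, ]
  for (i in (h + 1):(n_bands - h)) m[i, (i - h):(i + h)] <- fm[h + 1, ]
  for (i in seq_len(h)) {
    r <- n_bands - h + i
    m[r, (n_bands - window + 1):n_bands] <- fm[h + 1 + i, ]
  }
  m
}

#' Stratified train/test split
#'
#' Splits sample indices per class so that each class contributes
#' `round(test_fraction * n_c)` samples to the test set, matching the
#' stratified 8:2 protocol. Deterministic for a fixed seed.
#'
#' @param data a spectra table with a `class` column.
#' @param test_fraction fraction per class held out (default 0.2).
#' @param seed RNG seed.
#' @return A `split_result` list with disjoint `train_idx`, `test_idx`
#'   (1-based row indices) and the seed used.
#' @export
stratified_split <- function(data, test_fraction = 0.2, seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1)
    abort("`test_fraction` must be in (0, 1)", class = "spectraseed_config_error")
  labels <- spectra_labels(data)
  tab <- table(labels)
  if (any(tab < 2))
    abort("every class needs at least 2 samples to stratify",
          class = "spectraseed_config_error")
  test_idx <- integer(0)
  with_seed(seed, {
    for (cl in names(tab)) {
      idx <- which(labels == as.integer(cl))
      n_test <- round(test_fraction * length(idx))
      if (n_test > 0)
        test_idx <- c(test_idx, sample(idx, n_test))
    }
  })
  test_idx <- sort(test_idx)
  structure(list(train_idx = setdiff(seq_along(labels), test_idx),
                 test_idx = test_idx, seed = as.integer(seed)),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("# Stratified split: %d train / %d test (seed %d)\n",
              length(x$train_idx), length(x$test_idx), x$seed))
  invisible(x)
}

#' Per-band standardization fitted on the training set
#'
#' Centres and scales every band using training-set statistics only; any
#' additional sets are transformed with the same statistics (no test
#' leakage). Bands with zero training variance pass through centred, with a
#' note.
#'
#' @param train training spectra table.
#' @param ... further spectra tables to transform with the train statistics.
#' @return List with the transformed `train`, each transformed `...` set
#'   (by name), and the per-band `center` and `scale` vectors.
#' @export
standardize_spectra <- function(train, ...) {
  x <- spectra_matrix(train)
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  degenerate <- !is.finite(scale) | scale <= 0
  if (any(degenerate)) {
    inform(sprintf("standardize_spectra: %d constant band(s) left unscaled",
                   sum(degenerate)))
    scale[degenerate] <- 1
  }
  apply_stats <- function(df) {
    m <- sweep(sweep(spectra_matrix(df), 2, center), 2, scale, "/")
    df[grep("^wl_", names(df), value = TRUE)] <- m
    df
  }
  extra <- lapply(list(...), apply_stats)
  c(list(train = apply_stats(train)), extra,
    list(center = center, scale = scale))
}

#' Principal component projection of spectra
#'
#' Centred (unscaled) PCA for exploratory visualisation of variety
#' clustering. Note the variance captured by the leading components is a
#' property of the data set at hand.
#'
#' @param data a spectra table.
#' @param n_components components to keep in the scores (default 3).
#' @return A `pca_projection` with `scores` (tibble: `sample_id`, `class`,
#'   `.pc1..k`) and `explained_variance_ratio` over all components
#'   (non-increasing, summing to 1).
#' @export
pca_project <- function(data, n_components = 3) {
  x <- spectra_matrix(data)
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ratio <- p$sdev^2 / sum(p$sdev^2)
  k <- min(n_components, ncol(p$x))
  scores <- tibble::as_tibble(p$x[, seq_len(k), drop = FALSE],
                              .name_repair = ~ sprintf(".pc%d", seq_len(k)))
  scores <- dplyr::bind_cols(
    tibble::tibble(sample_id = data$sample_id, class = spectra_labels(data)),
    scores)
  structure(list(scores = scores, explained_variance_ratio = ratio,
                 rotation = p$rotation[, seq_len(k), drop = FALSE],
                 center = p$center),
            class = "pca_projection")
}

#' Fisher linear discriminant projection of spectra
#'
#' Projects spectra onto the directions maximizing between-class over
#' within-class scatter. The within-class scatter is shrunk towards a scaled
#' identity (`(1 - shrinkage) * Sw + shrinkage * mean(diag(Sw)) * I`), and if
#' it is still numerically singular a small ridge is added automatically
#' (with a note), so the projection is defined even for band counts
#' exceeding the sample count.
#'
#' @param data a spectra table with labels.
#' @param n_components at most `n_classes - 1`.
#' @param shrinkage shrinkage intensity in `[0, 1)` (default 0.01).
#' @return An `lda_projection` with a `scores` tibble (`.ld1..k`).
#' @export
lda_project <- function(data, n_components = 3, shrinkage = 0.01) {
  x <- spectra_matrix(data)
  labels <- spectra_labels(data)
  classes <- sort(unique(labels))
  if (n_components > length(classes) - 1)
    abort("`n_components` must be <= n_classes - 1",
          class = "spectraseed_config_error")
  mu <- colMeans(x)
  p <- ncol(x)
  sw <- matrix(0, p, p); sb <- matrix(0, p, p)
  for (cl in classes) {
    xi <- x[labels == cl, , drop = FALSE]
    mi <- colMeans(xi)
    xc <- sweep(xi, 2, mi)
    sw <- sw + crossprod(xc)
    sb <- sb + nrow(xi) * tcrossprod(mi - mu)
  }
  sw <- (1 - shrinkage) * sw + shrinkage * mean(diag(sw)) * diag(p)
  w <- tryCatch(solve(sw, sb), error = function(e) {
    inform("lda_project: within-class scatter singular, adding ridge")
    solve(sw + 1e-6 * mean(diag(sw)) * diag(p), sb)
  })
  e <- eigen(w)
  k <- n_components
  vecs <- Re(e$vectors[, seq_len(k), drop = FALSE])
  # fix sign for reproducibility: largest-magnitude loading positive
  for (j in seq_len(k)) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  proj <- sweep(x, 2, mu) %*% vecs
  scores <- tibble::as_tibble(proj, .name_repair = ~ sprintf(".ld%d", seq_len(k)))
  scores <- dplyr::bind_cols(
    tibble::tibble(sample_id = data$sample_id, class = labels), scores)
  structure(list(scores = scores, directions = vecs,
                 eigenvalues = Re(e$values[seq_len(k)]), center = mu),
            class = "lda_projection")
}
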