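new_feature_selection <- function(method, selected, B, wavelengths = NULL, ...) {
  structure(c(list(method = method,
                   selected_band_idx = sort(unique(as.integer(selected))),
                   n_bands = as.integer(B),
                   wavelengths_nm = wavelengths), list(...)),
            class = "feature_selection")
}

#' @export
print.feature_selection <- function(x, ...) {
  cat(sprintf("# %s wavelength selection: %d of %d bands\n",
              x$method, length(x$selected_band_idx), x$n_bands))
  invisible(x)
}

#' @method tidy feature_selection
#' @export
tidy.feature_selection <- function(x, ...) {
  if (x$method == "SPA") {
    tibble::tibble(subset_size = seq_along(x$rmse_path), rmse = x$rmse_path)
  } else {
    tibble::tibble(iteration = seq_along(x$rmsecv_path),
                   rmsecv = x$rmsecv_path,
                   retained_count = x$retained_count_path)
  }
}

#' @method glance feature_selection
#' @export
glance.feature_selection <- function(x, ...) {
  tibble::tibble(method = x$method,
                 n_selected = length(x$selected_band_idx),
                 best_iteration = x$best_iteration %||% NA_integer_)
}

#' Successive projections algorithm (SPA) wavelength selection
#'
#' Builds a chain of minimally collinear wavelengths by successive
#' orthogonal projection: given the current set, every remaining band column
#' is projected onto the orthogonal complement of the selected columns'
#' span, and the band with the largest residual norm joins the chain. With
#' `first_var = "auto"` every band is tried as the chain start and the chain
#' whose downstream least-squares regression achieves the lowest RMSE is
#' kept. `rmse_path[k]` is the cross-validated RMSE of an ordinary
#' least-squares model on the first `k` chain variables; the reported subset
#' size is the path's arg-min, or the point of maximum curvature when
#' `size_rule = "elbow"`.
#'
#' @param x predictor matrix or spectra table.
#' @param y response (class labels one-hot encoded when `y_is_class = TRUE`).
#' @param max_vars chain length, `<= min(N - 1, B)`.
#' @param first_var `"auto"` or a 1-based start column index.
#' @param y_is_class treat `y` as 0-based labels (default TRUE).
#' @param cv_folds_n folds for the RMSE path.
#' @param size_rule `"argmin"` (default) or `"elbow"`.
#' @param seed fold-assignment seed.
#' @return A `feature_selection` result with `selected_band_idx` (1-based),
#'   the full `chain`, and `rmse_path`.
#' @export
spa_select <- function(x, y, max_vars, first_var = "auto", y_is_class = TRUE,
                       cv_folds_n = 5, size_rule = c("argmin", "elbow"),
                       seed = 1) {
  size_rule <- match.arg(size_rule)
  if (is.data.frame(x)) x <- spectra_matrix(x)
  x <- as.matrix(x)
  ym <- if (y_is_class) one_hot(y) else as.matrix(y)
  n <- nrow(x); b <- ncol(x)
  max_vars <- check_count(max_vars, "max_vars")
  if (max_vars > min(n - 1, b))
    abort("`max_vars` exceeds min(N - 1, B)", class = "spectraseed_config_error")
  starts <- if (identical(first_var, "auto")) seq_len(b) else as.integer(first_var)
  best_chain <- NULL; best_rmse <- Inf
  for (s in starts) {
    ch <- spa_chain(x, s, max_vars)
    r <- ls_rmse(x[, ch, drop = FALSE], ym)
    if (r < best_rmse) { best_rmse <- r; best_chain <- ch }
  }
  chain <- best_chain
  path <- vapply(seq_along(chain), function(k)
    ls_rmsecv(x[, chain[seq_len(k)], drop = FALSE], ym, cv_folds_n, seed),
    numeric(1))
  k_sel <- if (size_rule == "argmin") which.min(path) else elbow_point(path)
  new_feature_selection("SPA", chain[seq_len(k_sel)], b,
                        chain = chain, rmse_path = path,
                        subset_size = k_sel, first_var = chain[1])
}

# greedy orthogonal-projection chain from a fixed start column; stops early
# (with a note) if all residual norms vanish (rank exhausted)
spa_chain <- function(x, start, max_vars) {
  r <- x
  b <- ncol(x)
  chain <- integer(0)
  sel <- start
  for (k in seq_len(max_vars)) {
    chain <- c(chain, sel)
    q <- r[, sel]
    nq <- sqrt(sum(q^2))
    if (nq < 1e-12) break
    q <- q / nq
    r <- r - q %*% crossprod(q, r)
    r[, chain] <- 0
    if (k == max_vars) break
    norms <- colSums(r^2)
    if (max(norms) < 1e-20) {
      inform(sprintf("spa: candidate space exhausted after %d variables", k))
      break
    }
    sel <- which.max(norms)
  }
  chain
}

ls_fit_predict <- function(x_tr, y_tr, x_te) {
  xa <- cbind(1, x_tr)
  coef <- qr.coef(qr(xa), y_tr)
  coef[is.na(coef)] <- 0
  cbind(1, x_te) %*% coef
}

ls_rmse <- function(x, y) rmse(y, ls_fit_predict(x, y, x))

ls_rmsecv <- function(x, y, k, seed) {
  n <- nrow(x)
  fold <- cv_folds(n, k, seed)
  press <- 0
  for (f in seq_len(k)) {
    tr <- fold != f
    press <- press + sum((y[!tr, , drop = FALSE] -
                            ls_fit_predict(x[tr, , drop = FALSE],
                                           y[tr, , drop = FALSE],
                                           x[!tr, , drop = FALSE]))^2)
  }
  sqrt(press / length(y))
}

# index of maximum discrete curvature of a decreasing path
elbow_point <- function(path) {
  if (length(path) < 3) return(length(path))
  curv <- diff(diff(path))
  which.max(curv) + 1L
}

#' Competitive adaptive reweighted sampling (CARS) wavelength selection
#'
#' Iterative wavelength selection coupling Monte Carlo subsampling with PLS
#' regression coefficients. Each iteration fits a PLS model on a random
#' `mc_ratio` subset of samples using the currently retained bands; the
#' retained count then follows the exponentially decreasing function
#' `r_i = round(a * exp(-k * i))` pinned to `r_1 = B` and
#' `r_N = 2` (coarse-to-fine selection); the `r_i` bands of largest
#' coefficient magnitude survive (enforced selection) and are then resampled
#' by adaptive reweighted sampling with weights proportional to coefficient
#' magnitude (competitive selection). The cross-validated RMSE of a PLS
#' model on the retained set over all samples is recorded each iteration and
#' the retained set at the arg-min RMSECV is returned. For classification
#' the response is one-hot and RMSECV is computed on the one-hot scale.
#' Coefficient-magnitude ties break to the lower band index, and the whole
#' procedure is deterministic given `seed`.
#'
#' @param x predictor matrix or spectra table.
#' @param y response (labels one-hot encoded when `y_is_class = TRUE`).
#' @param n_iterations Monte Carlo iterations (default 50).
#' @param mc_ratio fraction of samples drawn per iteration (default 0.8).
#' @param cv_folds_n RMSECV folds (default 5).
#' @param n_latent PLS components; `NULL` picks `<= 10` by inner
#'   cross-validation on the full data.
#' @param y_is_class treat `y` as 0-based labels (default TRUE).
#' @param ars disable to make step (c) purely deterministic truncation.
#' @param seed RNG seed.
#' @return A `feature_selection` result with `rmsecv_path`,
#'   `retained_count_path`, `coefficient_path` (`B x n_iterations`) and
#'   `best_iteration`.
#' @export
cars_select <- function(x, y, n_iterations = 50, mc_ratio = 0.8,
                        cv_folds_n = 5, n_latent = NULL, y_is_class = TRUE,
                        ars = TRUE, seed = 1) {
  if (is.data.frame(x)) x <- spectra_matrix(x)
  x <- as.matrix(x)
  labels <- if (y_is_class) as.integer(y) else NULL
  ym <- if (y_is_class) one_hot(y) else as.matrix(y)
  n <- nrow(x); b <- ncol(x)
  n_iterations <- check_count(n_iterations, "n_iterations", min = 2)
  if (is.null(n_latent)) n_latent <- choose_n_latent(x, ym, seed)
  # exponentially decreasing retention schedule pinned at B and 2
  kk <- log(b / 2) / (n_iterations - 1)
  aa <- b * exp(kk)
  edf <- pmax(2L, pmin(b, as.integer(round(aa * exp(-kk * seq_len(n_iterations))))))
  retained <- seq_len(b)
  rmsecv_path <- numeric(n_iterations)
  coef_path <- matrix(0, b, n_iterations)
  retained_sets <- vector("list", n_iterations)
  with_seed(seed, {
    for (i in seq_len(n_iterations)) {
      sub <- sample(n, max(2, round(mc_ratio * n)))
      nl <- min(n_latent, length(sub) - 1, length(retained))
      m <- pls_fit(x[sub, retained, drop = FALSE], ym[sub, , drop = FALSE], nl)
      wgt <- sqrt(rowSums(m$coefficients^2))
      coef_path[retained, i] <- wgt
      r_i <- min(edf[i], length(retained))
      # enforced selection: top |coefficient|, ties to the lower band index
      ord <- order(-wgt, retained)
      keep <- retained[ord[seq_len(r_i)]]
      keep_w <- wgt[ord[seq_len(r_i)]]
      if (ars && sum(keep_w) > 0) {
        draw <- keep[sample.int(length(keep), r_i, replace = TRUE,
                                prob = keep_w)]
        retained <- sort(unique(draw))
        if (length(retained) < 2)         # clamp: never drop below 2 bands
          retained <- sort(keep[seq_len(min(2, length(keep)))])
      } else {
        retained <- sort(keep)
      }
      rmsecv_path[i] <- pls_rmsecv(x[, retained, drop = FALSE], ym,
                                   min(n_latent, length(retained)),
                                   k = cv_folds_n, seed = seed + i,
                                   labels = labels)
      retained_sets[[i]] <- retained
    }
  })
  best <- which.min(rmsecv_path)
  new_feature_selection("CARS", retained_sets[[best]], b,
                        rmsecv_path = rmsecv_path,
                        retained_count_path = edf,
                        coefficient_path = coef_path,
                        retained_sets = retained_sets,
                        best_iteration = best, n_latent = n_latent)
}

# inner-CV choice of the PLS component count, capped at 10
choose_n_latent <- function(x, ym, seed, max_latent = 10) {
  cand <- seq_len(min(max_latent, nrow(x) - 2, ncol(x)))
  errs <- vapply(cand, function(nl) pls_rmsecv(x, ym, nl, k = 5, seed = seed),
                 numeric(1))
  cand[which.min(errs)]
}

#' @rdname cars_select
#' @param object a `feature_selection` result.
#' @param ... unused.
#' @method autoplot feature_selection
#' @export
autoplot.feature_selection <- function(object, ...) {
  df <- tidy(object)
  if (object$method == "SPA") {
    ggplot2::ggplot(df, ggplot2::aes(.data$subset_size, .data$rmse)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::geom_vline(xintercept = object$subset_size, linetype = 2) +
      ggplot2::labs(x = "number of selected variables", y = "RMSE (CV)") +
      ggplot2::theme_minimal()
  } else {
    df_long <- tidyr::pivot_longer(df, c("rmsecv", "retained_count"))
    ggplot2::ggplot(df_long, ggplot2::aes(.data$iteration, .data$value)) +
      ggplot2::geom_line() +
      ggplot2::geom_vline(xintercept = object$best_iteration, linetype = 2) +
      ggplot2::facet_wrap(~ name, scales = "free_y", ncol = 1) +
      ggplot2::theme_minimal()
  }
}

#' Write a feature-selection report as text
#'
#' @param result a `feature_selection` object.
#' @param path output file.
#' @export
write_selection_report <- function(result, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("method: %s", result$method), con)
  writeLines(sprintf("n_selected: %d", length(result$selected_band_idx)), con)
  if (!is.null(result$wavelengths_nm))
    writeLines(sprintf("selected_wavelengths_nm: %s",
                       paste(result$wavelengths_nm[result$selected_band_idx],
                             collapse = ", ")), con)
  writeLines(sprintf("selected_band_idx: %s",
                     paste(result$selected_band_idx, collapse = ", ")), con)
  writeLines("", con)
  utils::write.table(tidy(result), con, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
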