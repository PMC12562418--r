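#' Partial least squares regression (NIPALS)
#'
#' Multi-response PLS2 fitted by the NIPALS algorithm on centred data. For
#' classification the response is the one-hot label matrix (PLS-DA) and
#' prediction classifies by the arg-max response column.
#'
#' @param x predictor matrix (`N x B`) or spectra table.
#' @param y response: numeric vector/matrix, or integer class labels when
#'   `y_is_class = TRUE` (one-hot encoded internally).
#' @param n_latent number of latent components,
#'   `<= min(N - 1, B)`.
#' @param y_is_class treat `y` as 0-based class labels.
#' @param tol,max_iter NIPALS inner-loop convergence controls.
#' @return A `pls_model` with weights, loadings, scores, the `B x C`
#'   regression coefficient matrix and intercept.
#' @export
pls_fit <- function(x, y, n_latent, y_is_class = FALSE, tol = 1e-10,
                    max_iter = 500) {
  if (is.data.frame(x)) x <- spectra_matrix(x)
  x <- as.matrix(x)
  if (y_is_class) y <- one_hot(y)
  y <- as.matrix(y)
  n <- nrow(x); b <- ncol(x)
  n_latent <- check_count(n_latent, "n_latent")
  if (n_latent > min(n - 1, b))
    abort("`n_latent` exceeds min(N - 1, B)", class = "spectraseed_config_error")
  x_mean <- colMeans(x); y_mean <- colMeans(y)
  e <- sweep(x, 2, x_mean); f <- sweep(y, 2, y_mean)
  W <- matrix(0, b, n_latent); P <- matrix(0, b, n_latent)
  Q <- matrix(0, ncol(y), n_latent); Tm <- matrix(0, n, n_latent)
  a_used <- 0
  for (a in seq_len(n_latent)) {
    u <- f[, which.max(apply(f, 2, stats::var))]
    if (all(abs(u) < 1e-12)) break
    w_old <- NULL
    for (it in seq_len(max_iter)) {
      w <- crossprod(e, u); w <- w / sqrt(sum(w^2))
      tt <- e %*% w
      q <- crossprod(f, tt) / sum(tt^2)
      u <- f %*% q / sum(q^2)
      if (!is.null(w_old) && sum((w - w_old)^2) < tol) break
      w_old <- w
    }
    tt_ss <- sum(tt^2)
    if (tt_ss < 1e-12) break
    p <- crossprod(e, tt) / tt_ss
    e <- e - tt %*% t(p)
    f <- f - tt %*% t(q)
    W[, a] <- w; P[, a] <- p; Q[, a] <- q; Tm[, a] <- tt
    a_used <- a
  }
  if (a_used == 0)
    abort("PLS found no usable component (constant response?)",
          class = "spectraseed_config_error")
  idx <- seq_len(a_used)
  W <- W[, idx, drop = FALSE]; P <- P[, idx, drop = FALSE]
  Q <- Q[, idx, drop = FALSE]; Tm <- Tm[, idx, drop = FALSE]
  coef <- W %*% solve(crossprod(P, W), t(Q))
  structure(list(n_latent = a_used, x_weights = W, x_loadings = P,
                 y_loadings = Q, scores = Tm, coefficients = coef,
                 intercept = y_mean - drop(x_mean %*% coef),
                 x_mean = x_mean, y_mean = y_mean,
                 classification = y_is_class),
            class = "pls_model")
}

#' @rdname pls_fit
#' @param model a fitted `pls_model`.
#' @param newdata predictor matrix or spectra table.
#' @param type `"response"` for fitted values, `"class"` for arg-max labels.
#' @export
pls_predict <- function(model, newdata, type = c("response", "class")) {
  type <- match.arg(type)
  if (is.data.frame(newdata)) newdata <- spectra_matrix(newdata)
  yhat <- sweep(as.matrix(newdata) %*% model$coefficients, 2,
                model$intercept, "+")
  if (type == "class") max.col(yhat, ties.method = "first") - 1L else yhat
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("# PLS model: %d latent components, %d predictors, %d response(s)\n",
              x$n_latent, nrow(x$coefficients), ncol(x$coefficients)))
  invisible(x)
}

#' @method glance pls_model
#' @export
glance.pls_model <- function(x, ...) {
  tibble::tibble(n_latent = x$n_latent, n_predictors = nrow(x$coefficients),
                 n_responses = ncol(x$coefficients))
}

# RMSE over all response entries
rmse <- function(y, yhat) sqrt(mean((as.matrix(y) - as.matrix(yhat))^2))

# deterministic k-fold assignment; stratified by class when labels given
cv_folds <- function(n, k, seed, labels = NULL) {
  with_seed(seed, {
    if (is.null(labels)) {
      sample(rep_len(seq_len(k), n))
    } else {
      fold <- integer(n)
      for (cl in unique(labels)) {
        idx <- which(labels == cl)
        fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
      fold
    }
  })
}

# k-fold cross-validated RMSE of a PLS model on (x, y)
pls_rmsecv <- function(x, y, n_latent, k = 5, seed = 1, labels = NULL) {
  n <- nrow(x)
  fold <- cv_folds(n, k, seed, labels)
  press <- 0
  for (f in seq_len(k)) {
    tr <- fold != f
    nl <- min(n_latent, sum(tr) - 1, ncol(x))
    m <- pls_fit(x[tr, , drop = FALSE], y[tr, , drop = FALSE], nl)
    press <- press + sum((y[!tr, , drop = FALSE] -
                            pls_predict(m, x[!tr, , drop = FALSE]))^2)
  }
  sqrt(press / (n * ncol(as.matrix(y))))
}
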