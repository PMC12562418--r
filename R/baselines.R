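#' Classifier specifications
#'
#' One shared interface over the eight classifiers compared in the study:
#' an RBF-kernel support vector machine (`svm`), an extreme learning machine
#' (`elm`: one random sigmoid hidden layer with a ridge-regularised
#' closed-form readout), a two-hidden-layer backpropagation perceptron
#' (`bp`), a long short-term memory network over the band sequence
#' (`lstm`), and the convolutional family sharing the spectral-net engine:
#' `cnn1d` (plain conv front end), `rescnn1d` (residual front end),
#' `mambacnn1d` (plain front end + Mamba blocks) and `rm1dnet` (residual
#' front end + Mamba blocks).
#'
#' Hyperparameters are validated against the per-kind schema; unknown names
#' are an error.
#'
#' @param kind one of `"svm"`, `"elm"`, `"bp"`, `"lstm"`, `"cnn1d"`,
#'   `"rescnn1d"`, `"mambacnn1d"`, `"rm1dnet"`.
#' @param ... kind-specific hyperparameters overriding the defaults below.
#' @return A `baseline_spec`.
#' @export
baseline_spec <- function(kind = c("svm", "elm", "bp", "lstm", "cnn1d",
                                   "rescnn1d", "mambacnn1d", "rm1dnet"), ...) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    svm = list(cost_grid = c(1, 10, 100), gamma_scale = c(0.5, 1, 2),
               cv_folds = 3),
    elm = list(hidden = 1000, ridge = 1e-3),
    bp = list(hidden = c(256, 128), epochs = 80, learning_rate = 1e-3,
              batch_size = 64),
    lstm = list(hidden = 128, epochs = 40, learning_rate = 1e-3,
                batch_size = 64),
    list(residual_channels = c(64, 128, 256), kernel_size = 3,
         n_mamba_blocks = 2, state_dim = 16, conv_kernel = 4, expand = 2,
         dropout = 0.3))
  extra <- list(...)
  unknown <- setdiff(names(extra), names(defaults))
  if (length(unknown) > 0)
    abort(sprintf("unknown hyperparameter(s) for %s: %s", kind,
                  paste(unknown, collapse = ", ")),
          class = "spectraseed_config_error")
  structure(list(kind = kind, hyper = modifyList(defaults, extra)),
            class = "baseline_spec")
}

deep_kinds <- c("cnn1d", "rescnn1d", "mambacnn1d", "rm1dnet")

# next multiple of 2^n_stages so pooling halves cleanly; spectra with other
# band counts (e.g. after wavelength selection) are zero-padded
pad_bands_to <- function(b, n_stages = 3) as.integer(ceiling(b / 2^n_stages) * 2^n_stages)

pad_matrix <- function(x, to) {
  if (ncol(x) == to) return(x)
  cbind(x, matrix(0, nrow(x), to - ncol(x)))
}

#' Fit a classifier to a training spectra table
#'
#' Inputs are expected standardized (see [standardize_spectra()]). Deep
#' kinds carve a stratified validation fraction out of the training set for
#' the plateau scheduler and early stopping; band counts that do not divide
#' by the pooling factor are zero-padded.
#'
#' @param data training spectra table with labels.
#' @param spec a [baseline_spec()].
#' @param n_classes total class count (inferred from labels when missing).
#' @param config a [train_config()] for the deep kinds.
#' @param seed RNG seed covering initialisation, shuffling and dropout.
#' @return A fitted `seed_classifier`.
#' @export
fit_baseline <- function(data, spec, n_classes = NULL,
                         config = train_config(), seed = 1) {
  stopifnot(inherits(spec, "baseline_spec"))
  x <- spectra_matrix(data)
  y <- spectra_labels(data)
  if (is.null(n_classes)) n_classes <- max(y) + 1L
  h <- spec$hyper
  fitted <- with_seed(seed, switch(spec$kind,
    svm = fit_svm(x, y, h),
    elm = fit_elm(x, y, n_classes, h),
    bp = fit_mlp(x, y, n_classes, h),
    lstm = fit_lstm(x, y, n_classes, h),
    fit_deep(x, y, n_classes, spec$kind, h, config)))
  structure(list(kind = spec$kind, fit = fitted, n_classes = n_classes,
                 spec = spec), class = "seed_classifier")
}

#' @export
print.seed_classifier <- function(x, ...) {
  cat(sprintf("# Fitted %s classifier (%d classes)\n", x$kind, x$n_classes))
  invisible(x)
}

#' @rdname fit_baseline
#' @param object a fitted `seed_classifier`.
#' @param newdata spectra table or matrix.
#' @param ... unused.
#' @return A tibble with `.pred_class` and one `.pred_<c>` probability
#'   column per class.
#' @export
predict.seed_classifier <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) spectra_matrix(newdata) else as.matrix(newdata)
  probs <- switch(object$kind,
    svm = predict_svm(object$fit, x, object$n_classes),
    elm = predict_elm(object$fit, x),
    bp = predict_mlp(object$fit, x),
    lstm = predict_lstm(object$fit, x),
    net_predict_probs(object$fit$result$net, pad_matrix(x, object$fit$pad_to)))
  colnames(probs) <- sprintf(".pred_%d", seq_len(ncol(probs)) - 1L)
  dplyr::bind_cols(
    tibble::tibble(.pred_class = max.col(probs, ties.method = "first") - 1L),
    tibble::as_tibble(probs))
}

#' @method glance seed_classifier
#' @export
glance.seed_classifier <- function(x, ...) {
  tibble::tibble(kind = x$kind, n_classes = x$n_classes)
}

# ---- SVM (RBF) with a small internal CV grid search -------------------------

fit_svm <- function(x, y, h) {
  b <- ncol(x)
  yf <- factor(y)
  grid <- expand.grid(cost = h$cost_grid, gamma = h$gamma_scale / b)
  best <- NULL; best_acc <- -Inf
  if (nrow(grid) > 1) {
    fold <- cv_folds(nrow(x), h$cv_folds, seed = 1, labels = y)
    for (i in seq_len(nrow(grid))) {
      acc <- 0
      for (f in seq_len(h$cv_folds)) {
        tr <- fold != f
        m <- e1071::svm(x[tr, , drop = FALSE], yf[tr], kernel = "radial",
                        cost = grid$cost[i], gamma = grid$gamma[i])
        acc <- acc + mean(predict(m, x[!tr, , drop = FALSE]) == yf[!tr])
      }
      if (acc > best_acc) { best_acc <- acc; best <- grid[i, ] }
    }
  } else best <- grid[1, ]
  e1071::svm(x, yf, kernel = "radial", cost = best$cost, gamma = best$gamma,
             probability = TRUE)
}

predict_svm <- function(fit, x, n_classes) {
  pr <- attr(predict(fit, x, probability = TRUE), "probabilities")
  probs <- matrix(0, nrow(x), n_classes)
  probs[, as.integer(colnames(pr)) + 1L] <- pr
  probs
}

# ---- ELM: random sigmoid features + ridge least-squares readout -------------

fit_elm <- function(x, y, n_classes, h) {
  b <- ncol(x)
  w <- matrix(runif(b * h$hidden, -1, 1), b)
  bias <- runif(h$hidden, -1, 1)
  hm <- stats::plogis(x %*% w + matrix(bias, nrow(x), h$hidden, byrow = TRUE))
  target <- one_hot(y, n_classes)
  beta <- solve(crossprod(hm) + h$ridge * diag(h$hidden), crossprod(hm, target))
  list(w = w, bias = bias, beta = beta)
}

predict_elm <- function(fit, x) {
  hm <- stats::plogis(x %*% fit$w +
                        matrix(fit$bias, nrow(x), length(fit$bias), byrow = TRUE))
  softmax_rows(hm %*% fit$beta)
}

# ---- BP: two-hidden-layer perceptron trained by backpropagation -------------

mlp_init <- function(b, hidden, n_classes) {
  dims <- c(b, hidden, n_classes)
  lapply(seq_len(length(dims) - 1), function(i)
    list(w = he_init(dims[i + 1], dims[i]), b = numeric(dims[i + 1])))
}

mlp_forward <- function(layers, x) {  # x: features x batch
  acts <- list(x)
  a <- x
  for (i in seq_along(layers)) {
    a <- layers[[i]]$w %*% a + layers[[i]]$b
    if (i < length(layers)) a <- pmax(a, 0)
    acts[[i + 1]] <- a
  }
  acts
}

mlp_backward <- function(layers, acts, dlogits) {  # dlogits: C x batch
  grads <- vector("list", length(layers))
  da <- dlogits
  for (i in rev(seq_along(layers))) {
    grads[[i]] <- list(w = da %*% t(acts[[i]]), b = rowSums(da))
    if (i > 1) da <- crossprod(layers[[i]]$w, da) * (acts[[i]] > 0)
  }
  grads
}

fit_mlp <- function(x, y, n_classes, h) {
  layers <- mlp_init(ncol(x), h$hidden, n_classes)
  opt <- adam_new(h$learning_rate)
  n <- nrow(x)
  for (epoch in seq_len(h$epochs)) {
    idx <- sample(n)
    for (start in seq(1, n, by = h$batch_size)) {
      bi <- idx[start:min(n, start + h$batch_size - 1)]
      acts <- mlp_forward(layers, t(x[bi, , drop = FALSE]))
      lg <- label_smoothing_loss_grad(t(acts[[length(acts)]]), y[bi], 0)
      grads <- mlp_backward(layers, acts, t(lg$dlogits))
      layers <- adam_step(opt, layers, grads)
    }
  }
  list(layers = layers)
}

predict_mlp <- function(fit, x) {
  acts <- mlp_forward(fit$layers, t(x))
  softmax_rows(t(acts[[length(acts)]]))
}

# ---- LSTM over the band sequence, last-state readout ------------------------

lstm_init <- function(hidden, n_classes) {
  hs <- hidden
  p <- list(wx = matrix(rnorm(4 * hs) * 0.5, 4 * hs, 1),
            wh = matrix(rnorm(4 * hs * hs) * sqrt(1 / hs), 4 * hs, hs),
            b = numeric(4 * hs),
            head_w = he_init(n_classes, hs), head_b = numeric(n_classes))
  p$b[(hs + 1):(2 * hs)] <- 1  # forget-gate bias
  p
}

# x: N x T. Returns last hidden state (H x N) plus per-step caches for BPTT.
lstm_forward <- function(p, x) {
  n <- nrow(x); tt <- ncol(x); hs <- ncol(p$wh)
  h <- matrix(0, hs, n); cst <- matrix(0, hs, n)
  caches <- vector("list", tt)
  for (t in seq_len(tt)) {
    pre <- p$wx %*% matrix(x[, t], 1) + p$wh %*% h + p$b
    i <- stats::plogis(pre[1:hs, , drop = FALSE])
    f <- stats::plogis(pre[(hs + 1):(2 * hs), , drop = FALSE])
    g <- tanh(pre[(2 * hs + 1):(3 * hs), , drop = FALSE])
    o <- stats::plogis(pre[(3 * hs + 1):(4 * hs), , drop = FALSE])
    c_new <- f * cst + i * g
    caches[[t]] <- list(i = i, f = f, g = g, o = o, c_prev = cst,
                        c = c_new, h_prev = h, x = x[, t])
    cst <- c_new
    h <- o * tanh(c_new)
  }
  list(h = h, caches = caches)
}

lstm_backward <- function(p, fw, dh_last) {
  hs <- ncol(p$wh); tt <- length(fw$caches)
  g <- list(wx = p$wx * 0, wh = p$wh * 0, b = p$b * 0)
  dh <- dh_last; dc <- dh * 0
  for (t in rev(seq_len(tt))) {
    ca <- fw$caches[[t]]
    tc <- tanh(ca$c)
    do <- dh * tc * ca$o * (1 - ca$o)
    dc <- dc + dh * ca$o * (1 - tc^2)
    di <- dc * ca$g * ca$i * (1 - ca$i)
    df <- dc * ca$c_prev * ca$f * (1 - ca$f)
    dg <- dc * ca$i * (1 - ca$g^2)
    dpre <- rbind(di, df, dg, do)
    g$wx <- g$wx + dpre %*% matrix(ca$x, ncol = 1)
    g$wh <- g$wh + dpre %*% t(ca$h_prev)
    g$b <- g$b + rowSums(dpre)
    dh <- crossprod(p$wh, dpre)
    dc <- dc * ca$f
  }
  g
}

fit_lstm <- function(x, y, n_classes, h) {
  p <- lstm_init(h$hidden, n_classes)
  opt <- adam_new(h$learning_rate)
  n <- nrow(x)
  for (epoch in seq_len(h$epochs)) {
    idx <- sample(n)
    for (start in seq(1, n, by = h$batch_size)) {
      bi <- idx[start:min(n, start + h$batch_size - 1)]
      fw <- lstm_forward(p, x[bi, , drop = FALSE])
      logits <- t(p$head_w %*% fw$h + p$head_b)
      lg <- label_smoothing_loss_grad(logits, y[bi], 0)
      dlog <- t(lg$dlogits)
      grads <- list(head_w = dlog %*% t(fw$h), head_b = rowSums(dlog))
      dh <- crossprod(p$head_w, dlog)
      grads <- c(grads, lstm_backward(p, fw, dh))
      p <- adam_step(opt, p, grads)
    }
  }
  list(params = p)
}

predict_lstm <- function(fit, x) {
  fw <- lstm_forward(fit$params, x)
  softmax_rows(t(fit$params$head_w %*% fw$h + fit$params$head_b))
}

# ---- deep conv family sharing the spectral-net engine -----------------------

fit_deep <- function(x, y, n_classes, kind, h, config) {
  pad_to <- pad_bands_to(ncol(x), length(h$residual_channels))
  x <- pad_matrix(x, pad_to)
  spec <- model_spec(
    n_bands = pad_to, n_classes = n_classes,
    residual_channels = h$residual_channels, kernel_size = h$kernel_size,
    residual = kind %in% c("rescnn1d", "rm1dnet"),
    n_mamba_blocks = if (kind %in% c("mambacnn1d", "rm1dnet")) h$n_mamba_blocks else 0,
    state_dim = h$state_dim, conv_kernel = h$conv_kernel, expand = h$expand,
    dropout = h$dropout)
  # stratified validation carve-out for the scheduler
  vs <- stratified_split(spectra_tbl(x, seq_len(ncol(x)), labels = y),
                         test_fraction = config$validation_fraction,
                         seed = sample.int(.Machine$integer.max, 1))
  net <- build_rm1dnet(spec)
  result <- train_network(net, x[vs$train_idx, , drop = FALSE], y[vs$train_idx],
                          x[vs$test_idx, , drop = FALSE], y[vs$test_idx],
                          config)
  list(result = result, pad_to = pad_to, spec = spec)
}

#' Nearest-centroid reference classifier
#'
#' Classifies each spectrum to the nearest class-mean in Euclidean distance.
#' Serves as the simple geometric oracle against which the learned models
#' are compared on synthetic data.
#'
#' @param data training spectra table.
#' @return A `nearest_centroid` object with a `predict()` method returning
#'   0-based labels.
#' @export
nearest_centroid <- function(data) {
  x <- spectra_matrix(data)
  y <- spectra_labels(data)
  classes <- sort(unique(y))
  centroids <- t(vapply(classes, function(cl)
    colMeans(x[y == cl, , drop = FALSE]), numeric(ncol(x))))
  structure(list(centroids = centroids, classes = classes),
            class = "nearest_centroid")
}

#' @export
predict.nearest_centroid <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) spectra_matrix(newdata) else as.matrix(newdata)
  d2 <- outer(rowSums(x^2), rep(1, nrow(object$centroids))) -
    2 * x %*% t(object$centroids) +
    outer(rep(1, nrow(x)), rowSums(object$centroids^2))
  object$classes[max.col(-d2, ties.method = "first")]
}
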