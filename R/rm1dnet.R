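#' Spectral network architecture specification
#'
#' Describes the family of 1D spectral classifiers built from a convolutional
#' front end and optional selective state-space (Mamba) blocks:
#'
#' * `rm1dnet`: three residual blocks (channels 64/128/256 by default), each
#'   followed by max-pooling with factor 2, then learnable positional
#'   encodings and stacked Mamba blocks over the pooled sequence, a dropout
#'   layer and a fully connected classification head.
#' * `rescnn1d`: the same with zero Mamba blocks (pure residual CNN).
#' * `mambacnn1d`: plain (non-residual) convolution stages plus Mamba blocks.
#' * `cnn1d`: plain convolution stages and the head only.
#'
#' @param n_bands input spectral length (default 320); must be divisible by
#'   `2 ^ length(residual_channels)` so every pooling stage halves cleanly.
#' @param n_classes number of varieties (default 20).
#' @param residual_channels per-stage output channels (default 64, 128, 256).
#' @param kernel_size front-end convolution kernel (default 3).
#' @param residual use residual blocks (FALSE gives the plain conv stages).
#' @param n_mamba_blocks stacked Mamba blocks after the front end
#'   (default 2; 0 removes the state-space stage and positional encoding).
#' @param state_dim,conv_kernel,expand,dt_rank Mamba internals, see
#'   [mamba_block_params()].
#' @param dropout dropout probability before the head (default 0.3).
#' @return A `model_spec` list.
#' @export
model_spec <- function(n_bands = 320, n_classes = 20,
                       residual_channels = c(64, 128, 256), kernel_size = 3,
                       residual = TRUE, n_mamba_blocks = 2, state_dim = 16,
                       conv_kernel = 4, expand = 2, dt_rank = NULL,
                       dropout = 0.3) {
  n_bands <- check_count(n_bands, "n_bands", min = 2)
  n_stages <- length(residual_channels)
  if (n_bands %% 2^n_stages != 0 || n_bands %/% 2^n_stages < 1)
    abort(sprintf("n_bands must be divisible by 2^%d with at least one position left",
                  n_stages), class = "spectraseed_config_error")
  structure(list(
    n_bands = n_bands, n_classes = check_count(n_classes, "n_classes", min = 2),
    residual_channels = as.integer(residual_channels),
    kernel_size = check_count(kernel_size, "kernel_size"),
    residual = isTRUE(residual),
    n_mamba_blocks = check_count(n_mamba_blocks, "n_mamba_blocks", min = 0),
    state_dim = check_count(state_dim, "state_dim"),
    conv_kernel = check_count(conv_kernel, "conv_kernel"),
    expand = check_count(expand, "expand"),
    dt_rank = dt_rank, dropout = check_nonneg(dropout, "dropout"),
    seq_len_out = n_bands %/% 2^n_stages),
    class = "model_spec")
}

#' Build a spectral network
#'
#' Instantiates parameters for a [model_spec()]. Initialisation draws from
#' the current RNG stream (seed it, or pass `seed`, for reproducible
#' weights).
#'
#' @param spec a [model_spec()].
#' @param seed optional RNG seed for the initialisation.
#' @return A `spectral_net` with `spec` and a nested `params` list.
#' @export
build_rm1dnet <- function(spec = model_spec(), seed = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  with_seed(seed, {
    chans <- c(1L, spec$residual_channels)
    stages <- lapply(seq_along(spec$residual_channels), function(i) {
      if (spec$residual) {
        residual_block_params(chans[i], chans[i + 1], spec$kernel_size)
      } else {
        list(conv1_w = he_init(chans[i + 1], chans[i] * spec$kernel_size),
             conv1_b = numeric(chans[i + 1]),
             kernel_size = spec$kernel_size, residual = FALSE)
      }
    })
    d_model <- utils::tail(spec$residual_channels, 1)
    l_out <- spec$seq_len_out
    params <- list(stages = stages)
    if (spec$n_mamba_blocks > 0) {
      params$posenc <- matrix(rnorm(d_model * l_out) * 0.02, d_model, l_out)
      params$mamba <- lapply(seq_len(spec$n_mamba_blocks), function(i)
        mamba_block_params(d_model, spec$state_dim, spec$conv_kernel,
                           spec$expand, spec$dt_rank))
      # pre-normalisation per block keeps the state-space branch input at
      # unit scale (the standard Mamba backbone arrangement)
      params$mamba_ln <- lapply(seq_len(spec$n_mamba_blocks), function(i)
        list(gamma = rep(1, d_model), beta = numeric(d_model)))
    }
    params$head_w <- he_init(spec$n_classes, d_model * l_out)
    params$head_b <- numeric(spec$n_classes)
    structure(list(spec = spec, params = params), class = "spectral_net")
  })
}

#' @export
print.spectral_net <- function(x, ...) {
  s <- x$spec
  kind <- if (s$residual && s$n_mamba_blocks > 0) "residual + Mamba"
  else if (s$residual) "residual"
  else if (s$n_mamba_blocks > 0) "plain conv + Mamba"
  else "plain conv"
  cat(sprintf("# Spectral net (%s): %d bands -> %s channels -> L=%d%s -> %d classes (%s params)\n",
              kind, s$n_bands, paste(s$residual_channels, collapse = "/"),
              s$seq_len_out,
              if (s$n_mamba_blocks > 0) sprintf(" -> %d Mamba", s$n_mamba_blocks) else "",
              s$n_classes, format(n_params(x$params), big.mark = ",")))
  invisible(x)
}

n_params <- function(p) {
  if (is.list(p)) sum(vapply(p, n_params, numeric(1)))
  else if (is.numeric(p)) length(p)
  else 0
}

# X: N x n_bands matrix -> (1, n_bands, N) activation array
input_to_array <- function(x) {
  x <- as.matrix(x)
  array(t(x), c(1L, ncol(x), nrow(x)))
}

# forward pass; returns logits (N x C) and the caches needed for backprop.
# The convolutional stages and pre-normalised Mamba blocks run as fused
# compiled kernels; only stage-boundary activations cross into R.
net_forward <- function(net, x, training = FALSE, dropout_mask = NULL) {
  spec <- net$spec; p <- net$params
  a <- input_to_array(x)
  stage_inputs <- list()
  for (i in seq_along(p$stages)) {
    stage_inputs[[i]] <- a
    a <- nn_stage_forward(a, p$stages[[i]])
  }
  mamba_inputs <- list()
  if (spec$n_mamba_blocks > 0) {
    a <- a + as.vector(p$posenc)        # broadcast (C, L) over batch
    for (j in seq_along(p$mamba)) {
      mamba_inputs[[j]] <- a
      mp <- p$mamba[[j]]; ln <- p$mamba_ln[[j]]
      a <- nn_mamba_pre_forward(a, ln$gamma, ln$beta, mp$W_in, mp$conv_w,
                                mp$conv_b, mp$W_x, mp$W_dt, mp$b_dt,
                                mp$A_log, mp$D, mp$W_out)
    }
  }
  d <- dim(a)
  flat <- matrix(a, d[1] * d[2], d[3])  # features x batch
  if (training && spec$dropout > 0) {
    if (is.null(dropout_mask))
      dropout_mask <- matrix((runif(length(flat)) >= spec$dropout) /
                               (1 - spec$dropout), nrow(flat))
    flat_d <- flat * dropout_mask
  } else {
    dropout_mask <- NULL
    flat_d <- flat
  }
  logits <- t(p$head_w %*% flat_d + p$head_b)
  list(logits = logits,
       cache = list(stage_inputs = stage_inputs, mamba_inputs = mamba_inputs,
                    flat = flat, dropout_mask = dropout_mask, a_dim = d))
}

# backward pass; returns gradients in the same nested structure as params
net_backward <- function(net, cache, dlogits) {
  spec <- net$spec; p <- net$params
  grads <- list()
  flat_d <- if (is.null(cache$dropout_mask)) cache$flat
  else cache$flat * cache$dropout_mask
  grads$head_w <- t(dlogits) %*% t(flat_d)
  grads$head_b <- colSums(dlogits)
  dflat <- crossprod(p$head_w, t(dlogits))
  if (!is.null(cache$dropout_mask)) dflat <- dflat * cache$dropout_mask
  da <- array(dflat, cache$a_dim)
  if (spec$n_mamba_blocks > 0) {
    grads$mamba <- vector("list", length(p$mamba))
    grads$mamba_ln <- vector("list", length(p$mamba))
    for (j in rev(seq_along(p$mamba))) {
      mp <- p$mamba[[j]]; ln <- p$mamba_ln[[j]]
      g <- nn_mamba_pre_backward(cache$mamba_inputs[[j]], ln$gamma, ln$beta,
                                 mp$W_in, mp$conv_w, mp$conv_b, mp$W_x,
                                 mp$W_dt, mp$b_dt, mp$A_log, mp$D, mp$W_out,
                                 da)
      grads$mamba[[j]] <- list(W_in = g$dW_in, conv_w = g$dconv_w,
                               conv_b = g$dconv_b, W_x = g$dW_x,
                               W_dt = g$dW_dt, b_dt = g$db_dt,
                               A_log = g$dA_log, D = g$dD, W_out = g$dW_out)
      grads$mamba_ln[[j]] <- list(gamma = g$dln_gamma, beta = g$dln_beta)
      da <- g$dx
    }
    grads$posenc <- matrix(rowSums(matrix(da, cache$a_dim[1] * cache$a_dim[2],
                                          cache$a_dim[3])),
                           cache$a_dim[1], cache$a_dim[2])
  }
  grads$stages <- vector("list", length(p$stages))
  for (i in rev(seq_along(p$stages))) {
    sb <- nn_stage_backward(cache$stage_inputs[[i]], p$stages[[i]], da)
    da <- sb$dx
    sb$dx <- NULL
    grads$stages[[i]] <- sb
  }
  grads
}

#' Predict class probabilities from a spectral network
#'
#' @param net a `spectral_net`.
#' @param x `N x n_bands` matrix or spectra table.
#' @param batch_size forward batch size.
#' @return `N x n_classes` matrix of softmax probabilities.
#' @export
net_predict_probs <- function(net, x, batch_size = 256) {
  if (is.data.frame(x)) x <- spectra_matrix(x)
  x <- as.matrix(x)
  n <- nrow(x)
  out <- matrix(0, n, net$spec$n_classes)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(n, start + batch_size - 1)
    out[idx, ] <- softmax_rows(net_forward(net, x[idx, , drop = FALSE])$logits)
  }
  out
}
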