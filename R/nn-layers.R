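# Building blocks of the 1D spectral networks. Activations are
# (channels, length, batch) arrays; the heavy kernels live in compiled code.

he_init <- function(n_out, n_in) {
  matrix(rnorm(n_out * n_in) * sqrt(2 / n_in), n_out, n_in)
}

#' Residual 1D convolution block
#'
#' Two same-padded 1D convolutions with ReLU between them, layer
#' normalization over channels, and a skip connection; when the input and
#' output channel counts differ the skip path applies a 1x1 convolution.
#' The block preserves sequence length: `y = LN(conv2(relu(conv1(x)))) + P(x)`.
#'
#' @param in_channels,out_channels channel counts.
#' @param kernel_size convolution kernel (default 3, same padding).
#' @return A parameter list for [residual_block_forward()].
#' @export
residual_block_params <- function(in_channels, out_channels, kernel_size = 3) {
  p <- list(
    conv1_w = he_init(out_channels, in_channels * kernel_size),
    conv1_b = numeric(out_channels),
    conv2_w = he_init(out_channels, out_channels * kernel_size),
    conv2_b = numeric(out_channels),
    ln_gamma = rep(1, out_channels),
    ln_beta = numeric(out_channels),
    kernel_size = kernel_size, residual = TRUE)
  if (in_channels != out_channels)
    p$proj_w <- he_init(out_channels, in_channels)
  p
}

#' @rdname residual_block_params
#' @param x `(channels, length, batch)` array.
#' @param params from [residual_block_params()].
#' @export
residual_block_forward <- function(x, params) {
  residual_block_fwd(x, params)$y
}

residual_block_fwd <- function(x, p) {
  k <- p$kernel_size
  a1 <- nn_conv1d_forward(x, p$conv1_w, p$conv1_b, k)
  r1 <- pmax(a1, 0)
  a2 <- nn_conv1d_forward(r1, p$conv2_w, p$conv2_b, k)
  ln <- nn_layernorm_forward(a2, p$ln_gamma, p$ln_beta, 1e-5)
  skip <- if (!is.null(p$proj_w)) {
    nn_conv1d_forward(x, p$proj_w, numeric(nrow(p$proj_w)), 1L)
  } else x
  list(y = ln + skip, x = x, a1 = a1, r1 = r1, a2 = a2)
}

residual_block_bwd <- function(cache, p, dy) {
  k <- p$kernel_size
  g <- list()
  ln_b <- nn_layernorm_backward(cache$a2, p$ln_gamma, dy, 1e-5)
  g$ln_gamma <- ln_b$dgamma; g$ln_beta <- ln_b$dbeta
  c2 <- nn_conv1d_backward(cache$r1, p$conv2_w, ln_b$dx, k)
  g$conv2_w <- c2$dw; g$conv2_b <- c2$db
  da1 <- c2$dx * (cache$a1 > 0)
  c1 <- nn_conv1d_backward(cache$x, p$conv1_w, da1, k)
  g$conv1_w <- c1$dw; g$conv1_b <- c1$db
  dx <- c1$dx
  if (!is.null(p$proj_w)) {
    pr <- nn_conv1d_backward(cache$x, p$proj_w, dy, 1L)
    g$proj_w <- pr$dw
    dx <- dx + pr$dx
  } else {
    dx <- dx + dy
  }
  list(dx = dx, grads = g)
}

#' Selective state-space (Mamba) block
#'
#' A gated selective state-space layer: the input is projected to an
#' expanded width (two branches), branch one passes through a depthwise
#' causal convolution and SiLU, then a selective SSM scan whose step size
#' `Delta`, input matrix `B` and output matrix `C` are data-dependent
#' projections (the learned state matrix `A` is negative-real diagonal, one
#' ramp per channel); branch two gates the scan output multiplicatively via
#' SiLU; an output projection returns to model width and the block output is
#' added to its input (residual). Shape is preserved, and the scan is
#' causal: position `t` only sees positions `<= t`.
#'
#' @param model_dim channel width of the block input.
#' @param state_dim SSM state size per channel (default 16).
#' @param conv_kernel depthwise causal convolution width (default 4).
#' @param expand expansion factor of the inner width (default 2).
#' @param dt_rank rank of the `Delta` projection; default
#'   `ceiling(model_dim / 16)`.
#' @return A parameter list for [mamba_block_forward()].
#' @export
mamba_block_params <- function(model_dim, state_dim = 16, conv_kernel = 4,
                               expand = 2, dt_rank = NULL) {
  di <- expand * model_dim
  if (is.null(dt_rank)) dt_rank <- ceiling(model_dim / 16)
  # Delta bias so that softplus(b_dt) starts in [1e-3, 1e-1]
  dt0 <- exp(runif(di, log(1e-3), log(1e-1)))
  p <- list(
    W_in = matrix(rnorm(2 * di * model_dim) * sqrt(1 / model_dim), 2 * di),
    conv_w = matrix(rnorm(di * conv_kernel) * sqrt(1 / conv_kernel), di),
    conv_b = numeric(di),
    W_x = matrix(rnorm((dt_rank + 2 * state_dim) * di) * sqrt(1 / di),
                 dt_rank + 2 * state_dim),
    W_dt = matrix(rnorm(di * dt_rank) * sqrt(1 / dt_rank), di),
    b_dt = log(expm1(dt0)),
    A_log = matrix(log(seq_len(state_dim)), di, state_dim, byrow = TRUE),
    D = rep(1, di),
    W_out = matrix(rnorm(model_dim * di) * sqrt(1 / di), model_dim))
  p
}

#' @rdname mamba_block_params
#' @param x `(model_dim, length, batch)` array.
#' @param params from [mamba_block_params()].
#' @export
mamba_block_forward <- function(x, params) {
  p <- params
  nn_mamba_forward(x, p$W_in, p$conv_w, p$conv_b, p$W_x, p$W_dt, p$b_dt,
                   p$A_log, p$D, p$W_out)
}

mamba_block_bwd <- function(x, p, dy) {
  g <- nn_mamba_backward(x, p$W_in, p$conv_w, p$conv_b, p$W_x, p$W_dt,
                         p$b_dt, p$A_log, p$D, p$W_out, dy)
  list(dx = g$dx,
       grads = list(W_in = g$dW_in, conv_w = g$dconv_w, conv_b = g$dconv_b,
                    W_x = g$dW_x, W_dt = g$dW_dt, b_dt = g$db_dt,
                    A_log = g$dA_log, D = g$dD, W_out = g$dW_out))
}

#' Label-smoothing cross-entropy loss
#'
#' The smoothed target puts weight `(1 - epsilon) + epsilon / C` on the true
#' class and `epsilon / C` on every other class, and the loss is the
#' cross-entropy of the softmax predictions against that distribution,
#' averaged over the batch. `epsilon = 0` recovers the standard
#' cross-entropy.
#'
#' @param logits `N x C` matrix of unnormalised scores.
#' @param true_class integer labels in `0..C-1`.
#' @param epsilon smoothing factor in `[0, 1)` (default 0.1).
#' @return Scalar mean loss.
#' @export
label_smoothing_loss <- function(logits, true_class, epsilon = 0.1) {
  label_smoothing_loss_grad(logits, true_class, epsilon)$loss
}

label_smoothing_loss_grad <- function(logits, true_class, epsilon = 0.1) {
  if (epsilon < 0 || epsilon >= 1)
    abort("`epsilon` must be in [0, 1)", class = "spectraseed_config_error")
  logits <- as.matrix(logits)
  n <- nrow(logits); cc <- ncol(logits)
  # stable log-softmax
  mx <- apply(logits, 1, max)
  z <- logits - mx
  lse <- log(rowSums(exp(z)))
  logp <- z - lse
  target <- matrix(epsilon / cc, n, cc)
  target[cbind(seq_len(n), as.integer(true_class) + 1L)] <-
    (1 - epsilon) + epsilon / cc
  loss <- -mean(rowSums(target * logp))
  p <- exp(logp)
  list(loss = loss, dlogits = (p - target) / n, probs = p)
}

softmax_rows <- function(logits) {
  z <- exp(logits - apply(logits, 1, max))
  z / rowSums(z)
}
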