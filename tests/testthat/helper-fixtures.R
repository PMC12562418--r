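# Shared fixtures and independent reference implementations used as oracles.

tiny_cfg <- function(...) {
  args <- utils::modifyList(list(n_classes = 4, seeds_per_class = 10,
                                 n_bands = 64, rng_seed = 7), list(...))
  do.call(synth_config, args)
}

# a small, clearly separable two-class problem for classifier sanity checks
separable_sets <- function() {
  cfg <- synth_config(n_classes = 2, seeds_per_class = 100, n_bands = 64,
                      class_separation = 3, noise_sd = 0.005, rng_seed = 4)
  sp <- generate_spectra(cfg)
  div <- stratified_split(sp, 0.25, seed = 1)
  standardize_spectra(sp[div$train_idx, ], test = sp[div$test_idx, ])
}

# long enough to converge on the easy separable problem
sanity_train_config <- function() {
  train_config(max_epochs = 60, batch_size = 16, scheduler_patience = 15,
               early_stop_patience = 45, validation_fraction = 0.3,
               n_runs = 1, seeds = 1)
}

small_deep_spec <- function(kind, ...) {
  baseline_spec(kind, residual_channels = c(8, 16, 16), state_dim = 4,
                dropout = 0.1, ...)
}

small_train_config <- function(...) {
  args <- utils::modifyList(
    list(max_epochs = 40, batch_size = 8, scheduler_patience = 8,
         early_stop_patience = 16, validation_fraction = 0.25,
         n_runs = 1, seeds = 1), list(...))
  if (is.null(list(...)$seeds) && !is.null(list(...)$n_runs))
    args$seeds <- seq_len(args$n_runs)
  do.call(train_config, args)
}

# ---- double-precision R reference for the Mamba block (oracle) --------------

silu_ref <- function(v) v / (1 + exp(-v))

mamba_ref_forward <- function(p, x) {
  d <- dim(x)[1]; L <- dim(x)[2]; N <- dim(x)[3]
  di <- nrow(p$conv_w); K <- ncol(p$conv_w)
  st <- ncol(p$A_log); dtr <- ncol(p$W_dt)
  out <- x * 0
  for (n in seq_len(N)) {
    u <- matrix(x[, , n], d, L)
    xz <- p$W_in %*% u
    x1 <- xz[1:di, , drop = FALSE]
    z <- xz[(di + 1):(2 * di), , drop = FALSE]
    x1c <- matrix(0, di, L)
    for (t in seq_len(L)) {
      acc <- p$conv_b
      for (j in seq_len(K)) {
        src <- t - (K - 1) + j - 1
        if (src >= 1) acc <- acc + p$conv_w[, j] * x1[, src]
      }
      x1c[, t] <- acc
    }
    xa <- silu_ref(x1c)
    dbc <- p$W_x %*% xa
    dr <- dbc[1:dtr, , drop = FALSE]
    Bm <- dbc[dtr + (1:st), , drop = FALSE]
    Cm <- dbc[dtr + st + (1:st), , drop = FALSE]
    delta <- log1p(exp(p$W_dt %*% dr + p$b_dt))
    A <- -exp(p$A_log)
    h <- matrix(0, di, st)
    ys <- matrix(0, di, L)
    for (t in seq_len(L)) {
      h <- exp(A * delta[, t]) * h + (delta[, t] * xa[, t]) %*% t(Bm[, t])
      ys[, t] <- h %*% Cm[, t] + p$D * xa[, t]
    }
    out[, , n] <- u + p$W_out %*% (ys * silu_ref(z))
  }
  out
}

random_mamba_params <- function(d = 4, di = 8, st = 3, K = 4, dtr = 2) {
  list(W_in = matrix(rnorm(2 * di * d) * 0.3, 2 * di),
       conv_w = matrix(rnorm(di * K) * 0.3, di),
       conv_b = rnorm(di) * 0.1,
       W_x = matrix(rnorm((dtr + 2 * st) * di) * 0.3, dtr + 2 * st),
       W_dt = matrix(rnorm(di * dtr) * 0.3, di),
       b_dt = rnorm(di) * 0.1,
       A_log = matrix(log(matrix(seq_len(st), di, st, byrow = TRUE)), di),
       D = rnorm(di) * 0.5,
       W_out = matrix(rnorm(d * di) * 0.3, d))
}

# brute-force SPA step: project every column onto the orthogonal complement
# of the selected columns' span using a fresh QR factorisation each time
spa_oracle_chain <- function(x, start, max_vars) {
  chain <- start
  b <- ncol(x)
  while (length(chain) < max_vars) {
    qsel <- qr.Q(qr(x[, chain, drop = FALSE]))
    norms <- rep(-Inf, b)
    for (j in setdiff(seq_len(b), chain)) {
      r <- x[, j] - qsel %*% crossprod(qsel, x[, j])
      norms[j] <- sum(r^2)
    }
    if (max(norms) < 1e-20) break
    chain <- c(chain, which.max(norms))
  }
  chain
}

# brute-force largest inscribed rectangle via integral image
lir_oracle_area <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  ii <- apply(apply(mask, 2, cumsum), 1, cumsum)  # ii[c, r] after transpose
  s <- function(r1, r2, c1, c2) {                 # inclusive 1-based sums
    tot <- ii[c2, r2]
    if (r1 > 1) tot <- tot - ii[c2, r1 - 1]
    if (c1 > 1) tot <- tot - ii[c1 - 1, r2]
    if (r1 > 1 && c1 > 1) tot <- tot + ii[c1 - 1, r1 - 1]
    tot
  }
  best <- 0
  for (r1 in 1:nr) for (r2 in r1:nr) for (c1 in 1:nc) for (c2 in c1:nc) {
    area <- (r2 - r1 + 1) * (c2 - c1 + 1)
    if (area > best && s(r1, r2, c1, c2) == area) best <- area
  }
  best
}

roi_area <- function(r) (r$row_end - r$row_start) * (r$col_end - r$col_start)

roi_inside_mask <- function(r, mask) {
  all(mask[(r$row_start + 1):r$row_end, (r$col_start + 1):r$col_end])
}


# ---- double-precision R reference for the full spectral network -------------

conv_ref <- function(x, w, b, k) {        # x: (C_in, L, N)
  ci <- dim(x)[1]; L <- dim(x)[2]; N <- dim(x)[3]
  co <- nrow(w)
  padl <- (k - 1) %/% 2
  y <- array(0, c(co, L, N))
  for (n in seq_len(N)) for (t in seq_len(L)) {
    acc <- b
    for (j in seq_len(k)) {
      src <- t + (j - 1) - padl
      if (src >= 1 && src <= L)
        acc <- acc + w[, (j - 1) * ci + seq_len(ci), drop = FALSE] %*% x[, src, n]
    }
    y[, t, n] <- acc
  }
  y
}

ln_ref <- function(x, g, b, eps = 1e-5) {
  y <- x
  for (n in seq_len(dim(x)[3])) for (t in seq_len(dim(x)[2])) {
    v <- x[, t, n]
    mu <- mean(v)
    y[, t, n] <- g * (v - mu) / sqrt(mean((v - mu)^2) + eps) + b
  }
  y
}

pool_ref <- function(x) {
  L <- dim(x)[2]
  y <- array(0, c(dim(x)[1], L / 2, dim(x)[3]))
  for (t in seq_len(L / 2))
    y[, t, ] <- pmax(x[, 2 * t - 1, , drop = FALSE],
                     x[, 2 * t, , drop = FALSE])[, 1, ]
  y
}

net_ref_forward <- function(net, x) {
  spec <- net$spec; p <- net$params
  a <- array(t(as.matrix(x)), c(1, ncol(x), nrow(x)))
  for (i in seq_along(p$stages)) {
    sp <- p$stages[[i]]
    a1 <- conv_ref(a, sp$conv1_w, sp$conv1_b, sp$kernel_size)
    r1 <- pmax(a1, 0)
    if (isTRUE(sp$residual)) {
      a2 <- conv_ref(r1, sp$conv2_w, sp$conv2_b, sp$kernel_size)
      out <- ln_ref(a2, sp$ln_gamma, sp$ln_beta)
      skip <- if (!is.null(sp$proj_w))
        conv_ref(a, sp$proj_w, numeric(nrow(sp$proj_w)), 1) else a
      a <- pool_ref(out + skip)
    } else {
      a <- pool_ref(r1)
    }
  }
  if (spec$n_mamba_blocks > 0) {
    a <- a + as.vector(p$posenc)
    for (j in seq_along(p$mamba)) {
      an <- ln_ref(a, p$mamba_ln[[j]]$gamma, p$mamba_ln[[j]]$beta)
      a <- a + (mamba_ref_forward(p$mamba[[j]], an) - an)
    }
  }
  flat <- matrix(a, prod(dim(a)[1:2]), dim(a)[3])
  t(p$head_w %*% flat + p$head_b)
}
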