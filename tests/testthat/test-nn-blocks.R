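test_that("conv kernel matches a direct same-padded convolution", {
  set.seed(1)
  x <- array(rnorm(2 * 6 * 2), c(2, 6, 2))
  w <- matrix(rnorm(3 * 6) * 0.5, 3)   # (C_out = 3, C_in * k = 6)
  b <- rnorm(3)
  y <- spectraseed:::nn_conv1d_forward(x, w, b, 3L)
  ref <- array(0, c(3, 6, 2))
  for (n in 1:2) for (t in 1:6) for (co in 1:3) {
    acc <- b[co]
    for (j in 1:3) {
      src <- t + j - 2
      if (src >= 1 && src <= 6)
        for (ci in 1:2) acc <- acc + w[co, (j - 1) * 2 + ci] * x[ci, src, n]
    }
    ref[co, t, n] <- acc
  }
  expect_equal(y, ref, tolerance = 1e-5)
})

test_that("layer kernels pass finite-difference gradient checks", {
  set.seed(2)
  relerr <- function(a, b) max(abs(a - b)) / (max(abs(b)) + 1e-8)
  fd <- function(f, v, eps = 1e-3) {
    g <- v * 0
    for (i in seq_along(v)) {
      vp <- v; vp[i] <- v[i] + eps
      vm <- v; vm[i] <- v[i] - eps
      g[i] <- (f(vp) - f(vm)) / (2 * eps)
    }
    g
  }
  C <- 3; L <- 8; N <- 2; k <- 3
  x <- array(rnorm(C * L * N), c(C, L, N))
  w <- matrix(rnorm(4 * C * k) * 0.3, 4)
  b <- rnorm(4) * 0.1
  dy <- array(rnorm(4 * L * N), c(4, L, N))
  g <- spectraseed:::nn_conv1d_backward(x, w, dy, k)
  expect_lt(relerr(g$dx, fd(function(v)
    sum(spectraseed:::nn_conv1d_forward(array(v, dim(x)), w, b, k) * dy),
    c(x))), 1e-3)
  expect_lt(relerr(g$dw, fd(function(v)
    sum(spectraseed:::nn_conv1d_forward(x, matrix(v, 4), b, k) * dy),
    c(w))), 1e-3)
  # maxpool
  dyp <- array(rnorm(C * L / 2 * N), c(C, L / 2, N))
  gp <- spectraseed:::nn_maxpool2_backward(x, dyp)
  expect_lt(relerr(gp, fd(function(v)
    sum(spectraseed:::nn_maxpool2_forward(array(v, dim(x))) * dyp), c(x),
    eps = 1e-4)), 1e-2)
  # layernorm
  ga <- rnorm(C) + 1; be <- rnorm(C) * 0.1
  dyl <- array(rnorm(C * L * N), c(C, L, N))
  gl <- spectraseed:::nn_layernorm_backward(x, ga, dyl, 1e-5)
  expect_lt(relerr(gl$dx, fd(function(v)
    sum(spectraseed:::nn_layernorm_forward(array(v, dim(x)), ga, be, 1e-5) * dyl),
    c(x))), 2e-3)
  expect_lt(relerr(gl$dgamma, fd(function(v)
    sum(spectraseed:::nn_layernorm_forward(x, v, be, 1e-5) * dyl), ga)), 1e-3)
})

test_that("the Mamba kernel reproduces a double-precision reference forward", {
  set.seed(3)
  p <- random_mamba_params()
  x <- array(rnorm(4 * 6 * 2), c(4, 6, 2))
  mine <- mamba_block_forward(x, p)
  ref <- mamba_ref_forward(p, x)
  expect_lt(max(abs(mine - ref)), 1e-5)
})

test_that("Mamba parameter gradients match finite differences of the reference", {
  set.seed(4)
  p <- random_mamba_params()
  x <- array(rnorm(4 * 6 * 2), c(4, 6, 2))
  dy <- array(rnorm(4 * 6 * 2), c(4, 6, 2))
  g <- spectraseed:::mamba_block_bwd(x, p, dy)$grads
  relerr <- function(a, b) max(abs(a - b)) / (max(abs(b)) + 1e-8)
  for (nm in names(p)) {
    f <- function(v) {
      p2 <- p; p2[[nm]][] <- v
      sum(mamba_ref_forward(p2, x) * dy)
    }
    fdg <- vapply(seq_along(p[[nm]]), function(i) {
      eps <- 1e-6
      vp <- c(p[[nm]]); vm <- vp
      vp[i] <- vp[i] + eps; vm[i] <- vm[i] - eps
      (f(vp) - f(vm)) / (2 * eps)
    }, numeric(1))
    expect_lt(relerr(c(g[[nm]]), fdg), 1e-3)
  }
})

test_that("a Mamba block with zeroed output projection is the identity", {
  set.seed(5)
  p <- random_mamba_params()
  p$W_out[] <- 0
  x <- array(rnorm(4 * 5 * 3), c(4, 5, 3))
  expect_lt(max(abs(mamba_block_forward(x, p) - x)), 1e-6)
})

test_that("the Mamba scan is causal", {
  set.seed(6)
  p <- random_mamba_params()
  L <- 8
  x <- array(rnorm(4 * L * 1), c(4, L, 1))
  y0 <- mamba_block_forward(x, p)
  for (t_pert in c(3L, 6L)) {
    x2 <- x
    x2[, t_pert, 1] <- x2[, t_pert, 1] + 1
    y1 <- mamba_block_forward(x2, p)
    diff_by_t <- apply(abs(y1 - y0), 2, max)
    expect_lt(max(diff_by_t[seq_len(t_pert - 1)]), 1e-5)
    expect_gt(diff_by_t[t_pert], 1e-4)
  }
})

test_that("Mamba blocks preserve shape for short and long sequences", {
  set.seed(7)
  p <- random_mamba_params()
  for (L in c(1, 7, 40)) {
    x <- array(rnorm(4 * L * 2), c(4, L, 2))
    expect_equal(dim(mamba_block_forward(x, p)), c(4L, L, 2L))
  }
})

test_that("residual block identities hold", {
  set.seed(8)
  p <- residual_block_params(3, 3, 3)
  p$conv1_w[] <- 0; p$conv2_w[] <- 0
  x <- array(rnorm(3 * 6 * 2), c(3, 6, 2))
  # zeroed convs with equal channels: pure skip (LN of a constant is beta = 0)
  expect_lt(max(abs(residual_block_forward(x, p) - x)), 1e-5)
  expect_lt(max(abs(residual_block_forward(2 * x, p) - 2 * x)), 1e-5)
  # channel projection changes the channel count
  p2 <- residual_block_params(3, 5, 3)
  expect_equal(dim(residual_block_forward(x, p2)), c(5L, 6L, 2L))
})

test_that("label-smoothing loss limits and smoothed weights are exact", {
  set.seed(9)
  logits <- matrix(rnorm(40), 2, 20)
  truth <- c(3L, 11L)
  # epsilon = 0 is plain cross-entropy
  p <- spectraseed:::softmax_rows(logits)
  ce <- -mean(log(p[cbind(1:2, truth + 1)]))
  expect_equal(label_smoothing_loss(logits, truth, 0), ce)
  # uniform predictions give log C for any epsilon
  unif <- matrix(0, 3, 20)
  expect_equal(label_smoothing_loss(unif, c(0L, 5L, 19L), 0.1), log(20))
  expect_equal(label_smoothing_loss(unif, c(0L, 5L, 19L), 0.37), log(20))
  expect_equal(log(20), 2.9957, tolerance = 1e-4)
  # smoothed target weights at C = 20, epsilon = 0.1
  expect_equal((1 - 0.1) + 0.1 / 20, 0.905)
  expect_equal(0.1 / 20, 0.005)
  lg <- spectraseed:::label_smoothing_loss_grad(matrix(rnorm(20), 1), 4L, 0.1)
  target <- -lg$dlogits * 1 + lg$probs   # recover target from gradient
  expect_equal(unname(target[1, 5]), 0.905)
  expect_equal(unname(target[1, 1]), 0.005)
  expect_error(label_smoothing_loss(logits, truth, 1),
               class = "spectraseed_config_error")
})

test_that("the loss minimum over predictions is the smoothed target entropy", {
  eps <- 0.1; cc <- 3
  target <- c((1 - eps) + eps / cc, eps / cc, eps / cc)
  obj <- function(lg) label_smoothing_loss(matrix(lg, 1), 0L, eps)
  opt <- optim(c(0, 0, 0), obj, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 500))
  expect_equal(opt$value, -sum(target * log(target)), tolerance = 1e-5)
  p_star <- spectraseed:::softmax_rows(matrix(opt$par, 1))
  expect_equal(unname(c(p_star)), target, tolerance = 1e-3)
})
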