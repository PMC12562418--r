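test_that("SG smoothing preserves polynomials up to its degree", {
  wl <- seq(400, 700, length.out = 31)
  const <- spectra_tbl(matrix(0.5, 2, 31), wl)
  expect_equal(spectra_matrix(sg_smooth(const, 3, 1)), spectra_matrix(const))
  lin <- spectra_tbl(matrix(seq(0, 1, length.out = 31), 1, byrow = TRUE), wl)
  expect_equal(spectra_matrix(sg_smooth(lin, 5, 1)), spectra_matrix(lin),
               tolerance = 1e-12)
  # window 3, degree 2 reproduces any input exactly (why the default is degree 1)
  set.seed(1)
  noisy <- spectra_tbl(matrix(runif(31), 1), wl)
  expect_equal(spectra_matrix(sg_smooth(noisy, 3, 2)), spectra_matrix(noisy),
               tolerance = 1e-12)
})

test_that("the default 3-point degree-1 kernel is the 1/3 moving average", {
  wl <- seq(400, 500, length.out = 9)
  x <- matrix(0, 1, 9); x[1, 5] <- 3
  out <- spectra_matrix(sg_smooth(spectra_tbl(x, wl), 3, 1))
  expect_equal(unname(out[1, 4:6]), c(1, 1, 1))
})

test_that("SG smoothing agrees with the signal-package reference filter", {
  set.seed(2)
  wl <- seq(380, 1018, length.out = 50)
  x <- matrix(runif(150), 3)
  for (cfg in list(c(3, 1), c(7, 2), c(11, 3))) {
    mine <- spectra_matrix(sg_smooth(spectra_tbl(x, wl), cfg[1], cfg[2]))
    ref <- t(apply(x, 1, signal::sgolayfilt, p = cfg[2], n = cfg[1]))
    expect_equal(unname(mine), unname(ref), tolerance = 1e-10)
  }
})

test_that("SG configuration is validated", {
  sp <- generate_spectra(tiny_cfg())
  expect_error(sg_smooth(sp, 4, 1), class = "spectraseed_config_error")
  expect_error(sg_smooth(sp, 3, 3), class = "spectraseed_config_error")
  expect_error(sg_smooth(sp, 101, 1), class = "spectraseed_config_error")
})

test_that("stratified split respects per-class proportions and determinism", {
  cfg <- synth_config(n_classes = 20, seeds_per_class = 150, n_bands = 8,
                      rng_seed = 1)
  sp <- generate_spectra(cfg)
  div <- stratified_split(sp, 0.2, seed = 3)
  expect_length(div$train_idx, 2400)
  expect_length(div$test_idx, 600)
  expect_length(intersect(div$train_idx, div$test_idx), 0)
  expect_setequal(c(div$train_idx, div$test_idx), seq_len(3000))
  labs <- spectra_labels(sp)
  per_class <- table(labs[div$test_idx])
  expect_true(all(per_class == 30))
  expect_identical(stratified_split(sp, 0.2, seed = 3), div)
  expect_false(identical(stratified_split(sp, 0.2, seed = 4)$test_idx,
                         div$test_idx))
})

test_that("half split of two samples per class gives one each, and singletons fail", {
  sp2 <- generate_spectra(tiny_cfg(seeds_per_class = 2))
  div <- stratified_split(sp2, 0.5, seed = 1)
  expect_true(all(table(spectra_labels(sp2)[div$test_idx]) == 1))
  sp1 <- sp2[c(1, 3, 5, 7), ]
  expect_error(stratified_split(sp1, 0.5), class = "spectraseed_config_error")
})

test_that("standardization uses training statistics only", {
  sp <- generate_spectra(tiny_cfg())
  div <- stratified_split(sp, 0.25, seed = 2)
  std <- standardize_spectra(sp[div$train_idx, ], test = sp[div$test_idx, ])
  xtr <- spectra_matrix(std$train)
  expect_lt(max(abs(colMeans(xtr))), 1e-9)
  expect_lt(max(abs(apply(xtr, 2, sd) - 1)), 1e-9)
  # applying train stats to the train set itself reproduces it
  again <- standardize_spectra(sp[div$train_idx, ],
                               same = sp[div$train_idx, ])
  expect_equal(spectra_matrix(again$same), spectra_matrix(again$train))
  # constant bands pass through centred, with a note
  const <- sp
  const[[wl_col <- grep("^wl_", names(const), value = TRUE)[1]]] <- 1
  expect_message(out <- standardize_spectra(const), "constant band")
  expect_true(all(spectra_matrix(out$train)[, 1] == 0))
})

test_that("PCA scores and variance ratios behave as a centred decomposition", {
  sp <- generate_spectra(tiny_cfg())
  p <- pca_project(sp, 3)
  expect_equal(sum(p$explained_variance_ratio), 1)
  expect_true(all(diff(p$explained_variance_ratio) <= 1e-12))
  # rank-2 data: third component empty
  x <- matrix(rnorm(60), 30, 2) %*% matrix(rnorm(10), 2, 5)
  rank2 <- spectra_tbl(x, 1:5, labels = 0)
  p2 <- pca_project(rank2, 3)
  expect_lt(p2$explained_variance_ratio[3], 1e-12)
  # full reconstruction from all components
  pfull <- pca_project(rank2, 5)
  recon <- as.matrix(pfull$scores[, -(1:2)]) %*% t(pfull$rotation)
  recon <- sweep(recon, 2, pfull$center, "+")
  expect_equal(unname(recon), unname(x), tolerance = 1e-9)
})

test_that("LDA separates well-separated classes and validates dimensions", {
  set.seed(3)
  x <- rbind(matrix(rnorm(200, 0), 50), matrix(rnorm(200, 4), 50))
  sp <- spectra_tbl(x, 1:4, labels = rep(0:1, each = 50))
  l <- lda_project(sp, 1)
  s0 <- l$scores$.ld1[l$scores$class == 0]
  s1 <- l$scores$.ld1[l$scores$class == 1]
  expect_true(max(s0) < min(s1) || max(s1) < min(s0))
  expect_error(lda_project(sp, 2), class = "spectraseed_config_error")
})

test_that("LDA is order-invariant and tracks the MASS reference direction", {
  sp <- generate_spectra(tiny_cfg(n_bands = 16))
  l1 <- lda_project(sp, 2)
  perm <- sample(nrow(sp))
  l2 <- lda_project(sp[perm, ], 2)
  reord <- l2$scores[match(l1$scores$sample_id, l2$scores$sample_id), ]
  for (k in 1:2)
    expect_gt(abs(cor(l1$scores[[paste0(".ld", k)]],
                      reord[[paste0(".ld", k)]])), 0.999)
  skip_if_not_installed("MASS")
  m <- MASS::lda(spectra_matrix(sp), grouping = spectra_labels(sp))
  mine <- spectra_matrix(sp) %*% l1$directions[, 1]
  theirs <- spectra_matrix(sp) %*% m$scaling[, 1]
  expect_gt(abs(cor(mine, theirs)), 0.99)
})
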