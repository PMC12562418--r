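test_that("every classifier kind solves two linearly separable classes", {
  std <- separable_sets()
  truth <- spectra_labels(std$test)
  tc <- sanity_train_config()
  for (kind in c("svm", "elm", "bp", "lstm", "cnn1d", "rescnn1d",
                 "mambacnn1d", "rm1dnet")) {
    spec <- switch(kind,
      svm = baseline_spec("svm"),
      elm = baseline_spec("elm", hidden = 200),
      bp = baseline_spec("bp", hidden = c(32, 16), epochs = 50, batch_size = 8),
      lstm = baseline_spec("lstm", hidden = 16, epochs = 25, batch_size = 8),
      small_deep_spec(kind))
    m <- fit_baseline(std$train, spec, config = tc, seed = 5)
    pr <- predict(m, std$test)
    expect_equal(mean(pr$.pred_class == truth), 1,
                 label = sprintf("%s accuracy", kind))
    probs <- as.matrix(pr[, -1])
    expect_lt(max(abs(rowSums(probs) - 1)), 1e-6)
  }
})

test_that("unknown hyperparameters are rejected per kind", {
  expect_error(baseline_spec("svm", hidden = 10),
               class = "spectraseed_config_error")
  expect_error(baseline_spec("elm", cost_grid = 1),
               class = "spectraseed_config_error")
})

test_that("the ELM readout equals the explicit normal-equations solution", {
  set.seed(1)
  x <- matrix(rnorm(30 * 6), 30)
  y <- sample(0:2, 30, replace = TRUE)
  fit <- with_seed_fit <- spectraseed:::with_seed(9,
    spectraseed:::fit_elm(x, y, 3, list(hidden = 12, ridge = 1e-3)))
  h <- stats::plogis(x %*% fit$w + matrix(fit$bias, 30, 12, byrow = TRUE))
  target <- spectraseed:::one_hot(y, 3)
  beta_ref <- solve(t(h) %*% h + 1e-3 * diag(12), t(h) %*% target)
  expect_equal(fit$beta, beta_ref, tolerance = 1e-10)
})

test_that("a wide ridge-regularised ELM interpolates distinct training points", {
  set.seed(2)
  cfg <- synth_config(n_classes = 3, seeds_per_class = 10, n_bands = 24,
                      rng_seed = 3)
  sp <- generate_spectra(cfg)
  m <- fit_baseline(sp, baseline_spec("elm", hidden = 400, ridge = 1e-8),
                    seed = 4)
  pr <- predict(m, sp)
  expect_equal(mean(pr$.pred_class == spectra_labels(sp)), 1)
})

test_that("classifiers are chance-level when class structure is removed", {
  cfg <- synth_config(n_classes = 4, seeds_per_class = 25, n_bands = 24,
                      class_separation = 0, noise_sd = 0.02, rng_seed = 6)
  sp <- generate_spectra(cfg)
  div <- stratified_split(sp, 0.25, seed = 1)
  std <- standardize_spectra(sp[div$train_idx, ], test = sp[div$test_idx, ])
  truth <- spectra_labels(std$test)
  for (kind in c("svm", "elm")) {
    m <- fit_baseline(std$train, baseline_spec(kind), seed = 2)
    acc <- mean(predict(m, std$test)$.pred_class == truth)
    # 99.9% binomial band around 1/4 with n = 24
    expect_lt(abs(acc - 0.25), 0.30)
  }
})

test_that("the deep conv family beats the shallow ELM/BP mean on moderately separated data", {
  cfg <- synth_config(n_classes = 8, seeds_per_class = 60, n_bands = 64,
                      class_separation = 0.9, noise_sd = 0.03, rng_seed = 12)
  sp <- generate_spectra(cfg)
  div <- stratified_split(sp, 0.2, seed = 3)
  std <- standardize_spectra(sp[div$train_idx, ], test = sp[div$test_idx, ])
  truth <- spectra_labels(std$test)
  tc <- train_config(max_epochs = 25, batch_size = 32, scheduler_patience = 5,
                     early_stop_patience = 10, validation_fraction = 0.15,
                     n_runs = 1, seeds = 1)
  acc_of <- function(spec, seed) {
    m <- fit_baseline(std$train, spec, config = tc, seed = seed)
    mean(predict(m, std$test)$.pred_class == truth)
  }
  deep <- mean(c(
    vapply(1:2, function(s)
      acc_of(baseline_spec("rescnn1d", residual_channels = c(16, 32, 32),
                           state_dim = 4, dropout = 0.1), s), numeric(1)),
    vapply(1:2, function(s)
      acc_of(baseline_spec("cnn1d", residual_channels = c(16, 32, 32),
                           state_dim = 4, dropout = 0.1), s), numeric(1))))
  shallow <- mean(c(
    vapply(1:2, function(s) acc_of(baseline_spec("elm", hidden = 300), s),
           numeric(1)),
    vapply(1:2, function(s)
      acc_of(baseline_spec("bp", hidden = c(64, 32), epochs = 40), s),
      numeric(1))))
  expect_gt(deep, shallow)
})

test_that("nearest-centroid predictions equal the explicit distance argmin", {
  set.seed(7)
  sp <- generate_spectra(tiny_cfg())
  or <- nearest_centroid(sp)
  x <- spectra_matrix(sp)
  d <- as.matrix(dist(rbind(or$centroids, x)))[-(1:4), 1:4]
  expect_equal(predict(or, sp), or$classes[apply(d, 1, which.min)])
})
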