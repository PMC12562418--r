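test_that("PLS reaches an exact fit when Y is linear in X at full rank", {
  set.seed(1)
  x <- matrix(rnorm(150), 30, 5)
  y <- x %*% matrix(rnorm(10), 5, 2)
  m <- pls_fit(x, y, 5)
  expect_lt(rmse_val <- sqrt(mean((pls_predict(m, x) - y)^2)), 1e-8)
})

test_that("univariate PLS with one component equals ordinary least squares", {
  set.seed(2)
  x <- matrix(rnorm(25), 25, 1)
  y <- 2.5 * x[, 1] + rnorm(25, sd = 0.3)
  m <- pls_fit(x, y, 1)
  o <- stats::lm(y ~ x)
  expect_equal(m$coefficients[1, 1], unname(coef(o)[2]), tolerance = 1e-10)
  expect_equal(m$intercept[1], unname(coef(o)[1]), tolerance = 1e-10)
})

test_that("PLS coefficients are invariant to sample order and sized by B x C", {
  set.seed(3)
  x <- matrix(rnorm(200), 40, 5)
  y <- sample(0:2, 40, replace = TRUE)
  m1 <- pls_fit(x, y, 3, y_is_class = TRUE)
  perm <- sample(40)
  m2 <- pls_fit(x[perm, ], y[perm], 3, y_is_class = TRUE)
  expect_equal(m1$coefficients, m2$coefficients, tolerance = 1e-8)
  expect_equal(dim(m1$coefficients), c(5L, 3L))
  expect_error(pls_fit(x, y, 50, y_is_class = TRUE),
               class = "spectraseed_config_error")
})

test_that("SPA picks orthogonal columns in descending norm order", {
  x <- cbind(c(5, 0, 0, 0), c(0, 3, 0, 0), c(0, 0, 1, 0))
  r <- spa_select(x, c(0, 1, 0, 1), max_vars = 3, first_var = 1,
                  cv_folds_n = 2)
  expect_equal(r$chain, c(1L, 2L, 3L))
})

test_that("SPA never selects a duplicated column twice and honours max_vars = 1", {
  set.seed(4)
  x <- matrix(rnorm(40), 10, 4)
  x <- cbind(x, x[, 2])             # column 5 duplicates column 2
  y <- rnorm(10)
  r <- suppressMessages(spa_select(x, y, max_vars = 4, first_var = 2,
                                   y_is_class = FALSE))
  expect_false(all(c(2, 5) %in% r$chain))
  r1 <- spa_select(x, y, max_vars = 1, first_var = 3, y_is_class = FALSE)
  expect_equal(r1$selected_band_idx, 3L)
})

test_that("SPA chains equal the explicit Gram-Schmidt oracle on random matrices", {
  set.seed(5)
  for (trial in 1:30) {
    x <- matrix(rnorm(80), 10, 8)
    start <- sample(8, 1)
    mine <- spectraseed:::spa_chain(x, start, 5)
    expect_equal(mine, spa_oracle_chain(x, start, 5))
  }
})

test_that("SPA subset-size rules expose both the arg-min and the elbow", {
  set.seed(6)
  n <- 60
  x <- matrix(rnorm(n * 10), n)
  y <- x[, 3] - x[, 7] + rnorm(n, sd = 0.05)
  r_argmin <- spa_select(x, y, max_vars = 6, first_var = 3,
                         y_is_class = FALSE)
  r_elbow <- spa_select(x, y, max_vars = 6, first_var = 3,
                        y_is_class = FALSE, size_rule = "elbow")
  expect_equal(r_argmin$subset_size, which.min(r_argmin$rmse_path))
  expect_lte(r_elbow$subset_size, length(r_elbow$chain))
})

test_that("CARS retention schedule is nonincreasing and ends at 2", {
  set.seed(7)
  x <- matrix(rnorm(60 * 40), 60)
  y <- sample(0:1, 60, replace = TRUE)
  r <- cars_select(x, y, n_iterations = 20, n_latent = 3, seed = 1)
  expect_true(all(diff(r$retained_count_path) <= 0))
  expect_equal(r$retained_count_path[1], 40L)
  expect_equal(tail(r$retained_count_path, 1), 2L)
  expect_equal(r$best_iteration, which.min(r$rmsecv_path))
  expect_lte(r$rmsecv_path[r$best_iteration], r$rmsecv_path[1])
  expect_identical(r$selected_band_idx,
                   cars_select(x, y, n_iterations = 20, n_latent = 3,
                               seed = 1)$selected_band_idx)
})

test_that("CARS without resampling on noise-free data reduces to coefficient truncation", {
  set.seed(8)
  n <- 50; b <- 12
  x <- matrix(rnorm(n * b), n)
  y <- x[, c(2, 7, 11)] %*% c(2, -3, 2.5)
  r <- cars_select(x, y, n_iterations = 10, mc_ratio = 1, ars = FALSE,
                   n_latent = 5, y_is_class = FALSE, seed = 2)
  full <- pls_fit(x, y, 5)
  w <- sqrt(rowSums(full$coefficients^2))
  size <- length(r$selected_band_idx)
  expect_setequal(r$selected_band_idx, order(-w, seq_len(b))[seq_len(size)])
  expect_true(all(c(2, 7, 11) %in% r$selected_band_idx) || size < 3)
})

test_that("CARS recovers planted informative bands across seeds", {
  hits <- 0
  for (s in 1:4) {
    set.seed(100 + s)
    n <- 120; b <- 60
    x <- matrix(rnorm(n * b), n)
    planted <- c(5, 17, 29, 41, 53)
    y <- x[, planted] %*% c(3, -2.5, 2, 3.5, -3) + rnorm(n, sd = 0.3)
    r <- cars_select(x, y, n_iterations = 30, y_is_class = FALSE,
                     n_latent = 5, seed = s)
    hits <- hits + (length(intersect(planted, r$selected_band_idx)) >= 4)
  }
  expect_gte(hits, 3)
})

test_that("selection reports serialise with wavelengths and diagnostics", {
  set.seed(9)
  x <- matrix(rnorm(200), 20, 10)
  y <- rnorm(20)
  r <- cars_select(x, y, n_iterations = 8, n_latent = 2, y_is_class = FALSE,
                   seed = 1)
  r$wavelengths_nm <- seq(400, 850, 50)
  path <- withr::local_tempfile()
  write_selection_report(r, path)
  txt <- readLines(path)
  expect_match(txt[1], "CARS")
  expect_true(any(grepl("selected_wavelengths_nm", txt)))
  td <- tidy(r)
  expect_equal(nrow(td), 8)
  expect_named(td, c("iteration", "rmsecv", "retained_count"))
})
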