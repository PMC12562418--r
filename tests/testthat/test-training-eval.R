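test_that("the plateau scheduler halves the rate after each stagnant stretch", {
  sched <- plateau_scheduler(1e-3, factor = 0.5, patience = 5)
  acc <- c(0.5, rep(0.5, 15))      # improvement once, then flat
  lrs <- vapply(acc, sched$update, numeric(1))
  # stagnation counter starts after the initial best; halvings at epochs
  # 6, 11, 16 of this trace
  expect_equal(lrs[5], 1e-3)
  expect_equal(lrs[6], 5e-4)
  expect_equal(lrs[10], 5e-4)
  expect_equal(lrs[11], 2.5e-4)
  expect_equal(lrs[16], 1.25e-4)
})

test_that("improvement resets the early-stopping counter", {
  st <- early_stopper(patience = 10)
  for (m in c(0.6, rep(0.6, 8))) expect_false(st$update(m))
  expect_false(st$update(0.7))       # improvement at epoch 10 resets
  for (i in 1:9) expect_false(st$update(0.7))
  expect_true(st$update(0.7))        # 10th stagnant epoch stops
})

test_that("training history is finite and validation accuracy improves", {
  std <- separable_sets()
  x <- spectra_matrix(std$train); y <- spectra_labels(std$train)
  xt <- spectra_matrix(std$test); yt <- spectra_labels(std$test)
  set.seed(1)
  net <- build_rm1dnet(model_spec(n_bands = 64, n_classes = 2,
                                  residual_channels = c(4, 8, 8),
                                  state_dim = 4, dropout = 0.1))
  res <- train_network(net, x, y, xt, yt,
                       train_config(max_epochs = 15, batch_size = 8,
                                    scheduler_patience = 4,
                                    early_stop_patience = 8, n_runs = 1,
                                    seeds = 1))
  expect_true(all(is.finite(res$history$loss)))
  expect_gte(res$best_val_accuracy, res$history$val_accuracy[1])
  expect_equal(res$best_val_accuracy, max(res$history$val_accuracy))
})

test_that("confusion-derived metrics match a counting oracle on random matrices", {
  set.seed(2)
  for (trial in 1:300) {
    cc <- sample(2:8, 1)
    n <- sample(20:60, 1)
    truth <- sample(0:(cc - 1), n, replace = TRUE)
    est <- sample(0:(cc - 1), n, replace = TRUE)
    conf <- confusion_matrix(truth, est, cc)
    # brute-force per-element counts
    for (k in sample(cc, 2)) {
      tp <- sum(truth == k - 1 & est == k - 1)
      fp <- sum(truth != k - 1 & est == k - 1)
      fn <- sum(truth == k - 1 & est != k - 1)
      expect_equal(conf[k, k], tp)
      expect_equal(sum(conf[, k]) - conf[k, k], fp)
      expect_equal(sum(conf[k, ]) - conf[k, k], fn)
    }
    expect_equal(sum(diag(conf)), sum(truth == est))
    expect_equal(rowSums(conf), table(factor(truth, levels = 0:(cc - 1))) + 0,
                 ignore_attr = TRUE)
  }
})

test_that("per-class precision/recall/F1 follow their definitions with rounding", {
  m <- classification_metrics(tp = c(133, 150, 0), fp = c(14, 0, 0),
                              fn = c(17, 0, 5))
  expect_equal(m$recall[1], 88.67)
  expect_equal(m$precision[1], 90.48)   # 133 / 147
  expect_equal(m$precision[2], 100)
  expect_equal(m$recall[2], 100)
  expect_equal(m$f1[2], 100)
  expect_true(is.na(m$precision[3]))    # no positive predictions
  expect_equal(m$recall[3], 0)
  expect_equal(m$f1[3], 0)
  expect_equal(f1_from_pr(91.50, 88.70), 90.0782, tolerance = 1e-4)
})

test_that("eval reports satisfy the confusion identities", {
  set.seed(3)
  truth <- sample(0:4, 200, replace = TRUE)
  est <- ifelse(runif(200) < 0.7, truth, sample(0:4, 200, replace = TRUE))
  rep <- eval_report(truth, est, 5)
  expect_equal(sum(rep$confusion), 200)
  expect_equal(rep$per_class$tp, unname(diag(rep$confusion)))
  expect_equal(rep$accuracy, mean(truth == est) * 100)
  td <- tidy(rep)
  expect_named(td, c("class", "tp", "fp", "fn", "precision", "recall", "f1"))
  # perfect predictions
  perfect <- eval_report(truth, truth, 5)
  expect_true(all(tidy(perfect)$f1 == 100))
  expect_equal(perfect$accuracy, 100)
  # absent class flagged and excluded from macro averages
  expect_message(r2 <- eval_report(c(0, 1, 0, 1), c(0, 1, 1, 1), 3), "absent")
  expect_true(is.na(r2$per_class$recall[3]))
  expect_false(is.na(r2$macro_recall))
})

test_that("repeated evaluation reports average and highest accuracy coherently", {
  std <- separable_sets()
  ev <- repeated_eval(std$train, std$test, baseline_spec("elm", hidden = 100),
                      config = small_train_config(n_runs = 3, seeds = 1:3))
  expect_length(ev$accuracies, 3)
  expect_gte(ev$highest_accuracy, ev$average_accuracy)
  expect_equal(ev$average_accuracy, mean(ev$accuracies))
  gl <- glance(ev)
  expect_named(gl, c("model", "average_accuracy", "highest_accuracy",
                     "precision", "recall", "f1"))
})

test_that("reported percentages round half away from zero to two decimals", {
  expect_equal(spectraseed:::round_half_up(88.665), 88.67)
  expect_equal(spectraseed:::round_half_up(90.075), 90.08)
  expect_equal(spectraseed:::round_half_up(-1.005), -1.01)
})
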