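#' Confusion matrix
#'
#' Counts with rows = true class, columns = predicted class.
#'
#' @param truth,estimate 0-based integer label vectors.
#' @param n_classes class count (inferred when missing).
#' @export
confusion_matrix <- function(truth, estimate, n_classes = NULL) {
  truth <- as.integer(truth); estimate <- as.integer(estimate)
  if (is.null(n_classes)) n_classes <- max(truth, estimate) + 1L
  m <- matrix(0L, n_classes, n_classes,
              dimnames = list(true = 0:(n_classes - 1),
                              pred = 0:(n_classes - 1)))
  for (i in seq_along(truth)) m[truth[i] + 1L, estimate[i] + 1L] <-
      m[truth[i] + 1L, estimate[i] + 1L] + 1L
  m
}

#' Per-class classification metrics from counts
#'
#' Standard definitions on true/false positive and false negative counts:
#' `precision = TP / (TP + FP) * 100`, `recall = TP / (TP + FN) * 100`,
#' `F1 = 2 * P * R / (P + R)` (0 when `P + R = 0`), reported in percent
#' rounded half away from zero to 2 decimals. Precision (resp. recall) is
#' `NA` when its denominator is zero.
#'
#' @param tp,fp,fn count vectors.
#' @return Tibble with `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
classification_metrics <- function(tp, fp, fn) {
  precision <- ifelse(tp + fp > 0, tp / (tp + fp) * 100, NA_real_)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn) * 100, NA_real_)
  f1 <- f1_from_pr(precision, recall)
  tibble::tibble(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
                 precision = round_half_up(precision),
                 recall = round_half_up(recall),
                 f1 = round_half_up(f1))
}

#' @rdname classification_metrics
#' @param precision,recall percentages.
#' @export
f1_from_pr <- function(precision, recall) {
  ifelse(!is.na(precision) & !is.na(recall) & precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

#' Evaluation report for one prediction run
#'
#' Builds the confusion matrix and derives per-class TP/FP/FN (the diagonal
#' cell, its column sum minus it, its row sum minus it), precision, recall
#' and F1, plus overall accuracy and macro averages. Classes absent from
#' the test set have undefined metrics; they are flagged `NA` and excluded
#' from the macro averages (with a note).
#'
#' @param truth,estimate 0-based labels.
#' @param n_classes class count.
#' @return An `eval_report`.
#' @export
eval_report <- function(truth, estimate, n_classes = NULL) {
  conf <- confusion_matrix(truth, estimate, n_classes)
  tp <- diag(conf)
  fn <- rowSums(conf) - tp
  fp <- colSums(conf) - tp
  per_class <- dplyr::bind_cols(
    tibble::tibble(class = as.integer(rownames(conf))),
    classification_metrics(tp, fp, fn))
  empty <- rowSums(conf) == 0
  if (any(empty))
    inform(sprintf("eval_report: %d class(es) absent from the test set excluded from macro averages",
                   sum(empty)))
  ok <- !empty
  structure(list(
    confusion = conf, per_class = per_class,
    accuracy = sum(tp) / sum(conf) * 100,
    macro_precision = mean(per_class$precision[ok], na.rm = TRUE),
    macro_recall = mean(per_class$recall[ok], na.rm = TRUE),
    macro_f1 = mean(per_class$f1[ok], na.rm = TRUE)),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("# Evaluation: accuracy %.2f%%, macro P/R/F1 %.2f/%.2f/%.2f (%d classes)\n",
              x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1,
              nrow(x$per_class)))
  invisible(x)
}

#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) x$per_class

#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(accuracy = round_half_up(x$accuracy),
                 macro_precision = round_half_up(x$macro_precision),
                 macro_recall = round_half_up(x$macro_recall),
                 macro_f1 = round_half_up(x$macro_f1))
}

#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object, ...) {
  df <- tibble::as_tibble(as.data.frame(object$confusion))
  names(df) <- c("true", "pred", "n")
  ggplot2::ggplot(df, ggplot2::aes(.data$pred, .data$true, fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_discrete(limits = rev(levels(factor(df$true)))) +
    ggplot2::labs(x = "predicted", y = "true", fill = "count") +
    ggplot2::theme_minimal()
}

#' Evaluate a fitted classifier on a test set
#'
#' @param model a fitted `seed_classifier`.
#' @param data test spectra table.
#' @export
evaluate_classifier <- function(model, data) {
  pred <- predict(model, data)
  eval_report(spectra_labels(data), pred$.pred_class,
              n_classes = model$n_classes)
}

#' Repeated-run evaluation of one classifier
#'
#' Trains the classifier once per seed and evaluates each run on the fixed
#' test set, reporting per-run accuracies plus their average and the highest
#' value, alongside the per-class report of the best run.
#'
#' @param train,test spectra tables.
#' @param spec a [baseline_spec()].
#' @param config a [train_config()] (supplies `n_runs` and `seeds`).
#' @param n_classes class count.
#' @return A `repeated_eval` with `accuracies`, `average_accuracy`,
#'   `highest_accuracy`, `best_report` and all `reports`.
#' @export
repeated_eval <- function(train, test, spec, config = train_config(),
                          n_classes = NULL) {
  if (is.null(n_classes)) n_classes <- max(spectra_labels(train)) + 1L
  reports <- vector("list", config$n_runs)
  acc <- numeric(config$n_runs)
  for (r in seq_len(config$n_runs)) {
    m <- fit_baseline(train, spec, n_classes = n_classes, config = config,
                      seed = config$seeds[r])
    reports[[r]] <- evaluate_classifier(m, test)
    acc[r] <- reports[[r]]$accuracy
  }
  structure(list(kind = spec$kind, accuracies = acc,
                 average_accuracy = mean(acc), highest_accuracy = max(acc),
                 best_report = reports[[which.max(acc)]], reports = reports,
                 seeds = config$seeds), class = "repeated_eval")
}

#' @method glance repeated_eval
#' @export
glance.repeated_eval <- function(x, ...) {
  best <- x$best_report
  tibble::tibble(model = x$kind,
                 average_accuracy = round_half_up(x$average_accuracy),
                 highest_accuracy = round_half_up(x$highest_accuracy),
                 precision = round_half_up(best$macro_precision),
                 recall = round_half_up(best$macro_recall),
                 f1 = round_half_up(best$macro_f1))
}
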