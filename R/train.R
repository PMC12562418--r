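#' Training configuration
#'
#' Optimisation protocol for the deep spectral classifiers: Adam, a
#' reduce-on-plateau schedule that halves the learning rate when validation
#' accuracy has not improved for `scheduler_patience` consecutive epochs,
#' and early stopping after `early_stop_patience` epochs without
#' improvement (restoring the best-validation weights). The early-stopping
#' patience must exceed the scheduler patience so the schedule can act
#' before training terminates.
#'
#' @param learning_rate initial Adam learning rate (default 1e-3).
#' @param batch_size minibatch size (default 64).
#' @param max_epochs epoch cap (default 200).
#' @param scheduler_patience epochs of stagnant validation accuracy before
#'   the learning rate halves (default 5).
#' @param scheduler_factor multiplicative LR factor (default 0.5).
#' @param early_stop_patience epochs of stagnation before stopping
#'   (default 10).
#' @param label_smoothing epsilon of the label-smoothing loss (default 0.1).
#' @param validation_fraction stratified fraction of the training set carved
#'   out as the validation set monitored by the scheduler (default 0.1).
#' @param n_runs repeated-run count for the evaluation protocol (default 5).
#' @param seeds per-run seeds; defaults to `1:n_runs`.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 64,
                         max_epochs = 200, scheduler_patience = 5,
                         scheduler_factor = 0.5, early_stop_patience = 10,
                         label_smoothing = 0.1, validation_fraction = 0.1,
                         n_runs = 5, seeds = NULL) {
  if (early_stop_patience <= scheduler_patience)
    abort("early_stop_patience must exceed scheduler_patience",
          class = "spectraseed_config_error")
  if (is.null(seeds)) seeds <- seq_len(n_runs)
  if (length(seeds) != n_runs)
    abort("length(seeds) must equal n_runs", class = "spectraseed_config_error")
  structure(list(learning_rate = learning_rate,
                 batch_size = check_count(batch_size, "batch_size"),
                 max_epochs = check_count(max_epochs, "max_epochs"),
                 scheduler_patience = check_count(scheduler_patience, "scheduler_patience"),
                 scheduler_factor = scheduler_factor,
                 early_stop_patience = check_count(early_stop_patience, "early_stop_patience"),
                 label_smoothing = label_smoothing,
                 validation_fraction = validation_fraction,
                 n_runs = check_count(n_runs, "n_runs"),
                 seeds = as.integer(seeds)),
            class = "train_config")
}

#' Reduce-on-plateau learning-rate tracker
#'
#' A small stateful tracker usable on its own: feed it the monitored metric
#' once per epoch and it halves (or scales by `factor`) the learning rate
#' whenever the metric has failed to improve for `patience` consecutive
#' epochs, resetting the stagnation counter on improvement and after each
#' reduction.
#'
#' @param init_lr initial learning rate.
#' @param factor multiplicative reduction factor.
#' @param patience consecutive stagnant epochs tolerated.
#' @return An environment with `$update(metric)` returning the current
#'   learning rate, and fields `lr`, `best`, `count`.
#' @export
plateau_scheduler <- function(init_lr, factor = 0.5, patience = 5) {
  e <- new.env(parent = emptyenv())
  e$lr <- init_lr; e$best <- -Inf; e$count <- 0L
  e$update <- function(metric) {
    if (metric > e$best) {
      e$best <- metric; e$count <- 0L
    } else {
      e$count <- e$count + 1L
      if (e$count >= patience) {
        e$lr <- e$lr * factor
        e$count <- 0L
      }
    }
    e$lr
  }
  e
}

#' Early-stopping tracker
#'
#' Signals stop after `patience` consecutive epochs without improvement of
#' the monitored metric; any improvement resets the counter.
#'
#' @param patience consecutive stagnant epochs tolerated.
#' @return An environment with `$update(metric)` returning `TRUE` when
#'   training should stop.
#' @export
early_stopper <- function(patience = 10) {
  e <- new.env(parent = emptyenv())
  e$best <- -Inf; e$count <- 0L
  e$update <- function(metric) {
    if (metric > e$best) {
      e$best <- metric; e$count <- 0L
    } else {
      e$count <- e$count + 1L
    }
    e$count >= patience
  }
  e
}

# Adam optimiser over a nested parameter list; state mirrors the gradient
# structure and is created lazily.
adam_new <- function(lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  e <- new.env(parent = emptyenv())
  e$lr <- lr; e$beta1 <- beta1; e$beta2 <- beta2; e$eps <- eps
  e$t <- 0L; e$m <- NULL; e$v <- NULL
  e
}

adam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  step <- function(p, g, m, v) {
    if (is.list(g)) {
      if (is.null(m)) m <- list()
      if (is.null(v)) v <- list()
      keys <- if (is.null(names(g))) seq_along(g) else names(g)
      for (nm in keys) {
        if (is.null(g[[nm]])) next
        have <- if (is.character(nm)) nm %in% names(m) else length(m) >= nm && !is.null(m[[nm]])
        res <- step(p[[nm]], g[[nm]],
                    if (have) m[[nm]] else NULL,
                    if (have) v[[nm]] else NULL)
        p[[nm]] <- res$p; m[[nm]] <- res$m; v[[nm]] <- res$v
      }
      return(list(p = p, m = m, v = v))
    }
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- opt$beta1 * m + (1 - opt$beta1) * g
    v <- opt$beta2 * v + (1 - opt$beta2) * g^2
    p <- p - opt$lr * (m / bc1) / (sqrt(v / bc2) + opt$eps)
    list(p = p, m = m, v = v)
  }
  res <- step(params, grads, opt$m, opt$v)
  opt$m <- res$m; opt$v <- res$v
  res$p
}

#' Train a spectral network
#'
#' Minibatch Adam under the label-smoothing cross-entropy loss, with the
#' reduce-on-plateau schedule and early stopping monitoring validation
#' accuracy. The best-validation weights are restored at the end (accuracy
#' ties broken by the lower validation loss). All
#' randomness (shuffling, dropout) comes from R's RNG stream, so seeding
#' before the call makes training fully reproducible.
#'
#' @param net a `spectral_net` from [build_rm1dnet()].
#' @param x_train,y_train training spectra matrix (`N x B`) and 0-based labels.
#' @param x_val,y_val validation set monitored by the scheduler.
#' @param config a [train_config()].
#' @param verbose print per-epoch progress.
#' @return List with the trained `net` and a `history` tibble (epoch, mean
#'   training loss, validation accuracy, learning rate).
#' @export
train_network <- function(net, x_train, y_train, x_val, y_val,
                          config = train_config(), verbose = FALSE) {
  x_train <- as.matrix(x_train); x_val <- as.matrix(x_val)
  y_train <- as.integer(y_train); y_val <- as.integer(y_val)
  n <- nrow(x_train)
  opt <- adam_new(config$learning_rate)
  sched <- plateau_scheduler(config$learning_rate, config$scheduler_factor,
                             config$scheduler_patience)
  stopper <- early_stopper(config$early_stop_patience)
  best_acc <- -Inf; best_loss <- Inf
  best_params <- net$params; best_epoch <- 0L
  history <- vector("list", config$max_epochs)
  for (epoch in seq_len(config$max_epochs)) {
    idx <- sample(n)
    total_loss <- 0; n_batches <- 0L
    for (start in seq(1, n, by = config$batch_size)) {
      bi <- idx[start:min(n, start + config$batch_size - 1)]
      fw <- net_forward(net, x_train[bi, , drop = FALSE], training = TRUE)
      lg <- label_smoothing_loss_grad(fw$logits, y_train[bi],
                                      config$label_smoothing)
      if (!is.finite(lg$loss))
        abort(sprintf("non-finite loss at epoch %d (lr %.2e); aborting",
                      epoch, opt$lr), class = "spectraseed_training_error")
      grads <- net_backward(net, fw$cache, lg$dlogits)
      net$params <- adam_step(opt, net$params, grads)
      total_loss <- total_loss + lg$loss; n_batches <- n_batches + 1L
    }
    val_probs <- net_predict_probs(net, x_val)
    val_pred <- max.col(val_probs, ties.method = "first") - 1L
    val_acc <- mean(val_pred == y_val)
    val_loss <- -mean(log(pmax(val_probs[cbind(seq_along(y_val), y_val + 1L)],
                               1e-12)))
    # snapshot the best weights: accuracy first, ties broken by lower
    # validation loss (accuracy saturates early on easy problems)
    if (val_acc > best_acc || (val_acc == best_acc && val_loss < best_loss)) {
      best_acc <- val_acc; best_loss <- val_loss
      best_params <- net$params; best_epoch <- epoch
    }
    opt$lr <- sched$update(val_acc)
    history[[epoch]] <- tibble::tibble(epoch = epoch,
                                       loss = total_loss / n_batches,
                                       val_accuracy = val_acc, lr = opt$lr)
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  val %.4f  lr %.2e",
                      epoch, total_loss / n_batches, val_acc, opt$lr))
    if (stopper$update(val_acc)) break
  }
  net$params <- best_params
  list(net = net, history = dplyr::bind_rows(history),
       best_epoch = best_epoch, best_val_accuracy = best_acc)
}
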