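#' Experiment configuration
#'
#' One object describing a full pipeline run: synthetic-data conditions (or
#' an input spectra table), smoothing, the stratified split, wavelength
#' selection, the model roster and the training protocol. A single global
#' seed expands into per-stage seeds by fixed offsets so one knob
#' reproduces the whole experiment.
#'
#' @param seed global seed.
#' @param synth a [synth_config()]; its `rng_seed` is overridden by `seed`.
#' @param models classifier kinds to compare (see [baseline_spec()]).
#' @param feature_sets subset of `"full"`, `"spa"`, `"cars"`.
#' @param sg_window,sg_polyorder smoothing parameters.
#' @param test_fraction held-out fraction (default 0.2).
#' @param spa_max_vars SPA chain length.
#' @param spa_first_var SPA start: `"auto"` or an index; the default uses a
#'   fixed start for speed at full band counts.
#' @param cars_iterations CARS Monte Carlo iterations.
#' @param train a [train_config()]; its seeds are overridden by offsets of
#'   `seed`.
#' @param out_dir optional output directory for reports.
#' @export
experiment_config <- function(seed = 1, synth = synth_config(),
                              models = c("svm", "elm", "bp", "lstm", "cnn1d",
                                         "rescnn1d", "mambacnn1d", "rm1dnet"),
                              feature_sets = "full", sg_window = 3,
                              sg_polyorder = 1, test_fraction = 0.2,
                              spa_max_vars = 50, spa_first_var = "auto",
                              cars_iterations = 50,
                              train = train_config(), out_dir = NULL) {
  seed <- as.integer(seed)
  synth$rng_seed <- seed
  train$seeds <- seed + 3000L + seq_len(train$n_runs)
  structure(list(seed = seed, synth = synth, models = models,
                 feature_sets = match.arg(feature_sets,
                                          c("full", "spa", "cars"),
                                          several.ok = TRUE),
                 sg_window = sg_window, sg_polyorder = sg_polyorder,
                 test_fraction = test_fraction,
                 split_seed = seed + 1000L, selection_seed = seed + 2000L,
                 spa_max_vars = spa_max_vars, spa_first_var = spa_first_var,
                 cars_iterations = cars_iterations,
                 train = train, out_dir = out_dir),
            class = "experiment_config")
}

# keep only the selected band columns (plus ids/labels)
select_bands <- function(data, band_idx) {
  wl_cols <- grep("^wl_", names(data), value = TRUE)
  dplyr::select(data, dplyr::all_of(c("sample_id", "class",
                                      wl_cols[sort(band_idx)])))
}

#' Run a full comparison experiment
#'
#' Generates (or takes) a labelled spectra set, applies Savitzky-Golay
#' smoothing, splits 8:2 stratified, standardizes with training statistics,
#' optionally selects wavelengths by SPA and/or CARS on the training set,
#' then trains every configured model `n_runs` times per feature set and
#' evaluates on the untouched test set. Produces a summary table (average
#' and highest accuracy, macro metrics of each model's best run) and the
#' per-class detail of the overall best model. With `out_dir` set, writes
#' `summary.csv`, `runs.csv`, `per_class_best.csv`, `confusion_best.csv`,
#' selection reports and an echo of the configuration; identical
#' configurations and seeds produce byte-identical files.
#'
#' @param cfg an [experiment_config()].
#' @param data optional spectra table; defaults to `generate_spectra(cfg$synth)`.
#' @return An `experiment_result` list.
#' @export
run_experiment <- function(cfg, data = NULL) {
  stopifnot(inherits(cfg, "experiment_config"))
  if (is.null(data)) data <- generate_spectra(cfg$synth)
  data <- sg_smooth(data, cfg$sg_window, cfg$sg_polyorder)
  sp <- stratified_split(data, cfg$test_fraction, seed = cfg$split_seed)
  std <- standardize_spectra(data[sp$train_idx, ], test = data[sp$test_idx, ])
  train_df <- std$train; test_df <- std$test
  n_classes <- max(spectra_labels(data)) + 1L

  selections <- list()
  if ("spa" %in% cfg$feature_sets)
    selections$spa <- spa_select(train_df, spectra_labels(train_df),
                                 max_vars = cfg$spa_max_vars,
                                 first_var = cfg$spa_first_var,
                                 seed = cfg$selection_seed)
  if ("cars" %in% cfg$feature_sets)
    selections$cars <- cars_select(train_df, spectra_labels(train_df),
                                   n_iterations = cfg$cars_iterations,
                                   seed = cfg$selection_seed)

  band_sets <- list(full = seq_along(spectra_wavelengths(train_df)))
  for (nm in names(selections)) band_sets[[nm]] <- selections[[nm]]$selected_band_idx
  band_sets <- band_sets[intersect(cfg$feature_sets, names(band_sets))]

  summary_rows <- list(); run_rows <- list(); evals <- list()
  for (fs in names(band_sets)) {
    tr_fs <- select_bands(train_df, band_sets[[fs]])
    te_fs <- select_bands(test_df, band_sets[[fs]])
    for (kind in cfg$models) {
      ev <- repeated_eval(tr_fs, te_fs, baseline_spec(kind),
                          config = cfg$train, n_classes = n_classes)
      evals[[paste(kind, fs, sep = ".")]] <- ev
      summary_rows[[length(summary_rows) + 1]] <- dplyr::bind_cols(
        tibble::tibble(feature_set = fs,
                       n_variables = length(band_sets[[fs]])),
        glance(ev))
      run_rows[[length(run_rows) + 1]] <- tibble::tibble(
        model = kind, feature_set = fs, run = seq_along(ev$accuracies),
        seed = ev$seeds, accuracy = round_half_up(ev$accuracies))
    }
  }
  summary <- dplyr::bind_rows(summary_rows) |>
    dplyr::select("model", "feature_set", "n_variables",
                  average_accuracy = "average_accuracy",
                  highest_accuracy = "highest_accuracy",
                  "precision", "recall", "f1")
  runs <- dplyr::bind_rows(run_rows)
  best_key <- names(evals)[which.max(vapply(evals, function(e)
    e$average_accuracy, numeric(1)))]
  best <- evals[[best_key]]

  result <- structure(list(summary = summary, runs = runs,
                           best_model = best_key, best = best,
                           selections = selections, split = sp,
                           config = cfg), class = "experiment_result")
  if (!is.null(cfg$out_dir)) write_experiment(result, cfg$out_dir)
  result
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("# Experiment: %d model x feature-set combinations; best = %s (avg %.2f%%)\n",
              nrow(x$summary), x$best_model, x$best$average_accuracy))
  print(x$summary)
  invisible(x)
}

write_experiment <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, f) utils::write.table(
    df, file.path(out_dir, f), sep = ",", row.names = FALSE, quote = FALSE)
  wcsv(result$summary, "summary.csv")
  wcsv(result$runs, "runs.csv")
  wcsv(tidy(result$best$best_report), "per_class_best.csv")
  conf <- as.data.frame(result$best$best_report$confusion)
  wcsv(conf, "confusion_best.csv")
  for (nm in names(result$selections))
    write_selection_report(result$selections[[nm]],
                           file.path(out_dir, sprintf("selection_%s.txt", nm)))
  write_experiment_config(result$config, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}

#' Write / read an experiment configuration as YAML
#'
#' @param cfg an [experiment_config()].
#' @param path YAML file path.
#' @export
write_experiment_config <- function(cfg, path) {
  flat <- list(
    seed = cfg$seed, models = cfg$models, feature_sets = cfg$feature_sets,
    sg_window = cfg$sg_window, sg_polyorder = cfg$sg_polyorder,
    test_fraction = cfg$test_fraction, spa_max_vars = cfg$spa_max_vars,
    spa_first_var = cfg$spa_first_var, cars_iterations = cfg$cars_iterations,
    synth = unclass(cfg$synth), train = unclass(cfg$train))
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  experiment_config(
    seed = y$seed %||% 1,
    synth = do.call(synth_config, y$synth %||% list()),
    models = y$models %||% "rm1dnet",
    feature_sets = y$feature_sets %||% "full",
    sg_window = y$sg_window %||% 3, sg_polyorder = y$sg_polyorder %||% 1,
    test_fraction = y$test_fraction %||% 0.2,
    spa_max_vars = y$spa_max_vars %||% 50,
    spa_first_var = y$spa_first_var %||% "auto",
    cars_iterations = y$cars_iterations %||% 50,
    train = do.call(train_config, y$train %||% list()))
}

#' Save / load a trained spectral network
#'
#' Writes a directory holding a JSON manifest (format version, architecture
#' spec, parameter shapes) plus the flattened parameter values, and restores
#' the network bit-identically.
#'
#' @param net a `spectral_net`.
#' @param dir target directory.
#' @export
save_model <- function(net, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  flat <- flatten_params(net$params)
  manifest <- list(format_version = 1L,
                   spec = unclass(net$spec),
                   params = lapply(flat, function(p)
                     list(dim = if (is.matrix(p)) dim(p) else length(p))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(file.path(dir, "weights.bin"), "wb")
  on.exit(close(con))
  for (p in flat) writeBin(as.numeric(p), con, size = 8, endian = "little")
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  spec_args <- manifest$spec
  spec_args <- spec_args[setdiff(names(spec_args), "seq_len_out")]
  empty <- vapply(spec_args, function(z)
    is.null(z) || (is.list(z) && length(z) == 0), logical(1))
  spec <- do.call(model_spec, spec_args[!empty])
  net <- build_rm1dnet(spec, seed = 0)
  flat <- flatten_params(net$params)
  con <- file(file.path(dir, "weights.bin"), "rb")
  on.exit(close(con))
  for (nm in names(flat)) {
    v <- readBin(con, "numeric", n = length(flat[[nm]]), size = 8,
                 endian = "little")
    dim_keep <- dim(flat[[nm]])
    flat[[nm]] <- if (is.null(dim_keep)) v else array(v, dim_keep)
  }
  net$params <- unflatten_params(flat, net$params)
  net
}

flatten_params <- function(p, prefix = "") {
  out <- list()
  keys <- if (is.null(names(p))) as.character(seq_along(p)) else names(p)
  for (i in seq_along(p)) {
    key <- if (prefix == "") keys[i] else paste(prefix, keys[i], sep = ".")
    if (is.list(p[[i]])) out <- c(out, flatten_params(p[[i]], key))
    else if (is.numeric(p[[i]])) out[[key]] <- p[[i]]
  }
  out
}

unflatten_params <- function(flat, template, prefix = "") {
  keys <- if (is.null(names(template))) as.character(seq_along(template)) else names(template)
  for (i in seq_along(template)) {
    key <- if (prefix == "") keys[i] else paste(prefix, keys[i], sep = ".")
    if (is.list(template[[i]]))
      template[[i]] <- unflatten_params(flat, template[[i]], key)
    else if (is.numeric(template[[i]]) && key %in% names(flat))
      template[[i]] <- flat[[key]]
  }
  template
}

#' Plot a training history
#'
#' @param history the `history` tibble from [train_network()].
#' @export
plot_training_history <- function(history) {
  df <- tidyr::pivot_longer(history, c("loss", "val_accuracy"))
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ name, scales = "free_y", ncol = 1) +
    ggplot2::theme_minimal()
}
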