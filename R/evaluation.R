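#' Confusion matrix
#'
#' @param true_labels,predicted_labels Integer class labels (1-based),
#'   equal length.
#' @param n_classes Number of classes.
#' @return `confusion_matrix` object: n x n counts, rows = true, cols =
#'   predicted.
#' @export
confusion_matrix <- function(true_labels, predicted_labels, n_classes) {
  if (length(true_labels) != length(predicted_labels))
    stop_invalid("label vectors have different lengths (%d vs %d)",
                 length(true_labels), length(predicted_labels))
  if (length(true_labels) &&
      (any(true_labels < 1 | true_labels > n_classes) ||
       any(predicted_labels < 1 | predicted_labels > n_classes)))
    stop_invalid("labels out of range 1..%d", n_classes)
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(true_labels))
    cm[true_labels[i], predicted_labels[i]] <- cm[true_labels[i], predicted_labels[i]] + 1L
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' Classification accuracy
#'
#' Multiclass generalization `trace / total`; for two classes this is the
#' familiar `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param cm A [confusion_matrix()].
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop_invalid("empty confusion matrix")
  sum(diag(cm)) / total
}

#' Standard deviation of fold accuracies
#'
#' The sample standard deviation `sqrt(sum((x - mean)^2) / (N - 1))` across
#' the N cross-validation folds.
#'
#' @param accuracies Numeric vector of per-fold accuracies, length >= 2.
#' @return Non-negative scalar; 0 iff all folds agree.
#' @export
fold_std <- function(accuracies) {
  n <- length(accuracies)
  if (n < 2) stop_invalid("need at least 2 fold accuracies")
  xbar <- mean(accuracies)
  sqrt(sum((accuracies - xbar)^2) / (n - 1))
}

#' Per-class accuracy
#'
#' @param cm A [confusion_matrix()].
#' @return Vector of `counts[i,i] / row_total(i)`; classes with no test
#'   samples are `NA` and flagged in the `"undefined"` attribute rather
#'   than erroring.
#' @export
per_class_accuracy <- function(cm) {
  rt <- rowSums(cm)
  out <- ifelse(rt > 0, diag(as.matrix(cm)) / pmax(rt, 1), NA_real_)
  structure(out, undefined = which(rt == 0))
}

#' Experiment configuration
#'
#' Bundles the synthetic dataset spec, featurization options, model
#' architecture, training setup and split protocol into one reproducible
#' unit. The defaults are the package's reference experiment: the default
#' synthetic dataset, non-overlapping six-window samples, a compact
#' dual-stream model and a short Adam run under the piecewise-exponential
#' schedule (profile sizes are package choices, documented in the methods
#' vignette).
#'
#' @param dataset A [dataset_spec()].
#' @param window_s,t_steps,stride Featurization options (see
#'   [extract_features()]).
#' @param model A [model_config()].
#' @param train A [train_config()].
#' @param protocol Default split protocol for [run_experiment()].
#' @param k Folds for subject-dependent k-fold.
#' @param seed Master seed for splits, per-fold training streams and any
#'   other experiment-level randomness.
#' @return An `experiment_config`.
#' @export
experiment_config <- function(dataset = dataset_spec(),
                              window_s = 1, t_steps = 6L, stride = 6L,
                              model = model_config(
                                input_shape = c(8L, 9L, 4L),
                                cnn_channels = c(6L, 12L), lstm_hidden = 24L,
                                dcign_channels = c(6L, 12L, 24L),
                                latent_dim = 12L, fusion_hidden = 48L,
                                n_classes = length(dataset$classes)),
                              train = train_config(
                                epochs = 6L, batch_size = 128L,
                                schedule = lr_schedule(
                                  "piecewise_exponential", lr0 = 2e-3,
                                  boundaries = c(2, 4),
                                  gammas = c(1, 0.7, 0.5))),
                              protocol = "subject_dependent_kfold", k = 5L,
                              seed = 42L) {
  stopifnot(inherits(dataset, "dataset_spec"), inherits(model, "model_config"),
            inherits(train, "train_config"))
  structure(list(dataset = dataset, window_s = window_s,
                 t_steps = as.integer(t_steps), stride = as.integer(stride),
                 model = model, train = train, protocol = protocol,
                 k = as.integer(k), seed = as.integer(seed)),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' Recognised top-level keys: `dataset` (fields of [dataset_spec()] plus
#' `classes: seed3|deap2`), `features` (`window_s`, `t_steps`, `stride`),
#' `model` (fields of [model_config()]), `train` (fields of
#' [train_config()] with `schedule` as a nested map), `split`
#' (`protocol`, `k`) and `seed`. Missing keys keep package defaults.
#'
#' @param path YAML file path.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  ds_args <- y$dataset %||% list()
  if (!is.null(ds_args$classes) && is.character(ds_args$classes))
    ds_args$classes <- default_class_specs(ds_args$classes)
  dataset <- do.call(dataset_spec, ds_args)
  feat <- y$features %||% list()
  margs <- y$model %||% list()
  if (is.null(margs$n_classes)) margs$n_classes <- length(dataset$classes)
  for (f in c("cnn_channels", "dcign_channels"))
    if (!is.null(margs[[f]])) margs[[f]] <- as.integer(unlist(margs[[f]]))
  model <- do.call(model_config, margs)
  targs <- y$train %||% list()
  if (!is.null(targs$schedule)) targs$schedule <- do.call(lr_schedule, targs$schedule)
  train <- do.call(train_config, targs)
  sp <- y$split %||% list()
  args <- list(dataset = dataset, model = model, train = train)
  for (f in names(feat)) args[[f]] <- feat[[f]]
  if (!is.null(sp$protocol)) args$protocol <- sp$protocol
  if (!is.null(sp$k)) args$k <- sp$k
  if (!is.null(y$seed)) args$seed <- y$seed
  do.call(experiment_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a full cross-validated experiment
#'
#' Generates (or reuses) the synthetic features, builds the folds, trains
#' one model per fold with a fold-specific derived seed, and aggregates
#' per-fold, per-class and per-subject accuracies. Accuracies are reported
#' in percent. Deterministic for a fixed config.
#'
#' @param config An [experiment_config()], or a path to a YAML file.
#' @param protocol Optional override of the config's protocol.
#' @param features Optional precomputed `eeg_features` (skips extraction).
#' @param out_dir Optional directory for JSON + CSV reports.
#' @param verbose Print per-fold progress.
#' @return An `experiment_report`.
#' @export
run_experiment <- function(config, protocol = NULL, features = NULL,
                           out_dir = NULL, verbose = FALSE) {
  if (is.character(config)) config <- read_experiment_config(config)
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(protocol)) protocol <- config$protocol
  if (is.null(features))
    features <- extract_features(config$dataset, window_s = config$window_s,
                                 t_steps = config$t_steps,
                                 stride = config$stride)
  plan <- split_plan(protocol, k = config$k, seed = derive_seed(config$seed, "split"))
  folds <- make_splits(features, plan)
  K <- config$model$n_classes
  n <- n_samples(features)
  pred_all <- integer(n)
  fold_acc <- numeric(length(folds))
  histories <- vector("list", length(folds))
  for (i in seq_along(folds)) {
    fit <- train_model(features, config$model, config$train, fold = folds[[i]],
                       seed = derive_seed(config$seed, "fold", i))
    pr <- predict.fusion_model(fit$model, features, folds[[i]]$test)
    pred_all[folds[[i]]$test] <- pr$class
    cm <- confusion_matrix(features$labels[folds[[i]]$test], pr$class, K)
    fold_acc[i] <- 100 * accuracy(cm)
    histories[[i]] <- fit$history
    if (verbose)
      message(sprintf("fold %d/%d [%s]: %.2f%%", i, length(folds), protocol,
                      fold_acc[i]))
  }
  cm_all <- confusion_matrix(features$labels, pred_all, K)
  per_subject <- vapply(unique(features$subjects), function(s) {
    idx <- features$subjects == s
    100 * mean(pred_all[idx] == features$labels[idx])
  }, 0)
  report <- structure(list(
    protocol = protocol,
    n_samples = n,
    classes = features$label_levels,
    fold_acc = fold_acc,
    mean_acc = mean(fold_acc),
    std = fold_std(fold_acc),
    confusion = cm_all,
    per_class = setNames(100 * per_class_accuracy(cm_all), features$label_levels),
    per_subject = per_subject,
    schedule = config$train$schedule$kind,
    seed = config$seed,
    histories = histories),
    class = "experiment_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report [%s], schedule %s>\n", x$protocol, x$schedule))
  cat(sprintf("  fold accuracies (%%): %s\n",
              paste(sprintf("%.2f", x$fold_acc), collapse = ", ")))
  cat(sprintf("  Acc %.2f%%  Std %.2f\n", x$mean_acc, x$std))
  cat("  per-class (%): ",
      paste(sprintf("%s %.2f", names(x$per_class), x$per_class), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Write an experiment report to disk
#'
#' @param report An `experiment_report`.
#' @param out_dir Output directory (created if needed): `report.json` plus
#'   CSV tables of fold, per-class and per-subject accuracies and the
#'   pooled confusion matrix.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  j <- list(protocol = report$protocol, schedule = report$schedule,
            n_samples = report$n_samples,
            fold_acc = report$fold_acc, mean_acc = report$mean_acc,
            std = report$std,
            per_class = as.list(round(report$per_class, 2)),
            per_subject = as.list(round(report$per_subject, 2)),
            confusion = unclass(report$confusion), seed = report$seed)
  jsonlite::write_json(j, file.path(out_dir, "report.json"), auto_unbox = TRUE,
                       digits = NA)
  write.csv(data.frame(fold = seq_along(report$fold_acc),
                       accuracy_pct = round(report$fold_acc, 2)),
            file.path(out_dir, "fold_accuracies.csv"), row.names = FALSE)
  write.csv(data.frame(subject = names(report$per_subject),
                       accuracy_pct = round(report$per_subject, 2)),
            file.path(out_dir, "per_subject.csv"), row.names = FALSE)
  cmdf <- as.data.frame(unclass(report$confusion))
  names(cmdf) <- report$classes
  cmdf <- cbind(true = report$classes, cmdf)
  write.csv(cmdf, file.path(out_dir, "confusion.csv"), row.names = FALSE)
  invisible(out_dir)
}

#' Compare the five learning-rate schedules
#'
#' Re-runs the cross-validated experiment once per schedule kind (same
#' data, splits and per-fold seeds; only the schedule changes) and tabulates
#' mean accuracy and fold standard deviation for each.
#'
#' @param config An [experiment_config()].
#' @param kinds Schedule kinds to compare (default all five).
#' @param features Optional precomputed features.
#' @param verbose Print progress.
#' @return List: `table` (data.frame schedule / mean_acc / std) and
#'   `reports` (one `experiment_report` per kind).
#' @export
compare_schedules <- function(config,
                              kinds = c("constant", "piecewise_exponential",
                                        "cosine_annealing", "stepped",
                                        "linear"),
                              features = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(features))
    features <- extract_features(config$dataset, window_s = config$window_s,
                                 t_steps = config$t_steps, stride = config$stride)
  reports <- list()
  for (kind in kinds) {
    cfg <- config
    cfg$train$schedule <- schedule_for_epochs(kind, config$train$schedule$lr0,
                                              config$train$epochs)
    reports[[kind]] <- run_experiment(cfg, features = features,
                                      verbose = verbose)
  }
  tab <- data.frame(schedule = kinds,
                    mean_acc = vapply(reports, `[[`, 0, "mean_acc"),
                    std = vapply(reports, `[[`, 0, "std"),
                    row.names = NULL)
  list(table = tab, reports = reports)
}

# schedule of the given kind scaled to an epoch horizon, keeping lr0
schedule_for_epochs <- function(kind, lr0, epochs) {
  switch(kind,
    constant = lr_schedule("constant", lr0 = lr0),
    piecewise_exponential = lr_schedule(
      "piecewise_exponential", lr0 = lr0,
      boundaries = unique(pmax(1, round(epochs * c(0.4, 0.75)))),
      gammas = c(1, 0.8, 0.6)[seq_len(length(unique(pmax(1, round(epochs * c(0.4, 0.75))))) + 1L)]),
    cosine_annealing = lr_schedule("cosine_annealing", lr0 = lr0,
                                   T_max = epochs, lr_min = lr0 / 100),
    stepped = lr_schedule("stepped", lr0 = lr0,
                          step_size = max(1, ceiling(epochs / 4)),
                          step_gamma = 0.5),
    linear = lr_schedule("linear", lr0 = lr0, final_lr = lr0 / 100,
                         total_epochs = epochs),
    stop_invalid("unknown schedule kind `%s`", kind))
}

#' Export penultimate-layer embeddings
#'
#' Runs the trained model in eval mode and writes the fusion hidden-layer
#' activations (one row per sample) plus the true label as CSV, for
#' downstream projection or visualization.
#'
#' @param model A trained [fusion_model()] (from [train_model()]).
#' @param features An `eeg_features` set.
#' @param out_path CSV path.
#' @param batch_size Evaluation chunk size.
#' @return `out_path`, invisibly.
#' @export
export_embeddings <- function(model, features, out_path, batch_size = 256L) {
  stopifnot(inherits(model, "fusion_model"))
  if (!isTRUE(model$trained))
    stop_invalid("model has not been trained; refusing to export embeddings")
  n <- n_samples(features)
  emb <- matrix(NA_real_, n, model$config$fusion_hidden)
  idx_all <- seq_len(n)
  for (chunk in split(idx_all, ceiling(idx_all / batch_size))) {
    fw <- forward_full(model, feature_batch(features, chunk), mode = "eval")
    f1 <- dense_forward(rbind(fw$temporal, fw$mu), model$params$fuse$fc1$W,
                        model$params$fuse$fc1$b)
    emb[chunk, ] <- t(relu_forward(f1$out)$out)
  }
  df <- as.data.frame(emb)
  names(df) <- sprintf("f%03d", seq_len(ncol(emb)))
  df$label <- features$label_levels[features$labels]
  df$subject <- features$subjects
  write.csv(df, out_path, row.names = FALSE)
  invisible(out_path)
}
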