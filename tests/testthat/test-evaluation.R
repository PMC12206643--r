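test_that("confusion matrix, accuracy and per-class accuracy match hand counts", {
  cm <- confusion_matrix(c(1, 1, 2), c(1, 2, 2), 2)
  expect_equal(unclass(cm), matrix(c(1L, 0L, 1L, 1L), 2),
               ignore_attr = TRUE)
  expect_equal(unclass(confusion_matrix(1:3, 1:3, 3)), diag(3) * 1L,
               ignore_attr = TRUE)
  expect_equal(sum(confusion_matrix(integer(0), integer(0), 3)), 0)
  expect_error(confusion_matrix(1:3, 1:2, 3), "length")
  expect_error(confusion_matrix(c(1, 4), c(1, 1), 3), "range")

  # binary accuracy with TP=9 TN=8 FP=2 FN=1 -> 17/20
  cm2 <- matrix(c(9L, 2L, 1L, 8L), 2)   # rows true (pos, neg)
  expect_equal(accuracy(cm2), 0.85)
  expect_equal(accuracy(diag(c(10L, 10L, 10L))), 1)
  expect_error(accuracy(matrix(0L, 2, 2)), "empty")

  pc <- per_class_accuracy(matrix(c(8L, 4L, 2L, 6L), 2))
  expect_equal(as.vector(pc), c(0.8, 0.6))
  pc2 <- per_class_accuracy(matrix(c(3L, 0L, 1L, 0L), 2))
  expect_true(is.na(pc2[2]))
  expect_equal(attr(pc2, "undefined"), 2L)
})

test_that("accuracy of the confusion matrix equals direct label matching", {
  set.seed(12)
  for (k in 1:20) {
    n <- sample(5:80, 1); K <- sample(2:5, 1)
    truth <- sample.int(K, n, replace = TRUE)
    pred <- sample.int(K, n, replace = TRUE)
    expect_equal(accuracy(confusion_matrix(truth, pred, K)),
                 mean(truth == pred))
  }
})

test_that("fold standard deviation uses the N-1 denominator", {
  expect_equal(fold_std(c(90, 92, 94, 96, 98)), sqrt(40 / 4))
  expect_equal(fold_std(rep(93.5, 5)), 0)
  expect_error(fold_std(91), "at least 2")
  set.seed(5)
  x <- rnorm(9, 90, 3)
  expect_equal(fold_std(x), sqrt(sum((x - mean(x))^2) / 8), tolerance = 1e-12)
  expect_equal(fold_std(x), sd(x))   # two-pass textbook variance
})

test_that("a cross-validated experiment produces a coherent report", {
  cfg <- small_experiment_config()
  feats <- extract_features(cfg$dataset, stride = cfg$stride)
  rep3 <- run_experiment(cfg, features = feats)
  expect_s3_class(rep3, "experiment_report")
  expect_length(rep3$fold_acc, 3)
  expect_equal(rep3$mean_acc, mean(rep3$fold_acc))
  expect_equal(rep3$std, fold_std(rep3$fold_acc))
  expect_length(rep3$per_class, 3)
  expect_equal(sum(rep3$confusion), rep3$n_samples)
  expect_length(rep3$per_subject, 3)

  loso <- run_experiment(cfg, protocol = "leave_one_subject_out",
                         features = feats)
  expect_length(loso$fold_acc, 3)               # one fold per subject
  expect_length(loso$per_subject, 3)

  out <- withr::local_tempdir()
  write_report(rep3, out)
  j <- jsonlite::read_json(file.path(out, "report.json"), simplifyVector = TRUE)
  expect_equal(j$mean_acc, mean(j$fold_acc))    # self-consistent on re-load
  expect_equal(j$fold_acc, rep3$fold_acc)
  fa <- read.csv(file.path(out, "fold_accuracies.csv"))
  expect_equal(fa$accuracy_pct, round(rep3$fold_acc, 2))
})

test_that("schedule comparison tabulates one row per schedule kind", {
  cfg <- small_experiment_config()
  cfg$train$epochs <- 2L
  feats <- extract_features(cfg$dataset, stride = cfg$stride)
  cmp <- compare_schedules(cfg, kinds = c("constant", "piecewise_exponential",
                                          "cosine_annealing", "stepped",
                                          "linear"),
                           features = feats)
  expect_equal(nrow(cmp$table), 5)
  expect_setequal(cmp$table$schedule,
                  c("constant", "piecewise_exponential", "cosine_annealing",
                    "stepped", "linear"))
  expect_true(all(is.finite(cmp$table$mean_acc)))
  expect_true(all(cmp$table$std >= 0))
})

test_that("decay schedules rescue an over-large initial learning rate", {
  # noisy, weakly separated classes: the optimum is interior, so a
  # persistently large step size leaves a loss floor that decay removes
  bp <- function(theta, alpha)
    rbind(theta = rep(theta, 3), alpha = rep(alpha, 3),
          beta = rep(1, 3), gamma = rep(1, 3))
  spec <- dataset_spec(n_subjects = 2L, trials_per_class = 2L,
                       classes = list(
                         emotion_class_spec("a", bp(1.4, 1), jitter_sd = 0.8),
                         emotion_class_spec("b", bp(1, 1.4), jitter_sd = 0.8)),
                       duration_s = 12, fs = 200, montage = "cap32",
                       seed = 11L)
  feats <- extract_features(spec, stride = 6L)
  cfg <- model_config(cnn_channels = c(4L, 8L), lstm_hidden = 8L,
                      dcign_channels = c(4L, 8L), latent_dim = 4L,
                      fusion_hidden = 16L, n_classes = 2L)
  eval_loss <- function(model) {
    fw <- eegfusion:::forward_full(model, feats$x, mode = "eval")
    eegfusion:::loss_components(fw, feats$labels, 1, 1)$total
  }
  lr_hot <- 0.1                      # far above the package's 1e-3 default
  seeds <- c(2, 7, 13)
  final_loss <- function(schedule) {
    mean(vapply(seeds, function(s) {
      tc <- train_config(epochs = 15L, batch_size = 8L, schedule = schedule,
                         seed = s)
      eval_loss(train_model(feats, cfg, tc)$model)
    }, 0))
  }
  l_const <- final_loss(lr_schedule("constant", lr0 = lr_hot))
  l_piece <- final_loss(lr_schedule("piecewise_exponential", lr0 = lr_hot,
                                    boundaries = c(5, 10),
                                    gammas = c(1, 0.7, 0.5)))
  l_cos <- final_loss(lr_schedule("cosine_annealing", lr0 = lr_hot,
                                  T_max = 15, lr_min = 1e-5))
  expect_lte(l_piece, l_const)
  expect_lte(l_cos, l_const)
})

test_that("embedding export writes one labelled row per sample", {
  feats <- tiny_features()
  cfg <- tiny_model_config()
  tc <- train_config(epochs = 1L, batch_size = 8L,
                     schedule = lr_schedule("constant", lr0 = 1e-3), seed = 4)
  fit <- train_model(feats, cfg, tc)
  path <- withr::local_tempfile(fileext = ".csv")
  export_embeddings(fit$model, feats, path)
  df <- read.csv(path)
  expect_equal(nrow(df), dim(feats$x)[5])
  expect_equal(ncol(df), cfg$fusion_hidden + 2)
  expect_equal(df$label, feats$label_levels[feats$labels])
  # deterministic in eval mode
  path2 <- withr::local_tempfile(fileext = ".csv")
  export_embeddings(fit$model, feats, path2)
  expect_identical(readLines(path), readLines(path2))
  # untrained models refuse
  expect_error(export_embeddings(fusion_model(cfg), feats, path), "trained")
})
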