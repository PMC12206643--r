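test_that("all five schedules match an independently coded closed form", {
  set.seed(17)
  epochs <- sort(runif(100, 0, 80))
  scheds <- list(
    constant = list(s = lr_schedule("constant", lr0 = 3e-3),
                    o = function(e) oracle_lr("constant", e, 3e-3)),
    piecewise = list(
      s = lr_schedule("piecewise_exponential", lr0 = 1e-3,
                      boundaries = c(30, 60), gammas = c(1, 0.95, 0.9)),
      o = function(e) oracle_lr("piecewise_exponential", e, 1e-3,
                                boundaries = c(30, 60),
                                gammas = c(1, 0.95, 0.9))),
    cosine = list(s = lr_schedule("cosine_annealing", lr0 = 1e-3,
                                  T_max = 80, lr_min = 1e-5),
                  o = function(e) oracle_lr("cosine_annealing", e, 1e-3,
                                            T_max = 80, lr_min = 1e-5)),
    stepped = list(s = lr_schedule("stepped", lr0 = 1e-3, step_size = 20,
                                   step_gamma = 0.5),
                   o = function(e) oracle_lr("stepped", e, 1e-3,
                                             step_size = 20, step_gamma = 0.5)),
    linear = list(s = lr_schedule("linear", lr0 = 1e-3, final_lr = 1e-5,
                                  total_epochs = 80),
                  o = function(e) oracle_lr("linear", e, 1e-3, final_lr = 1e-5,
                                            total_epochs = 80)))
  for (nm in names(scheds)) {
    got <- lr_at(scheds[[nm]]$s, epochs)
    expect_equal(got, scheds[[nm]]$o(epochs), tolerance = 1e-12, label = nm)
    expect_true(all(got > 0))
    expect_true(all(diff(got) <= 1e-12), label = paste(nm, "non-increasing"))
  }
})

test_that("piecewise-exponential decay is continuous and matches hand values", {
  s <- lr_schedule("piecewise_exponential", lr0 = 1e-3, boundaries = 10,
                   gammas = c(1, 0.5))
  expect_equal(lr_at(s, 12), 1e-3 * 0.5^2)     # hand closed form
  s2 <- lr_schedule("piecewise_exponential", lr0 = 2e-3,
                    boundaries = c(10, 25), gammas = c(0.99, 0.9, 0.7))
  for (b in c(10, 25))
    expect_equal(lr_at(s2, b - 1e-9), lr_at(s2, b), tolerance = 1e-6)
  co <- lr_schedule("cosine_annealing", lr0 = 5e-3, T_max = 40, lr_min = 0)
  expect_equal(lr_at(co, 0), 5e-3)
  expect_equal(lr_at(co, 40), 0)
  expect_error(lr_at(co, 41), "range")
  expect_error(lr_at(co, -1), "range")
})

test_that("Gaussian KL identities and positivity hold", {
  expect_equal(kl_gaussian(0, 0), 0)
  expect_equal(kl_gaussian(1, 0), 0.5)
  expect_equal(kl_gaussian(0, log(2)), 0.5 * (2 - 1 - log(2)))
  set.seed(3)
  for (k in 1:200) {
    mu <- rnorm(8, sd = 2); lv <- rnorm(8, sd = 1.5)
    expect_gte(kl_gaussian(mu, lv), 0)
  }
  # matrix form is per-sample
  mu <- matrix(c(0, 0, 1, 0), 2)
  lv <- matrix(0, 2, 2)
  expect_equal(kl_gaussian(mu, lv), c(0, 0.5))
  expect_error(kl_gaussian(c(0, Inf), c(0, 0)), "finite")
})

test_that("the combined objective decomposes exactly into its terms", {
  m <- fusion_model(tiny_model_config(), seed = 5)
  x <- array(rnorm(6 * 8 * 9 * 4), c(6, 8, 9, 4))
  out <- model_forward(m, x)
  l_full <- total_loss(out, 1L, x, lambda_vae = 0.7, beta = 0.3)
  l_ce <- total_loss(out, 1L, x, lambda_vae = 0, beta = 0)
  comp <- attr(l_full, "components")
  expect_equal(as.numeric(l_ce), comp[["ce"]])
  expect_equal(as.numeric(l_full) - as.numeric(l_ce),
               0.7 * comp[["mse"]] + 0.3 * comp[["kl"]])
  expect_equal(comp[["ce"]], -log(out$probs[1]))
  # perfect reconstruction and prior-matched posterior leave only CE
  perfect <- out
  xd <- aperm(x, c(2, 3, 4, 1)); dim(xd) <- c(8, 9, 24)
  perfect$recon <- xd
  perfect$mu <- c(0, 0); perfect$logvar <- c(0, 0)
  expect_equal(as.numeric(total_loss(perfect, 1L, x)),
               -log(out$probs[1]))
  # one-hot on the true class -> CE essentially zero
  hot <- out; hot$probs <- c(1 - 1e-12, 1e-12)
  expect_lt(attr(total_loss(hot, 1L, x), "components")[["ce"]], 1e-6)
  expect_error(total_loss(out, 5L, x), "range")
})

test_that("split construction partitions samples with the stated structure", {
  feats <- tiny_features()                     # 16 samples, 2 subjects
  n <- dim(feats$x)[5]
  loso <- make_splits(feats, split_plan("leave_one_subject_out"))
  expect_length(loso, 2)
  for (f in loso) {
    expect_setequal(c(f$train, f$test), seq_len(n))
    expect_length(intersect(feats$subjects[f$train],
                            feats$subjects[f$test]), 0)
  }
  expect_setequal(unlist(lapply(loso, `[[`, "test")), seq_len(n))

  kf <- make_splits(feats, split_plan("subject_dependent_kfold", k = 4, seed = 2))
  sizes <- vapply(kf, function(f) length(f$test), 0L)
  expect_equal(sort(sizes), rep(4L, 4))        # 16 samples into 4 equal folds
  tests <- unlist(lapply(kf, `[[`, "test"))
  expect_equal(sort(tests), seq_len(n))        # partition: disjoint + complete
  kf2 <- make_splits(feats, split_plan("subject_dependent_kfold", k = 4, seed = 2))
  expect_identical(kf, kf2)

  one <- feats; one$subjects <- rep("s", n)
  expect_error(make_splits(one, split_plan("leave_one_subject_out")),
               "subjects")
})

test_that("training is a no-op at lr 0 and reproducible under one seed", {
  feats <- tiny_features()
  cfg <- tiny_model_config()
  tc0 <- train_config(epochs = 1L, batch_size = 8L,
                      schedule = lr_schedule("constant", lr0 = 1e-12), seed = 3)
  fit0 <- train_model(feats, cfg, tc0)
  init <- fusion_model(cfg, seed = eegfusion:::derive_seed(3L, "init"))
  expect_equal(eegfusion:::flatten_params(fit0$model$params),
               eegfusion:::flatten_params(init$params), tolerance = 1e-8)

  tc <- train_config(epochs = 2L, batch_size = 8L,
                     schedule = lr_schedule("constant", lr0 = 1e-3), seed = 7)
  f1 <- train_model(feats, cfg, tc)
  f2 <- train_model(feats, cfg, tc)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
  expect_equal(nrow(f1$history), 2)
  expect_equal(f1$history$lr, c(1e-3, 1e-3))
  expect_error(train_model(feats, cfg, tc, fold = list(train = integer(0))),
               "empty")
})

test_that("a separable two-class problem is learned to near-perfection", {
  feats <- tiny_features()                     # strong opposing signatures
  cfg <- model_config(cnn_channels = c(4L, 8L), lstm_hidden = 8L,
                      dcign_channels = c(4L, 8L), latent_dim = 4L,
                      fusion_hidden = 16L, n_classes = 2L)
  tc <- train_config(epochs = 30L, batch_size = 8L,
                     schedule = lr_schedule("piecewise_exponential", lr0 = 3e-3,
                                            boundaries = 20, gammas = c(1, 0.8)),
                     seed = 1)
  fit <- train_model(feats, cfg, tc)
  expect_gte(tail(fit$history$train_acc, 1), 0.99)
})
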