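test_that("convolution and max-pooling primitives match hand calculations", {
  # 2x2 input, 1x1 identity kernel, 2x2 max-pool -> the maximum, 4
  x <- array(c(1, 3, 2, 4), c(2, 2, 1, 1))      # [[1,2],[3,4]] column-major
  plan <- eegfusion:::conv_plan(2L, 2L, 1L, 1L, 1L)
  cv <- eegfusion:::conv_forward(x, matrix(1, 1, 1), 0, plan)
  expect_equal(drop(cv$out), matrix(c(1, 3, 2, 4), 2))
  pl <- eegfusion:::pool_forward(cv$out, eegfusion:::pool_plan(2L, 2L))
  expect_equal(as.vector(pl$out), 4)

  # 3x3 same-pad convolution against a direct double loop
  set.seed(4)
  x2 <- array(rnorm(8 * 9 * 3 * 2), c(8, 9, 3, 2))
  Wm <- matrix(rnorm(5 * 27), 5, 27)
  b <- rnorm(5)
  plan2 <- eegfusion:::conv_plan(8L, 9L, 3L, 3L, 1L)
  out <- eegfusion:::conv_forward(x2, Wm, b, plan2)$out
  Wa <- array(t(Wm), c(3, 3, 3, 5))
  xp <- array(0, c(10, 11, 3, 2)); xp[2:9, 2:10, , ] <- x2
  ref <- function(i, j, k, n)
    sum(Wa[, , , k] * xp[i:(i + 2), j:(j + 2), , n]) + b[k]
  for (pt in list(c(1, 1, 1, 1), c(4, 7, 3, 2), c(8, 9, 5, 1)))
    expect_equal(out[pt[1], pt[2], pt[3], pt[4]],
                 ref(pt[1], pt[2], pt[3], pt[4]))
})

test_that("cnn_encode obeys the ReLU zero cases and shape contract", {
  m <- fusion_model(tiny_model_config(), seed = 2)
  x <- array(rnorm(8 * 9 * 4), c(8, 9, 4))
  f <- cnn_encode(m, x)
  expect_length(f, m$plans$dims$cnn_flat)
  # zero input with zero biases -> zero features
  expect_equal(cnn_encode(m, array(0, c(8, 9, 4))),
               numeric(m$plans$dims$cnn_flat))
  # very negative biases drive all pre-activations below zero
  m2 <- m
  m2$params$cnn[[1]]$b <- rep(-1e6, length(m2$params$cnn[[1]]$b))
  expect_equal(cnn_encode(m2, x), numeric(m$plans$dims$cnn_flat))
  expect_error(cnn_encode(m, array(0, c(4, 4, 4))), "shape")
})

test_that("the BiLSTM recursion matches a scalar oracle and merge algebra", {
  # all-zero parameters -> h stays 0 (f = i = o = 0.5, c~ = 0)
  cfg <- model_config(cnn_channels = c(2L, 2L), lstm_hidden = 3L,
                      dcign_channels = c(2L, 2L), latent_dim = 2L,
                      fusion_hidden = 4L, n_classes = 2L)
  m <- fusion_model(cfg, seed = 1)
  D <- m$plans$dims$cnn_flat
  zero_dir <- list(Wx = matrix(0, 12, D), Wh = matrix(0, 12, 3), b = rep(0, 12))
  m0 <- m; m0$params$lstm <- list(fwd = zero_dir, bwd = zero_dir)
  xs <- lapply(1:6, function(t) rnorm(D))
  expect_equal(bilstm_encode(m0, xs), rep(0, 6))

  # sum vs average on identical params and input
  s <- bilstm_encode(m, xs, merge_mode = "sum")
  a <- bilstm_encode(m, xs, merge_mode = "average")
  expect_equal(a, s / 2)
  expect_length(bilstm_encode(m, xs, merge_mode = "concat"), 6)
  expect_error(bilstm_encode(m, list()), "empty")

  # one-unit LSTM against an independent scalar recursion
  set.seed(9)
  wx <- rnorm(4); wh <- rnorm(4); b <- rnorm(4)
  p <- list(Wx = matrix(wx, 4, 1), Wh = matrix(wh, 4, 1), b = b)
  x_seq <- rnorm(5)
  xs1 <- lapply(x_seq, function(v) matrix(v, 1, 1))
  got <- eegfusion:::lstm_forward(xs1, p, 1L)$h
  expect_equal(as.vector(got), oracle_lstm_scalar(x_seq, wx, wh, b),
               tolerance = 1e-10)
})

test_that("VAE encoder, reparameterization and decoder contracts hold", {
  cfg <- tiny_model_config()
  m <- fusion_model(cfg, seed = 6)
  x <- array(rnorm(8 * 9 * 24), c(8, 9, 24))
  enc <- dcign_encode(m, x)
  expect_length(enc$mu, 2)
  expect_length(enc$logvar, 2)
  # zero input and zeroed latent heads -> mu = logvar = 0
  m0 <- m
  m0$params$fc_mu$W[] <- 0; m0$params$fc_lv$W[] <- 0
  enc0 <- dcign_encode(m0, array(0, c(8, 9, 24)))
  expect_equal(enc0$mu, c(0, 0))
  expect_equal(enc0$logvar, c(0, 0))
  # different inputs give different mu; batches preserve order
  enc2 <- dcign_encode(m, x * 2 + 1)
  expect_false(isTRUE(all.equal(enc$mu, enc2$mu)))
  xb <- array(c(x, x * 2 + 1), c(8, 9, 24, 2))
  encb <- dcign_encode(m, xb)
  expect_equal(encb$mu[, 1], enc$mu)
  expect_equal(encb$mu[, 2], enc2$mu)

  # reparameterization: seeded, collapses to mu at tiny variance
  z1 <- reparameterize(enc$mu, enc$logvar, seed = 4)
  z2 <- reparameterize(enc$mu, enc$logvar, seed = 4)
  expect_identical(z1, z2)
  expect_equal(reparameterize(enc$mu, rep(-100, 2), seed = 1), enc$mu,
               tolerance = 1e-6)
  set.seed(31)
  z <- reparameterize(matrix(0, 1, 1e5), matrix(0, 1, 1e5))
  expect_lt(abs(mean(z)), 0.02)
  expect_lt(abs(var(as.vector(z)) - 1), 0.02)

  # decoder symmetry and zero case
  xr <- dcign_decode(m, enc$mu)
  expect_equal(dim(xr), c(8, 9, 24))
  md <- m
  md$params$dec_fc$W[] <- 0; md$params$dec_fc$b[] <- 0
  for (j in seq_along(md$params$dec_conv)) {
    md$params$dec_conv[[j]]$W[] <- 0; md$params$dec_conv[[j]]$b[] <- 0
  }
  expect_equal(dcign_decode(md, c(0, 0)), array(0, c(8, 9, 24)))
  zb <- matrix(rnorm(6), 2, 3)
  outb <- dcign_decode(m, zb)
  expect_equal(outb[, , , 2], dcign_decode(m, zb[, 2]))
  expect_error(dcign_decode(m, rnorm(5)), "latent_dim")
})

test_that("fusion head emits a simplex and saturates correctly", {
  cfg <- tiny_model_config()
  m <- fusion_model(cfg, seed = 8)
  tm <- rnorm(m$plans$dims$temporal_dim)
  mu <- rnorm(2)
  p <- fuse_and_classify(m, tm, mu)
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_true(all(p >= 0))
  # zero parameters -> uniform probabilities
  m0 <- m
  m0$params$fuse$fc1$W[] <- 0; m0$params$fuse$fc1$b[] <- 0
  m0$params$fuse$fc2$W[] <- 0; m0$params$fuse$fc2$b[] <- 0
  expect_equal(fuse_and_classify(m0, tm, mu), rep(0.5, 2))
  # saturated logits through the final layer
  msat <- m0
  msat$params$fuse$fc2$b <- c(1000, 0)
  expect_equal(fuse_and_classify(msat, tm, mu), c(1, 0))
  expect_error(fuse_and_classify(m, rnorm(3), mu), "dims")
})

test_that("model_forward is deterministic in eval mode and wires the streams", {
  cfg <- tiny_model_config()
  m <- fusion_model(cfg, seed = 10)
  x <- array(rnorm(6 * 8 * 9 * 4), c(6, 8, 9, 4))
  o1 <- model_forward(m, x)
  o2 <- model_forward(m, x)
  expect_identical(o1$probs, o2$probs)
  expect_identical(o1$recon, o2$recon)
  expect_equal(dim(o1$recon), c(8, 9, 24))
  expect_equal(sum(o1$probs), 1, tolerance = 1e-6)

  # forward == manual composition of the public per-component ops,
  # which also certifies the CNN weights are shared across all 6 steps
  feats <- lapply(1:6, function(t) cnn_encode(m, x[t, , , ]))
  tm <- bilstm_encode(m, feats)
  xd <- aperm(x, c(2, 3, 4, 1)); dim(xd) <- c(8, 9, 24)
  enc <- dcign_encode(m, xd)
  expect_equal(o1$mu, enc$mu)
  expect_equal(fuse_and_classify(m, tm, enc$mu), o1$probs)

  # train mode: stochastic in z, controlled entirely by the noise seed
  t1 <- model_forward(m, x, mode = "train", noise_seed = 3)
  t2 <- model_forward(m, x, mode = "train", noise_seed = 3)
  t3 <- model_forward(m, x, mode = "train", noise_seed = 4)
  expect_identical(t1$z, t2$z)
  expect_false(identical(t1$z, t3$z))
  expect_identical(t1$probs, o1$probs)    # classifier consumes mu, not z

  # probability simplex invariant over random params and inputs
  for (k in 1:25) {
    mk <- fusion_model(cfg, seed = 100 + k)
    xk <- array(rnorm(6 * 8 * 9 * 4, sd = runif(1, 0.1, 3)), c(6, 8, 9, 4))
    pk <- model_forward(mk, xk)$probs
    expect_equal(sum(pk), 1, tolerance = 1e-6)
    expect_true(all(pk >= 0))
  }
})

test_that("checkpoints round-trip bit-exactly with a JSON sidecar", {
  m <- fusion_model(tiny_model_config(), seed = 12)
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(m, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- load_checkpoint(path)
  expect_identical(back$params, m$params)
  expect_equal(unclass(back$config), unclass(m$config))
  x <- array(rnorm(6 * 8 * 9 * 4), c(6, 8, 9, 4))
  expect_identical(model_forward(back, x)$probs, model_forward(m, x)$probs)
  expect_error(load_checkpoint(withr::local_tempfile(lines = "x",
                                                     fileext = ".rds")))
})
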