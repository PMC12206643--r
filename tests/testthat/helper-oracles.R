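# Independent oracles and small shared fixtures. These deliberately avoid
# the package's own code paths: band power comes from direct periodogram
# integration, entropy from a histogram plug-in, schedules from literal
# re-statements of the closed forms, and the LSTM from a scalar recursion.

# raw-periodogram band power (uV^2) of a vector between lo and hi Hz
periodogram_band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  X <- fft(x - mean(x))
  half <- if (n %% 2 == 0) n / 2 - 1 else (n - 1) / 2
  k <- 2:(half + 1)
  f <- (k - 1) * fs / n
  p <- 2 * Mod(X[k])^2 / n^2
  sum(p[f > lo & f <= hi])
}

# histogram plug-in differential entropy (nats)
hist_entropy <- function(x, nbins = 100) {
  h <- hist(x, breaks = nbins, plot = FALSE)
  p <- h$counts / sum(h$counts)
  w <- diff(h$breaks)[1]
  p <- p[p > 0]
  -sum(p * log(p)) + log(w)
}

# literal closed-form learning-rate table, coded independently of lr_at()
oracle_lr <- function(kind, e, lr0, boundaries = NULL, gammas = NULL,
                      T_max = NULL, lr_min = NULL, step_size = NULL,
                      step_gamma = NULL, final_lr = NULL, total_epochs = NULL) {
  if (kind == "constant") return(rep(lr0, length(e)))
  if (kind == "cosine_annealing")
    return(lr_min + 0.5 * (lr0 - lr_min) * (1 + cos(pi * e / T_max)))
  if (kind == "stepped") return(lr0 * step_gamma^floor(e / step_size))
  if (kind == "linear") return(lr0 + (final_lr - lr0) * e / total_epochs)
  # piecewise exponential: walk epoch by epoch, multiplying by the factor of
  # the segment the epoch is entering (a different construction from lr_at)
  vapply(e, function(ei) {
    lr <- lr0
    if (ei < 1) return(lr * gammas[1]^ei)
    for (step in seq_len(floor(ei))) {
      seg <- findInterval(step - 1, boundaries) + 1
      lr <- lr * gammas[seg]
    }
    seg <- findInterval(floor(ei), boundaries) + 1
    lr * gammas[seg]^(ei - floor(ei))
  }, 0)
}

# scalar LSTM step oracle (single unit), literal gate equations
oracle_lstm_scalar <- function(x_seq, wx, wh, b, h0 = 0, c0 = 0) {
  sig <- function(u) 1 / (1 + exp(-u))
  h <- h0; cc <- c0
  for (x in x_seq) {
    i <- sig(wx[1] * x + wh[1] * h + b[1])
    f <- sig(wx[2] * x + wh[2] * h + b[2])
    g <- tanh(wx[3] * x + wh[3] * h + b[3])
    o <- sig(wx[4] * x + wh[4] * h + b[4])
    cc <- f * cc + i * g
    h <- o * tanh(cc)
  }
  h
}

# ---- small shared fixtures ------------------------------------------------

tiny_dataset_spec <- function(seed = 11L, jitter = 0.2, ...) {
  bp <- function(theta, alpha)
    rbind(theta = rep(theta, 3), alpha = rep(alpha, 3),
          beta = rep(1, 3), gamma = rep(1, 3))
  dataset_spec(n_subjects = 2L, trials_per_class = 2L,
               classes = list(
                 emotion_class_spec("low", bp(3, 0.8), jitter_sd = jitter),
                 emotion_class_spec("high", bp(0.8, 3), jitter_sd = jitter)),
               duration_s = 12, fs = 200, montage = "cap32", seed = seed, ...)
}

tiny_features <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- extract_features(tiny_dataset_spec(), stride = 6L)
    cache
  }
})

tiny_model_config <- function(n_classes = 2L)
  model_config(input_shape = c(8L, 9L, 4L), t_steps = 6L,
               cnn_channels = c(2L, 3L), lstm_hidden = 2L,
               dcign_channels = c(2L, 2L, 2L), latent_dim = 2L,
               fusion_hidden = 4L, n_classes = n_classes)

# a small separable experiment used by training/evaluation tests
small_experiment_config <- function(seed = 5L)
  experiment_config(
    dataset = dataset_spec(n_subjects = 3L, trials_per_class = 4L,
                           classes = default_class_specs("seed3"),
                           duration_s = 12, fs = 200, montage = "cap32",
                           seed = 21L),
    stride = 6L,
    model = model_config(input_shape = c(8L, 9L, 4L),
                         cnn_channels = c(4L, 8L), lstm_hidden = 8L,
                         dcign_channels = c(4L, 8L, 8L), latent_dim = 4L,
                         fusion_hidden = 16L, n_classes = 3L),
    train = train_config(epochs = 4L, batch_size = 16L,
                         schedule = lr_schedule("piecewise_exponential",
                                                lr0 = 3e-3, boundaries = 2,
                                                gammas = c(1, 0.6))),
    k = 3L, seed = seed)
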