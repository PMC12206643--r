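#' Dual-stream model configuration
#'
#' Describes the CNN-BiLSTM temporal stream, the convolutional-VAE
#' (DC-IGN-style) probabilistic stream, and the fully connected fusion head.
#' The CNN encodes each of the `t_steps` (row, col, band) maps with shared
#' weights (3x3 kernels, ReLU, ceil-mode 2x2 max-pooling); the BiLSTM runs
#' over the step features and merges directions by `merge_mode`; the VAE
#' encoder applies stride-2 3x3 convolutions to the full stack (bands x
#' time as channels) and parameterizes a diagonal Gaussian posterior of
#' dimension `latent_dim`; the decoder mirrors it with
#' upsample-convolution blocks. Fusion concatenates the temporal feature
#' with the latent mean and classifies through dense layers and softmax.
#'
#' @param input_shape Per-step tensor shape (rows, cols, bands); default
#'   `c(8, 9, 4)`.
#' @param t_steps Number of time steps per sample (default 6).
#' @param cnn_channels Channel widths of the per-step CNN conv blocks.
#' @param lstm_hidden BiLSTM hidden size H per direction.
#' @param merge_mode `"concat"` (dim 2H), `"sum"` or `"average"` (dim H).
#' @param dcign_channels Encoder channel ladder (one stride-2 conv each).
#' @param latent_dim Latent dimension d (>= 1).
#' @param fusion_hidden Width of the fusion hidden layer.
#' @param n_classes Number of emotion classes (>= 2).
#' @return A `model_config` object.
#' @export
model_config <- function(input_shape = c(8L, 9L, 4L), t_steps = 6L,
                         cnn_channels = c(32L, 64L), lstm_hidden = 64L,
                         merge_mode = "concat",
                         dcign_channels = c(32L, 64L, 128L),
                         latent_dim = 64L, fusion_hidden = 128L,
                         n_classes = 3L) {
  if (!merge_mode %in% c("concat", "sum", "average"))
    stop_invalid("merge_mode must be one of concat, sum, average")
  if (latent_dim < 1) stop_invalid("latent_dim must be >= 1")
  if (n_classes < 2) stop_invalid("n_classes must be >= 2")
  structure(list(input_shape = as.integer(input_shape),
                 t_steps = as.integer(t_steps),
                 cnn_channels = as.integer(cnn_channels),
                 cnn_kernel = 3L,
                 lstm_hidden = as.integer(lstm_hidden),
                 merge_mode = merge_mode,
                 dcign_channels = as.integer(dcign_channels),
                 dcign_kernel = 3L,
                 latent_dim = as.integer(latent_dim),
                 fusion_hidden = as.integer(fusion_hidden),
                 n_classes = as.integer(n_classes)),
            class = "model_config")
}

# spatial/width bookkeeping derived from a config
model_dims <- function(cfg) {
  H <- cfg$input_shape[1]; W <- cfg$input_shape[2]; C <- cfg$input_shape[3]
  cnn_sizes <- list(c(H, W))
  h <- H; w <- W
  for (i in seq_along(cfg$cnn_channels)) {
    h <- ceiling(h / 2); w <- ceiling(w / 2)   # after the 2x2 ceil pool
    cnn_sizes[[i + 1L]] <- c(h, w)
  }
  cnn_flat <- h * w * cfg$cnn_channels[length(cfg$cnn_channels)]
  temporal_dim <- if (cfg$merge_mode == "concat") 2L * cfg$lstm_hidden
                  else cfg$lstm_hidden
  Cd <- C * cfg$t_steps
  enc_sizes <- list(c(H, W))
  h <- H; w <- W
  for (i in seq_along(cfg$dcign_channels)) {
    h <- ceiling(h / 2); w <- ceiling(w / 2)   # stride-2 conv
    enc_sizes[[i + 1L]] <- c(h, w)
  }
  enc_flat <- h * w * cfg$dcign_channels[length(cfg$dcign_channels)]
  list(H = H, W = W, C = C, Cd = Cd, cnn_sizes = cnn_sizes,
       cnn_flat = cnn_flat, temporal_dim = temporal_dim,
       enc_sizes = enc_sizes, enc_flat = enc_flat,
       fusion_in = temporal_dim + cfg$latent_dim)
}

build_plans <- function(cfg) {
  dm <- model_dims(cfg)
  k <- cfg$cnn_kernel
  cnn <- list()
  cin <- dm$C
  for (i in seq_along(cfg$cnn_channels)) {
    sz <- dm$cnn_sizes[[i]]
    cnn[[i]] <- list(conv = conv_plan(sz[1], sz[2], cin, k, 1L),
                     pool = pool_plan(sz[1], sz[2]))
    cin <- cfg$cnn_channels[i]
  }
  kd <- cfg$dcign_kernel
  enc <- list()
  cin <- dm$Cd
  for (i in seq_along(cfg$dcign_channels)) {
    sz <- dm$enc_sizes[[i]]
    enc[[i]] <- conv_plan(sz[1], sz[2], cin, kd, 2L)
    cin <- cfg$dcign_channels[i]
  }
  ns <- length(cfg$dcign_channels)
  dec <- list()
  # stage j upsamples from enc size (ns + 1 - j + 1) to (ns + 1 - j) and
  # convolves; the final stage emits Cd channels linearly
  for (j in seq_len(ns)) {
    target <- dm$enc_sizes[[ns + 1L - j]]
    cin <- cfg$dcign_channels[ns + 1L - j]
    dec[[j]] <- list(target = target,
                     conv = conv_plan(target[1], target[2], cin, kd, 1L))
  }
  list(cnn = cnn, enc = enc, dec = dec, dims = dm)
}

he_conv <- function(K, kkC) matrix(rnorm(K * kkC, 0, sqrt(2 / kkC)), K, kkC)
he_dense <- function(nout, nin, scale = 2)
  matrix(rnorm(nout * nin, 0, sqrt(scale / nin)), nout, nin)

init_params <- function(cfg, seed = 1L) {
  dm <- model_dims(cfg)
  with_seed(seed, {
    k2 <- cfg$cnn_kernel^2
    cnn <- list(); cin <- dm$C
    for (i in seq_along(cfg$cnn_channels)) {
      K <- cfg$cnn_channels[i]
      cnn[[i]] <- list(W = he_conv(K, k2 * cin), b = numeric(K))
      cin <- K
    }
    H <- cfg$lstm_hidden; D <- dm$cnn_flat
    u <- 1 / sqrt(H)
    lstm_dir <- function()
      list(Wx = matrix(runif(4 * H * D, -u, u), 4 * H, D),
           Wh = matrix(runif(4 * H * H, -u, u), 4 * H, H),
           b = numeric(4 * H))
    lstm <- list(fwd = lstm_dir(), bwd = lstm_dir())
    kd2 <- cfg$dcign_kernel^2
    enc <- list(); cin <- dm$Cd
    for (i in seq_along(cfg$dcign_channels)) {
      K <- cfg$dcign_channels[i]
      enc[[i]] <- list(W = he_conv(K, kd2 * cin), b = numeric(K))
      cin <- K
    }
    d <- cfg$latent_dim
    fc_mu <- list(W = he_dense(d, dm$enc_flat, 1), b = numeric(d))
    fc_lv <- list(W = he_dense(d, dm$enc_flat, 1) * 0.1, b = numeric(d))
    ns <- length(cfg$dcign_channels)
    last_sz <- dm$enc_sizes[[ns + 1L]]
    dec_fc <- list(W = he_dense(last_sz[1] * last_sz[2] * cfg$dcign_channels[ns], d),
                   b = numeric(last_sz[1] * last_sz[2] * cfg$dcign_channels[ns]))
    dec_conv <- list()
    for (j in seq_len(ns)) {
      cin <- cfg$dcign_channels[ns + 1L - j]
      cout <- if (j < ns) cfg$dcign_channels[ns - j] else dm$Cd
      dec_conv[[j]] <- list(W = he_conv(cout, kd2 * cin), b = numeric(cout))
    }
    fuse <- list(fc1 = list(W = he_dense(cfg$fusion_hidden, dm$fusion_in),
                            b = numeric(cfg$fusion_hidden)),
                 fc2 = list(W = he_dense(cfg$n_classes, cfg$fusion_hidden, 1),
                            b = numeric(cfg$n_classes)))
    list(cnn = cnn, lstm = lstm, enc = enc, fc_mu = fc_mu, fc_lv = fc_lv,
         dec_fc = dec_fc, dec_conv = dec_conv, fuse = fuse)
  })
}

#' Construct an initialized dual-stream model
#'
#' @param config A [model_config()].
#' @param seed Integer seed for weight initialization.
#' @return A `fusion_model` (config, parameters and cached layer plans).
#' @export
fusion_model <- function(config = model_config(), seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  structure(list(config = config, params = init_params(config, seed),
                 plans = build_plans(config)),
            class = "fusion_model")
}

#' @export
print.fusion_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<fusion_model: CNN(%s)-BiLSTM(H=%d, %s) + convVAE(%s, d=%d)",
                     " -> fusion(%d) -> %d classes; %d parameters>\n"),
              paste(cfg$cnn_channels, collapse = "-"), cfg$lstm_hidden,
              cfg$merge_mode, paste(cfg$dcign_channels, collapse = "-"),
              cfg$latent_dim, cfg$fusion_hidden, cfg$n_classes,
              length(flatten_params(x$params))))
  invisible(x)
}

# ---- full forward/backward on a packed batch (H, W, C, T, N) --------------

cnn_stack_forward <- function(xb, params, plans) {
  caches <- list()
  x <- xb
  for (i in seq_along(plans$cnn)) {
    cv <- conv_forward(x, params$cnn[[i]]$W, params$cnn[[i]]$b, plans$cnn[[i]]$conv)
    rl <- relu_forward(cv$out)
    pl <- pool_forward(rl$out, plans$cnn[[i]]$pool)
    caches[[i]] <- list(conv = cv$cache, relu = rl$cache, pool = pl$cache)
    x <- pl$out
  }
  d <- dim(x)
  dim(x) <- c(d[1] * d[2] * d[3], d[4])
  list(out = x, caches = caches, out_dim = d)
}

cnn_stack_backward <- function(dflat, fwd, params, plans) {
  dx <- dflat
  dim(dx) <- fwd$out_dim
  grads <- vector("list", length(plans$cnn))
  for (i in rev(seq_along(plans$cnn))) {
    ch <- fwd$caches[[i]]
    dx <- pool_backward(dx, ch$pool)
    dx <- relu_backward(dx, ch$relu)
    cb <- conv_backward(dx, ch$conv)
    grads[[i]] <- list(W = cb$dW, b = cb$db)
    dx <- cb$dx
  }
  list(dx = dx, grads = grads)
}

encoder_forward <- function(xd, params, plans) {
  caches <- list()
  x <- xd
  for (i in seq_along(plans$enc)) {
    cv <- conv_forward(x, params$enc[[i]]$W, params$enc[[i]]$b, plans$enc[[i]])
    rl <- relu_forward(cv$out)
    caches[[i]] <- list(conv = cv$cache, relu = rl$cache)
    x <- rl$out
  }
  d <- dim(x)
  dim(x) <- c(d[1] * d[2] * d[3], d[4])
  mu_f <- dense_forward(x, params$fc_mu$W, params$fc_mu$b)
  lv_f <- dense_forward(x, params$fc_lv$W, params$fc_lv$b)
  list(mu = mu_f$out, logvar = lv_f$out,
       caches = list(conv = caches, flat_dim = d, mu = mu_f$cache,
                     lv = lv_f$cache))
}

encoder_backward <- function(dmu, dlv, fwd, params, plans) {
  gmu <- dense_backward(dmu, fwd$caches$mu)
  glv <- dense_backward(dlv, fwd$caches$lv)
  dflat <- gmu$dx + glv$dx
  dim(dflat) <- fwd$caches$flat_dim
  grads <- vector("list", length(plans$enc))
  dx <- dflat
  for (i in rev(seq_along(plans$enc))) {
    ch <- fwd$caches$conv[[i]]
    dx <- relu_backward(dx, ch$relu)
    cb <- conv_backward(dx, ch$conv)
    grads[[i]] <- list(W = cb$dW, b = cb$db)
    dx <- cb$dx
  }
  list(dx = dx, grads = grads,
       fc_mu = list(W = gmu$dW, b = gmu$db),
       fc_lv = list(W = glv$dW, b = glv$db))
}

decoder_forward <- function(z, params, plans, cfg) {
  ns <- length(plans$dec)
  fc <- dense_forward(z, params$dec_fc$W, params$dec_fc$b)
  rl0 <- relu_forward(fc$out)
  sz <- plans$dims$enc_sizes[[ns + 1L]]
  x <- rl0$out
  dim(x) <- c(sz[1], sz[2], cfg$dcign_channels[ns], ncol(z))
  caches <- vector("list", ns)
  for (j in seq_len(ns)) {
    st <- plans$dec[[j]]
    up <- upsample_forward(x, st$target[1], st$target[2])
    cv <- conv_forward(up$out, params$dec_conv[[j]]$W, params$dec_conv[[j]]$b,
                       st$conv)
    if (j < ns) {
      rl <- relu_forward(cv$out)
      caches[[j]] <- list(up = up$cache, conv = cv$cache, relu = rl$cache)
      x <- rl$out
    } else {
      caches[[j]] <- list(up = up$cache, conv = cv$cache)
      x <- cv$out
    }
  }
  list(out = x, caches = list(fc = fc$cache, relu0 = rl0$cache,
                              stages = caches, z_n = ncol(z)))
}

decoder_backward <- function(drecon, fwd, params, plans, cfg) {
  ns <- length(plans$dec)
  grads_conv <- vector("list", ns)
  dx <- drecon
  for (j in rev(seq_len(ns))) {
    ch <- fwd$caches$stages[[j]]
    if (j < ns) dx <- relu_backward(dx, ch$relu)
    cb <- conv_backward(dx, ch$conv)
    grads_conv[[j]] <- list(W = cb$dW, b = cb$db)
    dx <- upsample_backward(cb$dx, ch$up)
  }
  d <- dim(dx)
  dim(dx) <- c(d[1] * d[2] * d[3], d[4])
  dx <- relu_backward(dx, fwd$caches$relu0)
  gfc <- dense_backward(dx, fwd$caches$fc)
  list(dz = gfc$dx, dec_fc = list(W = gfc$dW, b = gfc$db),
       dec_conv = grads_conv)
}

fusion_forward <- function(temporal, mu, params) {
  ft <- rbind(temporal, mu)
  f1 <- dense_forward(ft, params$fuse$fc1$W, params$fuse$fc1$b)
  r1 <- relu_forward(f1$out)
  f2 <- dense_forward(r1$out, params$fuse$fc2$W, params$fuse$fc2$b)
  list(logits = f2$out,
       caches = list(f1 = f1$cache, r1 = r1$cache, f2 = f2$cache,
                     n_temporal = nrow(temporal)))
}

fusion_backward <- function(dlogits, fwd, params) {
  g2 <- dense_backward(dlogits, fwd$caches$f2)
  dr <- relu_backward(g2$dx, fwd$caches$r1)
  g1 <- dense_backward(dr, fwd$caches$f1)
  M <- fwd$caches$n_temporal
  list(dtemporal = g1$dx[seq_len(M), , drop = FALSE],
       dmu = g1$dx[-seq_len(M), , drop = FALSE],
       grads = list(fc1 = list(W = g1$dW, b = g1$db),
                    fc2 = list(W = g2$dW, b = g2$db)))
}

# Full forward pass over a packed batch xb (H, W, C, T, N).
# mode "eval": z = mu (deterministic). mode "train": z = mu + sigma * eps
# with eps either supplied (d x N, for gradient checking) or drawn from the
# current RNG stream.
forward_full <- function(model, xb, mode = "eval", eps = NULL) {
  cfg <- model$config; plans <- model$plans; params <- model$params
  d <- dim(xb)
  stopifnot(length(d) == 5L)
  T <- d[4]; N <- d[5]
  x4 <- xb
  dim(x4) <- c(d[1], d[2], d[3], T * N)
  cnn <- cnn_stack_forward(x4, params, plans)
  xs <- lapply(seq_len(T), function(t)
    cnn$out[, seq.int(t, T * N, by = T), drop = FALSE])
  bil <- bilstm_forward(xs, params$lstm, cfg$lstm_hidden, cfg$merge_mode)
  xd <- xb
  dim(xd) <- c(d[1], d[2], d[3] * T, N)
  enc <- encoder_forward(xd, params, plans)
  if (mode == "train") {
    if (is.null(eps))
      eps <- matrix(rnorm(cfg$latent_dim * N), cfg$latent_dim, N)
    z <- enc$mu + exp(enc$logvar / 2) * eps
  } else {
    eps <- NULL
    z <- enc$mu
  }
  dec <- decoder_forward(z, params, plans, cfg)
  fus <- fusion_forward(bil$out, enc$mu, params)
  zmax <- apply(fus$logits, 2, max)
  lse <- log(colSums(exp(sweep(fus$logits, 2, zmax)))) + zmax
  logp <- sweep(fus$logits, 2, lse)
  list(probs = exp(logp), logp = logp, mu = enc$mu, logvar = enc$logvar,
       z = z, eps = eps, recon = dec$out, xd = xd, temporal = bil$out,
       caches = list(cnn = cnn, bil = bil, enc = enc, dec = dec, fus = fus,
                     dims = d, mode = mode))
}

# Backward pass for L = CE + lambda*MSE + beta*KL averaged over the batch.
backward_full <- function(model, fw, labels, lambda_vae, beta) {
  cfg <- model$config; plans <- model$plans; params <- model$params
  d <- fw$caches$dims
  T <- d[4]; N <- d[5]
  K <- cfg$n_classes
  Y <- matrix(0, K, N)
  Y[cbind(labels, seq_len(N))] <- 1
  dlogits <- (fw$probs - Y) / N
  fb <- fusion_backward(dlogits, fw$caches$fus, params)

  numel <- prod(dim(fw$xd)[1:3])
  drecon <- (2 * lambda_vae / (numel * N)) * (fw$recon - fw$xd)
  db <- decoder_backward(drecon, fw$caches$dec, params, plans, cfg)

  dmu <- fb$dmu + db$dz + (beta / N) * fw$mu
  dlv <- (beta / N) * 0.5 * (exp(fw$logvar) - 1)
  if (identical(fw$caches$mode, "train")) {
    dlv <- dlv + db$dz * fw$eps * 0.5 * exp(fw$logvar / 2)
  }
  eb <- encoder_backward(dmu, dlv, fw$caches$enc, params, plans)

  bb <- bilstm_backward(fb$dtemporal, fw$caches$bil$cache, params$lstm)
  Fdim <- nrow(fw$caches$cnn$out)
  dflat <- matrix(0, Fdim, T * N)
  for (t in seq_len(T))
    dflat[, seq.int(t, T * N, by = T)] <- bb$dxs[[t]]
  cb <- cnn_stack_backward(dflat, fw$caches$cnn, params, plans)

  list(cnn = cb$grads, lstm = bb$grads, enc = eb$grads,
       fc_mu = eb$fc_mu, fc_lv = eb$fc_lv, dec_fc = db$dec_fc,
       dec_conv = db$dec_conv, fuse = fb$grads)
}

# loss components for a forward pass (means over the batch)
loss_components <- function(fw, labels, lambda_vae, beta) {
  N <- ncol(fw$probs)
  ce <- -mean(fw$logp[cbind(labels, seq_len(N))])
  numel <- prod(dim(fw$xd)[1:3])
  mse <- sum((fw$recon - fw$xd)^2) / (numel * N)
  kl <- mean(0.5 * colSums(fw$mu^2 + exp(fw$logvar) - 1 - fw$logvar))
  list(total = ce + lambda_vae * mse + beta * kl, ce = ce, mse = mse, kl = kl)
}

# ---- parameter flattening (stable depth-first order) ----------------------

flatten_params <- function(p) {
  if (is.list(p)) return(unlist(lapply(p, flatten_params), use.names = FALSE))
  as.numeric(p)
}

unflatten_params <- function(template, v) {
  pos <- 0L
  rebuild <- function(x) {
    if (is.list(x)) return(lapply(x, rebuild))
    n <- length(x)
    out <- v[(pos + 1L):(pos + n)]
    pos <<- pos + n
    attributes(out) <- attributes(x)
    out
  }
  rebuild(template)
}

# ---- public per-component operations --------------------------------------

as_packed_batch <- function(x, cfg) {
  if (inherits(x, "feature_4d_sample")) x <- x$tensor
  d <- dim(x)
  if (length(d) == 4L) {               # (t, row, col, band) single sample
    x <- aperm(x, c(2, 3, 4, 1))
    dim(x) <- c(d[2], d[3], d[4], d[1], 1L)
  } else if (length(d) != 5L) {
    stop_invalid("expected a (t, row, col, band) sample or packed batch")
  }
  d <- dim(x)
  expect <- c(cfg$input_shape, cfg$t_steps)
  if (!identical(as.integer(d[1:4]), as.integer(expect)))
    stop_invalid("input shape (%s) does not match model config (%s)",
                 paste(d[1:4], collapse = ","), paste(expect, collapse = ","))
  x
}

#' Encode one time-step tensor with the shared CNN
#'
#' @param model A [fusion_model()].
#' @param step_tensor A (rows, cols, bands) array, or a batch with a fourth
#'   sample dimension.
#' @return Feature vector (or matrix, columns = samples) of the CNN flatten
#'   size.
#' @export
cnn_encode <- function(model, step_tensor) {
  cfg <- model$config
  d <- dim(step_tensor)
  if (length(d) == 3L) dim(step_tensor) <- c(d, 1L)
  d <- dim(step_tensor)
  if (!identical(as.integer(d[1:3]), cfg$input_shape))
    stop_invalid("step tensor shape (%s) does not match config (%s)",
                 paste(d[1:3], collapse = ","),
                 paste(cfg$input_shape, collapse = ","))
  out <- cnn_stack_forward(step_tensor, model$params, model$plans)$out
  if (ncol(out) == 1L) drop(out) else out
}

#' Encode a step-feature sequence with the BiLSTM
#'
#' @param model A [fusion_model()].
#' @param sequence List of feature vectors/matrices (one per time step), or
#'   a features x t_steps matrix for a single sample.
#' @param merge_mode Optional override of the configured merge mode.
#' @return Temporal feature: length 2H for `"concat"`, H for `"sum"` /
#'   `"average"`.
#' @export
bilstm_encode <- function(model, sequence, merge_mode = NULL) {
  cfg <- model$config
  if (is.matrix(sequence))
    sequence <- lapply(seq_len(ncol(sequence)), function(t)
      sequence[, t, drop = FALSE])
  if (length(sequence) < 1L) stop_invalid("empty sequence")
  sequence <- lapply(sequence, function(x)
    if (is.matrix(x)) x else matrix(x, ncol = 1))
  mm <- if (is.null(merge_mode)) cfg$merge_mode else merge_mode
  out <- bilstm_forward(sequence, model$params$lstm, cfg$lstm_hidden, mm)$out
  if (ncol(out) == 1L) drop(out) else out
}

#' VAE encoder: posterior mean and log-variance
#'
#' @param model A [fusion_model()].
#' @param x A (rows, cols, bands x t_steps) array (the stacked sample), a
#'   batch of them, or a (t, row, col, band) sample.
#' @return List with `mu` and `logvar`, each latent_dim (x batch).
#' @export
dcign_encode <- function(model, x) {
  cfg <- model$config
  d <- dim(x)
  if (length(d) == 4L && d[1] == cfg$t_steps) {   # (t,row,col,band) sample
    x <- as_packed_batch(x, cfg)
    d5 <- dim(x)
    dim(x) <- c(d5[1], d5[2], d5[3] * d5[4], d5[5])
  } else if (length(d) == 3L) {
    dim(x) <- c(d, 1L)
  }
  d <- dim(x)
  dm <- model$plans$dims
  if (!identical(as.integer(d[1:3]), as.integer(c(dm$H, dm$W, dm$Cd))))
    stop_invalid("input shape (%s) does not match VAE input (%d,%d,%d)",
                 paste(d[1:3], collapse = ","), dm$H, dm$W, dm$Cd)
  enc <- encoder_forward(x, model$params, model$plans)
  squeeze <- function(m) if (ncol(m) == 1L) drop(m) else m
  list(mu = squeeze(enc$mu), logvar = squeeze(enc$logvar))
}

#' Reparameterization sampling
#'
#' Draws `z = mu + exp(logvar / 2) * eps` with `eps ~ N(0, I)` from a seeded
#' generator; with `logvar -> -Inf` (zero variance) `z` collapses to `mu`.
#'
#' @param mu,logvar Latent mean and log-variance (vectors or matrices of
#'   matching shape).
#' @param seed Optional integer seed for the noise draw.
#' @return A draw `z` of the same shape.
#' @export
reparameterize <- function(mu, logvar, seed = NULL) {
  stopifnot(length(mu) == length(logvar))
  if (any(!is.finite(mu)) || any(logvar == Inf) || any(is.na(logvar)))
    stop_invalid("mu and logvar must be finite (logvar may be -Inf)")
  eps <- with_seed(seed, rnorm(length(mu)))
  sigma <- exp(logvar / 2)
  out <- mu + sigma * eps
  attributes(out) <- attributes(mu)
  out
}

#' VAE decoder: reconstruct from a latent vector
#'
#' @param model A [fusion_model()].
#' @param z Latent vector of length latent_dim, or a matrix (columns =
#'   samples).
#' @return Reconstruction with the encoder's input shape (rows, cols,
#'   bands x t_steps), with a trailing batch dimension for matrix input.
#' @export
dcign_decode <- function(model, z) {
  cfg <- model$config
  single <- !is.matrix(z)
  if (single) z <- matrix(z, ncol = 1)
  if (nrow(z) != cfg$latent_dim)
    stop_invalid("z has length %d but latent_dim is %d", nrow(z), cfg$latent_dim)
  out <- decoder_forward(z, model$params, model$plans, cfg)$out
  if (single) {
    d <- dim(out)
    dim(out) <- d[1:3]
  }
  out
}

#' Fuse temporal and latent features and classify
#'
#' @param model A [fusion_model()].
#' @param temporal_feature BiLSTM output (vector or matrix).
#' @param latent_mu Latent mean (vector or matrix).
#' @return Class-probability simplex vector (or matrix, columns = samples).
#' @export
fuse_and_classify <- function(model, temporal_feature, latent_mu) {
  tm <- if (is.matrix(temporal_feature)) temporal_feature
        else matrix(temporal_feature, ncol = 1)
  mu <- if (is.matrix(latent_mu)) latent_mu else matrix(latent_mu, ncol = 1)
  dm <- model$plans$dims
  if (nrow(tm) != dm$temporal_dim || nrow(mu) != model$config$latent_dim)
    stop_invalid("fusion input dims (%d, %d) do not match config (%d, %d)",
                 nrow(tm), nrow(mu), dm$temporal_dim, model$config$latent_dim)
  fus <- fusion_forward(tm, mu, model$params)
  probs <- softmax_cols(fus$logits)
  if (ncol(probs) == 1L) drop(probs) else probs
}

#' Full dual-stream forward pass
#'
#' Runs the shared CNN on each of the six step tensors, the BiLSTM over the
#' step features, the VAE stream on the stacked tensor, and the fusion
#' classifier. `mode = "eval"` uses `z = mu` and is fully deterministic;
#' `mode = "train"` samples `z` by reparameterization.
#'
#' @param model A [fusion_model()].
#' @param sample A `feature_4d_sample`, a (t, row, col, band) array, or a
#'   packed (row, col, band, t, n) batch.
#' @param mode `"eval"` or `"train"`.
#' @param noise_seed Seed for the train-mode latent draw.
#' @return A `model_output`: `probs` (simplex), `mu`, `logvar`, `recon`.
#' @export
model_forward <- function(model, sample, mode = c("eval", "train"),
                          noise_seed = NULL) {
  mode <- match.arg(mode)
  xb <- as_packed_batch(sample, model$config)
  fw <- with_seed(noise_seed, forward_full(model, xb, mode = mode))
  single <- dim(xb)[5] == 1L
  squeeze <- function(m) if (single && is.matrix(m)) drop(m) else m
  recon <- fw$recon
  if (single) dim(recon) <- dim(recon)[1:3]
  structure(list(probs = squeeze(fw$probs), mu = squeeze(fw$mu),
                 logvar = squeeze(fw$logvar), recon = recon,
                 z = squeeze(fw$z)),
            class = "model_output")
}

#' Save / load a model checkpoint
#'
#' Writes the parameter arrays as a single archive plus a JSON sidecar
#' (`<path>.json`) describing the architecture; the round trip is bit-exact.
#'
#' @param model A [fusion_model()].
#' @param path Checkpoint path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored `fusion_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "fusion_model"))
  saveRDS(list(format = "eegfusion-checkpoint", version = 1L,
               config = unclass(model$config), params = model$params), path)
  jsonlite::write_json(unclass(model$config), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "eegfusion-checkpoint"))
    stop_invalid("not an eegfusion checkpoint: %s", path)
  cfg <- do.call(model_config, obj$config[setdiff(names(obj$config),
                                                  c("cnn_kernel", "dcign_kernel"))])
  m <- structure(list(config = cfg, params = obj$params,
                      plans = build_plans(cfg)),
                 class = "fusion_model")
  m
}
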