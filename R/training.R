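#' Learning-rate schedule
#'
#' Five policies with closed-form `lr(epoch)` (epochs counted from 0):
#' \describe{
#'   \item{constant}{`lr0` throughout.}
#'   \item{piecewise_exponential}{within segment i (delimited by
#'     `boundaries`), `lr = lr_enter(i) * gammas[i]^(e - e_start(i))`, with
#'     `lr_enter` chosen so the curve is continuous at every boundary.}
#'   \item{cosine_annealing}{`lr_min + (lr0 - lr_min)/2 * (1 + cos(pi * e /
#'     T_max))` over one half-period.}
#'   \item{stepped}{`lr0 * step_gamma^floor(e / step_size)`.}
#'   \item{linear}{`lr0 + (final_lr - lr0) * e / total_epochs`.}
#' }
#' The numeric defaults (boundaries 30/60 with per-epoch factors 1, 0.95,
#' 0.9; halving every 20 epochs; floors of 1e-5) are package defaults.
#'
#' @param kind One of `"constant"`, `"piecewise_exponential"`,
#'   `"cosine_annealing"`, `"stepped"`, `"linear"`.
#' @param lr0 Initial learning rate (> 0).
#' @param boundaries,gammas Piecewise-exponential segment boundaries
#'   (epochs) and per-epoch decay factors (`length(boundaries) + 1`).
#' @param T_max,lr_min Cosine half-period (epochs) and floor.
#' @param step_size,step_gamma Stepped-descent interval and factor.
#' @param final_lr,total_epochs Linear-descent endpoint.
#' @return An `lr_schedule` object for [lr_at()].
#' @export
lr_schedule <- function(kind = "piecewise_exponential", lr0 = 1e-3,
                        boundaries = c(30, 60), gammas = c(1, 0.95, 0.9),
                        T_max = 80, lr_min = 1e-5,
                        step_size = 20, step_gamma = 0.5,
                        final_lr = 1e-5, total_epochs = 80) {
  kinds <- c("constant", "piecewise_exponential", "cosine_annealing",
             "stepped", "linear")
  if (!kind %in% kinds)
    stop_invalid("kind must be one of: %s", paste(kinds, collapse = ", "))
  check_scalar_num(lr0, "lr0", positive = TRUE)
  s <- list(kind = kind, lr0 = lr0, horizon = Inf)
  if (kind == "piecewise_exponential") {
    boundaries <- sort(boundaries)
    if (length(gammas) != length(boundaries) + 1L)
      stop_invalid("need length(boundaries) + 1 gammas")
    if (any(gammas <= 0)) stop_invalid("gammas must be positive")
    s$boundaries <- boundaries; s$gammas <- gammas
  } else if (kind == "cosine_annealing") {
    check_scalar_num(T_max, "T_max", positive = TRUE)
    if (lr_min < 0 || lr_min > lr0) stop_invalid("need 0 <= lr_min <= lr0")
    s$T_max <- T_max; s$lr_min <- lr_min; s$horizon <- T_max
  } else if (kind == "stepped") {
    check_scalar_num(step_size, "step_size", positive = TRUE)
    if (step_gamma <= 0 || step_gamma > 1)
      stop_invalid("step_gamma must be in (0, 1]")
    s$step_size <- step_size; s$step_gamma <- step_gamma
  } else if (kind == "linear") {
    check_scalar_num(total_epochs, "total_epochs", positive = TRUE)
    if (final_lr <= 0 || final_lr > lr0)
      stop_invalid("need 0 < final_lr <= lr0")
    s$final_lr <- final_lr; s$total_epochs <- total_epochs
    s$horizon <- total_epochs
  }
  structure(s, class = "lr_schedule")
}

#' Evaluate a schedule at an epoch
#'
#' @param schedule An [lr_schedule()].
#' @param epoch Epoch number(s), `0 <= epoch <= horizon`.
#' @return Learning rate(s), exact closed-form values.
#' @export
lr_at <- function(schedule, epoch) {
  stopifnot(inherits(schedule, "lr_schedule"))
  if (any(epoch < 0) || any(epoch > schedule$horizon))
    stop_invalid("epoch out of range [0, %s]", format(schedule$horizon))
  e <- epoch
  switch(schedule$kind,
    constant = rep(schedule$lr0, length(e)),
    piecewise_exponential = {
      b <- schedule$boundaries; g <- schedule$gammas
      starts <- c(0, b)
      enter <- schedule$lr0
      enters <- numeric(length(starts))
      enters[1] <- enter
      for (i in seq_along(b)) {
        enter <- enter * g[i]^(b[i] - starts[i])
        enters[i + 1] <- enter
      }
      seg <- findInterval(e, b) + 1L
      enters[seg] * g[seg]^(e - starts[seg])
    },
    cosine_annealing = schedule$lr_min + 0.5 * (schedule$lr0 - schedule$lr_min) *
      (1 + cos(pi * e / schedule$T_max)),
    stepped = schedule$lr0 * schedule$step_gamma^floor(e / schedule$step_size),
    linear = schedule$lr0 + (schedule$final_lr - schedule$lr0) *
      e / schedule$total_epochs)
}

#' KL divergence of a diagonal Gaussian from the standard normal
#'
#' `KL(N(mu, diag(sigma^2)) || N(0, I)) = 0.5 * sum(mu^2 + sigma^2 - 1 -
#' log sigma^2)`, with `sigma^2 = exp(logvar)`. Non-negative, and zero only
#' at `mu = 0`, `logvar = 0`.
#'
#' @param mu,logvar Numeric vectors (one sample) or matrices (columns =
#'   samples) of matching shape.
#' @return Scalar, or per-sample vector for matrix input.
#' @export
kl_gaussian <- function(mu, logvar) {
  if (any(!is.finite(mu)) || any(!is.finite(logvar)))
    stop_invalid("mu and logvar must be finite")
  stopifnot(length(mu) == length(logvar))
  term <- mu^2 + exp(logvar) - 1 - logvar
  if (is.matrix(mu)) 0.5 * colSums(term) else 0.5 * sum(term)
}

#' Combined classification + VAE objective
#'
#' `L = CE(probs, target) + lambda_vae * MSE(recon, x) + beta *
#' KL(mu, logvar)`: the cross-entropy of the fused classifier plus the
#' (negated) evidence lower bound of the VAE stream, with configurable
#' weights. With `lambda_vae = beta = 0` it reduces exactly to the
#' cross-entropy.
#'
#' @param output A `model_output` from [model_forward()].
#' @param target_label True class index (1-based).
#' @param x_input The sample fed to the model ((t, row, col, band) array or
#'   the stacked VAE input shape).
#' @param lambda_vae Weight of the reconstruction term.
#' @param beta Weight of the KL term.
#' @return Scalar loss with attribute `"components"` (ce, mse, kl).
#' @export
total_loss <- function(output, target_label, x_input, lambda_vae = 1,
                       beta = 1) {
  probs <- output$probs
  if (is.matrix(probs)) stop_invalid("total_loss expects a single sample")
  k <- length(probs)
  if (target_label < 1 || target_label > k)
    stop_invalid("target_label %d out of range 1..%d", target_label, k)
  if (lambda_vae < 0 || beta < 0)
    stop_invalid("loss weights must be >= 0")
  ce <- -log(probs[target_label])
  x <- if (inherits(x_input, "feature_4d_sample")) x_input$tensor else x_input
  d <- dim(x)
  if (length(d) == 4L) x <- aperm(x, c(2, 3, 4, 1))   # to (row, col, band, t)
  if (length(x) != length(output$recon))
    stop_invalid("x_input size does not match reconstruction")
  mse <- mean((as.vector(output$recon) - as.vector(x))^2)
  kl <- kl_gaussian(as.vector(output$mu), as.vector(output$logvar))
  structure(ce + lambda_vae * mse + beta * kl,
            components = c(ce = ce, mse = mse, kl = kl))
}

#' Training configuration
#'
#' Adam with (beta1, beta2) = (0.9, 0.999), batch 64, 80 epochs and the
#' piecewise-exponential schedule by default; `lambda_vae` and `beta` weight
#' the reconstruction and KL terms of the objective.
#'
#' @param epochs Number of epochs (>= 1).
#' @param batch_size Mini-batch size.
#' @param schedule An [lr_schedule()].
#' @param lambda_vae,beta Loss weights (>= 0).
#' @param adam_beta1,adam_beta2,adam_eps Adam hyperparameters.
#' @param seed Seed controlling initialization, batch order and VAE noise.
#' @return A `train_config` object.
#' @export
train_config <- function(epochs = 80L, batch_size = 64L,
                         schedule = lr_schedule("piecewise_exponential"),
                         lambda_vae = 1, beta = 1,
                         adam_beta1 = 0.9, adam_beta2 = 0.999,
                         adam_eps = 1e-8, seed = 1L) {
  if (epochs < 1) stop_invalid("epochs must be >= 1")
  if (batch_size < 1) stop_invalid("batch_size must be >= 1")
  if (lambda_vae < 0 || beta < 0) stop_invalid("loss weights must be >= 0")
  stopifnot(inherits(schedule, "lr_schedule"))
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), schedule = schedule,
                 lambda_vae = lambda_vae, beta = beta,
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 adam_eps = adam_eps, seed = as.integer(seed)),
            class = "train_config")
}

#' Cross-validation split plan
#'
#' `"subject_dependent_kfold"`: samples are shuffled (stratified by class)
#' into k folds regardless of subject. `"leave_one_subject_out"`: one fold
#' per subject; train and test subjects are disjoint.
#'
#' @param protocol Split protocol.
#' @param k Number of folds (subject-dependent k-fold only).
#' @param seed Shuffling seed.
#' @return A `split_plan`.
#' @export
split_plan <- function(protocol = c("subject_dependent_kfold",
                                    "leave_one_subject_out"),
                       k = 5L, seed = 1L) {
  protocol <- match.arg(protocol)
  if (k < 2) stop_invalid("k must be >= 2")
  structure(list(protocol = protocol, k = as.integer(k),
                 seed = as.integer(seed)),
            class = "split_plan")
}

#' Build cross-validation folds
#'
#' @param features An `eeg_features` set.
#' @param plan A [split_plan()].
#' @return List of folds, each `list(train, test, test_subjects)`; test
#'   index sets partition the samples.
#' @export
make_splits <- function(features, plan) {
  stopifnot(inherits(features, "eeg_features"), inherits(plan, "split_plan"))
  n <- n_samples(features)
  if (n == 0L) stop_invalid("empty feature set")
  if (plan$protocol == "leave_one_subject_out") {
    subjects <- unique(features$subjects)
    if (length(subjects) < 2L)
      stop_invalid("leave-one-subject-out needs at least 2 subjects")
    folds <- lapply(subjects, function(s) {
      test <- which(features$subjects == s)
      list(train = setdiff(seq_len(n), test), test = test, test_subjects = s)
    })
    names(folds) <- subjects
    return(folds)
  }
  k <- plan$k
  if (k > n) stop_invalid("more folds (%d) than samples (%d)", k, n)
  assign <- integer(n)
  with_seed(plan$seed, {
    for (lab in unique(features$labels)) {
      idx <- which(features$labels == lab)
      idx <- idx[sample.int(length(idx))]
      assign[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  lapply(seq_len(k), function(i) {
    test <- which(assign == i)
    list(train = which(assign != i), test = test,
         test_subjects = unique(features$subjects[test]))
  })
}

# packed batch of the given sample indices: (H, W, C, T, |idx|)
feature_batch <- function(features, idx) {
  features$x[, , , , idx, drop = FALSE]
}

#' Predict classes for feature samples
#'
#' @param object A trained [fusion_model()].
#' @param features An `eeg_features` set.
#' @param indices Sample indices (default all).
#' @param batch_size Evaluation chunk size.
#' @param ... Unused.
#' @return List with `class` (integer labels) and `probs` (n x K matrix).
#' @export
predict.fusion_model <- function(object, features, indices = NULL,
                                 batch_size = 256L, ...) {
  if (is.null(indices)) indices <- seq_len(n_samples(features))
  K <- object$config$n_classes
  probs <- matrix(NA_real_, length(indices), K)
  at <- 1L
  for (chunk in split(indices, ceiling(seq_along(indices) / batch_size))) {
    fw <- forward_full(object, feature_batch(features, chunk), mode = "eval")
    probs[at:(at + length(chunk) - 1L), ] <- t(fw$probs)
    at <- at + length(chunk)
  }
  list(class = max.col(probs, ties.method = "first"), probs = probs)
}

#' Train the dual-stream model on one split
#'
#' Mini-batch Adam with the configured learning-rate schedule evaluated at
#' every epoch. Fully reproducible: initialization, batch order and the
#' VAE noise are all driven by `config$seed` (or the `seed` override).
#'
#' @param features An `eeg_features` set.
#' @param model_cfg A [model_config()].
#' @param config A [train_config()].
#' @param fold Optional `list(train, test)` of sample indices; defaults to
#'   training on all samples with no validation column.
#' @param seed Optional override of `config$seed` (used by the CV harness
#'   to give each fold its own stream).
#' @param verbose Print per-epoch progress.
#' @return List with the trained `model` and `history` (data.frame: epoch,
#'   lr, train_loss, train_acc, val_acc).
#' @export
train_model <- function(features, model_cfg, config, fold = NULL,
                        seed = NULL, verbose = FALSE) {
  stopifnot(inherits(features, "eeg_features"), inherits(config, "train_config"),
            inherits(model_cfg, "model_config"))
  if (is.null(seed)) seed <- config$seed
  train_idx <- if (is.null(fold)) seq_len(n_samples(features)) else fold$train
  if (length(train_idx) == 0L) stop_invalid("empty training split")
  test_idx <- if (is.null(fold)) integer(0) else fold$test
  xtr <- feature_batch(features, train_idx)
  ytr <- features$labels[train_idx]
  n <- length(train_idx)
  model <- fusion_model(model_cfg, seed = derive_seed(seed, "init"))
  theta <- flatten_params(model$params)
  m <- numeric(length(theta)); v <- numeric(length(theta))
  tstep <- 0L
  hist <- data.frame(epoch = integer(0), lr = numeric(0),
                     train_loss = numeric(0), train_acc = numeric(0),
                     val_acc = numeric(0))
  b1 <- config$adam_beta1; b2 <- config$adam_beta2; ae <- config$adam_eps
  with_seed(derive_seed(seed, "loop"), {
    for (epoch in 0:(config$epochs - 1L)) {
      lr <- lr_at(config$schedule, min(epoch, config$schedule$horizon))
      perm <- sample.int(n)
      nb <- ceiling(n / config$batch_size)
      ep_loss <- 0; ep_correct <- 0L
      for (bi in seq_len(nb)) {
        sel <- perm[(((bi - 1L) * config$batch_size) + 1L):min(bi * config$batch_size, n)]
        xb <- xtr[, , , , sel, drop = FALSE]
        yb <- ytr[sel]
        fw <- forward_full(model, xb, mode = "train")
        comp <- loss_components(fw, yb, config$lambda_vae, config$beta)
        if (!is.finite(comp$total))
          stop_invalid("non-finite loss at epoch %d batch %d (lr %.3g, ce %.3g, mse %.3g, kl %.3g)",
                       epoch, bi, lr, comp$ce, comp$mse, comp$kl)
        gr <- backward_full(model, fw, yb, config$lambda_vae, config$beta)
        g <- flatten_params(gr)
        tstep <- tstep + 1L
        m <- b1 * m + (1 - b1) * g
        v <- b2 * v + (1 - b2) * g * g
        mhat <- m / (1 - b1^tstep)
        vhat <- v / (1 - b2^tstep)
        theta <- theta - lr * mhat / (sqrt(vhat) + ae)
        model$params <- unflatten_params(model$params, theta)
        ep_loss <- ep_loss + comp$total * length(sel)
        ep_correct <- ep_correct + sum(max.col(t(fw$probs), "first") == yb)
      }
      val_acc <- NA_real_
      if (length(test_idx) > 0) {
        pr <- predict.fusion_model(model, features, test_idx)
        val_acc <- mean(pr$class == features$labels[test_idx])
      }
      hist <- rbind(hist, data.frame(epoch = epoch, lr = lr,
                                     train_loss = ep_loss / n,
                                     train_acc = ep_correct / n,
                                     val_acc = val_acc))
      if (verbose)
        message(sprintf("epoch %3d lr %.2e loss %.4f acc %.3f val %.3f",
                        epoch, lr, ep_loss / n, ep_correct / n, val_acc))
    }
  })
  model$trained <- TRUE
  list(model = model, history = hist)
}
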