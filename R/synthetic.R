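#' Class-conditioned emotion signature for the synthetic generator
#'
#' A class is defined by relative band-power multipliers over scalp regions:
#' a bands x regions matrix (rows theta/alpha/beta/gamma by default, columns
#' frontal/central/posterior row-blocks of the 8x9 grid). Trial-to-trial
#' variability is multiplicative log-normal noise on each band's power.
#'
#' @param label Class name (unique within a dataset spec).
#' @param band_power Numeric bands x regions matrix of positive multipliers,
#'   or a length-`n_bands` vector applied uniformly over regions.
#' @param jitter_sd Standard deviation (log scale) of per-trial multiplicative
#'   band-power jitter; 0 disables it.
#' @param score Optional continuous affect score (e.g. a 1-9 valence rating)
#'   carried through for threshold-style binary labelling.
#' @param n_bands Number of frequency bands (must match the feature band set).
#' @return An `emotion_class_spec` object.
#' @export
emotion_class_spec <- function(label, band_power, jitter_sd = 0.3,
                               score = NULL, n_bands = 4L) {
  stopifnot(is.character(label), length(label) == 1L)
  if (is.vector(band_power)) band_power <- matrix(band_power, n_bands, 3)
  band_power <- as.matrix(band_power)
  if (nrow(band_power) != n_bands)
    stop_invalid("band_power must have one row per band (%d)", n_bands)
  if (any(!is.finite(band_power)) || any(band_power <= 0))
    stop_invalid("all band-power multipliers must be positive and finite")
  check_scalar_num(jitter_sd, "jitter_sd")
  if (jitter_sd < 0) stop_invalid("jitter_sd must be >= 0")
  structure(list(label = label, band_power = band_power,
                 jitter_sd = jitter_sd, score = score),
            class = "emotion_class_spec")
}

#' Per-subject recording profile
#'
#' Captures the inter-subject variability the per-subject normalization stage
#' is meant to remove: per-channel multiplicative gain, additive baseline
#' noise, and per-band additive log-power offsets.
#'
#' @param subject_id Identifier string.
#' @param gain Per-channel multiplicative factor(s) (> 0; recycled).
#' @param baseline_noise_sd Additive white-noise standard deviation, in uV
#'   (>= 0).
#' @param band_offset Per-band additive log-power offset (recycled).
#' @return A `subject_profile` object.
#' @export
subject_profile <- function(subject_id, gain = 1, baseline_noise_sd = 3,
                            band_offset = 0) {
  stopifnot(length(subject_id) == 1L)
  if (any(!is.finite(gain)) || any(gain <= 0))
    stop_invalid("gain must be positive for all channels")
  check_scalar_num(baseline_noise_sd, "baseline_noise_sd")
  if (baseline_noise_sd < 0) stop_invalid("baseline_noise_sd must be >= 0")
  structure(list(subject_id = as.character(subject_id), gain = gain,
                 baseline_noise_sd = baseline_noise_sd,
                 band_offset = band_offset),
            class = "subject_profile")
}

#' Default emotion class signatures
#'
#' `"seed3"`: three film-clip-style classes (negative / neutral / positive)
#' with frontal-theta, alpha, and beta/gamma dominated signatures
#' respectively. `"deap2"`: two music-video-style valence classes (low /
#' high) carrying continuous scores on a 1-9 scale, binarized at the
#' midpoint 5.
#'
#' @param style `"seed3"` or `"deap2"`.
#' @return List of [emotion_class_spec()] objects.
#' @export
default_class_specs <- function(style = "seed3") {
  bp <- function(theta, alpha, beta, gamma)
    matrix(c(theta, alpha, beta, gamma), nrow = 4, byrow = TRUE,
           dimnames = list(c("theta", "alpha", "beta", "gamma"),
                           c("frontal", "central", "posterior")))
  switch(style,
    seed3 = list(
      emotion_class_spec("negative", bp(theta = c(3.0, 2.0, 1.5),
                                        alpha = c(0.7, 0.7, 0.7),
                                        beta  = c(1.0, 1.0, 1.0),
                                        gamma = c(1.2, 1.0, 1.0))),
      emotion_class_spec("neutral",  bp(theta = c(1.0, 1.0, 1.0),
                                        alpha = c(2.5, 2.0, 3.0),
                                        beta  = c(1.0, 1.0, 1.0),
                                        gamma = c(0.8, 0.8, 0.8))),
      emotion_class_spec("positive", bp(theta = c(1.0, 1.0, 1.0),
                                        alpha = c(1.0, 1.0, 1.0),
                                        beta  = c(2.5, 2.0, 2.0),
                                        gamma = c(2.0, 2.0, 3.0)))),
    deap2 = list(
      emotion_class_spec("low_valence", bp(theta = c(2.5, 1.8, 1.2),
                                           alpha = c(0.8, 0.8, 0.8),
                                           beta  = c(1.0, 1.0, 1.0),
                                           gamma = c(1.0, 1.0, 1.0)),
                         score = 2.5),
      emotion_class_spec("high_valence", bp(theta = c(1.0, 1.0, 1.0),
                                            alpha = c(1.8, 1.5, 2.2),
                                            beta  = c(1.8, 1.5, 1.5),
                                            gamma = c(1.5, 1.5, 2.0)),
                         score = 7.5)),
    stop_invalid("unknown class-spec style `%s`", style))
}

#' Synthetic dataset specification
#'
#' The defaults define the package's reference study conditions: 8 subjects,
#' 3 classes, 20 trials per class per subject, 60 s trials at 200 Hz on the
#' 62-channel cap, seed 42. The whole dataset is a pure function of this
#' spec (including the seed).
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param trials_per_class Trials per class per subject (>= 1).
#' @param classes List of [emotion_class_spec()].
#' @param duration_s Trial duration in seconds.
#' @param fs Sampling rate in Hz.
#' @param montage Montage name (see [default_montage()]).
#' @param seed Integer seed fixing the dataset bit-for-bit.
#' @param base_power Band power (uV^2) corresponding to a multiplier of 1.
#' @param gain_sd,band_offset_sd,noise_sd_range Population parameters for the
#'   subject profiles: log-normal gain sd, per-band log-power offset sd, and
#'   the range baseline noise sds are drawn from.
#' @return A `dataset_spec` object.
#' @export
dataset_spec <- function(n_subjects = 8L, trials_per_class = 20L,
                         classes = default_class_specs("seed3"),
                         duration_s = 60, fs = 200, montage = "cap62",
                         seed = 42L, base_power = 25,
                         gain_sd = 0.3, band_offset_sd = 0.4,
                         noise_sd_range = c(2, 4)) {
  if (n_subjects < 2) stop_invalid("n_subjects must be >= 2")
  if (trials_per_class < 1) stop_invalid("trials_per_class must be >= 1")
  labels <- vapply(classes, `[[`, "", "label")
  if (anyDuplicated(labels)) stop_invalid("class labels must be unique")
  check_scalar_num(duration_s, "duration_s", positive = TRUE)
  check_scalar_num(fs, "fs", positive = TRUE)
  default_montage(montage)  # validates the name
  structure(list(n_subjects = as.integer(n_subjects),
                 trials_per_class = as.integer(trials_per_class),
                 classes = classes, duration_s = duration_s, fs = fs,
                 montage = montage, seed = as.integer(seed),
                 base_power = base_power, gain_sd = gain_sd,
                 band_offset_sd = band_offset_sd,
                 noise_sd_range = noise_sd_range),
            class = "dataset_spec")
}

#' Generate one synthetic EEG trial
#'
#' Per band and channel, band-limited Gaussian noise is synthesized in the
#' frequency domain (independent complex-normal coefficients on the band's
#' bins) and scaled so its realized power equals class multiplier x subject
#' band offset x region weight x trial jitter x `base_power`. Band
#' components are summed, white baseline noise added, and the channel gain
#' applied. Band components occupy disjoint frequency bins, so per-band
#' power is calibrated exactly.
#'
#' @param class_spec An [emotion_class_spec()].
#' @param profile A [subject_profile()].
#' @param duration_s Trial length in seconds (`duration_s * fs` integral).
#' @param fs Sampling rate in Hz; must exceed twice the highest band edge.
#' @param seed Integer seed; same seed and inputs give bit-identical data.
#' @param montage Montage name or `montage` object.
#' @param bands Band set (default [default_bands()]).
#' @param base_power Band power (uV^2) for a unit multiplier.
#' @param trial_id Identifier stored on the recording.
#' @return An `eeg_recording`: channels x samples matrix (uV) plus metadata.
#' @export
generate_trial <- function(class_spec, profile, duration_s, fs, seed,
                           montage = "cap62", bands = default_bands(),
                           base_power = 25, trial_id = "t1") {
  check_scalar_num(duration_s, "duration_s", positive = TRUE)
  check_scalar_num(fs, "fs", positive = TRUE)
  n <- duration_s * fs
  if (abs(n - round(n)) > 1e-8)
    stop_invalid("duration_s * fs must be an integer number of samples")
  n <- as.integer(round(n))
  check_bands_for_fs(bands, fs)
  mon <- if (inherits(montage, "montage")) montage else default_montage(montage)
  gm <- grid_map(mon)
  nc <- length(gm$channel)
  regions <- channel_regions(gm)
  nb <- length(bands)
  if (nrow(class_spec$band_power) != nb)
    stop_invalid("class spec has %d band rows but %d bands supplied",
                 nrow(class_spec$band_power), nb)
  gain <- rep_len(profile$gain, nc)
  boff <- rep_len(profile$band_offset, nb)

  freqs <- (seq_len(n) - 1L) * fs / n
  half <- if (n %% 2L == 0L) n / 2L - 1L else (n - 1L) / 2L  # skip DC & Nyquist
  region_idx <- as.integer(regions)

  x <- with_seed(seed, {
    jitter <- if (class_spec$jitter_sd > 0)
      exp(rnorm(nb, 0, class_spec$jitter_sd)) else rep(1, nb)
    spec <- matrix(0 + 0i, n, nc)
    for (b in seq_len(nb)) {
      bins <- which(freqs > bands[[b]]$low_hz & freqs <= bands[[b]]$high_hz)
      bins <- bins[bins >= 2L & bins <= half + 1L]
      m <- length(bins)
      if (m == 0L)
        stop_invalid("band `%s` contains no frequency bins at this duration/fs",
                     bands[[b]]$name)
      g <- matrix(complex(real = rnorm(m * nc), imaginary = rnorm(m * nc)), m, nc)
      # target per-channel band power
      p <- base_power * class_spec$band_power[b, region_idx] *
        exp(boff[b]) * jitter[b]
      # exact calibration: realized variance of the component is
      # (2/n^2) * sum |X_k|^2, so rescale each channel's bins accordingly
      ssq <- colSums(Mod(g)^2)
      scl <- sqrt(p * n^2 / (2 * ssq))
      spec[bins, ] <- spec[bins, ] + g * rep(scl, each = m)
    }
    # Hermitian completion for a real signal
    conj_rows <- n + 2L - (2:(half + 1L))
    spec[conj_rows, ] <- Conj(spec[2:(half + 1L), ])
    sig <- Re(stats::mvfft(spec, inverse = TRUE)) / n
    if (profile$baseline_noise_sd > 0)
      sig <- sig + matrix(rnorm(n * nc, 0, profile$baseline_noise_sd), n, nc)
    sig
  })
  data <- t(x) * gain
  rownames(data) <- gm$channel
  structure(list(data = data, fs = fs, channel_names = gm$channel,
                 subject_id = profile$subject_id, label = class_spec$label,
                 trial_id = trial_id),
            class = "eeg_recording")
}

# Deterministic plan of profiles and per-trial seeds for a dataset spec.
dataset_plan <- function(spec) {
  mon <- default_montage(spec$montage)
  nc <- nrow(mon)
  nb <- nrow(spec$classes[[1L]]$band_power)
  ids <- sprintf("S%02d", seq_len(spec$n_subjects))
  profiles <- with_seed(spec$seed, lapply(ids, function(id) {
    subject_profile(
      subject_id = id,
      gain = exp(rnorm(nc, 0, spec$gain_sd)),
      baseline_noise_sd = runif(1, spec$noise_sd_range[1], spec$noise_sd_range[2]),
      band_offset = rnorm(nb, 0, spec$band_offset_sd))
  }))
  names(profiles) <- ids
  trials <- expand.grid(trial = seq_len(spec$trials_per_class),
                        class = seq_along(spec$classes),
                        subject = seq_len(spec$n_subjects))
  trials <- trials[order(trials$subject, trials$class, trials$trial), ]
  trials$seed <- mapply(function(s, k, j)
    derive_seed(spec$seed, ids[s], spec$classes[[k]]$label, j),
    trials$subject, trials$class, trials$trial)
  list(profiles = profiles, trials = trials, montage = mon)
}

#' Generate a full synthetic dataset
#'
#' Subject profiles are drawn reproducibly from the spec seed; every subject
#' receives `trials_per_class` trials of every class. The result is a pure
#' function of the spec. For large specs prefer passing the spec directly to
#' [extract_features()], which generates and featurizes one trial at a time.
#'
#' @param spec A [dataset_spec()].
#' @return An `eeg_dataset`: list of `eeg_recording` plus the spec.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "dataset_spec"))
  plan <- dataset_plan(spec)
  recs <- lapply(seq_len(nrow(plan$trials)), function(i) {
    tr <- plan$trials[i, ]
    generate_trial(spec$classes[[tr$class]], plan$profiles[[tr$subject]],
                   spec$duration_s, spec$fs, tr$seed,
                   montage = plan$montage, base_power = spec$base_power,
                   trial_id = sprintf("%s_%s_%02d",
                                      plan$profiles[[tr$subject]]$subject_id,
                                      spec$classes[[tr$class]]$label, tr$trial))
  })
  structure(list(recordings = recs, spec = spec), class = "eeg_dataset")
}

#' @export
print.eeg_dataset <- function(x, ...) {
  labs <- vapply(x$recordings, `[[`, "", "label")
  cat(sprintf("<eeg_dataset: %d recordings, %d subjects, classes: %s>\n",
              length(x$recordings),
              length(unique(vapply(x$recordings, `[[`, "", "subject_id"))),
              paste(unique(labs), collapse = ", ")))
  invisible(x)
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording %s: %d ch x %d samples @ %g Hz, subject %s, label %s>\n",
              x$trial_id, nrow(x$data), ncol(x$data), x$fs, x$subject_id, x$label))
  invisible(x)
}
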