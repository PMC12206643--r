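#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth applied forward and backward (zero phase), with
#' odd-reflection padding to suppress edge transients. Tones inside the
#' passband are preserved; tones in non-adjacent bands are strongly
#' suppressed (the two passes square the magnitude response).
#'
#' @param recording An `eeg_recording`, or a numeric vector/matrix of
#'   samples (columns = channels) with `fs` supplied.
#' @param band A [band_definition()].
#' @param fs Sampling rate, required when `recording` is not an
#'   `eeg_recording`.
#' @return Same shape as the input, filtered.
#' @export
bandpass_filter <- function(recording, band, fs = NULL) {
  if (inherits(recording, "eeg_recording")) {
    out <- recording
    out$data <- t(filter_matrix(t(recording$data), band, recording$fs))
    return(out)
  }
  if (is.null(fs)) stop_invalid("`fs` is required for raw numeric input")
  if (is.matrix(recording)) return(filter_matrix(recording, band, fs))
  drop(filter_matrix(matrix(recording, ncol = 1), band, fs))
}

# cache of Butterworth designs keyed by (fs, band edges)
.butter_cache <- new.env(parent = emptyenv())

butter_coefs <- function(band, fs) {
  if (band$high_hz >= fs / 2)
    stop_invalid("invalid band `%s`: upper edge %.1f Hz >= Nyquist %.1f Hz",
                 band$name, band$high_hz, fs / 2)
  if (band$low_hz <= 0) stop_invalid("invalid band: low edge must be > 0")
  key <- sprintf("%g|%g|%g", fs, band$low_hz, band$high_hz)
  bf <- .butter_cache[[key]]
  if (is.null(bf)) {
    bf <- signal::butter(4, c(band$low_hz, band$high_hz) / (fs / 2), type = "pass")
    .butter_cache[[key]] <- bf
  }
  bf
}

# samples x channels matrix in, same out
filter_matrix <- function(x, band, fs) {
  bf <- butter_coefs(band, fs)
  padlen <- max(27L, as.integer(round(fs)))
  .filtfilt_mat(bf$b, bf$a, x, padlen)
}

#' Cut a recording into time windows
#'
#' @param recording An `eeg_recording`.
#' @param window_s Window length in seconds (`window_s * fs` integral).
#' @param step_s Step between window starts; defaults to `window_s`
#'   (non-overlapping).
#' @return List of channels x window-samples matrices, in temporal order;
#'   `floor((samples - window) / step) + 1` of them.
#' @export
segment_windows <- function(recording, window_s, step_s = window_s) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$fs
  wlen <- window_s * fs
  step <- step_s * fs
  if (abs(wlen - round(wlen)) > 1e-8 || abs(step - round(step)) > 1e-8)
    stop_invalid("window_s and step_s must give an integer number of samples")
  wlen <- as.integer(round(wlen)); step <- as.integer(round(step))
  if (step < 1L) stop_invalid("step_s must be positive")
  n <- ncol(recording$data)
  if (wlen > n)
    stop_invalid("window (%d samples) longer than recording (%d samples)", wlen, n)
  nw <- (n - wlen) %/% step + 1L
  lapply(seq_len(nw), function(i) {
    recording$data[, ((i - 1L) * step + 1L):((i - 1L) * step + wlen), drop = FALSE]
  })
}

#' Differential entropy of a signal window (Gaussian closed form)
#'
#' For a band-limited Gaussian window the differential entropy is
#' `0.5 * log(2 * pi * e * sigma^2)` nats, with `sigma^2` the sample
#' variance. It is strictly increasing in the variance and satisfies
#' `DE(a * x) = DE(x) + log(|a|)` exactly.
#'
#' @param x Numeric vector of at least two samples.
#' @param eps Degeneracy guard: variance below `eps` is an error.
#' @return Differential entropy in nats.
#' @export
differential_entropy <- function(x, eps = 1e-12) {
  if (length(x) < 2L) stop_invalid("need at least 2 samples")
  v <- stats::var(x)
  if (!is.finite(v) || v < eps)
    stop_invalid("degenerate input: window variance %.3g is below %.3g", v, eps)
  0.5 * log(2 * pi * exp(1) * v)
}

#' Per-band windowed differential-entropy features for one recording
#'
#' Band-pass filters the recording in each band, cuts it into
#' non-overlapping windows, and computes the Gaussian differential entropy
#' of every (window, channel, band) cell. Near-constant windows are clamped
#' at the variance guard rather than erroring, so heavily attenuated
#' channels stay finite.
#'
#' @param recording An `eeg_recording`.
#' @param bands Band set (default [default_bands()]).
#' @param window_s Window length in seconds.
#' @param eps Variance guard.
#' @return A `de_tensor`: `values` array windows x channels x bands (nats)
#'   plus window/label/subject metadata.
#' @export
de_tensor <- function(recording, bands = default_bands(), window_s = 1,
                      eps = 1e-12) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$fs
  check_bands_for_fs(bands, fs)
  wlen <- window_s * fs
  if (abs(wlen - round(wlen)) > 1e-8)
    stop_invalid("window_s * fs must be integral")
  wlen <- as.integer(round(wlen))
  x <- t(recording$data)                      # samples x channels
  n <- nrow(x); nc <- ncol(x)
  nw <- n %/% wlen
  if (nw < 1L) stop_invalid("recording shorter than one window")
  nb <- length(bands)
  de <- array(NA_real_, c(nw, nc, nb),
              dimnames = list(NULL, recording$channel_names, band_names(bands)))
  keep <- seq_len(nw * wlen)
  for (b in seq_len(nb)) {
    f <- filter_matrix(x, bands[[b]], fs)[keep, , drop = FALSE]
    dim(f) <- c(wlen, nw * nc)
    mu <- colMeans(f)
    v <- (colSums(f * f) - wlen * mu * mu) / (wlen - 1)
    v <- pmax(v, eps)
    de[, , b] <- matrix(0.5 * log(2 * pi * exp(1) * v), nw, nc)
  }
  structure(list(values = de, window_s = window_s,
                 subject_id = recording$subject_id, label = recording$label,
                 channel_names = recording$channel_names),
            class = "de_tensor")
}

#' Place per-channel values on the topographic grid
#'
#' @param values Named numeric vector (channel names), or unnamed in the
#'   grid map's channel order.
#' @param grid A [grid_map()].
#' @return nrow x ncol matrix; cells without an electrode are exactly 0, so
#'   the matrix sum equals the sum of the channel values.
#' @export
map_to_grid <- function(values, grid) {
  stopifnot(inherits(grid, "grid_map"))
  m <- matrix(0, grid$nrow, grid$ncol)
  if (is.null(names(values))) {
    if (length(values) != length(grid$channel))
      stop_invalid("unnamed values must match the grid's %d channels",
                   length(grid$channel))
    m[grid$index] <- values
  } else {
    unknown <- setdiff(names(values), grid$channel)
    if (length(unknown))
      stop_invalid("channel not in grid map: %s", paste(unknown, collapse = ", "))
    pos <- match(names(values), grid$channel)
    m[grid$index[pos]] <- values
  }
  m
}

# Packed 4D assembly used by the pipeline: de values (nw, C, B) ->
# array (gr, gc, B, T, S) with S = floor((nw - T)/stride) + 1.
assemble_packed <- function(values, gm, t_steps, stride) {
  nw <- dim(values)[1]; nc <- dim(values)[2]; nb <- dim(values)[3]
  if (nw < t_steps)
    stop_invalid("insufficient windows: %d available, %d needed", nw, t_steps)
  if (stride < 1L) stop_invalid("stride must be >= 1")
  ns <- (nw - t_steps) %/% stride + 1L
  starts <- (seq_len(ns) - 1L) * stride
  wsel <- as.vector(outer(seq_len(t_steps), starts, `+`))   # T x S window ids
  dp <- aperm(values, c(2, 3, 1))                           # C, B, nw
  dim(dp) <- c(nc * nb, nw)
  sel <- dp[, wsel, drop = FALSE]                           # (C*B) x (T*S)
  ncell <- gm$nrow * gm$ncol
  out <- matrix(0, ncell * nb, t_steps * ns)
  rows <- rep(gm$index, nb) + ncell * rep(seq_len(nb) - 1L, each = nc)
  out[rows, ] <- sel
  dim(out) <- c(gm$nrow, gm$ncol, nb, t_steps, ns)
  out
}

#' Stack windowed DE maps into 4D samples
#'
#' Takes `t_steps` consecutive windows (default 6) and stacks their per-band
#' topographic maps into one sample of shape (time, row, col, band); with
#' the defaults, (6, 8, 9, 4). Cells without an electrode are exactly 0.
#'
#' @param de A [de_tensor()].
#' @param grid A [grid_map()]; every recording channel must appear in it.
#' @param t_steps Number of consecutive windows per sample.
#' @param stride Step (in windows) between consecutive samples.
#' @return List of `feature_4d_sample` objects (`tensor`, `label`,
#'   `subject_id`).
#' @export
assemble_4d <- function(de, grid, t_steps = 6L, stride = 1L) {
  stopifnot(inherits(de, "de_tensor"), inherits(grid, "grid_map"))
  unknown <- setdiff(de$channel_names, grid$channel)
  if (length(unknown))
    stop_invalid("channel not in grid map: %s", paste(unknown, collapse = ", "))
  # reorder channels into grid order
  pos <- match(grid$channel, de$channel_names)
  if (anyNA(pos))
    stop_invalid("recording lacks mapped channel(s): %s",
                 paste(grid$channel[is.na(pos)], collapse = ", "))
  vals <- de$values[, pos, , drop = FALSE]
  packed <- assemble_packed(vals, grid, as.integer(t_steps), as.integer(stride))
  ns <- dim(packed)[5]
  lapply(seq_len(ns), function(s) {
    structure(list(tensor = aperm(packed[, , , , s, drop = FALSE][, , , , 1],
                                  c(4, 1, 2, 3)),
                   label = de$label, subject_id = de$subject_id),
              class = "feature_4d_sample")
  })
}

make_feature_set <- function(x, labels, label_levels, subjects, gm, bands,
                             window_s, t_steps, stride, normalized = FALSE) {
  structure(list(x = x, labels = labels, label_levels = label_levels,
                 subjects = subjects, mask = grid_mask(gm), grid = gm,
                 bands = band_names(bands), window_s = window_s,
                 t_steps = t_steps, stride = stride, normalized = normalized),
            class = "eeg_features")
}

#' @export
print.eeg_features <- function(x, ...) {
  d <- dim(x$x)
  cat(sprintf("<eeg_features: %d samples of shape (%d, %d, %d, %d) [t, row, col, band], %d subjects, %d classes%s>\n",
              d[5], x$t_steps, d[1], d[2], d[3],
              length(unique(x$subjects)), length(x$label_levels),
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

n_samples <- function(features) dim(features$x)[5]

# tensor of sample i in the spec's (t, row, col, band) order
sample_tensor <- function(features, i) {
  aperm(features$x[, , , , i, drop = FALSE][, , , , 1], c(4, 1, 2, 3))
}

#' Standardize features within each subject
#'
#' Every subject's feature values (over all samples, time steps, bands and
#' electrode-bearing cells) are centred and scaled by that subject's own
#' mean and standard deviation, removing between-subject amplitude and
#' baseline offsets. Structurally-zero cells (no electrode) remain exactly 0.
#'
#' @param features An `eeg_features` set.
#' @return The feature set with `normalized = TRUE`.
#' @export
normalize_per_subject <- function(features) {
  stopifnot(inherits(features, "eeg_features"))
  d <- dim(features$x)
  ncell <- d[1] * d[2]
  rest <- d[3] * d[4]
  m_idx <- which(as.vector(features$mask) == 1)
  xm <- features$x
  dim(xm) <- c(ncell, rest, d[5])
  for (sub in unique(features$subjects)) {
    idx <- which(features$subjects == sub)
    if (length(idx) < 2L)
      stop_invalid("subject %s has fewer than 2 samples", sub)
    vals <- xm[m_idx, , idx, drop = FALSE]
    mu <- mean(vals)
    sdv <- stats::sd(as.vector(vals))
    if (!is.finite(sdv) || sdv < 1e-12)
      stop_invalid("subject %s has zero feature variance", sub)
    xm[m_idx, , idx] <- (vals - mu) / sdv
  }
  dim(xm) <- d
  features$x <- xm
  features$normalized <- TRUE
  features
}

#' Full 4D feature extraction
#'
#' Composes the pipeline per trial -- band-pass filtering, non-overlapping
#' windowing, differential entropy, grid mapping, 6-step stacking -- then
#' per-subject standardization. Accepts either a materialized `eeg_dataset`
#' or a [dataset_spec()]; given a spec, trials are generated and featurized
#' one at a time so the raw signal never has to be held in memory.
#'
#' @param x An `eeg_dataset` or `dataset_spec`.
#' @param bands Band set.
#' @param montage Montage name or object (defaults to the dataset's).
#' @param window_s Window length in seconds.
#' @param t_steps Time steps per sample (default 6).
#' @param stride Step in windows between samples (default 1).
#' @param normalize Apply [normalize_per_subject()] (default TRUE).
#' @return An `eeg_features` set; each sample has shape
#'   (`t_steps`, 8, 9, n_bands).
#' @export
extract_features <- function(x, bands = default_bands(), montage = NULL,
                             window_s = 1, t_steps = 6L, stride = 1L,
                             normalize = TRUE) {
  t_steps <- as.integer(t_steps); stride <- as.integer(stride)
  if (inherits(x, "dataset_spec")) {
    plan <- dataset_plan(x)
    gm <- grid_map(plan$montage)
    chunks <- vector("list", nrow(plan$trials))
    meta_lab <- character(0); meta_sub <- character(0)
    for (i in seq_len(nrow(plan$trials))) {
      tr <- plan$trials[i, ]
      rec <- generate_trial(x$classes[[tr$class]], plan$profiles[[tr$subject]],
                            x$duration_s, x$fs, tr$seed, montage = plan$montage,
                            bands = bands, base_power = x$base_power,
                            trial_id = as.character(i))
      ft <- trial_packed(rec, bands, gm, window_s, t_steps, stride)
      chunks[[i]] <- ft
      ns <- dim(ft)[5]
      meta_lab <- c(meta_lab, rep(rec$label, ns))
      meta_sub <- c(meta_sub, rep(rec$subject_id, ns))
    }
    levels <- vapply(x$classes, `[[`, "", "label")
  } else if (inherits(x, "eeg_dataset")) {
    if (length(x$recordings) == 0L) {
      mon <- resolve_montage(x, montage)
      gm <- grid_map(mon)
      nb <- length(bands)
      return(make_feature_set(array(0, c(gm$nrow, gm$ncol, nb, t_steps, 0)),
                              integer(0), character(0), character(0), gm,
                              bands, window_s, t_steps, stride))
    }
    mon <- resolve_montage(x, montage)
    gm <- grid_map(mon)
    chunks <- vector("list", length(x$recordings))
    meta_lab <- character(0); meta_sub <- character(0)
    for (i in seq_along(x$recordings)) {
      rec <- x$recordings[[i]]
      ft <- trial_packed(rec, bands, gm, window_s, t_steps, stride)
      chunks[[i]] <- ft
      ns <- dim(ft)[5]
      meta_lab <- c(meta_lab, rep(rec$label, ns))
      meta_sub <- c(meta_sub, rep(rec$subject_id, ns))
    }
    levels <- unique(meta_lab)
  } else stop_invalid("x must be an eeg_dataset or dataset_spec")

  nb <- length(bands)
  ns_tot <- sum(vapply(chunks, function(c) dim(c)[5], 0))
  gm0 <- if (exists("gm", inherits = FALSE)) gm else grid_map(default_montage())
  xarr <- array(0, c(gm0$nrow, gm0$ncol, nb, t_steps, ns_tot))
  at <- 0L
  for (ch in chunks) {
    ns <- dim(ch)[5]
    if (ns > 0) xarr[, , , , (at + 1L):(at + ns)] <- ch
    at <- at + ns
  }
  fs <- make_feature_set(xarr, match(meta_lab, levels), levels, meta_sub, gm0,
                         bands, window_s, t_steps, stride)
  if (normalize && ns_tot > 0) fs <- normalize_per_subject(fs)
  fs
}

resolve_montage <- function(dataset, montage) {
  if (!is.null(montage)) {
    if (inherits(montage, "montage")) return(montage)
    return(default_montage(montage))
  }
  if (!is.null(dataset$spec)) return(default_montage(dataset$spec$montage))
  if (!is.null(dataset$montage)) return(default_montage(dataset$montage))
  default_montage()
}

# one trial -> packed (8, 9, B, T, S) block, channels reordered to grid order
trial_packed <- function(rec, bands, gm, window_s, t_steps, stride) {
  unknown <- setdiff(rec$channel_names, gm$channel)
  if (length(unknown))
    stop_invalid("channel not in grid map: %s", paste(unknown, collapse = ", "))
  de <- de_tensor(rec, bands, window_s)
  pos <- match(gm$channel, de$channel_names)
  if (anyNA(pos))
    stop_invalid("recording lacks mapped channel(s): %s",
                 paste(gm$channel[is.na(pos)], collapse = ", "))
  assemble_packed(de$values[, pos, , drop = FALSE], gm, t_steps, stride)
}
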