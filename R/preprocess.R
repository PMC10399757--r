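#' Preprocessing configuration
#'
#' Parameters of the signal-conditioning chain applied to each raw EMG
#' channel: zero-phase Butterworth band-pass, movement-window extraction
#' driven by hand tangential velocity, rectified sliding-window integration,
#' zero-phase low-pass smoothing, and duration normalization onto a common
#' time base.
#'
#' @param sampling_rate Hz.
#' @param band_low,band_high band-pass corner frequencies in Hz
#'   (defaults 20 and 300).
#' @param filter_order Butterworth design order (default 4; the band-pass is
#'   order `2 * filter_order` overall, as in the MATLAB `butter` convention).
#' @param integrate_window sliding integration window in seconds
#'   (default 0.005, i.e. 5 ms).
#' @param envelope_cutoff low-pass smoothing cutoff in Hz (default 5).
#' @param pre_onset_margin seconds of signal kept before movement onset
#'   (default 0.200).
#' @param velocity_threshold_frac onset/offset threshold as a fraction of
#'   peak tangential velocity (default 0.05).
#' @param target_len common time-base length in samples (default 1000).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(sampling_rate = 1000, band_low = 20,
                              band_high = 300, filter_order = 4,
                              integrate_window = 0.005, envelope_cutoff = 5,
                              pre_onset_margin = 0.200,
                              velocity_threshold_frac = 0.05,
                              target_len = 1000) {
  cfg <- list(
    sampling_rate = check_number(sampling_rate, "sampling_rate", min = 1e-9),
    band_low = check_number(band_low, "band_low", min = 1e-9),
    band_high = check_number(band_high, "band_high", min = 1e-9),
    filter_order = check_count(filter_order, "filter_order"),
    integrate_window = check_number(integrate_window, "integrate_window", min = 0),
    envelope_cutoff = check_number(envelope_cutoff, "envelope_cutoff", min = 1e-9),
    pre_onset_margin = check_number(pre_onset_margin, "pre_onset_margin", min = 0),
    velocity_threshold_frac = check_number(velocity_threshold_frac,
                                           "velocity_threshold_frac"),
    target_len = check_count(target_len, "target_len", min = 2L)
  )
  if (!(cfg$band_low < cfg$band_high && cfg$band_high < cfg$sampling_rate / 2)) {
    stop_invalid("need 0 < band_low < band_high < sampling_rate / 2")
  }
  if (cfg$velocity_threshold_frac <= 0 || cfg$velocity_threshold_frac >= 1) {
    stop_invalid("velocity_threshold_frac must be in (0, 1)")
  }
  structure(cfg, class = "preprocess_config")
}

## Forward-backward filtering with odd-symmetric reflection padding at both
## ends (the MATLAB filtfilt convention), so edge transients decay inside the
## discarded pads instead of leaking into the output. `pad` is chosen as a
## few time constants of the slowest filter corner.
zero_phase <- function(filt, x, pad) {
  n <- length(x)
  pad <- max(0L, min(as.integer(pad), n - 1L))
  if (pad > 0L) {
    front <- 2 * x[1L] - x[(pad + 1L):2L]
    back <- 2 * x[n] - x[(n - 1L):(n - pad)]
    x <- c(front, x, back)
  }
  y <- signal::filtfilt(filt, x)
  y[(pad + 1L):(pad + n)]
}

#' Zero-phase Butterworth band-pass filter
#'
#' Forward-backward ("filtfilt") application of a Butterworth band-pass, so
#' the output has no phase lag and the same length as the input.
#'
#' @param series numeric vector; must be longer than `3 * filter_order`.
#' @param cfg a [preprocess_config()].
#' @return Filtered series of the same length.
#' @export
bandpass_filter <- function(series, cfg = preprocess_config()) {
  if (!is.numeric(series)) stop_invalid("series must be numeric")
  if (length(series) <= 3 * cfg$filter_order) {
    stop_invalid("series too short for stable zero-phase filtering (need > ",
                 3 * cfg$filter_order, " samples)")
  }
  ny <- cfg$sampling_rate / 2
  bf <- signal::butter(cfg$filter_order, c(cfg$band_low, cfg$band_high) / ny,
                       type = "pass")
  zero_phase(bf, as.numeric(series),
             pad = round(3 * cfg$sampling_rate / cfg$band_low))
}

#' Tangential velocity of a 3-axis marker trajectory
#'
#' Euclidean norm of the per-axis first differences times the sampling rate;
#' element `i` is the speed between samples `i` and `i + 1`.
#'
#' @param kinematics numeric matrix with 3 columns (X, Y, Z).
#' @param sampling_rate Hz.
#' @return Numeric vector of length `nrow(kinematics) - 1`.
#' @export
tangential_velocity <- function(kinematics, sampling_rate) {
  kinematics <- as.matrix(kinematics)
  if (ncol(kinematics) != 3L || nrow(kinematics) < 2L) {
    stop_invalid("kinematics must be an n x 3 matrix with n >= 2")
  }
  d <- diff(kinematics)
  sqrt(rowSums(d^2)) * sampling_rate
}

#' Detect the movement window from hand tangential velocity
#'
#' Onset is the first sample at which tangential velocity exceeds
#' `velocity_threshold_frac` of its maximum; offset is the first sample after
#' the global velocity peak at which it falls back below that threshold, or
#' the last sample if it never does. Indices are 1-based and refer to the
#' velocity series (and hence to the leading sample of each velocity step).
#'
#' @param kinematics numeric matrix with 3 columns (X, Y, Z), >= 3 rows.
#' @param cfg a [preprocess_config()].
#' @return Named integer vector `c(onset, offset)` with `onset < offset`.
#' @export
detect_movement_window <- function(kinematics, cfg = preprocess_config()) {
  kinematics <- as.matrix(kinematics)
  if (nrow(kinematics) < 3L) stop_invalid("kinematics must have >= 3 samples")
  v <- tangential_velocity(kinematics, cfg$sampling_rate)
  vmax <- max(v)
  if (vmax <= 0) {
    stop_with_class("emgdiff_no_movement", "no movement: tangential velocity is zero")
  }
  thr <- cfg$velocity_threshold_frac * vmax
  onset <- which(v > thr)[1L]
  peak <- which.max(v)
  after <- if (peak < length(v)) which(v[(peak + 1L):length(v)] < thr) else integer()
  offset <- if (length(after)) peak + after[1L] else length(v)
  if (!(onset < offset)) {
    stop_with_class("emgdiff_no_movement", "degenerate movement window (onset >= offset)")
  }
  c(onset = as.integer(onset), offset = as.integer(offset))
}

#' Extract the EMG analysis window around a movement
#'
#' Returns the samples from `pre_onset_margin` seconds before `onset` up to
#' and including `offset`. If the margin would reach before the start of the
#' recording, the window is clamped to the first sample with a warning.
#'
#' @param series numeric vector.
#' @param onset,offset 1-based sample indices, `onset < offset <= length(series)`.
#' @param cfg a [preprocess_config()].
#' @return The extracted subseries.
#' @export
extract_emg_window <- function(series, onset, offset, cfg = preprocess_config()) {
  onset <- check_count(onset, "onset")
  offset <- check_count(offset, "offset")
  if (offset <= onset) stop_invalid("offset must be greater than onset")
  if (offset > length(series)) stop_invalid("offset exceeds series length")
  margin <- round(cfg$pre_onset_margin * cfg$sampling_rate)
  start <- onset - margin
  if (start < 1L) {
    warning("pre-onset margin reaches before the recording start; clamped to sample 1")
    start <- 1L
  }
  series[start:offset]
}

## Centered moving average whose window shrinks at the boundaries (no
## padding). For even widths the extra sample is taken from the right.
moving_average <- function(x, width) {
  n <- length(x)
  if (width <= 1L || n == 0L) return(x)
  left <- (width - 1L) %/% 2L
  right <- width %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - left, 1L)
  hi <- pmin(seq_len(n) + right, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Rectified, integrated, smoothed EMG envelope
#'
#' Rectification (absolute value), a centered sliding-window integration of
#' `integrate_window` seconds (window shrinks at the edges), then a
#' zero-phase low-pass at `envelope_cutoff` Hz.
#'
#' @param series numeric vector (non-empty).
#' @param cfg a [preprocess_config()].
#' @param rectify rectify before integrating (default TRUE). The flag exists
#'   because the sliding integration of a zero-mean band-passed signal
#'   without rectification would cancel to near zero.
#' @return The envelope, same length as the input. Non-negative before the
#'   final low-pass; the low-pass may introduce small negative ripples.
#' @export
emg_envelope <- function(series, cfg = preprocess_config(), rectify = TRUE) {
  if (!length(series)) stop_invalid("series must be non-empty")
  r <- if (rectify) abs(as.numeric(series)) else as.numeric(series)
  w <- max(1L, as.integer(round(cfg$integrate_window * cfg$sampling_rate)))
  m <- moving_average(r, w)
  if (length(m) <= 3 * cfg$filter_order) return(m)
  lp <- signal::butter(cfg$filter_order,
                       cfg$envelope_cutoff / (cfg$sampling_rate / 2),
                       type = "low")
  zero_phase(lp, m, pad = round(3 * cfg$sampling_rate / cfg$envelope_cutoff))
}

#' Duration normalization onto a common time base
#'
#' Linear interpolation of a series onto `target_len` equally spaced points
#' spanning its first and last samples; endpoints are preserved exactly.
#'
#' @param series numeric vector of length >= 2.
#' @param target_len number of output samples (>= 2).
#' @return Numeric vector of length `target_len`.
#' @export
time_normalize <- function(series, target_len) {
  target_len <- check_count(target_len, "target_len", min = 2L)
  if (length(series) < 2L) stop_invalid("series must have >= 2 samples")
  stats::approx(x = seq(0, 1, length.out = length(series)), y = series,
                xout = seq(0, 1, length.out = target_len))$y
}

#' Preprocess one trial recording
#'
#' Applies the full conditioning chain to every channel of a trial: band-pass
#' (for raw EMG), movement-window extraction (from the trial's kinematics
#' when present, otherwise the full series is kept), envelope extraction, and
#' duration normalization to `cfg$target_len` samples.
#'
#' @param trial a list with `channels` (samples x channels matrix),
#'   `sampling_rate`, and optionally `kinematics` (n x 3 matrix).
#' @param cfg a [preprocess_config()].
#' @param raw is the input raw interference EMG (band-pass + rectify) or an
#'   already-smooth envelope (skip both)?
#' @return The trial with `channels` replaced by the `target_len` x channels
#'   envelope matrix.
#' @export
preprocess_trial <- function(trial, cfg = preprocess_config(), raw = TRUE) {
  ch <- as.matrix(trial$channels)
  if (!is.null(trial$kinematics)) {
    win <- detect_movement_window(trial$kinematics, cfg)
    margin_cfg <- cfg
  } else {
    win <- c(onset = 1L, offset = nrow(ch))
    margin_cfg <- cfg
    margin_cfg$pre_onset_margin <- 0
  }
  out <- matrix(0, nrow = cfg$target_len, ncol = ncol(ch),
                dimnames = list(NULL, colnames(ch)))
  for (ci in seq_len(ncol(ch))) {
    x <- ch[, ci]
    if (raw) x <- bandpass_filter(x, cfg)
    x <- extract_emg_window(x, win["onset"], win["offset"], margin_cfg)
    x <- emg_envelope(x, cfg, rectify = raw)
    out[, ci] <- time_normalize(x, cfg$target_len)
  }
  trial$channels <- out
  trial
}

#' Preprocess every trial of a dataset
#'
#' @param dataset an `emg_dataset`.
#' @param cfg a [preprocess_config()].
#' @param raw see [preprocess_trial()].
#' @return The dataset with all trials preprocessed.
#' @export
preprocess_dataset <- function(dataset, cfg = preprocess_config(), raw = TRUE) {
  dataset$trials <- lapply(dataset$trials, preprocess_trial, cfg = cfg, raw = raw)
  dataset
}
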