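#' Simulation configuration for synthetic EMG datasets
#'
#' Describes a two-condition pointing-style recording: `n_subjects` subjects
#' each perform `trials_per_condition` trials per condition while
#' `n_channels` muscle envelopes are sampled at `sampling_rate` over a
#' movement window of `window_len` samples. A subset of channels
#' (`planted_channels`) is direction-tuned: in the second condition their
#' whole envelope is scaled by `1 + effect_size` and their burst centres are
#' shifted by `timing_shift` of the window. The defaults mirror the study
#' design this generator emulates: 11 subjects, 9 trials per condition,
#' 9 muscles at 1000 Hz on a 1000-sample window.
#'
#' @param n_subjects number of subjects.
#' @param trials_per_condition trials per subject per condition.
#' @param n_channels number of EMG channels.
#' @param channel_names channel labels; defaults to the nine recorded arm and
#'   trunk muscles (AD, PD, MD, PM, LD, Tr, BB, TL, TS) when `n_channels <= 9`.
#' @param sampling_rate sampling frequency in Hz.
#' @param window_len samples per movement window.
#' @param planted_channels integer indices (1-based) of direction-tuned
#'   channels.
#' @param effect_size multiplicative amplitude difference between conditions
#'   on planted channels (>= 0; 0 means no amplitude effect).
#' @param timing_shift fraction of the window by which planted burst centres
#'   shift between conditions.
#' @param subject_gain_sd log-scale SD of the per-subject, per-channel
#'   multiplicative gain (electrode placement / impedance variability).
#' @param noise_sd dimensionless trial-to-trial variability: log-scale SD of
#'   per-burst amplitude jitter, burst-timing jitter of SD `noise_sd / 10`
#'   of the window, and additive sample noise of SD `noise_sd / 4`.
#' @param seed integer seed; identical configurations regenerate identical
#'   datasets.
#' @return An object of class `sim_config`.
#' @seealso [gen_emg_dataset()], [gen_kinematic_trial()]
#' @export
sim_config <- function(n_subjects = 11, trials_per_condition = 9, n_channels = 9,
                       channel_names = NULL, sampling_rate = 1000,
                       window_len = 1000, planted_channels = c(1L, 3L),
                       effect_size = 1.0, timing_shift = 0.15,
                       subject_gain_sd = 0.2, noise_sd = 0.4, seed = 1L) {
  cfg <- list(
    n_subjects = check_count(n_subjects, "n_subjects"),
    trials_per_condition = check_count(trials_per_condition, "trials_per_condition"),
    n_channels = check_count(n_channels, "n_channels"),
    sampling_rate = check_number(sampling_rate, "sampling_rate", min = 1),
    window_len = check_count(window_len, "window_len", min = 2L),
    effect_size = check_number(effect_size, "effect_size", min = 0),
    timing_shift = check_number(timing_shift, "timing_shift", min = -1, max = 1),
    subject_gain_sd = check_number(subject_gain_sd, "subject_gain_sd", min = 0),
    noise_sd = check_number(noise_sd, "noise_sd", min = 0),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (is.null(channel_names)) {
    channel_names <- default_channel_names(cfg$n_channels)
  }
  if (length(channel_names) != cfg$n_channels || anyDuplicated(channel_names)) {
    stop_invalid("channel_names must be ", cfg$n_channels, " unique labels")
  }
  planted_channels <- as.integer(planted_channels)
  if (length(planted_channels) &&
      (anyNA(planted_channels) || any(planted_channels < 1L) ||
       any(planted_channels > cfg$n_channels))) {
    stop_invalid("planted_channels must be indices in 1..n_channels")
  }
  cfg$channel_names <- as.character(channel_names)
  cfg$planted_channels <- sort(unique(planted_channels))
  structure(cfg, class = "sim_config")
}

#' Default channel labels
#'
#' The nine recorded arm and trunk muscles (anterior, posterior and medial
#' deltoid; pectoralis major; latissimus dorsi; trapezius; biceps brachii;
#' long and short triceps) for up to nine channels, generic labels beyond.
#'
#' @param n number of channels.
#' @return Character vector of length `n`.
#' @export
default_channel_names <- function(n) {
  muscles <- c("AD", "PD", "MD", "PM", "LD", "Tr", "BB", "TL", "TS")
  if (n <= length(muscles)) muscles[seq_len(n)] else sprintf("CH%02d", seq_len(n))
}

## Deterministic tri-phasic burst parameters for a channel: up to three
## Gaussian bumps (agonist / antagonist / second agonist), centres and
## amplitudes staggered across channels so no two muscles are identical.
burst_params <- function(ci, n_channels) {
  frac <- (ci - 1) / max(1L, n_channels)
  list(
    centers = c(0.25, 0.55, 0.80) + (frac - 0.5) * 0.08,
    widths = c(0.07, 0.10, 0.08),
    amps = c(1.0, 0.6, 0.4) * (0.8 + 0.4 * ((ci * 7) %% 9) / 9)
  )
}

#' Generate one synthetic point-to-point reach trajectory
#'
#' Produces a 3-axis (X, Y, Z) marker trajectory for a vertical reach. The
#' displacement follows a minimum-jerk profile along Y (sign set by
#' `direction`); X and Z carry only a small smooth drift proportional to the
#' same profile, plus noise. The tangential-velocity profile is therefore
#' unimodal (bell-shaped) with zero velocity at both ends when `noise_sd = 0`.
#'
#' @param direction `"up"` or `"down"`.
#' @param n_samples number of samples (>= 2).
#' @param noise_sd SD of additive position noise, in the same length units as
#'   `amplitude`.
#' @param seed integer seed.
#' @param amplitude movement amplitude (length units).
#' @return An `n_samples` x 3 matrix with columns `X`, `Y`, `Z`.
#' @export
gen_kinematic_trial <- function(direction = c("up", "down"), n_samples,
                                noise_sd = 0, seed = 1L, amplitude = 1) {
  direction <- match.arg(direction)
  n_samples <- check_count(n_samples, "n_samples", min = 2L)
  noise_sd <- check_number(noise_sd, "noise_sd", min = 0)
  tau <- seq(0, 1, length.out = n_samples)
  s <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5  # minimum-jerk displacement
  sgn <- if (direction == "up") 1 else -1
  out <- cbind(X = 0.01 * amplitude * s,
               Y = sgn * amplitude * s,
               Z = 0.01 * amplitude * s)
  if (noise_sd > 0) {
    out <- out + with_seed(seed, matrix(rnorm(3L * n_samples, 0, noise_sd),
                                        ncol = 3L))
  }
  out
}

## Noise-free mean envelope of one channel in one condition.
channel_mean_envelope <- function(cfg, channel, condition, baseline = 0.2) {
  bp <- burst_params(channel, cfg$n_channels)
  planted <- channel %in% cfg$planted_channels
  centers <- bp$centers
  scale <- 1
  if (planted && condition == 2L) {
    centers <- centers + cfg$timing_shift
    scale <- 1 + cfg$effect_size
  }
  tau <- seq(0, 1, length.out = cfg$window_len)
  env <- rep(baseline, cfg$window_len)
  for (j in seq_along(centers)) {
    env <- env + bp$amps[j] * exp(-(tau - centers[j])^2 / (2 * bp$widths[j]^2))
  }
  env * scale
}

## One trial's channel envelopes. Trial-to-trial variability (all scaled by
## noise_sd): lognormal per-burst amplitude jitter (log-SD noise_sd),
## per-burst timing jitter (SD noise_sd/10 of the window) and additive
## sample noise (SD noise_sd/4). Subject idiosyncrasy (scaled by
## subject_gain_sd): a multiplicative channel gain and a per-channel
## burst-timing offset (SD subject_gain_sd/10 of the window), emulating
## between-subject differences in motor style that make cross-subject
## generalization genuinely imperfect.
gen_emg_trial_channels <- function(cfg, subject_idx, condition_idx, trial_idx,
                                   gains, shifts, baseline = 0.2) {
  L <- cfg$window_len
  tau <- seq(0, 1, length.out = L)
  ch <- matrix(0, nrow = L, ncol = cfg$n_channels,
               dimnames = list(NULL, cfg$channel_names))
  with_seed(derive_seed(cfg$seed, subject_idx, condition_idx, trial_idx), {
    for (ci in seq_len(cfg$n_channels)) {
      bp <- burst_params(ci, cfg$n_channels)
      planted <- ci %in% cfg$planted_channels
      centers <- bp$centers + shifts[ci]
      scale <- 1
      if (planted && condition_idx == 2L) {
        centers <- centers + cfg$timing_shift
        scale <- 1 + cfg$effect_size
      }
      nb <- length(centers)
      if (cfg$noise_sd > 0) {
        jit <- exp(rnorm(nb, 0, cfg$noise_sd))
        centers <- centers + rnorm(nb, 0, cfg$noise_sd / 10)
      } else {
        jit <- rep(1, nb)
      }
      env <- rep(baseline, L)
      for (j in seq_len(nb)) {
        env <- env + bp$amps[j] * jit[j] *
          exp(-(tau - centers[j])^2 / (2 * bp$widths[j]^2))
      }
      env <- env * scale * gains[ci]
      if (cfg$noise_sd > 0) env <- env + rnorm(L, 0, cfg$noise_sd / 4)
      ch[, ci] <- pmax(env, 0)
    }
  })
  ch
}

#' Generate a two-condition synthetic EMG dataset
#'
#' Each channel of each trial is a tonic baseline plus up to three phasic
#' Gaussian bursts plus noise. Planted channels differ between the two
#' conditions in overall amplitude (factor `1 + effect_size`) and burst
#' timing (`timing_shift` of the window); all other channels are drawn from
#' identical distributions in both conditions. A multiplicative gain is drawn
#' once per subject and channel. With `mode = "raw"` the envelope
#' amplitude-modulates band-limited noise (20-300 Hz), emulating raw
#' interference EMG so the preprocessing chain can be exercised end to end.
#'
#' @param cfg a [sim_config()].
#' @param mode `"envelope"` (default) or `"raw"`.
#' @param conditions labels for the two conditions.
#' @return An object of class `emg_dataset`: a list with elements `trials`
#'   (each a list with `subject`, `trial`, `condition`, `sampling_rate` and a
#'   `window_len` x `n_channels` `channels` matrix; raw mode also stores the
#'   generating envelope as `envelope`), `config`, and `ground_truth`
#'   (planted channel labels, effect size, timing shift, seed).
#' @export
gen_emg_dataset <- function(cfg, mode = c("envelope", "raw"),
                            conditions = c("A", "B")) {
  if (!inherits(cfg, "sim_config")) stop_invalid("cfg must be a sim_config")
  mode <- match.arg(mode)
  if (length(conditions) != 2L || anyDuplicated(conditions)) {
    stop_invalid("conditions must be two distinct labels")
  }
  trials <- vector("list", cfg$n_subjects * 2L * cfg$trials_per_condition)
  n <- 0L
  for (si in seq_len(cfg$n_subjects)) {
    subj_draw <- with_seed(derive_seed(cfg$seed, si), {
      list(gains = exp(rnorm(cfg$n_channels, 0, cfg$subject_gain_sd)),
           shifts = rnorm(cfg$n_channels, 0, cfg$subject_gain_sd / 10))
    })
    for (cond in 1:2) {
      for (tr in seq_len(cfg$trials_per_condition)) {
        ch <- gen_emg_trial_channels(cfg, si, cond, tr, subj_draw$gains,
                                     subj_draw$shifts)
        trial <- list(subject = sprintf("S%02d", si), trial = tr,
                      condition = as.character(conditions[cond]),
                      sampling_rate = cfg$sampling_rate, channels = ch)
        if (mode == "raw") {
          trial$envelope <- ch
          trial$channels <- modulate_raw_emg(cfg, ch, si, cond, tr)
        }
        n <- n + 1L
        trials[[n]] <- trial
      }
    }
  }
  structure(list(
    trials = trials, config = cfg,
    ground_truth = list(
      planted_channels = cfg$channel_names[cfg$planted_channels],
      effect_size = cfg$effect_size, timing_shift = cfg$timing_shift,
      seed = cfg$seed)
  ), class = "emg_dataset")
}

## Amplitude-modulate unit-variance band-limited (20-300 Hz) noise with the
## envelope, producing a zero-mean raw-EMG-like interference signal.
modulate_raw_emg <- function(cfg, env, si, cond, tr) {
  ny <- cfg$sampling_rate / 2
  bf <- signal::butter(4, c(20, min(300, 0.99 * ny)) / ny, type = "pass")
  carrier <- with_seed(derive_seed(cfg$seed, si, cond, tr, 999L), {
    matrix(rnorm(nrow(env) * ncol(env)), nrow = nrow(env))
  })
  for (ci in seq_len(ncol(env))) {
    x <- signal::filtfilt(bf, carrier[, ci])
    carrier[, ci] <- env[, ci] * (x / stats::sd(x))
  }
  dimnames(carrier) <- dimnames(env)
  carrier
}

#' Generate a two-condition synthetic reach-kinematics dataset
#'
#' Upward vs downward point-to-point reaches for a panel of subjects; only
#' the Y axis differs between conditions by construction (see
#' [gen_kinematic_trial()]). Useful as a low-dimensional proof of concept for
#' the classification and feature-selection pipeline.
#'
#' @param n_subjects,trials_per_condition design counts.
#' @param n_samples samples per trial.
#' @param noise_sd SD of additive position noise (length units).
#' @param subject_gain_sd log-scale SD of per-subject movement amplitude.
#' @param trial_amplitude_sd log-scale SD of per-trial movement amplitude
#'   (trial-to-trial reach variability).
#' @param seed integer seed.
#' @return An `emg_dataset` whose channels are `X`, `Y`, `Z` and whose
#'   conditions are `"down"` and `"up"`; `ground_truth$planted_channels` is
#'   `"Y"`.
#' @export
gen_kinematic_dataset <- function(n_subjects = 11, trials_per_condition = 9,
                                  n_samples = 1000, noise_sd = 0.02,
                                  subject_gain_sd = 0.1,
                                  trial_amplitude_sd = 0.1, seed = 1L) {
  n_subjects <- check_count(n_subjects, "n_subjects")
  trials_per_condition <- check_count(trials_per_condition, "trials_per_condition")
  n_samples <- check_count(n_samples, "n_samples", min = 2L)
  seed <- check_count(seed, "seed", min = 0L)
  dirs <- c("down", "up")
  trials <- vector("list", n_subjects * 2L * trials_per_condition)
  n <- 0L
  for (si in seq_len(n_subjects)) {
    amp <- with_seed(derive_seed(seed, si), exp(rnorm(1, 0, subject_gain_sd)))
    for (cond in 1:2) {
      for (tr in seq_len(trials_per_condition)) {
        trial_amp <- amp * with_seed(derive_seed(seed, si, cond, tr, 7L),
                                     exp(rnorm(1, 0, trial_amplitude_sd)))
        ch <- gen_kinematic_trial(dirs[cond], n_samples, noise_sd = noise_sd,
                                  seed = derive_seed(seed, si, cond, tr),
                                  amplitude = trial_amp)
        n <- n + 1L
        trials[[n]] <- list(subject = sprintf("S%02d", si), trial = tr,
                            condition = dirs[cond], sampling_rate = 1000,
                            channels = ch)
      }
    }
  }
  structure(list(
    trials = trials,
    config = list(n_subjects = n_subjects,
                  trials_per_condition = trials_per_condition,
                  n_samples = n_samples, noise_sd = noise_sd,
                  subject_gain_sd = subject_gain_sd,
                  trial_amplitude_sd = trial_amplitude_sd, seed = seed),
    ground_truth = list(planted_channels = "Y", seed = seed)
  ), class = "emg_dataset")
}

#' Precision and recall of a recovered channel set against the planted one
#'
#' @param selected character vector of selected channel labels.
#' @param planted character vector of planted (ground-truth) channel labels.
#' @param universe all valid channel labels; both sets must be drawn from it.
#' @return A list with `precision` and `recall` in `[0, 1]`. An empty
#'   selection has precision 1 by convention (no false positives); an empty
#'   planted set has recall 1.
#' @export
recovery_score <- function(selected, planted, universe) {
  selected <- unique(as.character(selected))
  planted <- unique(as.character(planted))
  if (!all(selected %in% universe) || !all(planted %in% universe)) {
    stop_invalid("selected and planted labels must belong to the channel universe")
  }
  hit <- length(intersect(selected, planted))
  list(
    precision = if (length(selected) == 0L) 1 else hit / length(selected),
    recall = if (length(planted) == 0L) 1 else hit / length(planted)
  )
}
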