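# Synthetic multimodal trial generator.
#
# Emulates the structure of a four-emotion EEG + eye-tracking study
# (15 subjects x 3 sessions x 24 film-clip trials, 62 EEG channels at a
# nominal 200 Hz, 4 eye channels ordered pupil_X, pupil_Y, gaze_X, gaze_Y)
# with an analytically controlled signal model:
#
#   EEG   = unit-variance Gaussian noise band-limited to the filter passband
#           + class-dependent sinusoidal signatures on class-specific
#             channel subsets (amplitude `eeg_effect`)
#   gaze  = bounded random-walk noise + class-dependent slow drift
#           (amplitude `eye_effect`)
#   pupil = baseline + unit measurement noise + class-dependent slow
#           modulation (amplitude `eye_effect`) + ONE smooth illumination
#           waveform shared by all subjects for the same (session, trial)
#           index, scaled by `illumination_amplitude`
#
# Complementarity contract: classes 0 and 1 differ only through the EEG
# signature; classes 2 and 3 differ only through the eye signature; the pair
# {0,1} differs from {2,3} in both modalities. Within a session every
# subject sees the same label sequence (same clip order), which is also why
# the illumination waveform is shared across subjects per trial index.

PUPIL_BASELINE <- 30   # px-scale resting pupil size
PUPIL_SCALE    <- 2    # px per unit of the dimensionless pupil model
GAZE_CENTER    <- 512  # px-scale screen centre
GAZE_SCALE     <- 30   # px per unit of the dimensionless gaze model

# class signature constants (Hz; channel subsets for EEG)
EEG_SIG_FREQ  <- c(10, 20)                      # classes 0, 1
EEG_SIG_CHANS <- list(1:8, 9:16)                # classes 0, 1
# classes 2 and 3 only; chosen slow relative to the EEG band but fast
# enough that a 4-s analysis window sees a discriminable waveform
PUPIL_MOD_FREQ <- c(NA, NA, 0.5, 1.0)
GAZE_DRIFT_FREQ <- c(NA, NA, 0.3, 0.6)

#' Configuration of the synthetic trial generator
#'
#' The defaults mirror the design of a standard four-emotion multimodal
#' study: 15 subjects, 3 sessions, 24 trials per session (6 per class),
#' 120-s trials sampled at 200 Hz with 62 EEG channels and 4 eye channels.
#'
#' @param n_subjects,n_sessions,trials_per_session Positive integer counts;
#'   `trials_per_session` must be divisible by 4 so classes balance exactly
#'   within each session.
#' @param trial_seconds Trial duration in seconds; `trial_seconds *
#'   sample_rate_hz` must be an integer.
#' @param sample_rate_hz Sampling rate in Hz (both modalities).
#' @param n_classes Number of emotion classes; fixed at 4.
#' @param eeg_channels,eye_channels Channel counts (62 and 4 by default; the
#'   eye modality is fixed at 4 channels ordered pupil_X, pupil_Y, gaze_X,
#'   gaze_Y).
#' @param eeg_effect,eye_effect Amplitude of the class-dependent signatures
#'   relative to unit noise.
#' @param illumination_amplitude Amplitude of the participant-shared
#'   illumination component contaminating the pupil channels, relative to
#'   unit noise.
#' @param seed Integer root seed; every stochastic component draws from a
#'   named substream derived from it.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 15, n_sessions = 3,
                             trials_per_session = 24, trial_seconds = 120,
                             sample_rate_hz = 200, n_classes = 4,
                             eeg_channels = 62, eye_channels = 4,
                             eeg_effect = 1, eye_effect = 1,
                             illumination_amplitude = 1, seed = 1L) {
  cfg <- list(
    n_subjects = check_count(n_subjects, "n_subjects"),
    n_sessions = check_count(n_sessions, "n_sessions"),
    trials_per_session = check_count(trials_per_session, "trials_per_session"),
    trial_seconds = check_nonneg(trial_seconds, "trial_seconds"),
    sample_rate_hz = check_nonneg(sample_rate_hz, "sample_rate_hz"),
    n_classes = check_count(n_classes, "n_classes"),
    eeg_channels = check_count(eeg_channels, "eeg_channels"),
    eye_channels = check_count(eye_channels, "eye_channels"),
    eeg_effect = check_nonneg(eeg_effect, "eeg_effect"),
    eye_effect = check_nonneg(eye_effect, "eye_effect"),
    illumination_amplitude = check_nonneg(illumination_amplitude,
                                          "illumination_amplitude"),
    seed = check_count(abs(seed) + 1, "seed") - 1L
  )
  if (cfg$trial_seconds <= 0)
    stop_config("trial_seconds must be positive")
  n <- cfg$trial_seconds * cfg$sample_rate_hz
  if (abs(n - round(n)) > 1e-9)
    stop_config("trial_seconds * sample_rate_hz must be an integer, got ", n)
  if (cfg$n_classes != 4L)
    stop_config("n_classes is fixed at 4, got ", cfg$n_classes)
  if (cfg$eye_channels != 4L)
    stop_config("eye_channels is fixed at 4, got ", cfg$eye_channels)
  if (cfg$trials_per_session %% cfg$n_classes != 0L)
    stop_config("trials_per_session must be divisible by 4 for balanced ",
                "classes, got ", cfg$trials_per_session)
  if (cfg$eeg_channels < 16L)
    stop_config("eeg_channels must be >= 16 to host the class signatures")
  cfg$n_time <- as.integer(round(n))
  class(cfg) <- "synthetic_config"
  cfg
}

# unit-variance Gaussian noise band-limited to [low, high] Hz, built in the
# frequency domain (vectorised over channels via mvfft)
band_limited_noise <- function(n, channels, fs, low = 1, high = 75) {
  x <- matrix(stats::rnorm(n * channels), n, channels)
  f <- stats::mvfft(x)
  freq <- (seq_len(n) - 1) * fs / n
  freq <- pmin(freq, fs - freq) # fold negative frequencies
  keep <- freq >= low & freq <= high
  f[!keep, ] <- 0
  x <- Re(stats::mvfft(f, inverse = TRUE)) / n
  sdv <- apply(x, 2, stats::sd)
  sweep(x, 2, pmax(sdv, .Machine$double.eps), "/")
}

# smooth unit-sd illumination waveform for one (session, trial) index
illumination_waveform <- function(n, fs, seed) {
  with_seed(seed, {
    tt <- (seq_len(n) - 1) / fs
    fr <- stats::runif(3, 0.05, 0.3)
    am <- stats::runif(3, 0.5, 1)
    ph <- stats::runif(3, 0, 2 * pi)
    w <- am[1] * sin(2 * pi * fr[1] * tt + ph[1]) +
         am[2] * sin(2 * pi * fr[2] * tt + ph[2]) +
         am[3] * sin(2 * pi * fr[3] * tt + ph[3])
    w / max(stats::sd(w), .Machine$double.eps)
  })
}

session_labels <- function(cfg, session) {
  with_seed(substream_seed(cfg$seed, paste0("labels:", session)),
            sample(rep(0:3, cfg$trials_per_session / 4L)))
}

# one trial's raw signals; all random draws happen unconditionally so the
# realisation is invariant to the effect amplitudes (only the added class /
# illumination components scale)
generate_trial <- function(cfg, subject, session, trial, label, illum) {
  n <- cfg$n_time
  fs <- cfg$sample_rate_hz
  tt <- (seq_len(n) - 1) / fs
  with_seed(substream_seed(cfg$seed,
                           paste0("trial:", subject, ":", session, ":", trial)), {
    high <- min(75, 0.999 * fs / 2)
    eeg <- band_limited_noise(n, cfg$eeg_channels, fs, low = 1, high = high)
    phi <- stats::runif(4, 0, 2 * pi) # eeg sig, pupil mod, gaze drift x/y
    if (label <= 1L) {
      sig <- cfg$eeg_effect * sin(2 * pi * EEG_SIG_FREQ[label + 1L] * tt + phi[1])
      eeg[, EEG_SIG_CHANS[[label + 1L]]] <-
        eeg[, EEG_SIG_CHANS[[label + 1L]]] + sig
    }
    pupil_noise <- matrix(stats::rnorm(2 * n), n, 2)
    walk <- apply(matrix(stats::rnorm(2 * n, sd = 1 / sqrt(n)), n, 2), 2, cumsum)
    pupil_mod <- if (label >= 2L)
      cfg$eye_effect * sin(2 * pi * PUPIL_MOD_FREQ[label + 1L] * tt + phi[2])
    else 0
    gaze_drift <- if (label >= 2L)
      cbind(cfg$eye_effect * sin(2 * pi * GAZE_DRIFT_FREQ[label + 1L] * tt + phi[3]),
            cfg$eye_effect * sin(2 * pi * GAZE_DRIFT_FREQ[label + 1L] * tt + phi[4]))
    else 0
    pupil <- PUPIL_BASELINE + PUPIL_SCALE *
      (pupil_noise + pupil_mod + cfg$illumination_amplitude * illum)
    gaze <- GAZE_CENTER + GAZE_SCALE * (walk + gaze_drift)
    eye <- cbind(pupil, gaze)
    colnames(eye) <- c("pupil_X", "pupil_Y", "gaze_X", "gaze_Y")
    structure(list(eeg = eeg, eye = eye, label = as.integer(label),
                   subject_id = as.integer(subject),
                   session_id = as.integer(session),
                   trial_id = as.integer(trial)),
              class = "raw_trial")
  })
}

#' Generate a synthetic multimodal trial set
#'
#' Produces `n_subjects * n_sessions * trials_per_session` raw trials under
#' the signal model described in the package vignette: band-limited EEG
#' noise with class-specific sinusoidal signatures, random-walk gaze with
#' class-specific slow drift, and pupil series contaminated by a smooth
#' illumination waveform shared by every subject for the same
#' (session, trial) index. Deterministic for a fixed `seed`.
#'
#' @param config A [synthetic_config()].
#' @return A `trialset`: list with elements `trials` (list of `raw_trial`,
#'   ordered by subject, session, trial), `config`, and `provenance`
#'   documenting the signal model.
#' @export
generate_trialset <- function(config) {
  if (!inherits(config, "synthetic_config"))
    stop_config("config must be created by synthetic_config()")
  labels <- lapply(seq_len(config$n_sessions), function(s) session_labels(config, s))
  illum <- lapply(seq_len(config$n_sessions), function(s)
    lapply(seq_len(config$trials_per_session), function(j)
      illumination_waveform(config$n_time, config$sample_rate_hz,
                            substream_seed(config$seed, paste0("illum:", s, ":", j)))))
  trials <- vector("list",
                   config$n_subjects * config$n_sessions * config$trials_per_session)
  i <- 0L
  for (subj in seq_len(config$n_subjects)) {
    for (sess in seq_len(config$n_sessions)) {
      for (tr in seq_len(config$trials_per_session)) {
        i <- i + 1L
        trials[[i]] <- generate_trial(config, subj, sess, tr,
                                      labels[[sess]][tr], illum[[sess]][[tr]])
      }
    }
  }
  structure(list(
    trials = trials,
    config = config,
    provenance = list(
      generator = "emofuse::generate_trialset",
      signal_model = paste(
        "EEG: unit-variance Gaussian noise band-limited to the 1-75 Hz",
        "passband plus class-dependent sinusoids (classes 0/1 at",
        "10/20 Hz on channels 1-8/9-16, amplitude eeg_effect).",
        "Gaze: random-walk noise plus class-dependent slow drift",
        "(classes 2/3 at 0.3/0.6 Hz, amplitude eye_effect).",
        "Pupil: baseline + unit noise + class-dependent slow modulation",
        "(classes 2/3 at 0.5/1.0 Hz, amplitude eye_effect) + one smooth",
        "illumination waveform shared across subjects per (session, trial)",
        "index, scaled by illumination_amplitude.")
    )), class = "trialset")
}

#' Ground-truth shared illumination waveforms of a synthetic trial set
#'
#' Reconstructs, in pupil px units, the exact illumination component that
#' [generate_trialset()] injected into the pupil channels of every subject,
#' one column per (session, trial) index. Intended as an oracle when testing
#' light-reflex removal.
#'
#' @param trialset A `trialset` produced by [generate_trialset()].
#' @return Numeric matrix, time points by `n_sessions * trials_per_session`
#'   columns ordered session-major.
#' @export
shared_illumination_reference <- function(trialset) {
  if (!inherits(trialset, "trialset") ||
      !identical(trialset$provenance$generator %||% "", "emofuse::generate_trialset"))
    stop("trialset lacks generator provenance; reference waveforms are only ",
         "defined for sets produced by generate_trialset()")
  cfg <- trialset$config
  out <- matrix(0, cfg$n_time, cfg$n_sessions * cfg$trials_per_session)
  k <- 0L
  for (s in seq_len(cfg$n_sessions)) {
    for (j in seq_len(cfg$trials_per_session)) {
      k <- k + 1L
      out[, k] <- PUPIL_SCALE * cfg$illumination_amplitude *
        illumination_waveform(cfg$n_time, cfg$sample_rate_hz,
                              substream_seed(cfg$seed, paste0("illum:", s, ":", j)))
    }
  }
  out
}

#' @export
print.trialset <- function(x, ...) {
  cfg <- x$config
  cat("Multimodal trial set:", length(x$trials), "trials\n")
  if (inherits(cfg, "synthetic_config")) {
    cat(sprintf("  %d subjects x %d sessions x %d trials, %.4g s at %.4g Hz\n",
                cfg$n_subjects, cfg$n_sessions, cfg$trials_per_session,
                cfg$trial_seconds, cfg$sample_rate_hz))
    cat(sprintf("  effects: eeg %.3g, eye %.3g, illumination %.3g (seed %d)\n",
                cfg$eeg_effect, cfg$eye_effect, cfg$illumination_amplitude,
                cfg$seed))
  }
  tab <- table(vapply(x$trials, `[[`, integer(1), "label"))
  cat("  labels:", paste(sprintf("%s=%d", emotion_levels()[names(tab)], tab),
                         collapse = ", "), "\n")
  invisible(x)
}
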