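# Preprocessing: band-pass filtering, baseline correction, pupillary
# light-reflex removal by PCA across participants, and non-overlapping
# 4-s windowing with anti-aliased downsampling to 60 Hz.

#' Preprocessing configuration
#'
#' @param band_low_hz,band_high_hz Band-pass edges in Hz for the EEG
#'   channels (defaults 1 and 75).
#' @param window_seconds Non-overlapping window length in seconds.
#' @param target_rate_hz Output sampling rate after anti-aliased
#'   downsampling; `window_seconds * target_rate_hz` must be an integer
#'   (240 rows per window at the defaults).
#' @param filter_order Overall Butterworth band-pass order (even; applied
#'   forward-backward for zero phase).
#' @param pca_enabled Remove the participant-shared pupillary light reflex
#'   by PCA across subjects before windowing.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(band_low_hz = 1, band_high_hz = 75,
                              window_seconds = 4, target_rate_hz = 60,
                              filter_order = 4, pca_enabled = TRUE) {
  cfg <- list(band_low_hz = check_nonneg(band_low_hz, "band_low_hz"),
              band_high_hz = check_nonneg(band_high_hz, "band_high_hz"),
              window_seconds = check_nonneg(window_seconds, "window_seconds"),
              target_rate_hz = check_nonneg(target_rate_hz, "target_rate_hz"),
              filter_order = check_count(filter_order, "filter_order"),
              pca_enabled = isTRUE(pca_enabled))
  if (cfg$band_low_hz <= 0 || cfg$band_low_hz >= cfg$band_high_hz)
    stop_config("need 0 < band_low_hz < band_high_hz")
  if (cfg$filter_order %% 2L != 0L)
    stop_config("filter_order must be even")
  rows <- cfg$window_seconds * cfg$target_rate_hz
  if (abs(rows - round(rows)) > 1e-9)
    stop_config("window_seconds * target_rate_hz must be an integer, got ", rows)
  cfg$window_rows <- as.integer(round(rows))
  class(cfg) <- "preprocess_config"
  cfg
}

filtfilt_matrix <- function(filt, x) {
  for (j in seq_len(ncol(x))) x[, j] <- signal::filtfilt(filt, x[, j])
  x
}

#' Zero-phase Butterworth band-pass filter
#'
#' Filters each column of `x` forward and backward with a Butterworth
#' band-pass of overall order `cfg$filter_order`, removing DC and content
#' outside `[band_low_hz, band_high_hz]` without phase distortion.
#'
#' @param x Numeric matrix, time by channels.
#' @param fs Sampling rate in Hz; must exceed `2 * band_high_hz`.
#' @param cfg A [preprocess_config()].
#' @return Filtered matrix of the same shape.
#' @export
bandpass_filter <- function(x, fs, cfg = preprocess_config()) {
  x <- as.matrix(x)
  if (fs <= 2 * cfg$band_high_hz)
    stop("sampling rate ", fs, " Hz is too low for a band edge at ",
         cfg$band_high_hz, " Hz (need fs > ", 2 * cfg$band_high_hz, ")")
  if (nrow(x) <= 3 * cfg$filter_order)
    stop("signal too short for filter order ", cfg$filter_order)
  bf <- signal::butter(cfg$filter_order / 2,
                       c(cfg$band_low_hz, cfg$band_high_hz) / (fs / 2),
                       type = "pass")
  filtfilt_matrix(bf, x)
}

#' Per-channel baseline correction
#'
#' Subtracts each channel's mean over the whole trial from both modalities.
#' Idempotent.
#'
#' @param trial A `raw_trial` (list with matrices `eeg` and `eye`).
#' @return The trial with zero-mean channels.
#' @export
baseline_correct <- function(trial) {
  if (is.null(trial$eeg) || nrow(trial$eeg) == 0L) stop("empty trial")
  trial$eeg <- sweep(trial$eeg, 2, colMeans(trial$eeg))
  trial$eye <- sweep(trial$eye, 2, colMeans(trial$eye))
  trial
}

#' Remove the participant-shared pupillary light reflex
#'
#' Given a panel `M` (time points by participants) of one pupil channel's
#' responses to the same stimulus, z-normalizes each column, estimates the
#' shared light-reflex component as the projection onto the first principal
#' component across participants, and splits the normalized panel as
#' `M = A + B`: `A` the light component (removed), `B` the retained
#' emotional information.
#'
#' @param panel Numeric matrix, time by participants (at least 2 columns),
#'   or a `pupil_panel` from a previous call (its `values` are reused).
#' @return A `pupil_panel`: list with `values` (normalized panel),
#'   `component_light` (A) and `component_emotion` (B), where
#'   `values = component_light + component_emotion`.
#' @export
pupil_light_removal <- function(panel) {
  m <- if (inherits(panel, "pupil_panel")) panel$values else as.matrix(panel)
  if (ncol(m) < 2L)
    stop("need at least 2 participant columns to estimate a shared ",
         "component, got ", ncol(m))
  sdv <- apply(m, 2, stats::sd)
  if (any(sdv == 0)) stop("zero-variance participant column in pupil panel")
  mz <- scale(m)[, , drop = FALSE]
  attr(mz, "scaled:center") <- attr(mz, "scaled:scale") <- NULL
  u1 <- svd(mz, nu = 1, nv = 0)$u[, 1]
  a <- u1 %*% crossprod(u1, mz) # projection of each column onto PC1
  structure(list(values = mz, component_light = a,
                 component_emotion = mz - a),
            class = "pupil_panel")
}

# anti-alias low-pass (zero phase) then linear interpolation onto the
# target-rate grid; interpolation is local so windowing and downsampling
# commute exactly
decimate_matrix <- function(x, fs, target_hz, anti_alias = TRUE) {
  x <- as.matrix(x)
  if (target_hz > fs) stop("target rate exceeds sampling rate")
  if (target_hz == fs) return(x)
  if (anti_alias) {
    lp <- signal::butter(4, 0.9 * (target_hz / 2) / (fs / 2), type = "low")
    x <- filtfilt_matrix(lp, x)
  }
  n_out <- floor(nrow(x) * target_hz / fs)
  pos <- (seq_len(n_out) - 1) * fs / target_hz # 0-based source positions
  i0 <- pmin(floor(pos), nrow(x) - 2)
  fr <- pos - i0
  x[i0 + 1, , drop = FALSE] * (1 - fr) + x[i0 + 2, , drop = FALSE] * fr
}

#' Split a trial into non-overlapping windows and downsample
#'
#' Divides a (filtered, baseline-corrected) trial into half-open
#' `[k*window_seconds, (k+1)*window_seconds)` windows, anti-alias low-pass
#' filters once over the whole trial, and linearly interpolates each window
#' onto the `target_rate_hz` grid, yielding exactly
#' `window_seconds * target_rate_hz` rows per window (240 at the defaults).
#' Incomplete trailing windows are dropped, never padded. EEG and eye
#' windows share identical time support and inherit the trial label.
#'
#' @param trial A `raw_trial`.
#' @param cfg A [preprocess_config()].
#' @param fs Sampling rate of the trial in Hz.
#' @return List of `windowed_sample` objects (possibly empty), each with
#'   `eeg` (rows x 62), `eye` (rows x 4), `label` and id fields.
#' @export
window_and_downsample <- function(trial, cfg = preprocess_config(), fs) {
  n <- nrow(trial$eeg)
  win_raw <- cfg$window_seconds * fs
  if (abs(win_raw - round(win_raw)) > 1e-9)
    stop("window_seconds * fs must be an integer number of samples")
  win_raw <- as.integer(round(win_raw))
  n_win <- n %/% win_raw
  if (n_win == 0L) return(list())
  filt <- function(x) {
    if (cfg$target_rate_hz == fs) return(as.matrix(x))
    lp <- signal::butter(4, 0.9 * (cfg$target_rate_hz / 2) / (fs / 2),
                         type = "low")
    filtfilt_matrix(lp, as.matrix(x))
  }
  eeg_f <- filt(trial$eeg)
  eye_f <- filt(trial$eye)
  lapply(seq_len(n_win), function(k) {
    rows <- ((k - 1L) * win_raw + 1L):(k * win_raw)
    structure(list(
      eeg = decimate_matrix(eeg_f[rows, , drop = FALSE], fs,
                            cfg$target_rate_hz, anti_alias = FALSE),
      eye = decimate_matrix(eye_f[rows, , drop = FALSE], fs,
                            cfg$target_rate_hz, anti_alias = FALSE),
      label = trial$label,
      subject_id = trial$subject_id, session_id = trial$session_id,
      trial_id = trial$trial_id, window_index = k - 1L),
      class = "windowed_sample")
  })
}

#' Preprocess a trial set into a windowed dataset
#'
#' Runs the full preprocessing pipeline: EEG band-pass filtering, per-trial
#' baseline correction, PCA light-reflex removal on the pupil channels
#' (panels built per (session, trial, channel) across subjects; z-scoring
#' replaces the raw pupil series by the retained component), per-trial
#' z-normalization of the gaze channels, then non-overlapping windowing
#' with anti-aliased downsampling. Windows are ordered deterministically by
#' (subject, session, trial, window).
#'
#' @param trialset A `trialset`.
#' @param cfg A [preprocess_config()].
#' @param fs Sampling rate in Hz; defaults to the generator's rate when the
#'   trial set carries a synthetic config.
#' @return A `windowed_set`: list with arrays `eeg` (n x rows x 62) and
#'   `eye` (n x rows x 4), integer `labels` (codes 0-3), and a `meta`
#'   data.frame (subject, session, trial, window).
#' @export
preprocess_trialset <- function(trialset, cfg = preprocess_config(), fs = NULL) {
  fs <- fs %||% trialset$config$sample_rate_hz
  if (is.null(fs)) stop("sampling rate unknown: supply fs")
  trials <- trialset$trials
  # EEG filter + baseline for both modalities
  trials <- lapply(trials, function(tr) {
    tr$eeg <- bandpass_filter(tr$eeg, fs, cfg)
    baseline_correct(tr)
  })
  # pupil light removal across subjects per (session, trial index, channel)
  key <- vapply(trials, function(tr)
    paste0(tr$session_id, ":", tr$trial_id), character(1))
  if (cfg$pca_enabled) {
    for (k in unique(key)) {
      idx <- which(key == k)
      if (length(idx) < 2L) {
        for (i in idx) trials[[i]]$eye[, 1:2] <- scale(trials[[i]]$eye[, 1:2])
        next
      }
      for (ch in 1:2) {
        panel <- vapply(trials[idx], function(tr) tr$eye[, ch],
                        numeric(nrow(trials[[idx[1]]]$eye)))
        b <- pupil_light_removal(panel)$component_emotion
        for (j in seq_along(idx)) trials[[idx[j]]]$eye[, ch] <- b[, j]
      }
    }
  } else {
    trials <- lapply(trials, function(tr) {
      tr$eye[, 1:2] <- scale(tr$eye[, 1:2]); tr
    })
  }
  # gaze normalization per trial
  trials <- lapply(trials, function(tr) {
    sdv <- pmax(apply(tr$eye[, 3:4, drop = FALSE], 2, stats::sd),
                .Machine$double.eps)
    tr$eye[, 3:4] <- sweep(tr$eye[, 3:4, drop = FALSE], 2, sdv, "/")
    tr
  })
  ord <- order(vapply(trials, `[[`, integer(1), "subject_id"),
               vapply(trials, `[[`, integer(1), "session_id"),
               vapply(trials, `[[`, integer(1), "trial_id"))
  windows <- unlist(lapply(trials[ord], window_and_downsample, cfg = cfg,
                           fs = fs), recursive = FALSE)
  as_windowed_set(windows, cfg)
}

as_windowed_set <- function(windows, cfg = preprocess_config()) {
  n <- length(windows)
  if (n == 0L) stop("no windows produced (trials shorter than one window?)")
  rows <- nrow(windows[[1]]$eeg)
  eeg <- array(0, c(n, rows, ncol(windows[[1]]$eeg)))
  eye <- array(0, c(n, rows, ncol(windows[[1]]$eye)))
  for (i in seq_len(n)) {
    eeg[i, , ] <- windows[[i]]$eeg
    eye[i, , ] <- windows[[i]]$eye
  }
  meta <- data.frame(
    subject = vapply(windows, `[[`, integer(1), "subject_id"),
    session = vapply(windows, `[[`, integer(1), "session_id"),
    trial = vapply(windows, `[[`, integer(1), "trial_id"),
    window = vapply(windows, `[[`, integer(1), "window_index"))
  structure(list(eeg = eeg, eye = eye,
                 labels = vapply(windows, `[[`, integer(1), "label"),
                 meta = meta, window_rows = rows, config = cfg),
            class = "windowed_set")
}

#' @export
print.windowed_set <- function(x, ...) {
  cat("Windowed multimodal dataset:", dim(x$eeg)[1], "windows,",
      dim(x$eeg)[2], "rows,", dim(x$eeg)[3], "EEG +", dim(x$eye)[3],
      "eye channels\n")
  tab <- table(x$labels)
  cat("  labels:", paste(sprintf("%s=%d", emotion_levels()[names(tab)], tab),
                         collapse = ", "), "\n")
  invisible(x)
}

# subset a windowed_set by window indices
ws_subset <- function(ws, idx) {
  structure(list(eeg = ws$eeg[idx, , , drop = FALSE],
                 eye = ws$eye[idx, , , drop = FALSE],
                 labels = ws$labels[idx], meta = ws$meta[idx, , drop = FALSE],
                 window_rows = ws$window_rows, config = ws$config),
            class = "windowed_set")
}
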