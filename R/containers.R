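# Trial-set and windowed-dataset containers: a directory with a JSON
# manifest plus one Arrow/Feather table per matrix. Feather stores IEEE
# doubles exactly, so containers round-trip losslessly.

eye_channel_names <- c("pupil_X", "pupil_Y", "gaze_X", "gaze_Y")

matrix_to_table <- function(m, prefix) {
  colnames(m) <- if (ncol(m) == 4 && prefix == "eye") eye_channel_names
  else paste0(prefix, seq_len(ncol(m)))
  as.data.frame(m)
}

#' Write a trial set container
#'
#' Serializes a `trialset` to a directory: `manifest.json` (config,
#' provenance, trial index with ids and labels) plus one Feather file per
#' trial holding the EEG and eye matrices side by side. Lossless for
#' doubles.
#'
#' @param trialset A `trialset`.
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_trialset <- function(trialset, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  n_eeg <- ncol(trialset$trials[[1]]$eeg)
  idx <- data.frame(
    file = sprintf("trial_%04d.feather", seq_along(trialset$trials)),
    subject_id = vapply(trialset$trials, `[[`, integer(1), "subject_id"),
    session_id = vapply(trialset$trials, `[[`, integer(1), "session_id"),
    trial_id = vapply(trialset$trials, `[[`, integer(1), "trial_id"),
    label = vapply(trialset$trials, `[[`, integer(1), "label"))
  cfg <- trialset$config
  manifest <- list(container = "emofuse.trialset", version = 1L,
                   n_eeg_channels = n_eeg,
                   config = if (inherits(cfg, "synthetic_config"))
                     unclass(cfg) else cfg,
                   config_class = class(cfg)[1] %||% NA,
                   provenance = trialset$provenance, trials = idx)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (i in seq_along(trialset$trials)) {
    tr <- trialset$trials[[i]]
    arrow::write_feather(cbind(matrix_to_table(tr$eeg, "eeg"),
                               matrix_to_table(tr$eye, "eye")),
                         file.path(path, idx$file[i]))
  }
  invisible(path)
}

#' Read a trial set container
#'
#' @param path Directory written by [write_trialset()].
#' @return A `trialset`.
#' @export
read_trialset <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json under ", path)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(manifest$container, "emofuse.trialset"))
    stop("not an emofuse trial-set container: ", path)
  n_eeg <- manifest$n_eeg_channels
  idx <- manifest$trials
  trials <- lapply(seq_len(nrow(idx)), function(i) {
    tab <- as.data.frame(arrow::read_feather(file.path(path, idx$file[i])))
    structure(list(eeg = unname(as.matrix(tab[, seq_len(n_eeg)])),
                   eye = as.matrix(tab[, n_eeg + 1:4]),
                   label = as.integer(idx$label[i]),
                   subject_id = as.integer(idx$subject_id[i]),
                   session_id = as.integer(idx$session_id[i]),
                   trial_id = as.integer(idx$trial_id[i])),
              class = "raw_trial")
  })
  cfg <- manifest$config
  if (identical(manifest$config_class, "synthetic_config") && !is.null(cfg))
    cfg <- do.call(synthetic_config,
                   cfg[setdiff(names(cfg), "n_time")])
  structure(list(trials = trials, config = cfg,
                 provenance = manifest$provenance), class = "trialset")
}

#' Write a windowed dataset container
#'
#' One Feather table with all windows stacked (rows ordered by window,
#' then time), a Feather metadata table and a JSON manifest; ordering is
#' deterministic (subject, session, trial, window).
#'
#' @param ws A `windowed_set`.
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_windowed_set <- function(ws, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  n <- dim(ws$eeg)[1]; rows <- dim(ws$eeg)[2]
  flat <- function(a) matrix(aperm(a, c(2, 1, 3)), n * rows, dim(a)[3])
  arrow::write_feather(cbind(matrix_to_table(flat(ws$eeg), "eeg"),
                             matrix_to_table(flat(ws$eye), "eye")),
                       file.path(path, "windows.feather"))
  arrow::write_feather(cbind(ws$meta, label = ws$labels),
                       file.path(path, "meta.feather"))
  jsonlite::write_json(list(container = "emofuse.windows", version = 1L,
                            n_windows = n, window_rows = rows,
                            n_eeg_channels = dim(ws$eeg)[3]),
                       file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a windowed dataset container
#'
#' @param path Directory written by [write_windowed_set()].
#' @return A `windowed_set`.
#' @export
read_windowed_set <- function(path) {
  manifest <- jsonlite::read_json(file.path(path, "manifest.json"),
                                  simplifyVector = TRUE)
  if (!identical(manifest$container, "emofuse.windows"))
    stop("not an emofuse windowed container: ", path)
  n <- manifest$n_windows; rows <- manifest$window_rows
  ne <- manifest$n_eeg_channels
  tab <- as.data.frame(arrow::read_feather(file.path(path, "windows.feather")))
  meta <- as.data.frame(arrow::read_feather(file.path(path, "meta.feather")))
  unflat <- function(m) aperm(array(as.matrix(m), c(rows, n, ncol(m))),
                              c(2, 1, 3))
  structure(list(eeg = unname(unflat(tab[, seq_len(ne)])),
                 eye = unname(unflat(tab[, ne + 1:4])),
                 labels = as.integer(meta$label),
                 meta = meta[, c("subject", "session", "trial", "window")],
                 window_rows = rows, config = NULL),
            class = "windowed_set")
}
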