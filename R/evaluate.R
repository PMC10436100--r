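# Evaluation: stratified k-fold splitting (optionally grouped by trial so
# windows of one trial never straddle a split), confusion-matrix metrics
# (accuracy, macro precision/recall/F1, Cohen's kappa), cross-validated
# evaluation and paired single-modality ablations.

#' Stratified k-fold partition
#'
#' Partitions indices into `k` disjoint folds such that every fold contains
#' every class and per-class fold sizes differ by at most one. With
#' `groups` supplied, whole groups (e.g. trials) are assigned to folds,
#' stratified by the group's label, so no group straddles folds.
#'
#' @param labels Integer class codes, one per sample.
#' @param k Number of folds.
#' @param seed Integer seed (deterministic assignment).
#' @param groups Optional grouping vector aligned with `labels`; all
#'   samples of a group share its label.
#' @return List of `k` integer index vectors (the held-out sets), an exact
#'   partition of `seq_along(labels)`.
#' @export
stratified_kfold <- function(labels, k, seed = 1L, groups = NULL) {
  k <- check_count(k, "k")
  labels <- as.integer(labels)
  if (is.null(groups)) {
    units <- seq_along(labels)
    unit_lab <- labels
  } else {
    if (length(groups) != length(labels))
      stop("groups must align with labels")
    units <- unique(groups)
    unit_lab <- labels[match(units, groups)]
    if (any(tapply(labels, groups, function(l) length(unique(l))) != 1L))
      stop("all samples of a group must share one label")
  }
  counts <- table(unit_lab)
  if (length(counts) < 1L || any(counts < k))
    stop("need at least k = ", k, " units per class; got minimum ",
         min(counts))
  fold_of <- integer(length(units))
  with_seed(substream_seed(seed, "kfold"), {
    for (lv in sort(unique(unit_lab))) {
      iu <- which(unit_lab == lv)
      iu <- iu[sample.int(length(iu))]
      fold_of[iu] <- rep_len(sample.int(k), length(iu))
    }
  })
  lapply(seq_len(k), function(f) {
    if (is.null(groups)) which(fold_of == f)
    else which(groups %in% units[fold_of == f])
  })
}

#' Confusion matrix from labels and predictions
#'
#' @param truth,pred Integer class codes `0:(M-1)`.
#' @param n_classes Number of classes.
#' @return Integer matrix, rows = true class, columns = predicted.
#' @export
confusion_matrix <- function(truth, pred, n_classes = 4) {
  cm <- matrix(0L, n_classes, n_classes,
               dimnames = list(truth = emotion_levels()[seq_len(n_classes)],
                               pred = emotion_levels()[seq_len(n_classes)]))
  for (i in seq_along(truth))
    cm[truth[i] + 1L, pred[i] + 1L] <- cm[truth[i] + 1L, pred[i] + 1L] + 1L
  cm
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy (trace over total), one-vs-rest precision/recall/F1 per class
#' with macro averaging, and Cohen's kappa computed from the marginals.
#' A class that receives no predictions has undefined precision; it
#' contributes 0 with a warning.
#'
#' @param cm Square count matrix, rows = true class, columns = predicted.
#' @return A `metric_report`: list with `accuracy`, `precision`, `recall`,
#'   `f1`, `kappa`, `per_class` data frame and the `confusion` matrix.
#' @export
compute_metrics <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  total <- sum(cm)
  if (total <= 0) stop("empty confusion matrix")
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  if (any(tp + fp == 0))
    warning("class(es) ", paste(which(tp + fp == 0), collapse = ", "),
            " received no predictions; precision set to 0")
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  po <- sum(tp) / total
  pe <- sum(rowSums(cm) * colSums(cm)) / total^2
  kappa <- if (abs(1 - pe) < 1e-12) 0 else (po - pe) / (1 - pe)
  structure(list(accuracy = po, precision = mean(prec), recall = mean(rec),
                 f1 = mean(f1), kappa = kappa,
                 per_class = data.frame(class = seq_len(nrow(cm)) - 1L,
                                        precision = prec, recall = rec,
                                        f1 = f1, row.names = NULL),
                 confusion = cm, n = total),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "accuracy %.4f | macro precision %.4f | recall %.4f | F1 %.4f | kappa %.4f (n=%d)\n",
    x$accuracy, x$precision, x$recall, x$f1, x$kappa, x$n))
  invisible(x)
}

# chance-level discrimination between one pair of classes, read off the
# confusion matrix restricted to that pair
pair_discrimination <- function(cm, i, j) {
  ii <- i + 1L; jj <- j + 1L
  sub <- cm[c(ii, jj), c(ii, jj)]
  if (sum(sub) == 0) return(NA_real_)
  sum(diag(sub)) / sum(sub)
}

#' Cross-validated evaluation of the classifier
#'
#' Fits and evaluates the model over stratified folds: each fold is held
#' out in turn (20% at `k = 5`, matching an 80/20 split), the model is
#' trained on the remainder and scored on the held-out windows. By default
#' folds are grouped by trial so windows of one trial never appear on both
#' sides of a split.
#'
#' @param x A `windowed_set`.
#' @param mode `"fused"`, `"eeg_only"` or `"eye_only"`.
#' @param train A [train_config()]; its `k_folds` and `seed` drive the
#'   fold assignment.
#' @param folds Optional precomputed fold list (from [stratified_kfold()])
#'   to reuse across paired runs.
#' @param max_folds Evaluate only the first `max_folds` folds (a single
#'   fold is one 80/20 split).
#' @param group_by_trial Assign whole trials to folds (recommended).
#' @param ... Passed to [emofuse()] (branch/fusion configuration).
#' @return An `emofuse_cv`: list with `reports` (per-fold
#'   `metric_report`s), `pooled` (metrics over pooled held-out
#'   predictions), `folds`, `mode` and `fits`.
#' @export
evaluate_emofuse <- function(x, mode = "fused", train = train_config(),
                             folds = NULL, max_folds = NULL,
                             group_by_trial = TRUE, ...) {
  groups <- if (group_by_trial)
    interaction(x$meta$subject, x$meta$session, x$meta$trial, drop = TRUE)
  else NULL
  folds <- folds %||% stratified_kfold(x$labels, train$k_folds,
                                       seed = train$seed, groups = groups)
  use <- seq_len(if (is.null(max_folds)) length(folds)
                 else min(max_folds, length(folds)))
  reports <- list()
  fits <- list()
  all_truth <- integer(0); all_pred <- integer(0)
  for (f in use) {
    test_idx <- folds[[f]]
    fit <- emofuse(ws_subset(x, setdiff(seq_along(x$labels), test_idx)),
                   mode = mode, train = train, ...)
    pred <- predict(fit, ws_subset(x, test_idx))
    cm <- confusion_matrix(x$labels[test_idx], pred, train$n_classes)
    rep_f <- compute_metrics(cm)
    rep_f$fold <- f
    reports[[f]] <- rep_f
    fits[[f]] <- fit
    all_truth <- c(all_truth, x$labels[test_idx])
    all_pred <- c(all_pred, pred)
  }
  pooled <- compute_metrics(confusion_matrix(all_truth, all_pred,
                                             train$n_classes))
  structure(list(reports = reports[use], pooled = pooled, folds = folds,
                 used_folds = use, mode = mode, fits = fits[use]),
            class = "emofuse_cv")
}

#' @export
print.emofuse_cv <- function(x, ...) {
  cat("Cross-validated evaluation (", x$mode, " mode, ",
      length(x$reports), " fold(s))\n", sep = "")
  for (r in x$reports) { cat(sprintf("  fold %d: ", r$fold)); print(r) }
  cat("  pooled: "); print(x$pooled)
  invisible(x)
}

#' Paired single-modality ablation study
#'
#' Evaluates the requested modes on identical folds with identical seeds,
#' so held-out sets are the same across modes and accuracies are directly
#' comparable (fused vs EEG-only vs eye-only).
#'
#' @param x A `windowed_set`.
#' @param modes Modes to evaluate.
#' @param train A [train_config()].
#' @param max_folds Evaluate only the first folds (see
#'   [evaluate_emofuse()]).
#' @param group_by_trial Assign whole trials to folds.
#' @param ... Passed to [emofuse()].
#' @return Named list of `emofuse_cv` objects, one per mode, sharing the
#'   `folds` attribute.
#' @export
ablation_run <- function(x, modes = c("eeg_only", "eye_only", "fused"),
                         train = train_config(), max_folds = NULL,
                         group_by_trial = TRUE, ...) {
  bad <- setdiff(modes, c("eeg_only", "eye_only", "fused"))
  if (length(bad)) stop("unknown mode(s): ", paste(bad, collapse = ", "))
  groups <- if (group_by_trial)
    interaction(x$meta$subject, x$meta$session, x$meta$trial, drop = TRUE)
  else NULL
  folds <- stratified_kfold(x$labels, train$k_folds, seed = train$seed,
                            groups = groups)
  out <- lapply(modes, function(m)
    evaluate_emofuse(x, mode = m, train = train, folds = folds,
                     max_folds = max_folds, group_by_trial = group_by_trial,
                     ...))
  names(out) <- modes
  out
}
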