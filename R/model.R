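# Full network: dual branches -> fusion -> classifier head, with the
# training loop (cross-entropy + Adam) behind the classic fit-function
# interface `emofuse()`.

#' Training configuration
#'
#' Defaults follow the standard recipe for this architecture: learning
#' rate 0.001, 100 epochs, batch size 256, dropout 0.2 and a 256-unit
#' hidden layer, with 5-fold stratified cross-validation holding out 20%
#' per fold.
#'
#' @param learning_rate Adam learning rate.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param dropout Dropout probability on the hidden layer.
#' @param hidden_units Width of the hidden layer.
#' @param n_classes Number of emotion classes (4).
#' @param k_folds Folds for cross-validated evaluation.
#' @param test_fraction Held-out fraction per evaluation split (the
#'   complement of one fold at `k_folds = 5`).
#' @param seed Integer root seed for initialization, shuffling, dropout
#'   and fold assignment.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, epochs = 100,
                         batch_size = 256, dropout = 0.2,
                         hidden_units = 256, n_classes = 4,
                         k_folds = 5, test_fraction = 0.2, seed = 1L) {
  cfg <- list(learning_rate = check_nonneg(learning_rate, "learning_rate"),
              epochs = check_count(epochs, "epochs"),
              batch_size = check_count(batch_size, "batch_size"),
              dropout = check_nonneg(dropout, "dropout"),
              hidden_units = check_count(hidden_units, "hidden_units"),
              n_classes = check_count(n_classes, "n_classes"),
              k_folds = check_count(k_folds, "k_folds"),
              test_fraction = check_nonneg(test_fraction, "test_fraction"),
              seed = as.integer(seed))
  if (cfg$learning_rate <= 0) stop_config("learning_rate must be positive")
  if (cfg$test_fraction <= 0 || cfg$test_fraction >= 1)
    stop_config("test_fraction must be in (0, 1)")
  class(cfg) <- "train_config"
  cfg
}

#' Mean cross-entropy loss
#'
#' Mean over the batch of the negative log predicted probability of the
#' true class. Probabilities are clamped at `1e-12` inside the log so a
#' zero predicted probability yields a large finite loss, never infinity.
#'
#' @param pred_probs Numeric matrix, batch x classes; rows must sum to 1.
#' @param labels Integer class codes `0:(M-1)` (or 1-based when
#'   `one_based = TRUE`).
#' @param one_based Interpret `labels` as 1-based indices.
#' @return Nonnegative scalar loss.
#' @export
cross_entropy <- function(pred_probs, labels, one_based = FALSE) {
  pred_probs <- as.matrix(pred_probs)
  lab1 <- as.integer(labels) + if (one_based) 0L else 1L
  if (any(lab1 < 1L | lab1 > ncol(pred_probs)))
    stop("labels out of range for ", ncol(pred_probs), " classes")
  if (length(lab1) != nrow(pred_probs))
    stop("length(labels) must equal nrow(pred_probs)")
  if (any(abs(rowSums(pred_probs) - 1) > 1e-6))
    stop("rows of pred_probs must sum to 1")
  -mean(log(pmax(pred_probs[cbind(seq_along(lab1), lab1)], 1e-12)))
}

# assemble trainable parameter pack for a mode
build_net <- function(mode, branch_eeg, branch_eye, fusion_r, fusion_L,
                      train_cfg, seed) {
  eeg <- if (mode != "eye_only") init_branch_params(branch_eeg, seed) else NULL
  eye <- if (mode != "eeg_only") init_branch_params(branch_eye, seed) else NULL
  fus <- NULL
  head_in <- NA_integer_
  if (mode == "fused") {
    C <- branch_eeg$channel_widths[branch_eeg$blocks]
    if (C != branch_eye$channel_widths[branch_eye$blocks])
      stop_config("branch channel widths must agree for fusion")
    fus <- init_fusion_params(C, r = fusion_r, L = fusion_L, seed = seed)
    head_in <- prod(branch_eeg$output_grid) * C
  } else if (mode == "eeg_only") {
    head_in <- branch_eeg$channel_widths[branch_eeg$blocks]
  } else {
    head_in <- branch_eye$channel_widths[branch_eye$blocks]
  }
  head <- with_seed(substream_seed(seed, "head"), list(
    fc1 = dense_init(head_in, train_cfg$hidden_units),
    fc2 = dense_init(train_cfg$hidden_units, train_cfg$n_classes)))
  list(mode = mode, eeg = eeg, eye = eye, fusion = fus, head = head,
       head_in = head_in)
}

net_trainable <- function(net) {
  p <- list(head = net$head)
  if (!is.null(net$eeg)) p$eeg <- net$eeg$par
  if (!is.null(net$eye)) p$eye <- net$eye$par
  if (!is.null(net$fusion)) p$fusion <- net$fusion$par
  p
}

net_set_trainable <- function(net, p) {
  net$head <- p$head
  if (!is.null(net$eeg)) net$eeg$par <- p$eeg
  if (!is.null(net$eye)) net$eye$par <- p$eye
  if (!is.null(net$fusion)) net$fusion$par <- p$fusion
  net
}

# batch slices of windowed arrays -> branch input tensors
batch_tensors <- function(ws, idx) {
  n <- length(idx)
  rows <- dim(ws$eeg)[2]
  eeg_slice <- ws$eeg[idx, , , drop = FALSE]
  eye_slice <- ws$eye[idx, , , drop = FALSE]
  # rows ordered h fastest, then w, then n
  eeg <- nn_tensor(matrix(aperm(eeg_slice, c(2, 3, 1)), ncol = 1),
                   rows, dim(ws$eeg)[3], n)
  eye <- nn_tensor(matrix(aperm(eye_slice, c(2, 1, 3)),
                          nrow = rows * n, ncol = dim(ws$eye)[3]),
                   rows, 1L, n)
  list(eeg = eeg, eye = eye)
}

# flatten fused tensor (H*W*N x C) to per-sample rows N x (H*W*C)
flatten_tensor <- function(x) {
  arr <- array(x$mat, c(x$H * x$W, x$N, ncol(x$mat)))
  matrix(aperm(arr, c(2, 1, 3)), x$N, x$H * x$W * ncol(x$mat))
}

unflatten_tensor <- function(d, H, W, N, C) {
  arr <- aperm(array(d, c(N, H * W, C)), c(2, 1, 3))
  nn_tensor(matrix(arr, H * W * N, C), H, W, N)
}

gap_tensor <- function(x) {
  grp <- rep(seq_len(x$N), each = x$H * x$W)
  list(out = rowsum(x$mat, grp, reorder = TRUE) / (x$H * x$W), grp = grp)
}

net_fwd <- function(net, tens, training = FALSE, dropout = 0) {
  cc <- list()
  if (net$mode == "fused") {
    fe <- branch_fwd(net$eeg, tens$eeg, training); cc$eeg <- fe
    fy <- branch_fwd(net$eye, tens$eye, training); cc$eye <- fy
    fu <- fusion_fwd(net$fusion, fe$out, fy$out, training); cc$fusion <- fu
    h <- flatten_tensor(fu$out)
    cc$fdim <- c(fu$out$H, fu$out$W, fu$out$N, ncol(fu$out$mat))
  } else if (net$mode == "eeg_only") {
    fe <- branch_fwd(net$eeg, tens$eeg, training); cc$eeg <- fe
    g <- gap_tensor(fe$out); cc$gap <- g; cc$gdim <- fe$out
    h <- g$out
  } else {
    fy <- branch_fwd(net$eye, tens$eye, training); cc$eye <- fy
    g <- gap_tensor(fy$out); cc$gap <- g; cc$gdim <- fy$out
    h <- g$out
  }
  d1 <- dense_fwd(h, net$head$fc1); cc$fc1 <- d1$cache
  r1 <- list(out = d1$out * (d1$out > 0), cache = d1$out > 0)
  cc$relu <- r1$cache
  dr <- dropout_fwd(r1$out, dropout, training); cc$drop <- dr$cache
  d2 <- dense_fwd(dr$out, net$head$fc2); cc$fc2 <- d2$cache
  list(logits = d2$out, cache = cc)
}

net_bwd <- function(net, cc, dlogits) {
  b2 <- dense_bwd(net$head$fc2, cc$fc2, dlogits)
  dh <- dropout_bwd(cc$drop, b2$dx)
  dh <- relu_bwd(cc$relu, dh)
  b1 <- dense_bwd(net$head$fc1, cc$fc1, dh)
  g <- list(head = list(fc1 = b1$dpar, fc2 = b2$dpar))
  if (net$mode == "fused") {
    fd <- cc$fdim
    dfuse <- unflatten_tensor(b1$dx, fd[1], fd[2], fd[3], fd[4])
    fb <- fusion_bwd(net$fusion, cc$fusion, dfuse$mat)
    g$fusion <- fb$dpar
    eb <- branch_bwd(net$eeg, cc$eeg,
                     nn_tensor(fb$dve, fd[1], fd[2], fd[3]))
    yb <- branch_bwd(net$eye, cc$eye,
                     nn_tensor(fb$dvy, fd[1], fd[2], fd[3]))
    g$eeg <- eb$dpar
    g$eye <- yb$dpar
  } else {
    gt <- cc$gdim
    dmap <- b1$dx[cc$gap$grp, , drop = FALSE] / (gt$H * gt$W)
    if (net$mode == "eeg_only") {
      eb <- branch_bwd(net$eeg, cc$eeg, nn_tensor(dmap, gt$H, gt$W, gt$N))
      g$eeg <- eb$dpar
    } else {
      yb <- branch_bwd(net$eye, cc$eye, nn_tensor(dmap, gt$H, gt$W, gt$N))
      g$eye <- yb$dpar
    }
  }
  # must mirror net_trainable()'s element order for the optimizer walk
  g[intersect(c("head", "eeg", "eye", "fusion"), names(g))]
}

net_update_state <- function(net, cc) {
  if (!is.null(cc$eeg)) net$eeg$st <- cc$eeg$st
  if (!is.null(cc$eye)) net$eye$st <- cc$eye$st
  if (!is.null(cc$fusion)) net$fusion$st <- cc$fusion$st
  net
}

#' Fit a multimodal emotion classifier
#'
#' Trains the dual-branch convolutional network with multi-scale attentive
#' fusion (or a single-modality ablation of it) on a windowed dataset by
#' minimizing cross-entropy with the Adam optimizer. Deterministic for a
#' fixed `train$seed`: initialization, shuffling and dropout all draw from
#' named substreams of the root seed.
#'
#' In `"fused"` mode the classifier head sees the flattened fused feature
#' map; in `"eeg_only"`/`"eye_only"` modes the corresponding branch's
#' globally pooled feature vector is routed directly to the head.
#'
#' @param x A `windowed_set` (see [preprocess_trialset()]).
#' @param mode `"fused"`, `"eeg_only"` or `"eye_only"`.
#' @param branch_eeg,branch_eye [branch_config()]s for the two branches.
#' @param fusion_r,fusion_L Reduction ratio and floor of the fusion
#'   descriptor dimension.
#' @param train A [train_config()].
#' @param verbose Print per-epoch loss.
#' @return An object of class `emofuse` with elements `net` (parameters),
#'   `loss_history` (per-epoch mean training loss), `mode`, and the
#'   configurations used.
#' @export
emofuse <- function(x, mode = c("fused", "eeg_only", "eye_only"),
                    branch_eeg = branch_config("eeg"),
                    branch_eye = branch_config("eye"),
                    fusion_r = 2, fusion_L = 32,
                    train = train_config(), verbose = FALSE) {
  mode <- match.arg(mode)
  if (!inherits(x, "windowed_set")) stop("x must be a windowed_set")
  n <- dim(x$eeg)[1]
  labs <- as.integer(x$labels)
  present <- sort(unique(labs))
  if (!identical(present, 0:(train$n_classes - 1L)))
    stop("training set must contain every class; found codes ",
         paste(present, collapse = ", "))
  if (dim(x$eeg)[2] != branch_eeg$in_rows)
    stop_config("window rows ", dim(x$eeg)[2], " do not match branch input ",
                branch_eeg$in_rows)
  old_rng <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_rng)) assign(".Random.seed", old_rng, globalenv()))
  net <- build_net(mode, branch_eeg, branch_eye, fusion_r, fusion_L,
                   train, train$seed)
  params <- net_trainable(net)
  opt <- adam_init(params)
  loss_hist <- numeric(train$epochs)
  for (ep in seq_len(train$epochs)) {
    ord <- with_seed(substream_seed(train$seed, paste0("shuffle:", ep)),
                     sample.int(n))
    ep_seed <- substream_seed(train$seed, paste0("dropout:", ep))
    losses <- c()
    set.seed(ep_seed)
    for (start in seq(1, n, by = train$batch_size)) {
      idx <- ord[start:min(start + train$batch_size - 1L, n)]
      if (length(idx) < 2L) next # BN needs >= 2 rows
      tens <- batch_tensors(x, idx)
      fw <- net_fwd(net, tens, training = TRUE, dropout = train$dropout)
      sc <- softmax_ce_fwd(fw$logits, labs[idx] + 1L)
      losses <- c(losses, sc$loss)
      grads <- net_bwd(net, fw$cache, softmax_ce_bwd(sc$probs, labs[idx] + 1L))
      up <- adam_step(params, grads, opt, train$learning_rate)
      params <- up$params
      opt <- up$state
      net <- net_set_trainable(net, params)
      net <- net_update_state(net, fw$cache)
    }
    loss_hist[ep] <- mean(losses)
    if (verbose) message(sprintf("epoch %3d  loss %.4f", ep, loss_hist[ep]))
  }
  structure(list(net = net, mode = mode, loss_history = loss_hist,
                 branch_eeg = branch_eeg, branch_eye = branch_eye,
                 fusion_r = fusion_r, fusion_L = fusion_L, train = train,
                 n_train = n), class = "emofuse")
}

#' Predict from a fitted emotion classifier
#'
#' @param object An `emofuse` fit.
#' @param newdata A `windowed_set`.
#' @param type `"class"` for integer label codes (0-3), `"prob"` for the
#'   softmax probability matrix.
#' @param batch_size Evaluation batch size.
#' @param ... Unused.
#' @return Integer vector of class codes or a probability matrix.
#' @export
predict.emofuse <- function(object, newdata, type = c("class", "prob"),
                            batch_size = 256, ...) {
  type <- match.arg(type)
  n <- dim(newdata$eeg)[1]
  probs <- matrix(NA_real_, n, object$train$n_classes)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    tens <- batch_tensors(newdata, idx)
    fw <- net_fwd(object$net, tens, training = FALSE)
    probs[idx, ] <- softmax_probs(fw$logits)
  }
  if (type == "prob") probs else max.col(probs, ties.method = "first") - 1L
}

#' Attention weights of a fitted fused model on a dataset
#'
#' Runs the fusion stage in inference mode and returns the per-window
#' attention weights plus the pooled descriptor and compact descriptor,
#' for inspection or export.
#'
#' @param object A fitted `emofuse` with `mode = "fused"`.
#' @param newdata A `windowed_set`.
#' @param batch_size Evaluation batch size.
#' @return List with matrices `a` (EEG weights, windows x channels),
#'   `x` (descriptor) and `y` (compact descriptor).
#' @export
attention_weights <- function(object, newdata, batch_size = 256) {
  if (object$mode != "fused") stop("attention weights exist only for fused models")
  n <- dim(newdata$eeg)[1]
  a <- NULL; xs <- NULL; ys <- NULL
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    tens <- batch_tensors(newdata, idx)
    fe <- branch_fwd(object$net$eeg, tens$eeg, FALSE)
    fy <- branch_fwd(object$net$eye, tens$eye, FALSE)
    fu <- fusion_fwd(object$net$fusion, fe$out, fy$out, FALSE)
    a <- rbind(a, fu$a); xs <- rbind(xs, fu$x); ys <- rbind(ys, fu$y)
  }
  list(a = a, x = xs, y = ys)
}

#' @export
print.emofuse <- function(x, ...) {
  cat("Multimodal emotion classifier (", x$mode, " mode)\n", sep = "")
  cat(sprintf("  trained %d epochs on %d windows; final loss %.4f\n",
              length(x$loss_history), x$n_train,
              x$loss_history[length(x$loss_history)]))
  invisible(x)
}

#' @export
summary.emofuse <- function(object, ...) {
  np <- 0
  if (!is.null(object$net$eeg)) np <- np + branch_n_params(object$net$eeg)
  if (!is.null(object$net$eye)) np <- np + branch_n_params(object$net$eye)
  cnt <- function(p) if (is.list(p)) sum(vapply(p, cnt, numeric(1))) else length(p)
  if (!is.null(object$net$fusion)) np <- np + cnt(object$net$fusion$par)
  np <- np + cnt(object$net$head)
  print(object)
  cat(sprintf("  %d trainable parameters; hidden %d, dropout %.2f, lr %g\n",
              np, object$train$hidden_units, object$train$dropout,
              object$train$learning_rate))
  invisible(object)
}

#' @export
coef.emofuse <- function(object, ...) net_trainable(object$net)

#' @export
plot.emofuse <- function(x, ...) {
  graphics::plot(seq_along(x$loss_history), x$loss_history, type = "l",
                 xlab = "epoch", ylab = "mean training loss",
                 main = paste0("Training loss (", x$mode, ")"), ...)
  invisible(x)
}
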