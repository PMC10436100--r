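# Multi-scale feature fusion with cross-channel two-way soft attention.
#
# Pipeline on a pair of (H, W, C) branch feature maps:
#   V = V_eeg + V_eye                      (element-wise sum)
#   x_c = mean over H x W of V channel c   (global average pooling)
#   y = ReLU(BN(W x)), W in R^{d x C}      (compact descriptor, d = max(ceil(C/r), L))
#   a_c = exp(A_c y) / (exp(A_c y) + exp(B_c y)), b_c = 1 - a_c
#   F_c = a_c V_eeg,c + b_c V_eye,c        (convex per-channel recombination)

#' Compact-descriptor dimension
#'
#' `d = max(ceil(C / r), L)`: the bottleneck width of the fusion
#' descriptor, never below the floor `L`. The ratio `C / r` is rounded up
#' so the dimension stays integral without undershooting.
#'
#' @param C Channel count of the branch feature maps.
#' @param r Reduction ratio (positive integer).
#' @param L Floor on the descriptor dimension (default 32).
#' @return Integer `d`.
#' @export
reduced_dim <- function(C, r, L = 32) {
  C <- check_count(C, "C"); r <- check_count(r, "r"); L <- check_count(L, "L")
  max(as.integer(ceiling(C / r)), L)
}

#' Initialize fusion parameters
#'
#' @param C Channel count of the branch feature maps.
#' @param r Reduction ratio controlling the descriptor dimension.
#' @param L Floor on the descriptor dimension.
#' @param seed Integer seed (deterministic initialization).
#' @return A `fusion_params` object: projection `proj` (`d x C`), batch
#'   norm over the descriptor, and attention matrices `attn_eeg`,
#'   `attn_eye` (`C x d`).
#' @export
init_fusion_params <- function(C, r = 2, L = 32, seed = 1L) {
  d <- reduced_dim(C, r, L)
  with_seed(substream_seed(seed, "fusion"), {
    bn <- bn_init(d)
    structure(list(
      C = as.integer(C), d = d, r = as.integer(r), L = as.integer(L),
      par = list(proj = matrix(stats::rnorm(d * C, sd = sqrt(2 / C)), d, C),
                 bn = bn$par,
                 attn_eeg = matrix(stats::rnorm(C * d, sd = 1 / sqrt(d)), C, d),
                 attn_eye = matrix(stats::rnorm(C * d, sd = 1 / sqrt(d)), C, d)),
      st = bn$st), class = "fusion_params")
  })
}

#' Global average pooling of a feature map
#'
#' Reduces an `(H, W, C)` feature map to one scalar per channel, the mean
#' over the spatial grid.
#'
#' @param v Numeric array `(H, W, C)`.
#' @return Numeric vector of length `C`.
#' @export
global_avg_pool <- function(v) {
  stopifnot(length(dim(v)) == 3)
  apply(v, 3, mean)
}

#' Compact fusion descriptor
#'
#' `y = ReLU(BN(W x))` with the batch norm in inference mode (running
#' statistics), mapping the pooled channel summary `x` (length `C`) to the
#' bottleneck descriptor (length `d`).
#'
#' @param x Numeric vector of length `C`.
#' @param params A [init_fusion_params()] object.
#' @return Nonnegative numeric vector of length `d`.
#' @export
compact_descriptor <- function(x, params) {
  if (length(x) != params$C)
    stop(sprintf("descriptor length %d does not match C = %d",
                 length(x), params$C))
  z <- drop(params$par$proj %*% x)
  b <- bn_fwd(matrix(z, 1), params$par$bn, params$st, training = FALSE)
  pmax(drop(b$out), 0)
}

#' Cross-channel two-way soft attention weights
#'
#' Per channel `c`, a two-way softmax over the logits `A_c y` (EEG) and
#' `B_c y` (eye), computed with logit shifting for numerical stability.
#' The weights are convex: `a_c + b_c = 1`, `0 <= a_c <= 1`.
#'
#' @param y Compact descriptor, numeric vector of length `d`.
#' @param params A [init_fusion_params()] object.
#' @return An `attention_weights` object: list with vectors `a` (EEG) and
#'   `b` (eye) of length `C`.
#' @export
channel_attention <- function(y, params) {
  if (length(y) != params$d)
    stop(sprintf("compact descriptor length %d does not match d = %d",
                 length(y), params$d))
  delta <- drop((params$par$attn_eeg - params$par$attn_eye) %*% y)
  a <- stats::plogis(delta) # exp(Ay) / (exp(Ay) + exp(By)), shifted
  structure(list(a = a, b = 1 - a), class = "attention_weights")
}

#' Fuse two branch feature maps
#'
#' Runs the full fusion pipeline on one pair of feature maps (inference
#' mode) and returns the fused map with all intermediates for inspection.
#'
#' @param v_eeg,v_eye Numeric arrays `(H, W, C)` of identical shape.
#' @param params A [init_fusion_params()] object with matching `C`.
#' @param weights Optional `attention_weights` to force (bypassing the
#'   descriptor/attention computation), e.g. for ablation.
#' @return A `fused_feature`: list with `values` (`(H, W, C)` array),
#'   `weights`, `descriptor` (`x`, length `C`) and `compact` (`y`,
#'   length `d`).
#' @export
fuse_features <- function(v_eeg, v_eye, params, weights = NULL) {
  de <- dim(v_eeg); dy <- dim(v_eye)
  if (!identical(de, dy))
    stop("feature map shapes differ: (", paste(de, collapse = "x"),
         ") vs (", paste(dy, collapse = "x"), ")")
  if (de[3] != params$C)
    stop(sprintf("feature maps have %d channels but params expect %d",
                 de[3], params$C))
  x <- global_avg_pool(v_eeg + v_eye)
  y <- compact_descriptor(x, params)
  w <- weights %||% channel_attention(y, params)
  aw <- array(rep(w$a, each = de[1] * de[2]), de)
  fused <- aw * v_eeg + (1 - aw) * v_eye
  structure(list(values = fused, weights = w, descriptor = x, compact = y),
            class = "fused_feature")
}

# ---- batch forward/backward used during training -------------------------

# ve, vy: nn_tensors with C channels; returns fused tensor + cache
fusion_fwd <- function(fp, ve, vy, training = FALSE) {
  hw <- ve$H * ve$W
  n <- ve$N
  vsum <- ve$mat + vy$mat
  grp <- rep(seq_len(n), each = hw)
  x <- rowsum(vsum, grp, reorder = TRUE) / hw # N x C
  z <- x %*% t(fp$par$proj)                   # N x d
  b <- bn_fwd(z, fp$par$bn, fp$st, training)
  y <- b$out * (b$out > 0)
  delta <- (y %*% t(fp$par$attn_eeg - fp$par$attn_eye)) # N x C
  a <- stats::plogis(delta)
  a_exp <- a[grp, , drop = FALSE]
  fused <- a_exp * ve$mat + (1 - a_exp) * vy$mat
  list(out = nn_tensor(fused, ve$H, ve$W, n),
       cache = list(ve = ve, vy = vy, grp = grp, hw = hw, x = x,
                    bn = b$cache, y = y, a = a, a_exp = a_exp),
       st = b$st, x = x, y = y, a = a)
}

fusion_bwd <- function(fp, fwd, dmat) {
  cc <- fwd$cache
  dve <- dmat * cc$a_exp
  dvy <- dmat * (1 - cc$a_exp)
  da <- rowsum(dmat * (cc$ve$mat - cc$vy$mat), cc$grp, reorder = TRUE)
  ddelta <- da * cc$a * (1 - cc$a) # N x C
  dattn_e <- crossprod(ddelta, cc$y)
  dattn_y <- -dattn_e
  dy <- ddelta %*% (fp$par$attn_eeg - fp$par$attn_eye) # N x d
  dz_post <- dy * (cc$y > 0)
  bb <- bn_bwd(fp$par$bn, cc$bn, dz_post)
  dproj <- crossprod(bb$dx, cc$x)
  dx <- bb$dx %*% fp$par$proj # N x C
  dsum <- dx[cc$grp, , drop = FALSE] / cc$hw
  list(dpar = list(proj = dproj, bn = bb$dpar,
                   attn_eeg = dattn_e, attn_eye = dattn_y),
       dve = dve + dsum, dvy = dvy + dsum)
}

#' @export
print.attention_weights <- function(x, ...) {
  cat("Cross-channel attention over", length(x$a), "channels: mean EEG",
      sprintf("weight %.3f (range %.3f-%.3f)\n", mean(x$a), min(x$a),
              max(x$a)))
  invisible(x)
}
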