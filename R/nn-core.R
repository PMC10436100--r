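# Minimal neural-network core used by the dual-branch extractor and the
# fusion/classifier head. A batch "tensor" is a list(mat, H, W, N): `mat`
# is an (H*W*N) x C matrix whose rows are ordered h fastest, then w, then
# sample n; channels are columns. Convolutions along an axis are computed
# as sums of row-shifted copies times per-tap weight matrices, so the heavy
# lifting is plain BLAS matrix products. Each layer has an explicit
# forward (returning a cache) and backward (returning parameter and input
# gradients); nothing is autodifferentiated.

nn_tensor <- function(mat, H, W, N) list(mat = mat, H = H, W = W, N = N)

# rows of `mat` shifted by `off` along the given axis, zero-filled at the
# borders ("same" padding)
axis_shift <- function(mat, H, W, N, axis, off) {
  if (off == 0L) return(mat)
  out <- matrix(0, nrow(mat), ncol(mat))
  if (axis == "H") {
    src <- seq_len(H) + off
    ok <- src >= 1L & src <= H
    if (!any(ok)) return(out)
    dst_h <- which(ok)
    blk <- rep((0:(W * N - 1L)) * H, each = length(dst_h))
    out[dst_h + blk, ] <- mat[src[ok] + blk, ]
  } else {
    src <- seq_len(W) + off
    ok <- src >= 1L & src <= W
    if (!any(ok)) return(out)
    dst_w <- which(ok)
    hh <- seq_len(H)
    dst <- rep(hh, times = length(dst_w) * N) +
      rep((rep(dst_w, each = H) - 1L) * H, times = N) +
      rep((0:(N - 1L)) * H * W, each = H * length(dst_w))
    srcr <- rep(hh, times = length(dst_w) * N) +
      rep((rep(src[ok], each = H) - 1L) * H, times = N) +
      rep((0:(N - 1L)) * H * W, each = H * length(dst_w))
    out[dst, ] <- mat[srcr, ]
  }
  out
}

conv_offsets <- function(k) seq_len(k) - (k + 1L) %/% 2L

# conv params: list(w = list of K matrices Cin x Cout, b = length Cout)
conv_init <- function(k, c_in, c_out) {
  sdv <- sqrt(2 / (k * c_in))
  list(w = lapply(seq_len(k), function(i)
    matrix(stats::rnorm(c_in * c_out, sd = sdv), c_in, c_out)),
    b = numeric(c_out))
}

# Convolution along one axis, optionally with the ReLU fused into the
# kernel epilogue (the cache then holds the rectified output for the
# backward mask).
conv_fwd <- function(x, par, axis, relu = FALSE) {
  y <- cpp_conv_fwd(x$mat, x$H, x$W, x$N, par$w, par$b, axis == "H", relu)
  list(out = nn_tensor(y, x$H, x$W, x$N),
       cache = list(x = x, axis = axis, yout = if (relu) y))
}

conv_bwd <- function(par, cache, dy) {
  x <- cache$x
  g <- cpp_conv_bwd(x$mat, dy, x$H, x$W, x$N, par$w, cache$axis == "H",
                    cache$yout)
  list(dpar = list(w = g$w, b = drop(g$b)),
       dx = nn_tensor(g$dx, x$H, x$W, x$N))
}

# plain-R reference implementations of the convolution, kept as the
# independent oracle the compiled kernels are tested against
conv_fwd_ref <- function(x, par, axis) {
  off <- conv_offsets(length(par$w))
  y <- matrix(par$b, nrow(x$mat), length(par$b), byrow = TRUE)
  for (i in seq_along(off))
    y <- y + axis_shift(x$mat, x$H, x$W, x$N, axis, off[i]) %*% par$w[[i]]
  nn_tensor(y, x$H, x$W, x$N)
}

conv_bwd_ref <- function(par, cache, dy) {
  x <- cache$x
  off <- conv_offsets(length(par$w))
  dw <- vector("list", length(off))
  dx <- matrix(0, nrow(x$mat), ncol(x$mat))
  for (i in seq_along(off)) {
    xs <- axis_shift(x$mat, x$H, x$W, x$N, cache$axis, off[i])
    dw[[i]] <- crossprod(xs, dy)
    dx <- dx + axis_shift(dy, x$H, x$W, x$N, cache$axis, -off[i]) %*% t(par$w[[i]])
  }
  list(dpar = list(w = dw, b = colSums(dy)),
       dx = nn_tensor(dx, x$H, x$W, x$N))
}

relu_fwd <- function(x) {
  y <- x$mat * (x$mat > 0)
  list(out = nn_tensor(y, x$H, x$W, x$N), cache = y > 0)
}

relu_bwd <- function(cache, dy) dy * cache

# batch normalization per channel (column), statistics over all rows
# (sample x space). par: gamma, beta; st: mean, var (running, inference).
bn_init <- function(c) list(par = list(gamma = rep(1, c), beta = numeric(c)),
                            st = list(mean = numeric(c), var = rep(1, c)))

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# column-broadcast helpers: sweep() materialises its STATS argument with
# aperm(), which dominates runtime on the (H*W*N) x C activations, so
# broadcasting is done with an explicit recycled vector instead
col_bcast <- function(v, m) rep(v, each = m)

bn_fwd <- function(mat, par, st, training) {
  m <- nrow(mat)
  f <- cpp_bn_fwd(mat, par$gamma, par$beta, st$mean, st$var, training, BN_EPS)
  if (training) {
    st$mean <- (1 - BN_MOMENTUM) * st$mean + BN_MOMENTUM * drop(f$mu)
    st$var <- (1 - BN_MOMENTUM) * st$var +
      BN_MOMENTUM * drop(f$var) * ifelse(m > 1, m / (m - 1), 1)
  }
  list(out = f$y, cache = list(x = mat, mu = drop(f$mu), inv = drop(f$inv)),
       st = st)
}

bn_bwd <- function(par, cache, dy) {
  g <- cpp_bn_bwd(cache$x, dy, par$gamma, cache$mu, cache$inv)
  list(dpar = list(gamma = drop(g$dgamma), beta = drop(g$dbeta)), dx = g$dx)
}

# plain-R batch norm, the oracle the compiled kernel is tested against
bn_fwd_ref <- function(mat, par, st, training) {
  m <- nrow(mat)
  if (training) {
    mu <- colMeans(mat)
    va <- colMeans((mat - col_bcast(mu, m))^2)
  } else {
    mu <- st$mean
    va <- st$var
  }
  inv <- 1 / sqrt(va + BN_EPS)
  xh <- (mat - col_bcast(mu, m)) * col_bcast(inv, m)
  xh * col_bcast(par$gamma, m) + col_bcast(par$beta, m)
}

# max pooling of size 2 (stride 2) along H; H must be even
maxpool2_fwd <- function(x) {
  stopifnot(x$H %% 2L == 0L)
  p <- cpp_maxpool2_fwd(x$mat, x$H, x$W, x$N)
  list(out = nn_tensor(p$out, x$H %/% 2L, x$W, x$N),
       cache = list(take_a = p$take_a, H = x$H, W = x$W, N = x$N))
}

maxpool2_bwd <- function(cache, dy) {
  cpp_maxpool2_bwd(dy, cache$take_a, cache$H, cache$W, cache$N)
}

# adaptive average pooling to (Ho, Wo): partition bins of near-equal size
adapt_bins <- function(n, out) {
  lo <- floor((0:(out - 1)) * n / out) + 1L
  hi <- floor((1:out) * n / out)
  rep.int(seq_len(out), hi - lo + 1L)
}

adapt_avg_fwd <- function(x, ho, wo) {
  bh <- adapt_bins(x$H, ho)
  bw <- adapt_bins(x$W, wo)
  grp <- rep(bh, times = x$W * x$N) +
    ho * (rep(rep(bw, each = x$H), times = x$N) - 1L) +
    ho * wo * rep(0:(x$N - 1L), each = x$H * x$W)
  cnt <- tabulate(grp, nbins = ho * wo * x$N)
  y <- rowsum(x$mat, grp, reorder = TRUE) / cnt
  list(out = nn_tensor(y, ho, wo, x$N),
       cache = list(grp = grp, cnt = cnt, H = x$H, W = x$W))
}

adapt_avg_bwd <- function(cache, dy) {
  (dy / cache$cnt)[cache$grp, , drop = FALSE]
}

dense_init <- function(n_in, n_out) {
  list(w = matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out),
       b = numeric(n_out))
}

dense_fwd <- function(x, par) {
  list(out = x %*% par$w + col_bcast(par$b, nrow(x)), cache = x)
}

dense_bwd <- function(par, cache, dy) {
  list(dpar = list(w = crossprod(cache, dy), b = colSums(dy)),
       dx = tcrossprod(dy, par$w))
}

dropout_fwd <- function(x, p, training) {
  if (!training || p <= 0) return(list(out = x, cache = NULL))
  mask <- (matrix(stats::runif(length(x)), nrow(x)) >= p) / (1 - p)
  list(out = x * mask, cache = mask)
}

dropout_bwd <- function(cache, dy) if (is.null(cache)) dy else dy * cache

# softmax with cross-entropy; labels are 1-based integers
softmax_probs <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

softmax_ce_fwd <- function(logits, labels1) {
  p <- softmax_probs(logits)
  pc <- pmax(p[cbind(seq_len(nrow(p)), labels1)], 1e-12)
  list(loss = -mean(log(pc)), probs = p)
}

softmax_ce_bwd <- function(probs, labels1) {
  g <- probs
  g[cbind(seq_len(nrow(g)), labels1)] <- g[cbind(seq_len(nrow(g)), labels1)] - 1
  g / nrow(g)
}

# ---- recursive parameter utilities (Adam) --------------------------------

map2_rec <- function(a, b, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- map2_rec(a[[i]], b[[i]], f)
    out
  } else f(a, b)
}

zeros_like <- function(p) {
  if (is.list(p)) lapply(p, zeros_like) else p * 0
}

adam_init <- function(params) list(m = zeros_like(params),
                                   v = zeros_like(params), t = 0L)

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- map2_rec(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- map2_rec(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  params <- map2_rec(params, map2_rec(state$m, state$v, function(m, v)
    (m / bc1) / (sqrt(v / bc2) + eps)), function(p, u) p - lr * u)
  list(params = params, state = state)
}

sum_grads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  map2_rec(a, b, `+`)
}
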