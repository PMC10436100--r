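test_that("descriptor bottleneck dimension follows max(ceil(C/r), L)", {
  # spot checks on the defining cases
  expect_equal(reduced_dim(64, 2, 32), 32)
  expect_equal(reduced_dim(256, 2, 32), 128)
  expect_equal(reduced_dim(16, 4, 32), 32)
  expect_equal(reduced_dim(65, 2, 16), 33) # ceiling, not floor
})

test_that("global average pooling reduces each channel to its spatial mean", {
  v <- array(3, c(4, 2, 5))
  expect_equal(global_avg_pool(v), rep(3, 5))
  v2 <- array(0, c(2, 2, 1))
  v2[, , 1] <- matrix(c(1, 3, 2, 4), 2, 2)
  expect_equal(global_avg_pool(v2), 2.5)
  expect_equal(global_avg_pool(array(0, c(3, 3, 2))), c(0, 0))
})

test_that("compact descriptor is ReLU(norm(Wx)) and validates dimensions", {
  fp <- init_fusion_params(C = 8, r = 2, L = 4, seed = 2)
  expect_equal(compact_descriptor(numeric(8), fp), numeric(fp$d))
  # independent dense + ReLU oracle (inference-mode norm on unit stats)
  set.seed(4)
  x <- rnorm(8)
  manual <- pmax(drop(fp$par$proj %*% x) / sqrt(1 + 1e-5), 0)
  expect_equal(compact_descriptor(x, fp), manual, tolerance = 1e-12)
  expect_true(all(compact_descriptor(x, fp) >= 0))
  expect_error(compact_descriptor(numeric(5), fp), "does not match C")
})

test_that("channel attention is a two-way softmax with convex weights", {
  fp <- init_fusion_params(C = 6, r = 2, L = 3, seed = 5)
  # equal attention matrices give exactly half/half
  fp$par$attn_eye <- fp$par$attn_eeg
  w <- channel_attention(rnorm(fp$d), fp)
  expect_equal(w$a, rep(0.5, 6))
  expect_equal(w$b, rep(0.5, 6))
  # a logit difference of ln 3 gives weight 3/4 (closed form)
  fp2 <- init_fusion_params(C = 1, r = 1, L = 2, seed = 5)
  fp2$par$attn_eeg <- matrix(c(log(3), 0), 1, 2)
  fp2$par$attn_eye <- matrix(0, 1, 2)
  expect_equal(channel_attention(c(1, 0), fp2)$a, 0.75, tolerance = 1e-12)
  expect_error(channel_attention(numeric(99), fp), "does not match d")
})

test_that("attention weights always sum to one across many random draws", {
  fp <- init_fusion_params(C = 64, r = 2, L = 32, seed = 9)
  set.seed(10)
  worst <- 0
  for (i in 1:200) {
    w <- channel_attention(rnorm(fp$d, sd = 5), fp)
    worst <- max(worst, abs(w$a + w$b - 1))
    expect_true(all(w$a >= 0 & w$a <= 1))
  }
  expect_lt(worst, 1e-6)
})

test_that("attention is monotone in the modality logit", {
  fp <- init_fusion_params(C = 4, r = 2, L = 2, seed = 1)
  y <- abs(rnorm(fp$d)) + 0.5
  a1 <- channel_attention(y, fp)$a
  fp$par$attn_eeg[2, ] <- fp$par$attn_eeg[2, ] + 1 # raise channel-2 EEG logit
  a2 <- channel_attention(y, fp)$a
  expect_gt(a2[2], a1[2])
  expect_equal(a2[-2], a1[-2])
})

test_that("fusion matches a fully unrolled scalar oracle on a toy tensor", {
  fp <- init_fusion_params(C = 2, r = 1, L = 2, seed = 6)
  set.seed(7)
  ve <- array(rnorm(8), c(2, 2, 2))
  vy <- array(rnorm(8), c(2, 2, 2))
  fu <- fuse_features(ve, vy, fp)
  # oracle: every step in scalar arithmetic
  x <- c(mean(ve[, , 1] + vy[, , 1]), mean(ve[, , 2] + vy[, , 2]))
  z <- as.numeric(fp$par$proj %*% x) / sqrt(1 + 1e-5)
  y <- pmax(z, 0)
  la <- as.numeric(fp$par$attn_eeg %*% y)
  lb <- as.numeric(fp$par$attn_eye %*% y)
  a <- exp(la) / (exp(la) + exp(lb))
  manual <- array(0, c(2, 2, 2))
  for (c_ in 1:2) manual[, , c_] <- a[c_] * ve[, , c_] + (1 - a[c_]) * vy[, , c_]
  expect_equal(fu$descriptor, x, tolerance = 1e-12)
  expect_equal(fu$compact, y, tolerance = 1e-10)
  expect_equal(fu$weights$a, a, tolerance = 1e-10)
  expect_equal(fu$values, manual, tolerance = 1e-10)
})

test_that("degenerate weights recover a single branch; equal inputs are fixed points", {
  fp <- init_fusion_params(C = 3, r = 1, L = 3, seed = 8)
  set.seed(9)
  ve <- array(rnorm(3 * 4 * 2), c(4, 2, 3))
  vy <- array(rnorm(3 * 4 * 2), c(4, 2, 3))
  forced <- structure(list(a = rep(1, 3), b = rep(0, 3)),
                      class = "attention_weights")
  expect_identical(fuse_features(ve, vy, fp, weights = forced)$values, ve)
  expect_equal(fuse_features(ve, ve, fp)$values, ve, tolerance = 1e-12)
})

test_that("fused values are convex combinations (elementwise boundedness)", {
  fp <- init_fusion_params(C = 16, r = 2, L = 8, seed = 12)
  set.seed(13)
  for (i in 1:5) {
    ve <- array(rnorm(16 * 5 * 2), c(5, 2, 16))
    vy <- array(rnorm(16 * 5 * 2), c(5, 2, 16))
    f <- fuse_features(ve, vy, fp)$values
    expect_true(all(f >= pmin(ve, vy) - 1e-12 & f <= pmax(ve, vy) + 1e-12))
  }
})

test_that("fusion is equivariant under channel permutation", {
  fp <- init_fusion_params(C = 6, r = 2, L = 3, seed = 3)
  set.seed(14)
  ve <- array(rnorm(6 * 4), c(2, 2, 6))
  vy <- array(rnorm(6 * 4), c(2, 2, 6))
  perm <- c(3, 1, 6, 2, 5, 4)
  fp_p <- fp
  fp_p$par$proj <- fp$par$proj[, perm]
  fp_p$par$attn_eeg <- fp$par$attn_eeg[perm, ]
  fp_p$par$attn_eye <- fp$par$attn_eye[perm, ]
  f1 <- fuse_features(ve, vy, fp)$values
  f2 <- fuse_features(ve[, , perm], vy[, , perm], fp_p)$values
  expect_equal(f2, f1[, , perm], tolerance = 1e-12)
})

test_that("shape mismatches raise errors naming the shapes", {
  fp <- init_fusion_params(C = 4, r = 2, L = 2, seed = 1)
  expect_error(fuse_features(array(0, c(2, 2, 4)), array(0, c(2, 3, 4)), fp),
               "2x2x4.*2x3x4")
  expect_error(fuse_features(array(0, c(2, 2, 5)), array(0, c(2, 2, 5)), fp),
               "expect 4")
})

test_that("every fusion parameter tensor receives gradient on a random batch", {
  parts <- tiny_net_parts()
  tc <- train_config(epochs = 1, batch_size = 8, dropout = 0,
                     hidden_units = 5, seed = 9)
  net <- emofuse:::build_net("fused", parts$eeg, parts$eye, 2, 4, tc, 9L)
  ws <- tiny_ws()
  tens <- emofuse:::batch_tensors(ws, 1:8)
  fw <- emofuse:::net_fwd(net, tens, training = TRUE, dropout = 0)
  sc <- emofuse:::softmax_ce_fwd(fw$logits, ws$labels + 1L)
  g <- emofuse:::net_bwd(net, fw$cache,
                         emofuse:::softmax_ce_bwd(sc$probs, ws$labels + 1L))
  for (nm in names(g$fusion)) {
    norms <- vapply(unlist(g$fusion[nm], recursive = TRUE), abs, numeric(1))
    expect_gt(sum(norms), 0)
  }
})
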