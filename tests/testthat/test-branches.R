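test_that("compiled convolution kernels agree with the plain-R reference", {
  set.seed(3)
  for (axis in c("H", "W")) {
    for (K in c(3, 5)) {
      for (chans in list(c(1, 8), c(6, 5), c(16, 16))) {
        x <- emofuse:::nn_tensor(matrix(rnorm(12 * 7 * 4 * chans[1]),
                                        12 * 7 * 4, chans[1]), 12L, 7L, 4L)
        par <- emofuse:::conv_init(K, chans[1], chans[2])
        f <- emofuse:::conv_fwd(x, par, axis, relu = TRUE)
        yref <- emofuse:::conv_fwd_ref(x, par, axis)
        expect_lt(max(abs(f$out$mat - pmax(yref$mat, 0))), 1e-12)
        dy <- matrix(rnorm(length(yref$mat)), nrow(yref$mat))
        b1 <- emofuse:::conv_bwd(par, f$cache, dy)
        b2 <- emofuse:::conv_bwd_ref(par, list(x = x, axis = axis),
                                     dy * (yref$mat > 0))
        expect_lt(max(abs(b1$dx$mat - b2$dx$mat)), 1e-11)
        expect_lt(max(abs(unlist(b1$dpar$w) - unlist(b2$dpar$w))), 1e-11)
        expect_lt(max(abs(b1$dpar$b - b2$dpar$b)), 1e-11)
      }
    }
  }
})

test_that("a single-tap convolution reproduces a hand-computed cross-correlation", {
  # 6 x 5 toy input, one channel, 3-tap temporal kernel, direct oracle
  set.seed(8)
  x <- matrix(rnorm(30), 6, 5)
  w <- rnorm(3)
  par <- list(w = lapply(w, function(v) matrix(v, 1, 1)), b = 0.3)
  tensor <- emofuse:::nn_tensor(matrix(as.vector(x), ncol = 1), 6L, 5L, 1L)
  out <- emofuse:::conv_fwd(tensor, par, "H")$out$mat
  manual <- matrix(0, 6, 5)
  xp <- rbind(0, x, 0) # zero padding
  for (h in 1:6) for (col in 1:5)
    manual[h, col] <- 0.3 + sum(w * xp[h:(h + 2), col])
  expect_equal(matrix(out, 6, 5), manual, tolerance = 1e-12)
})

test_that("batch-norm kernel matches the reference in both modes", {
  set.seed(5)
  m <- matrix(rnorm(500 * 7), 500, 7)
  bn <- emofuse:::bn_init(7)
  bn$par$gamma <- runif(7, 0.5, 2)
  bn$par$beta <- rnorm(7)
  f <- emofuse:::bn_fwd(m, bn$par, bn$st, training = TRUE)
  expect_lt(max(abs(f$out - emofuse:::bn_fwd_ref(m, bn$par, bn$st, TRUE))),
            1e-12)
  st <- list(mean = rnorm(7), var = runif(7, 0.5, 2))
  f2 <- emofuse:::bn_fwd(m, bn$par, st, training = FALSE)
  expect_lt(max(abs(f2$out - emofuse:::bn_fwd_ref(m, bn$par, st, FALSE))),
            1e-12)
})

test_that("branch outputs have the contracted common shape for any input", {
  bp <- init_branch_params(branch_config("eeg"), seed = 3)
  be <- init_branch_params(branch_config("eye"), seed = 3)
  for (seed in 1:2) {
    set.seed(seed)
    fm <- eeg_branch_forward(matrix(rnorm(240 * 62), 240, 62), bp)
    fe <- eye_branch_forward(matrix(rnorm(240 * 4), 240, 4), be)
    expect_equal(dim(fm), c(15, 1, 64))
    expect_equal(dim(fe), c(15, 1, 64))
    expect_true(all(is.finite(fm)) && all(is.finite(fe)))
  }
  expect_identical(attr(fm, "provenance"), "eeg")
})

test_that("all-zero input with zero biases maps to an all-zero feature map", {
  bp <- init_branch_params(branch_config("eeg"), seed = 3)
  expect_equal(max(abs(eeg_branch_forward(matrix(0, 240, 62), bp))), 0)
  be <- init_branch_params(branch_config("eye"), seed = 3)
  expect_equal(max(abs(eye_branch_forward(matrix(0, 240, 4), be))), 0)
})

test_that("branch forward is deterministic and initialization is seed-controlled", {
  cfg <- branch_config("eeg", channel_widths = test_widths)
  p1 <- init_branch_params(cfg, seed = 7)
  p2 <- init_branch_params(cfg, seed = 7)
  p3 <- init_branch_params(cfg, seed = 8)
  expect_identical(p1, p2)
  expect_false(identical(p1$par, p3$par))
  set.seed(1)
  x <- matrix(rnorm(240 * 62), 240, 62)
  expect_identical(eeg_branch_forward(x, p1), eeg_branch_forward(x, p1))
})

test_that("parameter count matches the closed-form architecture count", {
  cfg <- branch_config("eeg") # widths 16 32 64 64, kernels 3 and 5
  bp <- init_branch_params(cfg, seed = 1)
  widths <- c(1, cfg$channel_widths)
  expected <- 0
  for (i in 1:4) {
    cin <- widths[i]; cout <- widths[i + 1]
    expected <- expected +
      (3 * cin * cout + cout) +   # temporal conv + bias
      (5 * cout * cout + cout) +  # spatial conv + bias
      2 * cout                    # batch-norm gamma, beta
  }
  expect_equal(emofuse:::branch_n_params(bp), expected)
})

test_that("wrong input shapes produce informative errors", {
  bp <- init_branch_params(branch_config("eeg"), seed = 1)
  expect_error(eeg_branch_forward(matrix(0, 100, 62), bp), "100 x 62")
  be <- init_branch_params(branch_config("eye"), seed = 1)
  expect_error(eye_branch_forward(matrix(0, 240, 5), be), "240 x 5")
  expect_error(eeg_branch_forward(matrix(0, 240, 62), be), "not an EEG")
})

test_that("branch parameters round-trip through the versioned archive", {
  cfg <- branch_config("eye", channel_widths = test_widths)
  bp <- init_branch_params(cfg, seed = 4)
  f <- withr::local_tempfile(fileext = ".rds")
  write_branch_params(bp, f)
  bp2 <- read_branch_params(f)
  expect_equal(bp2$par, bp$par)
  expect_equal(bp2$st, bp$st)
  expect_equal(unclass(bp2$cfg), unclass(bp$cfg), ignore_attr = TRUE)
  set.seed(2)
  x <- matrix(rnorm(240 * 4), 240, 4)
  expect_equal(eye_branch_forward(x, bp2), eye_branch_forward(x, bp))
  saveRDS(list(format = "other"), f)
  expect_error(read_branch_params(f), "archive")
})
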