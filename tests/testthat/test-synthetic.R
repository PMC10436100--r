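test_that("generator produces the configured number and shape of trials", {
  cfg <- synthetic_config(n_subjects = 2, n_sessions = 1,
                          trials_per_session = 8, trial_seconds = 4,
                          sample_rate_hz = 200, seed = 7)
  ts <- generate_trialset(cfg)
  expect_length(ts$trials, 2 * 1 * 8)
  expect_equal(dim(ts$trials[[1]]$eeg), c(4 * 200, 62))
  expect_equal(dim(ts$trials[[1]]$eye), c(4 * 200, 4))
  expect_true(all(vapply(ts$trials, `[[`, integer(1), "label") %in% 0:3))
  # balanced classes within the session
  expect_equal(unname(table(vapply(ts$trials, `[[`, integer(1), "label"))),
               rep(4L, 4), ignore_attr = TRUE)
})

test_that("generation is bit-reproducible for a fixed seed", {
  cfg <- synthetic_config(n_subjects = 2, n_sessions = 1,
                          trials_per_session = 4, trial_seconds = 2, seed = 3)
  expect_identical(generate_trialset(cfg), generate_trialset(cfg))
})

test_that("same trial index means same label and same illumination for every subject", {
  ts <- small_trialset()
  key <- vapply(ts$trials, function(tr) paste(tr$session_id, tr$trial_id),
                character(1))
  labs <- vapply(ts$trials, `[[`, integer(1), "label")
  for (k in unique(key))
    expect_length(unique(labs[key == k]), 1)
})

test_that("invalid configurations are rejected with informative errors", {
  expect_error(synthetic_config(n_subjects = 0), "n_subjects")
  expect_error(synthetic_config(n_classes = 3), "fixed at 4")
  expect_error(synthetic_config(trials_per_session = 6), "divisible by 4")
  expect_error(synthetic_config(trial_seconds = 1.003), "integer")
  expect_error(generate_trialset(list()), "synthetic_config")
})

test_that("illumination reference reproduces the injected waveform exactly", {
  base <- list(n_subjects = 2, n_sessions = 1, trials_per_session = 4,
               trial_seconds = 5, seed = 17)
  ts1 <- generate_trialset(do.call(synthetic_config,
                                   c(base, illumination_amplitude = 1.5)))
  ts0 <- generate_trialset(do.call(synthetic_config,
                                   c(base, illumination_amplitude = 0)))
  ref <- shared_illumination_reference(ts1)
  # the only difference between the two sets is the injected waveform
  for (i in c(1, 4, 6)) {
    d <- ts1$trials[[i]]$eye[, 1] - ts0$trials[[i]]$eye[, 1]
    expect_lt(max(abs(d - ref[, ts1$trials[[i]]$trial_id])), 1e-10)
  }
  expect_true(all(shared_illumination_reference(ts0) == 0))
  expect_error(shared_illumination_reference(structure(list(), class = "trialset")),
               "provenance")
})

test_that("dominant illumination shows up as the shared component across subjects", {
  cfg <- synthetic_config(n_subjects = 6, n_sessions = 1,
                          trials_per_session = 4, trial_seconds = 10,
                          illumination_amplitude = 5, seed = 3)
  ts <- generate_trialset(cfg)
  ref <- shared_illumination_reference(ts)
  for (j in 1:2) {
    panel <- vapply(Filter(function(t) t$trial_id == j, ts$trials),
                    function(t) t$eye[, 1], numeric(cfg$n_time))
    expect_gt(cor(rowMeans(panel), ref[, j]), 0.9)
  }
})

test_that("zero effect sizes leave class-conditional channel means indistinguishable", {
  cfg <- synthetic_config(n_subjects = 13, n_sessions = 1,
                          trials_per_session = 16, trial_seconds = 2,
                          eeg_effect = 0, eye_effect = 0,
                          illumination_amplitude = 0, seed = 29)
  ts <- generate_trialset(cfg) # 52 trials per class
  labs <- vapply(ts$trials, `[[`, integer(1), "label")
  # per-trial band powers of the features a classifier could exploit
  # (per-channel variance is fixed by construction, so band content is the
  # discriminative statistic); expect only the nominal false-positive rate
  band_power <- function(x, fs, lo, hi) {
    sp <- abs(stats::fft(x - mean(x)))^2
    f <- (seq_along(x) - 1) * fs / length(x)
    mean(sp[f >= lo & f <= hi])
  }
  feats <- t(vapply(ts$trials, function(tr) c(
    band_power(tr$eeg[, 3], 200, 8, 12),
    band_power(tr$eeg[, 12], 200, 18, 22),
    band_power(tr$eye[, 1], 200, 0.4, 1.2),
    band_power(tr$eye[, 3], 200, 0.2, 0.8),
    mean(tr$eye[, 2])), numeric(5)))
  pvals <- c()
  for (pair in list(c(0, 1), c(2, 3), c(0, 2))) {
    for (ch in seq_len(ncol(feats)))
      pvals <- c(pvals, stats::t.test(feats[labs == pair[1], ch],
                                      feats[labs == pair[2], ch])$p.value)
  }
  expect_lt(mean(pvals < 0.01), 0.15) # 15 tests at alpha = 0.01
})
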