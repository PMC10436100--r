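test_that("analytic gradients match finite differences through the whole network", {
  parts <- tiny_net_parts()
  tc <- train_config(epochs = 1, batch_size = 8, dropout = 0,
                     hidden_units = 5, seed = 9)
  ws <- tiny_ws()
  tens <- emofuse:::batch_tensors(ws, 1:8)
  labs1 <- ws$labels + 1L
  for (mode in c("fused", "eeg_only", "eye_only")) {
    net <- emofuse:::build_net(mode, parts$eeg, parts$eye, 2, 4, tc, 9L)
    fw <- emofuse:::net_fwd(net, tens, training = TRUE, dropout = 0)
    sc <- emofuse:::softmax_ce_fwd(fw$logits, labs1)
    g <- emofuse:::net_bwd(net, fw$cache,
                           emofuse:::softmax_ce_bwd(sc$probs, labs1))
    params <- emofuse:::net_trainable(net)
    lossfn <- function(p) {
      n2 <- emofuse:::net_set_trainable(net, p)
      f <- emofuse:::net_fwd(n2, tens, training = TRUE, dropout = 0)
      emofuse:::softmax_ce_fwd(f$logits, labs1)$loss
    }
    # probe a few entries of every leaf tensor against central differences
    paths <- list()
    collect <- function(p, pref) {
      if (is.list(p)) for (i in seq_along(p)) collect(p[[i]], c(pref, i))
      else paths[[length(paths) + 1]] <<- pref
    }
    collect(params, integer(0))
    worst <- 0
    for (pa in paths) {
      leaf <- params; gleaf <- g
      for (i in pa) { leaf <- leaf[[i]]; gleaf <- gleaf[[i]] }
      for (k in unique(c(1L, length(leaf)))) {
        h <- 1e-5
        perturb <- function(d) {
          p2 <- params
          leaf2 <- leaf
          leaf2[k] <- leaf2[k] + d
          p2[[pa]] <- leaf2
          p2
        }
        fd <- (lossfn(perturb(h)) - lossfn(perturb(-h))) / (2 * h)
        worst <- max(worst, abs(fd - gleaf[k]) /
                       max(1e-6, abs(fd) + abs(gleaf[k])))
      }
    }
    expect_lt(worst, 1e-5)
  }
})

test_that("training reduces the loss and the fit is seed-deterministic", {
  ws <- small_ws()
  parts <- test_branches()
  tc <- train_config(epochs = 6, batch_size = 64, seed = 5)
  f1 <- emofuse(ws, "fused", branch_eeg = parts$eeg, branch_eye = parts$eye,
                train = tc)
  expect_length(f1$loss_history, 6)
  expect_lt(f1$loss_history[6], f1$loss_history[1])
  f2 <- emofuse(ws, "fused", branch_eeg = parts$eeg, branch_eye = parts$eye,
                train = tc)
  expect_identical(f1$loss_history, f2$loss_history)
  expect_identical(predict(f1, ws), predict(f2, ws))
  probs <- predict(f1, ws, type = "prob")
  expect_equal(rowSums(probs), rep(1, nrow(probs)), tolerance = 1e-9)
})

test_that("strongly separable synthetic classes are learned well above chance", {
  ws <- small_ws()
  parts <- test_branches()
  tc <- train_config(epochs = 30, batch_size = 64, seed = 5)
  cv <- evaluate_emofuse(ws, "fused", train = tc, max_folds = 1,
                         branch_eeg = parts$eeg, branch_eye = parts$eye)
  expect_gt(cv$reports[[1]]$accuracy, 0.5) # chance is 0.25
})

test_that("with zero effect sizes held-out accuracy stays near chance", {
  cfg <- synthetic_config(n_subjects = 3, n_sessions = 1,
                          trials_per_session = 8, trial_seconds = 20,
                          eeg_effect = 0, eye_effect = 0, seed = 12)
  ws0 <- preprocess_trialset(generate_trialset(cfg))
  parts <- test_branches()
  tc <- train_config(epochs = 6, batch_size = 64, seed = 5)
  cv <- evaluate_emofuse(ws0, "fused", train = tc, max_folds = 1,
                         branch_eeg = parts$eeg, branch_eye = parts$eye)
  # 24 held-out windows; binomial(24, .25) stays below 0.55 with prob > 0.999
  expect_lt(cv$reports[[1]]$accuracy, 0.55)
})

test_that("a training set missing a class is rejected", {
  ws <- tiny_ws()
  keep <- ws$labels != 3
  sub <- emofuse:::ws_subset(ws, which(keep))
  expect_error(emofuse(sub, "fused"), "every class")
})

test_that("fit object methods print, summarise, plot and expose coefficients", {
  ws <- tiny_ws()
  parts <- tiny_net_parts()
  tc <- train_config(epochs = 2, batch_size = 8, hidden_units = 5, seed = 1)
  fit <- emofuse(ws, "eeg_only", branch_eeg = parts$eeg,
                 branch_eye = parts$eye, train = tc)
  expect_output(print(fit), "eeg_only")
  expect_output(summary(fit), "trainable parameters")
  cf <- coef(fit)
  expect_named(cf, c("head", "eeg"))
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
  expect_error(attention_weights(fit, ws), "only for fused")
})

test_that("paired ablation shares identical held-out folds across modes", {
  ws <- small_ws()
  parts <- test_branches()
  tc <- train_config(epochs = 2, batch_size = 64, seed = 7)
  res <- suppressWarnings( # 2-epoch fits may leave a class unpredicted
    ablation_run(ws, modes = c("eeg_only", "eye_only"), train = tc,
                 max_folds = 1, branch_eeg = parts$eeg,
                 branch_eye = parts$eye))
  expect_identical(res$eeg_only$folds, res$eye_only$folds)
  expect_error(ablation_run(ws, modes = "both"), "unknown mode")
})
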