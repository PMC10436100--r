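# Shared fixtures, all generated in code and cached for the test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixtures)) assign(key, expr, .fixtures)
  get(key, .fixtures)
}

# narrow branch pair used wherever the architecture itself is not under test
test_widths <- c(4, 8, 16, 16)
test_branches <- function() {
  list(eeg = branch_config("eeg", channel_widths = test_widths),
       eye = branch_config("eye", channel_widths = test_widths))
}

# small multimodal set with strong, learnable class structure
small_trialset <- function() {
  memo("small_ts", generate_trialset(
    synthetic_config(n_subjects = 3, n_sessions = 1, trials_per_session = 8,
                     trial_seconds = 20, eeg_effect = 2, eye_effect = 2,
                     seed = 11)))
}

small_ws <- function() memo("small_ws", preprocess_trialset(small_trialset()))

# random windowed set (no structure) for mechanical network tests
random_ws <- function(n = 16, rows = 240, seed = 1) {
  set.seed(seed)
  structure(list(
    eeg = array(stats::rnorm(n * rows * 62), c(n, rows, 62)),
    eye = array(stats::rnorm(n * rows * 4), c(n, rows, 4)),
    labels = rep(0:3, length.out = n),
    meta = data.frame(subject = 1, session = 1,
                      trial = rep(seq_len(ceiling(n / 4)), each = 4)[1:n],
                      window = 0),
    window_rows = rows, config = NULL), class = "windowed_set")
}

# tiny branch configs with non-standard input geometry for gradient checks
tiny_net_parts <- function(rows = 16, eeg_cols = 6) {
  bc_eeg <- branch_config("eeg", blocks = 2, channel_widths = c(3, 6),
                          output_grid = c(2, 1), pool_blocks = 1)
  bc_eeg$in_rows <- rows
  bc_eeg$in_cols <- eeg_cols
  bc_eye <- branch_config("eye", blocks = 2, channel_widths = c(3, 6),
                          output_grid = c(2, 1), pool_blocks = 1:2)
  bc_eye$in_rows <- rows
  list(eeg = bc_eeg, eye = bc_eye)
}

tiny_ws <- function(n = 8, rows = 16, eeg_cols = 6, seed = 42) {
  set.seed(seed)
  structure(list(
    eeg = array(stats::rnorm(n * rows * eeg_cols), c(n, rows, eeg_cols)),
    eye = array(stats::rnorm(n * rows * 4), c(n, rows, 4)),
    labels = rep(0:3, length.out = n),
    meta = data.frame(subject = 1, session = 1, trial = seq_len(n),
                      window = 0),
    window_rows = rows, config = NULL), class = "windowed_set")
}
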