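#' @keywords internal
#' @useDynLib emofuse, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

# Deterministic substream seeds: every stochastic stage draws from its own
# stream derived from one root seed, so generation order never matters and
# components can be regenerated in isolation (e.g. the shared illumination
# reference). Linear-congruential hash over the key bytes; exact in doubles
# (intermediates stay below 2^53) and the result stays below 2^31.
substream_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  m <- 2147483647 # 2^31 - 1
  h <- (abs(seed) %% m)
  for (b in utf8ToInt(as.character(key))) {
    h <- (h * 69069 + b) %% m
  }
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(structure(class = c("emofuse_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x))
    stop_config(name, " must be a positive integer count, got ", deparse(x))
  as.integer(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
    stop_config(name, " must be a nonnegative real, got ", deparse(x))
  as.numeric(x)
}

#' Emotion label codes
#'
#' Labels are carried as integer codes `0:3` throughout the package; this
#' helper gives the conventional name for each code.
#'
#' @return Named character vector mapping codes `"0".."3"` to
#'   `happy`, `sad`, `fear`, `neutral`.
#' @export
emotion_levels <- function() {
  c(`0` = "happy", `1` = "sad", `2` = "fear", `3` = "neutral")
}

# The convolutional stack issues many small-to-medium BLAS products; these
# gain nothing from BLAS threading, and an oversubscribed thread pool (more
# threads than schedulable cores) degrades them catastrophically. Pin the
# pool to one thread at load unless the user has chosen a setting.
.onLoad <- function(libname, pkgname) {
  pin <- Sys.getenv("OPENBLAS_NUM_THREADS") == ""
  for (v in c("OPENBLAS_NUM_THREADS", "OMP_NUM_THREADS")) {
    if (Sys.getenv(v) == "") do.call(Sys.setenv, stats::setNames(list("1"), v))
  }
  cpp_tune_runtime(pin)
}
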