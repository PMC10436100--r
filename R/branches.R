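# Dual-branch convolutional feature extractors.
#
# EEG branch: the 240 x 62 window is treated as a 2-D image (time x
# electrodes, one input channel). Each of the four blocks applies a 3-tap
# temporal convolution, ReLU, a 5-tap spatial convolution across
# electrodes, ReLU, batch normalization, and (blocks 1-3) a size-2
# temporal max-pool; a final adaptive average pool maps any geometry to a
# common (15, 1) grid.
#
# Eye branch: the four pupil/gaze series are input feature channels of a
# 1-D signal; each block applies a 5-tap temporal convolution, ReLU, batch
# normalization and a size-2 temporal max-pool (all four blocks), so the
# 240-sample window arrives at the same (15, 1) grid.
#
# Both branches emit feature maps of identical shape (H, W, C) so the
# fusion stage can sum and recombine them per channel.

#' Branch architecture configuration
#'
#' @param type `"eeg"` or `"eye"`.
#' @param blocks Number of convolutional blocks (default 4).
#' @param channel_widths Output channels per block; the last entry is the
#'   channel count `C` consumed by the fusion stage and must match between
#'   the two branches.
#' @param temporal_kernel Taps of the temporal (along-time) convolution.
#' @param spatial_kernel Taps of the spatial (across-electrode)
#'   convolution; for the eye branch this kernel runs along time since the
#'   four eye series are input feature channels, not a spatial axis.
#' @param output_grid Target `(H, W)` of the final adaptive average pool.
#' @param pool_blocks Indices of blocks followed by a size-2 temporal
#'   max-pool (EEG default 1:3; eye default all blocks).
#' @return An object of class `branch_config`.
#' @export
branch_config <- function(type = c("eeg", "eye"), blocks = 4,
                          channel_widths = c(16, 32, 64, 64),
                          temporal_kernel = 3, spatial_kernel = 5,
                          output_grid = c(15, 1),
                          pool_blocks = NULL) {
  type <- match.arg(type)
  blocks <- check_count(blocks, "blocks")
  if (length(channel_widths) != blocks)
    stop_config("channel_widths must have one entry per block")
  pool_blocks <- pool_blocks %||% (if (type == "eeg") seq_len(min(3, blocks))
                                   else seq_len(blocks))
  structure(list(type = type, blocks = blocks,
                 channel_widths = as.integer(channel_widths),
                 temporal_kernel = check_count(temporal_kernel, "temporal_kernel"),
                 spatial_kernel = check_count(spatial_kernel, "spatial_kernel"),
                 output_grid = as.integer(output_grid),
                 pool_blocks = as.integer(pool_blocks),
                 in_channels = if (type == "eeg") 1L else 4L,
                 in_rows = 240L,
                 in_cols = if (type == "eeg") 62L else 1L),
            class = "branch_config")
}

#' Initialize branch parameters
#'
#' He-normal weights for every convolution, zero biases, unit-gain batch
#' normalization; deterministic for a fixed seed.
#'
#' @param config A [branch_config()].
#' @param seed Integer seed.
#' @return A `branch_params` object: list with `cfg`, trainable `par` and
#'   batch-norm running statistics `st`.
#' @export
init_branch_params <- function(config, seed = 1L) {
  with_seed(substream_seed(seed, paste0("branch:", config$type)), {
    c_in <- config$in_channels
    par <- vector("list", config$blocks)
    st <- vector("list", config$blocks)
    for (i in seq_len(config$blocks)) {
      c_out <- config$channel_widths[i]
      if (config$type == "eeg") {
        par[[i]] <- list(tconv = conv_init(config$temporal_kernel, c_in, c_out),
                         sconv = conv_init(config$spatial_kernel, c_out, c_out))
      } else {
        par[[i]] <- list(tconv = conv_init(config$spatial_kernel, c_in, c_out))
      }
      bn <- bn_init(c_out)
      par[[i]]$bn <- bn$par
      st[[i]] <- bn$st
      c_in <- c_out
    }
    structure(list(cfg = config, par = par, st = st), class = "branch_params")
  })
}

branch_n_params <- function(bp) {
  count <- function(p) if (is.list(p)) sum(vapply(p, count, numeric(1)))
    else length(p)
  count(bp$par)
}

# batch forward; x is an nn_tensor with C = cfg$in_channels
branch_fwd <- function(bp, x, training = FALSE) {
  cfg <- bp$cfg
  caches <- vector("list", cfg$blocks)
  st <- bp$st
  for (i in seq_len(cfg$blocks)) {
    cc <- list()
    if (cfg$type == "eeg") {
      f <- conv_fwd(x, bp$par[[i]]$tconv, "H", relu = TRUE)
      cc$tconv <- f$cache; x <- f$out
      f <- conv_fwd(x, bp$par[[i]]$sconv, "W", relu = TRUE)
      cc$sconv <- f$cache; x <- f$out
    } else {
      f <- conv_fwd(x, bp$par[[i]]$tconv, "H", relu = TRUE)
      cc$tconv <- f$cache; x <- f$out
    }
    b <- bn_fwd(x$mat, bp$par[[i]]$bn, st[[i]], training)
    cc$bn <- b$cache; st[[i]] <- b$st
    x <- nn_tensor(b$out, x$H, x$W, x$N)
    if (i %in% cfg$pool_blocks) {
      p <- maxpool2_fwd(x); cc$pool <- p$cache; x <- p$out
    }
    caches[[i]] <- cc
  }
  a <- adapt_avg_fwd(x, cfg$output_grid[1], cfg$output_grid[2])
  list(out = a$out, caches = caches, final_pool = a$cache, st = st)
}

branch_bwd <- function(bp, fwd, dy) {
  cfg <- bp$cfg
  dmat <- adapt_avg_bwd(fwd$final_pool, dy$mat)
  dpar <- vector("list", cfg$blocks)
  for (i in rev(seq_len(cfg$blocks))) {
    cc <- fwd$caches[[i]]
    if (i %in% cfg$pool_blocks) dmat <- maxpool2_bwd(cc$pool, dmat)
    bb <- bn_bwd(bp$par[[i]]$bn, cc$bn, dmat)
    dmat <- bb$dx
    # element order must mirror init_branch_params (tconv[, sconv], bn);
    # the ReLU masks are applied inside conv_bwd (fused forward)
    if (cfg$type == "eeg") {
      sb <- conv_bwd(bp$par[[i]]$sconv, cc$sconv, dmat)
      tb <- conv_bwd(bp$par[[i]]$tconv, cc$tconv, sb$dx$mat)
      dpar[[i]] <- list(tconv = tb$dpar, sconv = sb$dpar, bn = bb$dpar)
      dmat <- tb$dx$mat
    } else {
      tb <- conv_bwd(bp$par[[i]]$tconv, cc$tconv, dmat)
      dpar[[i]] <- list(tconv = tb$dpar, bn = bb$dpar)
      dmat <- tb$dx$mat
    }
  }
  list(dpar = dpar, dx = dmat)
}

# single-sample matrix -> nn_tensor in branch input layout
sample_to_tensor <- function(sample, type) {
  sample <- as.matrix(sample)
  if (type == "eeg") nn_tensor(matrix(as.vector(sample), ncol = 1),
                               nrow(sample), ncol(sample), 1L)
  else nn_tensor(sample, nrow(sample), 1L, 1L)
}

tensor_to_feature_map <- function(x, branch_id) {
  structure(array(x$mat, c(x$H, x$W, ncol(x$mat))),
            provenance = branch_id)
}

branch_forward_one <- function(sample, params, expected) {
  if (!inherits(params, "branch_params"))
    stop("params must come from init_branch_params()")
  sample <- as.matrix(sample)
  if (nrow(sample) != expected[1] || ncol(sample) != expected[2])
    stop(sprintf("input shape %d x %d does not match expected %d x %d",
                 nrow(sample), ncol(sample), expected[1], expected[2]))
  x <- sample_to_tensor(sample, params$cfg$type)
  tensor_to_feature_map(branch_fwd(params, x, training = FALSE)$out,
                        params$cfg$type)
}

#' EEG branch forward pass
#'
#' Runs one 240 x 62 EEG window through the spatio-temporal convolutional
#' branch in inference mode (batch-norm running statistics) and returns the
#' feature map consumed by the fusion stage.
#'
#' @param sample Numeric matrix, `in_rows` x 62 (240 x 62 at defaults).
#' @param params A `branch_params` from [init_branch_params()] with
#'   `type = "eeg"`.
#' @return Numeric array of dimension `(H, W, C)` (default 15 x 1 x 64)
#'   with attribute `provenance = "eeg"`.
#' @export
eeg_branch_forward <- function(sample, params) {
  if (params$cfg$type != "eeg") stop("params are not an EEG branch")
  branch_forward_one(sample, params,
                     c(params$cfg$in_rows, params$cfg$in_cols))
}

#' Eye branch forward pass
#'
#' Runs one 240 x 4 eye-movement window (pupil_X, pupil_Y, gaze_X, gaze_Y
#' as input feature channels) through the temporal convolutional branch in
#' inference mode.
#'
#' @param sample Numeric matrix, 240 x 4.
#' @param params A `branch_params` with `type = "eye"`.
#' @return Numeric array `(H, W, C)` identical in shape to the EEG branch
#'   output, with attribute `provenance = "eye"`.
#' @export
eye_branch_forward <- function(sample, params) {
  if (params$cfg$type != "eye") stop("params are not an eye branch")
  branch_forward_one(sample, params, c(params$cfg$in_rows, 4L))
}

#' Serialize branch parameters to a single archive
#'
#' Writes the configuration, trainable parameters and batch-norm running
#' statistics to one RDS archive carrying a format-version tag, and reads
#' them back. The configuration also round-trips through YAML inside the
#' archive so it remains human-recoverable.
#'
#' @param params A `branch_params` object.
#' @param path File path for the archive.
#' @return `path` (write) or the restored `branch_params` (read).
#' @export
write_branch_params <- function(params, path) {
  if (!inherits(params, "branch_params"))
    stop("params must come from init_branch_params()")
  saveRDS(list(format = "emofuse.branch_params", version = 1L,
               config_yaml = yaml::as.yaml(unclass(params$cfg)),
               par = params$par, st = params$st),
          path)
  invisible(path)
}

#' @rdname write_branch_params
#' @export
read_branch_params <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "emofuse.branch_params"))
    stop("not a branch-parameter archive: ", path)
  cfg <- yaml::yaml.load(obj$config_yaml)
  cfg$channel_widths <- as.integer(cfg$channel_widths)
  cfg$output_grid <- as.integer(cfg$output_grid)
  cfg$pool_blocks <- as.integer(cfg$pool_blocks)
  cfg[c("blocks", "temporal_kernel", "spatial_kernel", "in_channels",
        "in_rows", "in_cols")] <-
    lapply(cfg[c("blocks", "temporal_kernel", "spatial_kernel",
                 "in_channels", "in_rows", "in_cols")], as.integer)
  class(cfg) <- "branch_config"
  structure(list(cfg = cfg, par = obj$par, st = obj$st),
            class = "branch_params")
}
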