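# Five classical time-series augmentation operators, applied to 101 x 9 gait
# cycles. Every operator preserves the cycle shape and the example's label;
# all randomness flows through an injected gait_rng stream.

#' Augmentation configuration
#'
#' Parameters of the five augmentation operators and which of them are
#' enabled. Defaults are conventional values from the time-series-augmentation
#' literature; every field is tunable per model.
#'
#' @param jitter_sigma Standard deviation (degrees) of additive Gaussian
#'   noise. Default 0.5.
#' @param scale_sigma Standard deviation of the per-angle multiplicative
#'   factor around 1. Default 0.1.
#' @param warp_window_ratio Fraction of the cycle warped by window warping,
#'   in (0, 1]. Default 0.1.
#' @param warp_scales Set of stretch/compression factors window warping draws
#'   from. Default `c(0.5, 2)`.
#' @param permute_segments Number of contiguous segments permutation shuffles,
#'   1..101. Default 4.
#' @param slice_ratio Fraction of the cycle retained by window slicing, in
#'   (0, 1]. Default 0.9.
#' @param enabled Character vector naming the enabled operators, a subset of
#'   `c("jitter", "scale", "window_warp", "permute", "window_slice")`.
#' @return An `augmentation_config` list.
#' @export
augmentation_config <- function(jitter_sigma = 0.5,
                                scale_sigma = 0.1,
                                warp_window_ratio = 0.1,
                                warp_scales = c(0.5, 2),
                                permute_segments = 4L,
                                slice_ratio = 0.9,
                                enabled = c("jitter", "scale", "window_warp",
                                            "permute", "window_slice")) {
  ops <- c("jitter", "scale", "window_warp", "permute", "window_slice")
  enabled <- as.character(enabled)
  if (length(enabled) && !all(enabled %in% ops)) {
    stop("unknown augmentation operator(s): ",
         paste(setdiff(enabled, ops), collapse = ", "), call. = FALSE)
  }
  stopifnot(jitter_sigma >= 0, scale_sigma >= 0,
            warp_window_ratio > 0, warp_window_ratio <= 1,
            length(warp_scales) >= 1, all(warp_scales > 0),
            permute_segments >= 1, permute_segments <= 101,
            slice_ratio > 0, slice_ratio <= 1)
  structure(list(jitter_sigma = jitter_sigma, scale_sigma = scale_sigma,
                 warp_window_ratio = warp_window_ratio,
                 warp_scales = warp_scales,
                 permute_segments = as.integer(permute_segments),
                 slice_ratio = slice_ratio, enabled = enabled),
            class = "augmentation_config")
}

as_cycle_matrix <- function(cycle) {
  m <- unclass(cycle)
  attr(m, "cycle_id") <- NULL
  m
}

rebuild_cycle <- function(values, template) {
  gait_cycle(values, cycle_id = attr(template, "cycle_id"))
}

#' Jittering: additive Gaussian noise
#'
#' @param cycle A [gait_cycle()].
#' @param sigma Noise standard deviation in degrees (>= 0).
#' @param rng A [local_rng()] stream.
#' @return Augmented [gait_cycle()].
#' @export
aug_jitter <- function(cycle, sigma, rng) {
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  m <- as_cycle_matrix(cycle)
  if (sigma > 0) m <- m + matrix(rng$rnorm(length(m), 0, sigma), nrow(m), ncol(m))
  rebuild_cycle(m, cycle)
}

#' Scaling: per-angle multiplicative factor
#'
#' Multiplies each of the nine angle columns by its own factor drawn from
#' `Normal(1, sigma^2)`.
#'
#' @inheritParams aug_jitter
#' @export
aug_scale <- function(cycle, sigma, rng) {
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  m <- as_cycle_matrix(cycle)
  if (sigma > 0) {
    f <- rng$rnorm(ncol(m), 1, sigma)
    m <- sweep(m, 2L, f, `*`)
  }
  rebuild_cycle(m, cycle)
}

resample_rows <- function(m, n_out) {
  # linear resampling of each column onto n_out uniformly spaced points
  n_in <- nrow(m)
  if (n_in == n_out) return(m)
  x_in <- seq(0, 1, length.out = n_in)
  x_out <- seq(0, 1, length.out = n_out)
  apply(m, 2L, function(col) stats::approx(x_in, col, xout = x_out)$y)
}

#' Window warping: stretch or compress a random time window
#'
#' Selects a random contiguous window of length `round(window_ratio * 101)`,
#' rescales its duration by a factor drawn uniformly from `scales` (linear
#' interpolation), then resamples the full series back to 101 points.
#'
#' @inheritParams aug_jitter
#' @param window_ratio Window length as a fraction of the cycle, in (0, 1].
#' @param scales Non-empty set of positive warp factors.
#' @export
aug_window_warp <- function(cycle, window_ratio, scales, rng) {
  if (window_ratio <= 0 || window_ratio > 1) {
    stop("window_ratio must be in (0, 1]", call. = FALSE)
  }
  if (!length(scales) || any(scales <= 0)) {
    stop("scales must be positive and non-empty", call. = FALSE)
  }
  m <- as_cycle_matrix(cycle)
  n <- nrow(m)
  w <- max(2L, min(n, as.integer(round(window_ratio * n))))
  start <- rng$sample(n - w + 1L, size = 1L)
  f <- scales[rng$sample(length(scales), size = 1L)]
  idx <- start:(start + w - 1L)
  warped_len <- max(2L, as.integer(round(w * f)))
  mid <- resample_rows(m[idx, , drop = FALSE], warped_len)
  pre <- if (start > 1L) m[1:(start - 1L), , drop = FALSE] else NULL
  post <- if (start + w - 1L < n) m[(start + w):n, , drop = FALSE] else NULL
  full <- rbind(pre, mid, post)
  rebuild_cycle(resample_rows(full, n), cycle)
}

#' Permutation: shuffle contiguous time segments
#'
#' Splits the time axis into `n_segments` contiguous near-equal segments (the
#' first `101 %% n_segments` segments take the extra point), permutes them
#' uniformly at random and concatenates. All nine angles are permuted
#' identically.
#'
#' @inheritParams aug_jitter
#' @param n_segments Number of segments, 1..101.
#' @export
aug_permute <- function(cycle, n_segments, rng) {
  n_segments <- as.integer(n_segments)
  if (n_segments < 1L || n_segments > 101L) {
    stop("n_segments must be in 1..101", call. = FALSE)
  }
  m <- as_cycle_matrix(cycle)
  if (n_segments == 1L) return(rebuild_cycle(m, cycle))
  n <- nrow(m)
  base <- n %/% n_segments
  extra <- n %% n_segments
  lens <- rep(base, n_segments) + c(rep(1L, extra), rep(0L, n_segments - extra))
  ends <- cumsum(lens)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  ord <- rng$sample(n_segments)
  idx <- unlist(lapply(ord, function(s) starts[s]:ends[s]))
  rebuild_cycle(m[idx, , drop = FALSE], cycle)
}

#' Window slicing: crop a random window and resample
#'
#' Extracts a random contiguous window of length `round(slice_ratio * 101)`
#' and linearly resamples it back to 101 points, so downstream models keep a
#' fixed input length.
#'
#' @inheritParams aug_jitter
#' @param slice_ratio Retained fraction of the cycle, in (0, 1].
#' @export
aug_window_slice <- function(cycle, slice_ratio, rng) {
  if (slice_ratio <= 0 || slice_ratio > 1) {
    stop("slice_ratio must be in (0, 1]", call. = FALSE)
  }
  m <- as_cycle_matrix(cycle)
  n <- nrow(m)
  w <- max(2L, min(n, as.integer(round(slice_ratio * n))))
  start <- rng$sample(n - w + 1L, size = 1L)
  sliced <- m[start:(start + w - 1L), , drop = FALSE]
  rebuild_cycle(resample_rows(sliced, n), cycle)
}

apply_one_op <- function(op, cycle, config, rng) {
  switch(op,
    jitter = aug_jitter(cycle, config$jitter_sigma, rng),
    scale = aug_scale(cycle, config$scale_sigma, rng),
    window_warp = aug_window_warp(cycle, config$warp_window_ratio,
                                  config$warp_scales, rng),
    permute = aug_permute(cycle, config$permute_segments, rng),
    window_slice = aug_window_slice(cycle, config$slice_ratio, rng),
    stop("unknown operator: ", op, call. = FALSE))
}

#' Apply the enabled operators in a random order
#'
#' Draws one uniformly random order of the enabled operators (per call; in
#' training, one order per batch) and applies them in sequence. Deterministic
#' under a fixed stream state.
#'
#' @param cycle A [gait_cycle()].
#' @param config An [augmentation_config()].
#' @param rng A [local_rng()] stream.
#' @param order Optional precomputed operator order (used by the training
#'   loop to share one order across a batch).
#' @return Augmented [gait_cycle()].
#' @export
compose_augmentations <- function(cycle, config, rng, order = NULL) {
  stopifnot(inherits(config, "augmentation_config"))
  ops <- config$enabled
  if (!length(ops)) return(cycle)
  if (is.null(order)) order <- ops[rng$sample(length(ops))]
  for (op in order) cycle <- apply_one_op(op, cycle, config, rng)
  cycle
}

#' Draw a random application order for the enabled operators
#'
#' @inheritParams compose_augmentations
#' @return Character vector of operator names.
#' @export
draw_augmentation_order <- function(config, rng) {
  ops <- config$enabled
  if (!length(ops)) return(character(0))
  ops[rng$sample(length(ops))]
}
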