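# Frequency-domain image encoding of gait cycles: the 2D discrete Fourier
# transform of the 101 x 9 cycle matrix, scaled by 1/(T*N), with the
# zero-frequency bin optionally shifted to the image center.

#' 2D-FFT magnitude spectrum of a gait cycle
#'
#' Computes the two-dimensional discrete Fourier transform of the 101 x 9
#' cycle matrix over the full grid, with overall scaling `1/(T*N)` (T = 101
#' time samples, N = 9 angles), and returns the entrywise modulus.
#'
#' @param cycle A [gait_cycle()].
#' @return A `spectrum_image` list with fields `magnitude` (101 x 9
#'   non-negative matrix), `centralized` (FALSE) and `tiled_width` (1).
#' @export
fft2_magnitude <- function(cycle) {
  stopifnot(is_gait_cycle(cycle))
  m <- unclass(cycle)
  attr(m, "cycle_id") <- NULL
  dimnames(m) <- NULL
  F <- stats::fft(m) / (nrow(m) * ncol(m))
  structure(list(magnitude = Mod(F), centralized = FALSE, tiled_width = 1L),
            class = "spectrum_image")
}

#' @export
print.spectrum_image <- function(x, ...) {
  cat("<spectrum_image> ", nrow(x$magnitude), " x ", ncol(x$magnitude),
      if (x$centralized) ", centralized" else "",
      if (x$tiled_width > 1L) paste0(", width x", x$tiled_width) else "",
      "\n", sep = "")
  invisible(x)
}

#' Shift the zero-frequency bin to the image center
#'
#' Circularly shifts the magnitude so the DC bin moves from (0,0) to
#' (floor(101/2), floor(9/2)) = (50, 4) in 0-based coordinates, making the
#' spectrum image visually centered. The multiset of values is preserved.
#'
#' @param spec An uncentralized `spectrum_image`.
#' @return The centralized `spectrum_image`.
#' @export
centralize <- function(spec) {
  stopifnot(inherits(spec, "spectrum_image"))
  if (spec$centralized) stop("spectrum is already centralized", call. = FALSE)
  m <- spec$magnitude
  sr <- nrow(m) %/% 2L
  sc <- ncol(m) %/% 2L
  ri <- ((seq_len(nrow(m)) - 1L - sr) %% nrow(m)) + 1L
  ci <- ((seq_len(ncol(m)) - 1L - sc) %% ncol(m)) + 1L
  spec$magnitude <- m[ri, ci, drop = FALSE]
  spec$centralized <- TRUE
  spec
}

#' Undo the center shift
#'
#' @param spec A centralized `spectrum_image`.
#' @return The uncentralized `spectrum_image`.
#' @export
decentralize <- function(spec) {
  stopifnot(inherits(spec, "spectrum_image"))
  if (!spec$centralized) stop("spectrum is not centralized", call. = FALSE)
  m <- spec$magnitude
  sr <- nrow(m) %/% 2L
  sc <- ncol(m) %/% 2L
  ri <- ((seq_len(nrow(m)) - 1L + sr) %% nrow(m)) + 1L
  ci <- ((seq_len(ncol(m)) - 1L + sc) %% ncol(m)) + 1L
  spec$magnitude <- m[ri, ci, drop = FALSE]
  spec$centralized <- FALSE
  spec
}

#' Tile a spectrum along its width
#'
#' Repeats the image `k` times along the width (angle-frequency) dimension,
#' e.g. k = 4 turns 101 x 9 into 101 x 36, meeting the 32-pixel minimum input
#' width of VGG-style backbones.
#'
#' @param spec A `spectrum_image`.
#' @param k Integer >= 1 repetition count.
#' @return The tiled `spectrum_image` (tiled_width multiplied by `k`).
#' @export
repeat_width <- function(spec, k) {
  stopifnot(inherits(spec, "spectrum_image"))
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (k > 1L) {
    spec$magnitude <- do.call(cbind, rep(list(spec$magnitude), k))
    spec$tiled_width <- spec$tiled_width * k
  }
  spec
}

#' Encode gait cycles as centralized spectrum images
#'
#' Convenience wrapper: 2D-FFT magnitude, centered, optionally width-tiled.
#'
#' @param cycles List of [gait_cycle()] objects.
#' @param tile Width repetition factor (1 = untiled, 4 for 32-px-minimum
#'   backbones).
#' @return List of `spectrum_image` objects.
#' @export
encode_spectra <- function(cycles, tile = 1L) {
  lapply(cycles, function(cy) repeat_width(centralize(fft2_magnitude(cy)), tile))
}

#' Stack spectrum images into a model input array
#'
#' @param specs List of `spectrum_image` objects of identical size.
#' @return Numeric array `[batch, height, width, 1]`.
#' @export
spectra_to_array <- function(specs) {
  h <- nrow(specs[[1]]$magnitude); w <- ncol(specs[[1]]$magnitude)
  out <- array(0, dim = c(length(specs), h, w, 1L))
  for (i in seq_along(specs)) out[i, , , 1L] <- specs[[i]]$magnitude
  out
}
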