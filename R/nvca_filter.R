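#' Filter mask geometry
#'
#' The NVCA and moving-average filters operate on an `N x N x K`
#' neighborhood: `N x N` pixels spatially (N odd, symmetric about the
#' center) by `K` frames temporally. The temporal window is strictly
#' causal - the current frame plus the `K - 1` preceding ones - which is
#' what makes streaming, real-time operation possible. `k_temporal = 1`
#' yields a purely spatial filter; `n_spatial = 1` a purely temporal one.
#'
#' @param n_spatial Odd integer `N >= 1`, spatial extent per axis.
#' @param k_temporal Integer `K >= 1`, temporal extent.
#' @return An object of class `mask_spec`.
#' @examples
#' mask_spec(5, 5)   # the 5 x 5 x 5 mask
#' @export
mask_spec <- function(n_spatial, k_temporal) {
  n_spatial <- as.integer(n_spatial)
  k_temporal <- as.integer(k_temporal)
  if (is.na(n_spatial) || n_spatial < 1L || n_spatial %% 2L == 0L) {
    stop("`n_spatial` must be an odd integer >= 1")
  }
  if (is.na(k_temporal) || k_temporal < 1L) {
    stop("`k_temporal` must be an integer >= 1")
  }
  structure(list(n_spatial = n_spatial, k_temporal = k_temporal),
            class = "mask_spec")
}

#' @export
print.mask_spec <- function(x, ...) {
  cat(sprintf("<mask_spec> %d x %d x %d (N x N x K)\n",
              x$n_spatial, x$n_spatial, x$k_temporal))
  invisible(x)
}

#' Precomputed threshold lookup table
#'
#' Hardware implementations of the NVCA filter avoid the per-pixel
#' square root by storing the thresholds for the whole gray-level range
#' in a lookup table. This builds such a table on a uniform grid:
#' `thresholds[i] = threshold_at(noise, factor, levels[i])`.
#'
#' @param noise A [noise_params()] object.
#' @param factor Threshold factor `F >= 0`.
#' @param n_levels Number of grid levels (>= 2). Default `2^16`,
#'   emulating a 16-bit digitizer.
#' @param range Length-2 numeric `[lo, hi]` covering the data range.
#'   Defaults to the noise parameters' declared `level_range`.
#' @return An object of class `threshold_lut` with `levels`,
#'   `thresholds`, `quantization` (grid step) and `factor`.
#' @export
build_threshold_lut <- function(noise, factor, n_levels = 65536L,
                                range = NULL) {
  stopifnot(inherits(noise, "noise_params"))
  n_levels <- as.integer(n_levels)
  if (is.na(n_levels) || n_levels < 2L) stop("`n_levels` must be >= 2")
  if (is.null(range)) range <- noise$level_range
  if (length(range) != 2L || !all(is.finite(range)) || range[1] >= range[2]) {
    stop("`range` must be a finite [lo, hi] with lo < hi")
  }
  levels <- seq(range[1], range[2], length.out = n_levels)
  structure(
    list(
      levels = levels,
      thresholds = threshold_at(noise, factor, levels),
      quantization = (range[2] - range[1]) / (n_levels - 1),
      factor = factor,
      range = as.numeric(range)
    ),
    class = "threshold_lut"
  )
}

# Map values to nearest LUT grid index (ties round half up).
lut_index <- function(lut, values) {
  k <- floor((values - lut$range[1]) / lut$quantization + 0.5)
  pmin(pmax(k, 0), length(lut$levels) - 1) + 1L
}

#' NVCA filter configuration
#'
#' Bundles the mask geometry with the thresholding rule. Exactly one of
#' `noise` (thresholds computed per pixel as
#' `threshold_at(noise, threshold_factor, center)`) or `lut` (thresholds
#' looked up at the nearest grid level) drives thresholding at run time.
#'
#' @param mask A [mask_spec()].
#' @param threshold_factor Dimensionless `F >= 0`. Ignored when a `lut`
#'   is supplied (the LUT was built with its own factor).
#' @param noise A [noise_params()] object, or `NULL` when using `lut`.
#' @param lut A [build_threshold_lut()] result, or `NULL`.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(mask, threshold_factor, noise = NULL, lut = NULL) {
  stopifnot(inherits(mask, "mask_spec"))
  if (is.null(noise) == is.null(lut)) {
    stop("supply exactly one of `noise` or `lut`")
  }
  if (!is.null(noise)) stopifnot(inherits(noise, "noise_params"))
  if (!is.null(lut)) stopifnot(inherits(lut, "threshold_lut"))
  if (missing(threshold_factor) && !is.null(lut)) {
    threshold_factor <- lut$factor
  }
  if (!is.numeric(threshold_factor) || length(threshold_factor) != 1L ||
      is.na(threshold_factor) || threshold_factor < 0) {
    stop("`threshold_factor` must be a single number >= 0")
  }
  structure(
    list(mask = mask, threshold_factor = threshold_factor,
         noise = noise, lut = lut),
    class = "filter_config"
  )
}

check_mask_fits <- function(seq, mask) {
  if (mask$n_spatial > seq$height || mask$n_spatial > seq$width) {
    stop(sprintf(
      "spatial mask extent %d exceeds the %d x %d frame",
      mask$n_spatial, seq$height, seq$width
    ))
  }
}

#' Noise Variance Conditioned Average filter
#'
#' Edge-preserving spatio-temporal denoising: each output pixel is the
#' mean of those neighbors in its `N x N x K` causal window whose
#' absolute difference from the center pixel does not exceed the local
#' threshold `T = F * sigma(center)` derived from the quantum-noise
#' model. Neighbors on the far side of an edge differ by more than the
#' noise allows and are excluded, so edges - including those of moving
#' objects - are not smeared, while flat regions receive the full
#' averaging.
#'
#' The temporal window covers the current frame and the `K - 1`
#' preceding frames only (causal). At the sequence start and at spatial
#' borders the window truncates to the available pixels; the denominator
#' adapts, no data is invented. The center pixel always passes the rule,
#' so the output is always defined and every output pixel is a convex
#' combination of admitted input pixels (it can never leave their
#' min-max range).
#'
#' @param seq A `frame_sequence`.
#' @param config A [filter_config()].
#' @return The filtered `frame_sequence`.
#' @examples
#' np <- noise_params(43.9e-4, 0)
#' ph <- make_step_sequence(step_phantom_spec(64, 64, n_frames = 10),
#'                          np, seed = 1)
#' den <- nvca_filter(ph$noisy,
#'                    filter_config(mask_spec(5, 5), 2, noise = np))
#' @export
nvca_filter <- function(seq, config) {
  stopifnot(is_frame_sequence(seq), inherits(config, "filter_config"))
  check_mask_fits(seq, config$mask)
  centers <- seq$frames
  if (!is.null(config$lut)) {
    thr <- config$lut$thresholds[lut_index(config$lut, centers)]
  } else {
    thr <- threshold_at(config$noise, config$threshold_factor, centers)
  }
  out <- nvca_core(
    as.vector(centers), dim(centers), as.vector(thr),
    config$mask$n_spatial, config$mask$k_temporal
  )
  frame_sequence(array(out, dim = dim(centers)),
                 bit_depth_hint = seq$bit_depth_hint,
                 metadata = seq$metadata)
}

#' Spatio-temporal moving average
#'
#' The unconditioned baseline: the plain mean over the same causal
#' `N x N x K` window used by [nvca_filter()], with the same border and
#' start-up truncation (all in-bounds neighbors are admitted). Identical
#' to the NVCA filter in the limit of an arbitrarily large threshold.
#'
#' @param seq A `frame_sequence`.
#' @param mask A [mask_spec()].
#' @return The filtered `frame_sequence`.
#' @export
moving_average <- function(seq, mask) {
  stopifnot(is_frame_sequence(seq), inherits(mask, "mask_spec"))
  check_mask_fits(seq, mask)
  out <- nvca_core(as.vector(seq$frames), dim(seq$frames), Inf,
                   mask$n_spatial, mask$k_temporal)
  frame_sequence(array(out, dim = dim(seq$frames)),
                 bit_depth_hint = seq$bit_depth_hint,
                 metadata = seq$metadata)
}
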