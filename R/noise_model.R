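#' Mixed Poissonian-Gaussian noise parameters
#'
#' Low-dose fluoroscopy pixels are dominated by quantum noise: the photon
#' count in a pixel is Poisson distributed, scaled by the detector gain,
#' and summed with signal-independent Gaussian detector/electronics noise.
#' The resulting expected value-variance relationship is affine,
#'
#' \deqn{\sigma^2(h) = A \cdot h + B,}
#'
#' where `h` is the noise-free pixel value (a.u.), `A` (a.u.) is set by
#' the detector gain and `B` (a.u.^2) by the additive Gaussian noise. This
#' pair fully parameterizes sampling, variance-conditioned thresholds and
#' the generalized Anscombe transform.
#'
#' Fitted `B` values can come out slightly negative on real data, which
#' would make \eqn{\sigma^2 \le 0} at very low gray levels. When
#' `a_gain >= 0` such a pair is accepted with a warning naming the
#' affected level range; evaluated variances are floored at a tiny
#' positive `eps` (see [variance_at()]). When `a_gain < 0` the pair must
#' yield a strictly positive variance over the whole declared
#' `level_range`, otherwise construction fails.
#'
#' @param a_gain Slope `A` of the expected value-variance line (a.u.).
#' @param b_offset Intercept `B` (a.u.^2).
#' @param level_range Numeric length-2 vector `[level_min, level_max]`
#'   declaring the valid pixel-value range these parameters apply to.
#'   Defaults to `c(0, 1)`, the normalized detector scale.
#' @return An object of class `noise_params`.
#' @examples
#' noise_params(43.90e-4, 0)           # paper-magnitude quantum noise
#' noise_params(0, 0.25)               # signal-independent Gaussian limit
#' @export
noise_params <- function(a_gain, b_offset, level_range = c(0, 1)) {
  stopifnot(
    is.numeric(a_gain), length(a_gain) == 1L, is.finite(a_gain),
    is.numeric(b_offset), length(b_offset) == 1L, is.finite(b_offset),
    is.numeric(level_range), length(level_range) == 2L,
    all(is.finite(level_range))
  )
  if (level_range[1] >= level_range[2]) {
    stop("`level_range` must satisfy level_min < level_max")
  }
  var_ends <- a_gain * level_range + b_offset
  if (a_gain < 0) {
    if (any(var_ends <= 0)) {
      stop(
        "with a_gain < 0 the variance a_gain * level + b_offset must be ",
        "positive over the whole declared level_range"
      )
    }
  } else if (min(var_ends) < 0) {
    # affine in level, a_gain >= 0: non-positive only below the zero crossing
    crossing <- if (a_gain > 0) -b_offset / a_gain else Inf
    warning(sprintf(
      paste0(
        "sigma^2(level) = A*level + B is non-positive for levels in ",
        "[%.4g, %.4g]; variances there are floored at eps"
      ),
      level_range[1], min(crossing, level_range[2])
    ), call. = FALSE)
  }
  structure(
    list(
      a_gain = a_gain, b_offset = b_offset,
      level_range = as.numeric(level_range)
    ),
    class = "noise_params"
  )
}

#' @export
print.noise_params <- function(x, ...) {
  cat(sprintf(
    "<noise_params> sigma^2(h) = %.6g * h + %.6g over levels [%.4g, %.4g]\n",
    x$a_gain, x$b_offset, x$level_range[1], x$level_range[2]
  ))
  invisible(x)
}

#' Local noise variance at a gray level
#'
#' Evaluates the affine expected value-variance law
#' \eqn{\sigma^2(h) = A h + B}, floored at a small positive `eps` so
#' thresholds stay defined even where a fitted (slightly negative) `B`
#' would push the line below zero.
#'
#' @param params A [noise_params()] object.
#' @param level Pixel value(s) in a.u.; vectorized.
#' @param eps Positive variance floor (a.u.^2). Default `1e-12`.
#' @return Variance(s) in a.u.^2, always `>= eps`.
#' @examples
#' p <- noise_params(2, 1)
#' variance_at(p, 3)  # 7
#' @export
variance_at <- function(params, level, eps = 1e-12) {
  stopifnot(inherits(params, "noise_params"), eps > 0)
  if (!is.numeric(level) || length(level) == 0L) {
    stop("`level` must be numeric")
  }
  bad <- !is.finite(level)
  if (any(bad)) {
    stop(sprintf(
      "non-finite level value(s): %s",
      paste(utils::head(format(level[bad]), 3L), collapse = ", ")
    ))
  }
  pmax(params$a_gain * level + params$b_offset, eps)
}

#' Variance-conditioned inclusion threshold
#'
#' The NVCA decision rule admits a neighbor into the average only if its
#' absolute difference from the center pixel does not exceed
#' \eqn{T = F \cdot \sigma(h)}, i.e. `factor` times the local noise
#' standard deviation at the center's gray level.
#'
#' @inheritParams variance_at
#' @param factor Dimensionless threshold factor `F >= 0`.
#' @return Threshold(s) `T` in a.u.
#' @examples
#' threshold_at(noise_params(1, 0), factor = 2, level = 4)  # 4
#' @export
threshold_at <- function(params, factor, level, eps = 1e-12) {
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) ||
      factor < 0) {
    stop("`factor` must be a single finite number >= 0")
  }
  factor * sqrt(variance_at(params, level, eps = eps))
}

#' Corrupt a clean sequence with signal-dependent noise
#'
#' Draws noisy realizations of a noise-free sequence under the affine
#' expected value-variance law. Two generators are provided:
#'
#' * `"gaussian_approx"`: `g = h + N(0, A h + B)` - the Gaussian
#'   approximation valid when more than ~10 photons are detected per
#'   pixel (the usual fluoroscopy regime). Non-positive variances are
#'   treated as exactly zero so the zero-noise limit `A = B = 0`
#'   reproduces the clean data bit-for-bit.
#' * `"poisson_gaussian"`: `g = A P + n`, `P ~ Poisson(h / A)`,
#'   `n ~ N(0, B)` - the physical mixture. Requires `A > 0`, `B >= 0`
#'   and non-negative clean values.
#'
#' Both have mean `h` and variance `A h + B`.
#'
#' @param clean A `frame_sequence` of noise-free values.
#' @param params A [noise_params()] object; clean values must lie within
#'   its declared `level_range`.
#' @param mode `"gaussian_approx"` or `"poisson_gaussian"`.
#' @param seed Optional integer seed; with a fixed seed the output is
#'   reproducible and the global RNG state is left untouched. The seed is
#'   recorded in the output metadata.
#' @return A `frame_sequence` of noisy values.
#' @examples
#' clean <- frame_sequence(array(0.5, dim = c(4, 8, 8)))
#' noisy <- sample_noisy(clean, noise_params(43.9e-4, 0),
#'                       mode = "poisson_gaussian", seed = 1)
#' @export
sample_noisy <- function(clean, params,
                         mode = c("gaussian_approx", "poisson_gaussian"),
                         seed = NULL) {
  stopifnot(is_frame_sequence(clean), inherits(params, "noise_params"))
  mode <- match.arg(mode)
  h <- clean$frames
  rng <- range(h)
  if (rng[1] < params$level_range[1] || rng[2] > params$level_range[2]) {
    stop(sprintf(
      "clean values span [%.4g, %.4g], outside the declared level range [%.4g, %.4g]",
      rng[1], rng[2], params$level_range[1], params$level_range[2]
    ))
  }
  a <- params$a_gain
  b <- params$b_offset
  noisy <- with_seed(seed, {
    if (mode == "gaussian_approx") {
      sd <- sqrt(pmax(a * h + b, 0))
      h + stats::rnorm(length(h), mean = 0, sd = sd)
    } else {
      if (a <= 0) {
        stop("poisson_gaussian sampling requires a_gain > 0 (detector gain)")
      }
      if (b < 0) {
        stop("poisson_gaussian sampling requires b_offset >= 0 (Gaussian variance)")
      }
      if (rng[1] < 0) stop("poisson_gaussian sampling requires clean values >= 0")
      g <- a * stats::rpois(length(h), lambda = h / a)
      if (b > 0) g <- g + stats::rnorm(length(h), mean = 0, sd = sqrt(b))
      g
    }
  })
  noisy <- array(noisy, dim = dim(h))
  md <- clean$metadata
  md$noise <- list(
    a_gain = a, b_offset = b, mode = mode,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
  )
  frame_sequence(noisy, bit_depth_hint = clean$bit_depth_hint, metadata = md)
}

#' Generalized Anscombe transform parameters
#'
#' Bundles the noise parameters with an optional additive acquisition
#' pedestal (baseline offset `m`, a.u., default 0) for the generalized
#' Anscombe transform pair.
#'
#' @param noise A [noise_params()] object with `a_gain > 0`.
#' @param pedestal Additive baseline of the acquisition in a.u.
#' @return An object of class `anscombe_params`.
#' @export
anscombe_params <- function(noise, pedestal = 0) {
  stopifnot(
    inherits(noise, "noise_params"),
    is.numeric(pedestal), length(pedestal) == 1L, is.finite(pedestal)
  )
  if (noise$a_gain <= 0) {
    stop("the generalized Anscombe transform requires a_gain > 0")
  }
  structure(list(noise = noise, pedestal = pedestal),
            class = "anscombe_params")
}

#' Generalized Anscombe transform (forward)
#'
#' Variance-stabilizes mixed Poissonian-Gaussian data: with gain `A`,
#' Gaussian variance `B` and pedestal `m`,
#'
#' \deqn{f(z) = \frac{2}{A}\sqrt{A z + \tfrac{3}{8}A^2 + B - A m},}
#'
#' whose output noise is approximately unit-variance Gaussian once the
#' scaled intensity `h / A` exceeds roughly 10. The argument of the
#' square root is clamped at zero before taking the root; the number of
#' clamped pixels is recorded in the output metadata
#' (`gat_clamp_count`).
#'
#' With `B = 0`, `m = 0`, `A = 1` this reduces to the classical Anscombe
#' transform \eqn{2\sqrt{z + 3/8}}.
#'
#' @param seq A `frame_sequence`.
#' @param params An [anscombe_params()] object.
#' @return A transformed `frame_sequence`.
#' @seealso [gat_inverse_algebraic()]
#' @export
gat_forward <- function(seq, params) {
  stopifnot(is_frame_sequence(seq), inherits(params, "anscombe_params"))
  a <- params$noise$a_gain
  b <- params$noise$b_offset
  m <- params$pedestal
  arg <- a * seq$frames + (3 / 8) * a^2 + b - a * m
  clamped <- sum(arg < 0)
  arg[arg < 0] <- 0
  out <- (2 / a) * sqrt(arg)
  md <- seq$metadata
  md$gat_clamp_count <- clamped
  frame_sequence(array(out, dim = dim(seq$frames)),
                 bit_depth_hint = seq$bit_depth_hint, metadata = md)
}

#' Algebraic inverse of the generalized Anscombe transform
#'
#' The exact functional inverse of [gat_forward()] on its non-clamped
#' domain:
#'
#' \deqn{f^{-1}(y) = \frac{A}{4} y^2 - \frac{3}{8} A - \frac{B}{A} + m.}
#'
#' No debiasing is applied (this is the plain algebraic inverse, not the
#' exact-unbiased inverse of the variance-stabilization literature).
#'
#' @inheritParams gat_forward
#' @return A `frame_sequence` on the original intensity scale.
#' @export
gat_inverse_algebraic <- function(seq, params) {
  stopifnot(is_frame_sequence(seq), inherits(params, "anscombe_params"))
  a <- params$noise$a_gain
  b <- params$noise$b_offset
  m <- params$pedestal
  out <- (a / 4) * seq$frames^2 - (3 / 8) * a - b / a + m
  frame_sequence(array(out, dim = dim(seq$frames)),
                 bit_depth_hint = seq$bit_depth_hint,
                 metadata = seq$metadata)
}
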