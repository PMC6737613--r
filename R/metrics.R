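#' Edge profile
#'
#' A 1-D sample of pixel values across an edge, at strictly increasing,
#' uniformly unit-spaced positions.
#'
#' @param values Numeric pixel values (a.u.).
#' @param positions Pixel coordinates along the profile; defaults to
#'   `0, 1, 2, ...`.
#' @param orientation Which image axis the profile runs along:
#'   `"horizontal"` (along columns, across a vertical edge) or
#'   `"vertical"` (along rows, across a horizontal edge).
#' @return An object of class `edge_profile`.
#' @export
edge_profile <- function(values, positions = seq_along(values) - 1,
                         orientation = c("horizontal", "vertical")) {
  orientation <- match.arg(orientation)
  stopifnot(is.numeric(values), is.numeric(positions),
            length(values) == length(positions), length(values) >= 4L,
            all(is.finite(values)), all(is.finite(positions)))
  d <- diff(positions)
  if (any(d <= 0) || max(abs(d - d[1])) > 1e-8) {
    stop("`positions` must be strictly increasing with uniform spacing")
  }
  structure(list(positions = as.numeric(positions),
                 values = as.numeric(values),
                 orientation = orientation),
            class = "edge_profile")
}

# Error function via the normal CDF.
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Error-function edge model
#'
#' The unit edge spread function
#' `psi(x) = 0.5 * (1 - erf((x - c) / (sqrt(2) d))) = pnorm(-(x - c) / d)`:
#' a falling edge centered at `c` whose underlying Gaussian line spread
#' function has sigma `d`.
#'
#' @param x Positions (pixels).
#' @param c Edge center (pixels).
#' @param d Spread parameter (pixels), the LSF Gaussian sigma.
#' @return `psi(x)` in `[0, 1]`.
#' @export
edge_psi <- function(x, c, d) stats::pnorm(-(x - c) / d)

#' Fit an error-function edge model to a profile
#'
#' The edge spread function of an imaging chain with a Gaussian line
#' spread function is an error-function step,
#' \deqn{\psi(x) = 0.5 (1 - \mathrm{erf}((x - c)/(\sqrt{2} d))),}
#' with edge center `c` and spread `d` (the LSF's Gaussian sigma), so
#' the LSF full width at half maximum is `FWHM = 2.355 * d`. Measured
#' profiles are neither normalized nor zero-based, so the 4-parameter
#' extension `offset + amplitude * psi(x; c, d)` is fitted by nonlinear
#' least squares (Levenberg-Marquardt, `d` bounded below at 0). A
#' falling edge has positive `amplitude`; a rising edge fits with
#' negative `amplitude` and the same `d`.
#'
#' Initialization: `c` at the maximum-|gradient| sample, several starts
#' for `d` (0.3, 1 and 3 px), offset/amplitude from the medians of the
#' first and last three samples; the converged start with the lowest
#' residual sum of squares wins.
#'
#' The `d -> 0` limit of the model is an ideal step between two samples.
#' A digital edge can be sharper than the sampling grid, in which case
#' the least-squares solution lies in that limit and gradient-based
#' optimization degenerates; `fit_edge` therefore also evaluates the
#' exact step-limit least-squares fit (best split point with per-side
#' means) and returns it - with `d = 0`, hence `fwhm = 0`, and
#' `diagnostics = "step-limit"` - whenever it has a lower residual sum
#' of squares than every converged erf fit. If nothing converges and
#' even the step limit explains the profile poorly, the result is
#' flagged via the `r2_floor` rule; fits with `r_squared` below
#' `r2_floor` are always flagged.
#'
#' @param profile An [edge_profile()] or a plain numeric vector
#'   (interpreted at unit positions).
#' @param r2_floor Fits with `r_squared` below this are flagged.
#' @return An object of class `edge_fit` with `c`, `d`, `offset`,
#'   `amplitude`, `r_squared`, `fwhm` (`= 2.355 * d`), `converged`,
#'   `flagged` and `diagnostics`.
#' @examples
#' x <- 0:20
#' y <- 0.2 + 0.3 * edge_psi(x, c = 10, d = 2)
#' fit_edge(edge_profile(y, x))
#' @export
fit_edge <- function(profile, r2_floor = 0.5) {
  if (!inherits(profile, "edge_profile")) {
    profile <- edge_profile(as.numeric(profile))
  }
  x <- profile$positions
  y <- profile$values
  if (stats::sd(y) == 0) {
    stop("flat profile: no edge to fit")
  }
  g <- abs(diff(y))
  c0 <- x[which.max(g)] + (x[2] - x[1]) / 2
  left <- stats::median(y[seq_len(min(3L, length(y)))])
  right <- stats::median(y[seq.int(length(y) - min(3L, length(y)) + 1L,
                                   length(y))])
  tss <- sum((y - mean(y))^2)

  # exact least squares in the d -> 0 (ideal step) limit of the model:
  # split between two samples, per-side means
  n <- length(y)
  step <- NULL
  for (i in seq_len(n - 1L)) {
    l <- mean(y[seq_len(i)])
    r <- mean(y[seq.int(i + 1L, n)])
    rss <- sum((y[seq_len(i)] - l)^2) + sum((y[seq.int(i + 1L, n)] - r)^2)
    if (is.null(step) || rss < step$rss) {
      step <- list(c = (x[i] + x[i + 1L]) / 2, offset = r,
                   amplitude = l - r, rss = rss)
    }
  }

  best <- NULL
  for (d0 in c(1, 0.3, 3)) {
    start <- list(offset = right, amplitude = left - right, c0 = c0, d = d0)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ offset + amplitude * stats::pnorm(-(x - c0) / d),
        start = start,
        lower = c(-Inf, -Inf, -Inf, 1e-9),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) {
      cf <- stats::coef(fit)
      best <- list(c = unname(cf[["c0"]]), d = unname(cf[["d"]]),
                   offset = unname(cf[["offset"]]),
                   amplitude = unname(cf[["amplitude"]]), rss = rss)
    }
  }

  if (is.null(best) || step$rss < best$rss) {
    r2 <- 1 - step$rss / tss
    return(structure(
      list(
        c = step$c, d = 0, offset = step$offset, amplitude = step$amplitude,
        r_squared = r2, fwhm = 0,
        converged = TRUE, flagged = r2 < r2_floor,
        diagnostics = "step-limit (edge sharper than the sampling grid)"
      ),
      class = "edge_fit"
    ))
  }
  r2 <- 1 - best$rss / tss
  structure(
    list(
      c = best$c, d = best$d,
      offset = best$offset, amplitude = best$amplitude,
      r_squared = r2, fwhm = 2.355 * best$d,
      converged = TRUE, flagged = r2 < r2_floor,
      diagnostics = NULL
    ),
    class = "edge_fit"
  )
}

#' @export
print.edge_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<edge_fit> did not converge:", x$diagnostics, "\n")
  } else {
    cat(sprintf(
      "<edge_fit> c = %.3f px, d = %.4f px, FWHM = %.4f px, R^2 = %.4f%s\n",
      x$c, x$d, x$fwhm, x$r_squared, if (x$flagged) " [flagged]" else ""
    ))
  }
  invisible(x)
}

#' FWHM over consecutive edge profiles
#'
#' Estimates spatial resolution at an edge the way a phantom study does:
#' `n_profiles` consecutive, 1-px-spaced parallel profiles are extracted
#' from the ROI perpendicular to the edge, each is fitted with
#' [fit_edge()], and the FWHM is summarized as mean over profiles with
#' the standard deviation as its uncertainty. Flagged or non-converged
#' fits are excluded and counted.
#'
#' @param x A single frame (matrix) or a `frame_sequence` (then `frame`
#'   selects the frame).
#' @param roi A [roi_spec()] containing the edge for all profiles.
#' @param n_profiles Number of consecutive profiles (rows for
#'   `direction = "horizontal"`, columns for `"vertical"`). Default: all
#'   available.
#' @param direction Axis the profiles run along: `"horizontal"`
#'   profiles read across columns (for a vertical edge), `"vertical"`
#'   profiles read across rows (for a horizontal edge).
#' @param frame Frame index when `x` is a sequence.
#' @param r2_floor Passed to [fit_edge()].
#' @return An object of class `fwhm_summary` with `mean_fwhm`,
#'   `std_fwhm` (pixels), `n_profiles` (successful fits), `n_flagged`
#'   and the individual `fits`.
#' @export
fwhm_over_profiles <- function(x, roi, n_profiles = NULL,
                               direction = c("horizontal", "vertical"),
                               frame = NULL, r2_floor = 0.5) {
  direction <- match.arg(direction)
  if (is_frame_sequence(x)) {
    if (is.null(frame)) stop("`frame` must be given for a frame_sequence")
    x <- get_frame(x, frame)
  }
  block <- roi_extract(x, roi)
  if (direction == "vertical") block <- t(block)
  avail <- nrow(block)
  if (is.null(n_profiles)) n_profiles <- avail
  if (n_profiles > avail) {
    stop(sprintf("ROI provides only %d profiles, %d requested",
                 avail, n_profiles))
  }
  fits <- vector("list", n_profiles)
  fwhms <- rep(NA_real_, n_profiles)
  for (i in seq_len(n_profiles)) {
    f <- tryCatch(
      fit_edge(edge_profile(block[i, ],
                            orientation = direction),
               r2_floor = r2_floor),
      error = function(e) {
        structure(list(converged = FALSE, flagged = TRUE, fwhm = NA_real_,
                       diagnostics = conditionMessage(e)),
                  class = "edge_fit")
      }
    )
    fits[[i]] <- f
    if (f$converged && !f$flagged) fwhms[i] <- f$fwhm
  }
  ok <- !is.na(fwhms)
  if (!any(ok)) {
    stop(sprintf(
      "no successful edge fits (%d profiles attempted, %d flagged or failed)",
      n_profiles, sum(!ok)
    ))
  }
  structure(
    list(
      mean_fwhm = mean(fwhms[ok]),
      std_fwhm = if (sum(ok) > 1L) stats::sd(fwhms[ok]) else 0,
      n_profiles = sum(ok),
      n_flagged = sum(!ok),
      fits = fits
    ),
    class = "fwhm_summary"
  )
}

#' @export
print.fwhm_summary <- function(x, ...) {
  cat(sprintf(
    "<fwhm_summary> FWHM = %.4f +/- %.4f px over %d profiles (%d excluded)\n",
    x$mean_fwhm, x$std_fwhm, x$n_profiles, x$n_flagged
  ))
  invisible(x)
}

#' Contrast-to-noise ratio between two ROIs
#'
#' \deqn{\mathrm{CNR} = \sqrt{2}\,\frac{\mu_A - \mu_B}
#'   {\sqrt{\sigma_A^2 + \sigma_B^2}},}
#' with means and sample standard deviations computed within the two
#' (disjoint) regions of interest. Invariant to adding a constant to the
#' image and to multiplying it by a positive constant.
#'
#' @param x A single frame (matrix) or a `frame_sequence` (then the CNR
#'   is computed per frame and summarized by its mean).
#' @param roiA,roiB Disjoint [roi_spec()]s, each of at least 4 pixels.
#' @return For a frame: an object of class `cnr_result` with `cnr`,
#'   `roiA_mean`, `roiB_mean`, `roiA_std`, `roiB_std`. For a sequence:
#'   the same object for the mean plus `per_frame`, the vector of
#'   per-frame CNR values.
#' @examples
#' img <- rbind(matrix(rnorm(200, 0.6, 0.05), 10),
#'              matrix(rnorm(200, 0.4, 0.05), 10))
#' cnr(img, roi_spec(0, 0, 10, 20), roi_spec(10, 0, 10, 20))
#' @export
cnr <- function(x, roiA, roiB) {
  stopifnot(inherits(roiA, "roi_spec"), inherits(roiB, "roi_spec"))
  if (roiA$height * roiA$width < 4L || roiB$height * roiB$width < 4L) {
    stop("each ROI must contain at least 4 pixels")
  }
  overlap <- !(roiA$top + roiA$height <= roiB$top ||
               roiB$top + roiB$height <= roiA$top ||
               roiA$left + roiA$width <= roiB$left ||
               roiB$left + roiB$width <= roiA$left)
  if (overlap) stop("`roiA` and `roiB` must be disjoint")

  cnr_frame <- function(fr) {
    a <- as.vector(roi_extract(fr, roiA))
    b <- as.vector(roi_extract(fr, roiB))
    pooled <- stats::sd(a)^2 + stats::sd(b)^2
    if (pooled == 0) stop("zero pooled variance: CNR undefined")
    structure(
      list(
        cnr = sqrt(2) * (mean(a) - mean(b)) / sqrt(pooled),
        roiA_mean = mean(a), roiB_mean = mean(b),
        roiA_std = stats::sd(a), roiB_std = stats::sd(b)
      ),
      class = "cnr_result"
    )
  }
  if (is.matrix(x)) return(cnr_frame(x))
  stopifnot(is_frame_sequence(x))
  per <- vapply(seq_len(x$n_frames),
                function(t) cnr_frame(get_frame(x, t))$cnr, numeric(1))
  res <- cnr_frame(get_frame(x, x$n_frames))
  res$cnr <- mean(per)
  res$per_frame <- per
  res
}

#' @export
print.cnr_result <- function(x, ...) {
  cat(sprintf("<cnr_result> CNR = %.4f (ROIA %.4g +/- %.4g, ROIB %.4g +/- %.4g)\n",
              x$cnr, x$roiA_mean, x$roiA_std, x$roiB_mean, x$roiB_std))
  invisible(x)
}

#' Reference frame from the temporal average
#'
#' For a motionless scene the pixel-wise temporal mean over many frames
#' approaches the noise-free image (residual noise variance shrinks as
#' `1/n_frames`); it serves as the reference for full-reference quality
#' indices such as [fsim()].
#'
#' @param seq A `frame_sequence` of a motionless scene.
#' @return A `height x width` matrix.
#' @export
reference_from_time_average <- function(seq) {
  stopifnot(is_frame_sequence(seq))
  colMeans(seq$frames)
}
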