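#' Temporal estimation of the noise parameters
#'
#' Estimates the expected value-variance line \eqn{\sigma^2(h) = A h + B}
#' from a motionless sequence: for every pixel, its temporal mean and
#' unbiased temporal variance are computed over all frames, and the
#' variances are regressed on the means by ordinary least squares over
#' all retained pixels. This exploits the fact that a fluoroscopy
#' detector's lag is far shorter than the frame interval, so the time
#' series of a static pixel is a set of independent draws from its local
#' noise distribution.
#'
#' @param seq A `frame_sequence` depicting a motionless scene, with at
#'   least two (recommended >= 10) frames and flat regions at several
#'   gray levels.
#' @param exclude_clipped If `TRUE`, pixels whose temporal mean lies
#'   within `clip_margin` of the global minimum or maximum pixel value of
#'   the sequence are excluded (a crude guard against digitizer
#'   saturation).
#' @param clip_margin Margin in a.u. used by `exclude_clipped`.
#' @param method `"pixels"` (default) regresses over all per-pixel
#'   `(mean, variance)` pairs; `"binned"` first averages the pairs in
#'   `n_bins` equal-width bins of the mean and regresses the bin
#'   averages.
#' @param n_bins Number of bins for `method = "binned"`.
#' @return An object of class `ev_var_fit` with fields `a_hat` (a.u.),
#'   `b_hat` (a.u.^2), `r_squared`, `n_points` and `excluded_clipped`.
#' @examples
#' ph <- make_step_sequence(step_phantom_spec(64, 64, n_frames = 60),
#'                          noise_params(43.9e-4, 0), seed = 1)
#' estimate_temporal(ph$noisy)
#' @export
estimate_temporal <- function(seq, exclude_clipped = FALSE, clip_margin = 0,
                              method = c("pixels", "binned"), n_bins = 50L) {
  stopifnot(is_frame_sequence(seq))
  method <- match.arg(method)
  n <- seq$n_frames
  if (n < 2L) stop("temporal estimation needs at least 2 frames")
  fr <- seq$frames
  m <- colMeans(fr)                                   # height x width
  v <- (colSums(fr^2) - n * m^2) / (n - 1)            # unbiased temporal var
  v <- pmax(v, 0)                                     # guard fp cancellation
  if (max(v) == 0) {
    stop("all per-pixel temporal variances are zero (noiseless sequence); ",
         "the regression is degenerate")
  }
  keep <- rep(TRUE, length(m))
  excluded <- 0L
  if (exclude_clipped) {
    lo <- min(fr)
    hi <- max(fr)
    keep <- (m > lo + clip_margin) & (m < hi - clip_margin)
    excluded <- sum(!keep)
    if (sum(keep) < 2L) stop("clipping exclusion removed almost all pixels")
  }
  mm <- as.vector(m)[keep]
  vv <- as.vector(v)[keep]
  if (method == "binned") {
    cuts <- cut(mm, breaks = n_bins)
    mm2 <- tapply(mm, cuts, mean)
    vv2 <- tapply(vv, cuts, mean)
    ok <- is.finite(mm2) & is.finite(vv2)
    mm <- as.numeric(mm2[ok])
    vv <- as.numeric(vv2[ok])
  }
  if (stats::sd(mm) == 0) {
    stop("pixel means show no spread (single flat level); a multi-level ",
         "phantom is required to identify the expected value-variance line")
  }
  fit <- stats::lm.fit(cbind(1, mm), vv)
  b_hat <- unname(fit$coefficients[1L])
  a_hat <- unname(fit$coefficients[2L])
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((vv - mean(vv))^2)
  structure(
    list(
      a_hat = a_hat, b_hat = b_hat,
      r_squared = 1 - ss_res / ss_tot,
      n_points = length(mm),
      excluded_clipped = excluded,
      method = method
    ),
    class = "ev_var_fit"
  )
}

#' @export
print.ev_var_fit <- function(x, ...) {
  cat(sprintf(
    "<ev_var_fit> A = %.6g a.u., B = %.6g a.u.^2, R^2 = %.4f (%d points%s)\n",
    x$a_hat, x$b_hat, x$r_squared, x$n_points,
    if (x$excluded_clipped > 0) {
      sprintf(", %d clipped pixels excluded", x$excluded_clipped)
    } else ""
  ))
  invisible(x)
}

# Biased (1/N) linear 2-D autocovariance of a zero-mean matrix via FFT.
# Returns a (2H-1) x (2W-1) matrix with lag (0,0) at the center.
autocov2d <- function(x) {
  h <- nrow(x)
  w <- ncol(x)
  pad <- matrix(0, 2 * h - 1, 2 * w - 1)
  pad[1:h, 1:w] <- x
  f <- stats::fft(pad)
  cc <- Re(stats::fft(f * Conj(f), inverse = TRUE)) / length(pad)
  # circular correlation of the zero-padded matrix = linear correlation;
  # rearrange so lag (0,0) sits at the center
  cc <- cc[c((h + 1):(2 * h - 1), 1:h), c((w + 1):(2 * w - 1), 1:w)]
  cc / (h * w)
}

#' Spatial autocovariance of a flat region
#'
#' Quantifies inter-pixel spatial correlation (e.g. introduced by the
#' imaging system's point spread function) that would violate the
#' whiteness assumption of the noise model. For each frame the ROI mean
#' is subtracted and the 2-D autocovariance of the ROI is computed; the
#' matrices are averaged over frames and reduced to a 1-D curve by radial
#' averaging over integer-rounded lag radii. Values are unnormalized
#' autocovariances in a.u.^2 (lag 0 is the ROI-averaged mean-square,
#' i.e. the 1/N-normalized sample variance); a lag-0-normalized view is
#' returned alongside.
#'
#' The ROI should cover a flat, uniform region: structure inside the ROI
#' shows up as long-range correlation.
#'
#' @param seq A `frame_sequence`.
#' @param roi A [roi_spec()] selecting a flat region.
#' @return An object of class `autocorr_result` with `spatial_lags`
#'   (pixels), `spatial_values` (a.u.^2), `spatial_normalized` and the
#'   `roi` used.
#' @export
spatial_autocorrelation <- function(seq, roi) {
  stopifnot(is_frame_sequence(seq))
  block <- roi_extract(seq, roi)       # (t, h, w)
  h <- dim(block)[2L]
  w <- dim(block)[3L]
  if (h < 2L || w < 2L) stop("ROI must be at least 2 x 2 for spatial lags")
  acc <- matrix(0, 2 * h - 1, 2 * w - 1)
  for (t in seq_len(dim(block)[1L])) {
    x <- matrix(block[t, , ], h, w)
    x <- x - mean(x)
    acc <- acc + autocov2d(x)
  }
  acc <- acc / dim(block)[1L]
  dy <- seq.int(-(h - 1L), h - 1L)
  dx <- seq.int(-(w - 1L), w - 1L)
  r <- round(sqrt(outer(dy^2, dx^2, `+`)))
  prof <- tapply(as.vector(acc), as.vector(r), mean)
  lags <- as.integer(names(prof))
  vals <- as.numeric(prof)
  structure(
    list(
      spatial_lags = lags, spatial_values = vals,
      spatial_normalized = if (vals[1L] > 0) vals / vals[1L] else vals,
      temporal_lags = NULL, temporal_values = NULL,
      roi = roi
    ),
    class = "autocorr_result"
  )
}

#' Temporal autocovariance of a motionless region
#'
#' Measures frame-to-frame correlation of the noise: for every ROI pixel
#' the mean-subtracted temporal autocovariance of its time series is
#' computed (1/T normalization) and the curves are averaged over all ROI
#' pixels. Lag 0 equals the ROI-averaged temporal variance; for an ideal
#' quantum-noise sequence all nonzero lags are statistically zero.
#'
#' @param seq A `frame_sequence` of a motionless scene with >= 2 frames.
#' @param roi A [roi_spec()].
#' @param max_lag Largest frame lag reported (default
#'   `min(n_frames - 1, 100)`).
#' @return An `autocorr_result` with `temporal_lags` (frames),
#'   `temporal_values` (a.u.^2) and `temporal_normalized`.
#' @export
temporal_autocorrelation <- function(seq, roi, max_lag = NULL) {
  stopifnot(is_frame_sequence(seq))
  n <- seq$n_frames
  if (n < 2L) stop("temporal autocovariance needs at least 2 frames")
  if (is.null(max_lag)) max_lag <- min(n - 1L, 100L)
  max_lag <- min(as.integer(max_lag), n - 1L)
  block <- roi_extract(seq, roi)                   # (t, h, w)
  ts <- matrix(block, nrow = n)                    # t x (h*w)
  ts <- sweep(ts, 2L, colMeans(ts))
  npad <- 2L * n
  pad <- rbind(ts, matrix(0, npad - n, ncol(ts)))
  f <- stats::mvfft(pad)
  cc <- Re(stats::mvfft(f * Conj(f), inverse = TRUE)) / npad
  vals <- rowMeans(cc[seq_len(max_lag + 1L), , drop = FALSE]) / n
  structure(
    list(
      spatial_lags = NULL, spatial_values = NULL,
      temporal_lags = 0:max_lag, temporal_values = vals,
      temporal_normalized = if (vals[1L] > 0) vals / vals[1L] else vals,
      roi = roi
    ),
    class = "autocorr_result"
  )
}

#' @export
print.autocorr_result <- function(x, ...) {
  if (!is.null(x$spatial_lags)) {
    cat(sprintf(
      "<autocorr_result> spatial, %d radial lags; var(lag 0) = %.4g a.u.^2\n",
      length(x$spatial_lags), x$spatial_values[1L]
    ))
  }
  if (!is.null(x$temporal_lags)) {
    cat(sprintf(
      "<autocorr_result> temporal, lags 0..%d; var(lag 0) = %.4g a.u.^2\n",
      max(x$temporal_lags), x$temporal_values[1L]
    ))
  }
  invisible(x)
}
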