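# FSIM: feature-similarity index for full-reference image quality
# assessment, combining phase congruency (computed with a multi-scale
# log-Gabor filter bank) with gradient magnitude (Scharr operator).

# Swap quadrants so the zero-frequency component moves from the center
# to element (1, 1) (inverse fft-shift).
ifftshift2 <- function(m) {
  h <- nrow(m)
  w <- ncol(m)
  m[c((floor(h / 2) + 1):h, 1:floor(h / 2)),
    c((floor(w / 2) + 1):w, 1:floor(w / 2))]
}

# Normalized frequency grids (radius, theta), zero frequency at (1, 1).
freq_grids <- function(rows, cols) {
  xr <- if (cols %% 2 == 1) {
    seq(-(cols - 1) / 2, (cols - 1) / 2) / (cols - 1)
  } else {
    seq(-cols / 2, cols / 2 - 1) / cols
  }
  yr <- if (rows %% 2 == 1) {
    seq(-(rows - 1) / 2, (rows - 1) / 2) / (rows - 1)
  } else {
    seq(-rows / 2, rows / 2 - 1) / rows
  }
  x <- matrix(xr, rows, cols, byrow = TRUE)
  y <- matrix(yr, rows, cols)
  radius <- ifftshift2(sqrt(x^2 + y^2))
  theta <- ifftshift2(atan2(-y, x))
  radius[1, 1] <- 1
  list(radius = radius, theta = theta)
}

# Butterworth low-pass filter in the frequency domain.
lowpass_filter <- function(rows, cols, cutoff = 0.45, n = 15) {
  g <- freq_grids(rows, cols)
  1 / (1 + (g$radius / cutoff)^(2 * n))
}

fft2 <- function(m) stats::fft(m)
ifft2 <- function(m) stats::fft(m, inverse = TRUE) / length(m)

# Phase congruency map (moment over orientations of local energy over
# summed amplitude), with scale-1-based noise-energy compensation.
phase_congruency <- function(im, nscale = 4L, norient = 4L,
                             min_wavelength = 6, mult = 2,
                             sigma_onf = 0.55, d_theta_on_sigma = 1.2,
                             k = 2, epsilon = 1e-4) {
  rows <- nrow(im)
  cols <- ncol(im)
  theta_sigma <- pi / norient / d_theta_on_sigma
  imfft <- fft2(im)
  g <- freq_grids(rows, cols)
  lp <- lowpass_filter(rows, cols)
  log_gabor <- vector("list", nscale)
  for (s in seq_len(nscale)) {
    fo <- 1 / (min_wavelength * mult^(s - 1))
    lg <- exp(-(log(g$radius / fo))^2 / (2 * log(sigma_onf)^2)) * lp
    lg[1, 1] <- 0
    log_gabor[[s]] <- lg
  }
  sin_t <- sin(g$theta)
  cos_t <- cos(g$theta)

  energy_all <- matrix(0, rows, cols)
  an_all <- matrix(0, rows, cols)
  for (o in seq_len(norient)) {
    angl <- (o - 1) * pi / norient
    ds <- sin_t * cos(angl) - cos_t * sin(angl)
    dc <- cos_t * cos(angl) + sin_t * sin(angl)
    dtheta <- abs(atan2(ds, dc))
    spread <- exp(-dtheta^2 / (2 * theta_sigma^2))

    sum_e <- matrix(0, rows, cols)
    sum_o <- matrix(0, rows, cols)
    sum_an <- matrix(0, rows, cols)
    eo <- vector("list", nscale)
    ifft_filters <- vector("list", nscale)
    em_n <- 0
    for (s in seq_len(nscale)) {
      filt <- log_gabor[[s]] * spread
      ifft_filters[[s]] <- Re(ifft2(filt)) * sqrt(rows * cols)
      eo[[s]] <- ifft2(imfft * filt)
      an <- Mod(eo[[s]])
      sum_an <- sum_an + an
      sum_e <- sum_e + Re(eo[[s]])
      sum_o <- sum_o + Im(eo[[s]])
      if (s == 1L) em_n <- sum(filt^2)
    }
    x_energy <- sqrt(sum_e^2 + sum_o^2) + epsilon
    mean_e <- sum_e / x_energy
    mean_o <- sum_o / x_energy
    energy <- matrix(0, rows, cols)
    for (s in seq_len(nscale)) {
      e <- Re(eo[[s]])
      od <- Im(eo[[s]])
      energy <- energy + e * mean_e + od * mean_o -
        abs(e * mean_o - od * mean_e)
    }
    # noise-energy threshold from the smallest-scale amplitude statistics
    median_e2n <- stats::median(Mod(eo[[1]])^2)
    mean_e2n <- median_e2n / log(2)
    noise_power <- mean_e2n / em_n
    est_sum_an2 <- matrix(0, rows, cols)
    for (s in seq_len(nscale)) {
      est_sum_an2 <- est_sum_an2 + ifft_filters[[s]]^2
    }
    est_sum_aiaj <- matrix(0, rows, cols)
    for (si in seq_len(nscale - 1)) {
      for (sj in seq.int(si + 1, nscale)) {
        est_sum_aiaj <- est_sum_aiaj +
          ifft_filters[[si]] * ifft_filters[[sj]]
      }
    }
    est_noise_energy2 <- 2 * noise_power * sum(est_sum_an2) +
      4 * noise_power * sum(est_sum_aiaj)
    tau <- sqrt(est_noise_energy2 / 2)
    est_noise_energy <- tau * sqrt(pi / 2)
    est_noise_sigma <- sqrt((2 - pi / 2) * tau^2)
    t_thr <- (est_noise_energy + k * est_noise_sigma) / 1.7
    energy <- pmax(energy - t_thr, 0)

    energy_all <- energy_all + energy
    an_all <- an_all + sum_an
  }
  energy_all / (an_all + epsilon)
}

# 2-D convolution, zero-padded, 'same' size (kernel is flipped, i.e.
# true convolution).
conv2_same <- function(x, kern) {
  kh <- nrow(kern)
  kw <- ncol(kern)
  h <- nrow(x)
  w <- ncol(x)
  kern <- kern[kh:1, kw:1, drop = FALSE]   # flip -> correlate
  cy <- (kh + 1) %/% 2
  cx <- (kw + 1) %/% 2
  out <- matrix(0, h, w)
  for (u in seq_len(kh)) {
    for (v in seq_len(kw)) {
      kv <- kern[u, v]
      if (kv == 0) next
      dy <- u - cy
      dx <- v - cx
      sr <- max(1, 1 + dy):min(h, h + dy)
      sc <- max(1, 1 + dx):min(w, w + dx)
      out[sr - dy, sc - dx] <- out[sr - dy, sc - dx] + kv * x[sr, sc]
    }
  }
  out
}

scharr_gradient <- function(x) {
  dx <- matrix(c(3, 10, 3, 0, 0, 0, -3, -10, -3), 3, 3) / 16
  gx <- conv2_same(x, dx)
  gy <- conv2_same(x, t(dx))
  sqrt(gx^2 + gy^2)
}

#' FSIM feature-similarity index
#'
#' Full-reference image quality index combining two low-level features
#' the human visual system is sensitive to: phase congruency (computed
#' with a 4-scale, 4-orientation log-Gabor filter bank, with noise
#' compensation) as the primary feature and Scharr gradient magnitude as
#' secondary. Per-pixel similarity maps of the two features are
#' multiplied and pooled with the pointwise maximum phase congruency as
#' weight:
#' \deqn{\mathrm{FSIM} = \frac{\sum_x S_{PC}(x)\,S_G(x)\,PC_m(x)}
#'   {\sum_x PC_m(x)}.}
#'
#' Both inputs are jointly affinely rescaled to a 0-255 dynamic range
#' before evaluation (so the index is invariant to a common affine gray
#' rescaling) and, for large images, downsampled by the standard factor
#' `max(1, round(min(dim) / 256))` after box averaging.
#'
#' @param test,reference Equal-sized numeric matrices; `reference` must
#'   be nonconstant.
#' @return An object of class `fsim_result` with `fsim` in `[0, 1]` and
#'   `parameters`, the record of all constants used.
#' @examples
#' ref <- matrix(rep(sin(seq(0, 6 * pi, length.out = 64)), 64), 64, 64)
#' fsim(ref + 0.1 * rnorm(length(ref)), ref)
#' @export
fsim <- function(test, reference) {
  if (!is.matrix(test) || !is.matrix(reference)) {
    stop("`test` and `reference` must be matrices")
  }
  if (!all(dim(test) == dim(reference))) {
    stop(sprintf("shape mismatch: %d x %d vs %d x %d",
                 nrow(test), ncol(test), nrow(reference), ncol(reference)))
  }
  rng <- range(c(test, reference))
  if (diff(range(reference)) == 0) {
    stop("`reference` is constant: FSIM undefined")
  }
  scale <- 255 / (rng[2] - rng[1])
  i1 <- (test - rng[1]) * scale
  i2 <- (reference - rng[1]) * scale

  f <- max(1, round(min(dim(i1)) / 256))
  if (f > 1) {
    avek <- matrix(1 / f^2, f, f)
    i1 <- conv2_same(i1, avek)[seq(1, nrow(i1), by = f),
                               seq(1, ncol(i1), by = f)]
    i2 <- conv2_same(i2, avek)[seq(1, nrow(i2), by = f),
                               seq(1, ncol(i2), by = f)]
  }

  pc1 <- phase_congruency(i1)
  pc2 <- phase_congruency(i2)
  g1 <- scharr_gradient(i1)
  g2 <- scharr_gradient(i2)

  t1 <- 0.85
  t2 <- 160
  s_pc <- (2 * pc1 * pc2 + t1) / (pc1^2 + pc2^2 + t1)
  s_g <- (2 * g1 * g2 + t2) / (g1^2 + g2^2 + t2)
  pcm <- pmax(pc1, pc2)
  value <- sum(s_pc * s_g * pcm) / sum(pcm)

  structure(
    list(
      fsim = value,
      parameters = list(
        nscale = 4L, norient = 4L, min_wavelength = 6, mult = 2,
        sigma_onf = 0.55, d_theta_on_sigma = 1.2, k = 2,
        T1 = t1, T2 = t2, dynamic_range = 255,
        downsample_factor = f
      )
    ),
    class = "fsim_result"
  )
}

#' @export
print.fsim_result <- function(x, ...) {
  cat(sprintf("<fsim_result> FSIM = %.4f\n", x$fsim))
  invisible(x)
}
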