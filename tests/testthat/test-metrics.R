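test_that("edge_profile validates spacing and length", {
  expect_s3_class(edge_profile(c(1, 2, 3, 4)), "edge_profile")
  expect_error(edge_profile(c(1, 2, 3)), "length")
  expect_error(edge_profile(1:4, positions = c(0, 1, 1, 2)), "increasing")
  expect_error(edge_profile(1:4, positions = c(0, 1, 2, 4)), "uniform")
})

test_that("fit_edge recovers exact erf-edge parameters to 1e-6", {
  x <- 0:30
  for (d_true in c(0.5, 1, 2, 5)) {
    for (c_true in c(8, 10.5, 12)) {
      y <- 0.2 + 0.3 * edge_psi(x, c_true, d_true)
      f <- fit_edge(edge_profile(y, x))
      expect_true(f$converged)
      expect_false(f$flagged)
      expect_lt(abs(f$d - d_true), 1e-6)
      expect_lt(abs(f$c - c_true), 1e-6)
      expect_lt(abs(f$offset - 0.2), 1e-6)
      expect_lt(abs(f$amplitude - 0.3), 1e-6)
      expect_gt(f$r_squared, 1 - 1e-10)
      # FWHM is stored exactly as 2.355 * d
      expect_identical(f$fwhm, 2.355 * f$d)
    }
  }
})

test_that("a rising edge fits with negative amplitude and the same spread", {
  x <- 0:24
  fall <- fit_edge(edge_profile(0.1 + 0.4 * edge_psi(x, 12, 1.5), x))
  rise <- fit_edge(edge_profile(0.5 - 0.4 * edge_psi(x, 12, 1.5), x))
  expect_lt(abs(fall$d - rise$d), 1e-6)
  expect_lt(abs(fall$amplitude + rise$amplitude), 1e-6)
})

test_that("fit_edge is symmetric under profile mirroring", {
  x <- 0:24
  y <- 0.3 + 0.2 * edge_psi(x, 10, 2)
  f1 <- fit_edge(edge_profile(y, x))
  f2 <- fit_edge(edge_profile(rev(y), x))
  expect_lt(abs(f1$d - f2$d), 1e-6)
  expect_lt(abs(f2$c - (24 - f1$c)), 1e-6)
})

test_that("degenerate profiles are rejected or flagged, not mis-fitted", {
  expect_error(fit_edge(rep(0.5, 10)), "flat")
  # pure white noise: either non-converged or flagged by the R^2 floor
  set.seed(30)
  f <- fit_edge(rnorm(20))
  expect_true(!f$converged || f$flagged)
})

test_that("fwhm_over_profiles averages row-wise fits", {
  x <- 0:19
  prof <- 0.2 + 0.5 * edge_psi(x, 9, 1.2)
  block <- matrix(prof, nrow = 12, ncol = 20, byrow = TRUE)
  s <- fwhm_over_profiles(block, roi_spec(0, 0, 12, 20))
  expect_equal(s$mean_fwhm, 2.355 * 1.2, tolerance = 1e-6)
  expect_equal(s$std_fwhm, 0, tolerance = 1e-9)
  expect_equal(s$n_profiles, 12)
  expect_equal(s$n_flagged, 0)
  # vertical direction on the transposed block gives the same answer
  sv <- fwhm_over_profiles(t(block), roi_spec(0, 0, 20, 12),
                           direction = "vertical")
  expect_equal(sv$mean_fwhm, s$mean_fwhm)
  expect_error(fwhm_over_profiles(block, roi_spec(0, 0, 12, 20),
                                  n_profiles = 13), "only 12")
  # sequences require an explicit frame
  seq3 <- frame_sequence(array(rep(block, each = 3), dim = c(3, 12, 20)))
  expect_error(fwhm_over_profiles(seq3, roi_spec(0, 0, 12, 20)), "frame")
  sf <- fwhm_over_profiles(seq3, roi_spec(0, 0, 12, 20), frame = 2)
  expect_equal(sf$mean_fwhm, s$mean_fwhm)
})

test_that("flat rows are excluded and counted, not fatal", {
  x <- 0:19
  block <- matrix(0.2 + 0.5 * edge_psi(x, 9, 1.2), 6, 20, byrow = TRUE)
  block[4, ] <- 0.35
  s <- fwhm_over_profiles(block, roi_spec(0, 0, 6, 20))
  expect_equal(s$n_profiles, 5)
  expect_equal(s$n_flagged, 1)
  expect_equal(s$mean_fwhm, 2.355 * 1.2, tolerance = 1e-6)
})

test_that("spatial box averaging widens the fitted edge", {
  x <- 0:39
  frame <- matrix(0.2 + 0.5 * edge_psi(x, 20, 1), 30, 40, byrow = TRUE)
  s <- frame_sequence(array(rep(frame, each = 5), dim = c(5, 30, 40)))
  roi <- roi_spec(5, 8, 20, 24)
  raw <- fwhm_over_profiles(get_frame(s, 1), roi)
  blurred <- moving_average(s, mask_spec(5, 1))
  ma <- fwhm_over_profiles(blurred, roi, frame = 3)
  expect_equal(raw$mean_fwhm, 2.355, tolerance = 1e-6)
  expect_gt(ma$mean_fwhm, 1.5 * raw$mean_fwhm)
})

test_that("cnr reproduces exactly constructed sample statistics", {
  set.seed(31)
  z1 <- as.vector(scale(rnorm(200)))  # mean 0, sample sd exactly 1
  z2 <- as.vector(scale(rnorm(200)))
  roiA <- roi_spec(0, 0, 10, 20)
  roiB <- roi_spec(10, 0, 10, 20)
  img1 <- rbind(matrix(1 + z1, 10, 20), matrix(z2, 10, 20))
  expect_equal(cnr(img1, roiA, roiB)$cnr, 1)
  img4 <- rbind(matrix(4 + z1, 10, 20), matrix(z2, 10, 20))
  r4 <- cnr(img4, roiA, roiB)
  expect_equal(r4$cnr, 4)
  expect_equal(r4$roiA_mean, 4)
  expect_equal(r4$roiA_std, 1)
})

test_that("cnr is invariant to affine rescaling and antisymmetric", {
  set.seed(32)
  img <- matrix(rnorm(400, 0.5, 0.1), 20, 20)
  img[1:10, ] <- img[1:10, ] + 0.2
  roiA <- roi_spec(0, 0, 10, 20)
  roiB <- roi_spec(10, 0, 10, 20)
  base <- cnr(img, roiA, roiB)$cnr
  expect_equal(cnr(3 * img + 0.7, roiA, roiB)$cnr, base)
  expect_equal(cnr(img, roiB, roiA)$cnr, -base)
})

test_that("cnr validates its ROIs and variance", {
  img <- matrix(runif(400), 20, 20)
  expect_error(cnr(img, roi_spec(0, 0, 10, 20), roi_spec(5, 0, 10, 20)),
               "disjoint")
  expect_error(cnr(img, roi_spec(0, 0, 1, 2), roi_spec(10, 0, 4, 4)),
               "at least 4")
  flat <- matrix(0.5, 20, 20)
  expect_error(cnr(flat, roi_spec(0, 0, 4, 4), roi_spec(10, 10, 4, 4)),
               "zero pooled variance")
})

test_that("sequence cnr is the mean of per-frame values", {
  np <- noise_params(0, 1e-3)
  cl <- matrix(0.4, 16, 16)
  cl[, 1:8] <- 0.6
  s <- sample_noisy(frame_sequence(array(rep(cl, each = 20),
                                         dim = c(20, 16, 16))),
                    np, "gaussian_approx", seed = 33)
  roiA <- roi_spec(4, 0, 8, 8)
  roiB <- roi_spec(4, 8, 8, 8)
  r <- cnr(s, roiA, roiB)
  expect_length(r$per_frame, 20)
  expect_equal(r$cnr, mean(r$per_frame))
  expect_equal(cnr(get_frame(s, 7), roiA, roiB)$cnr, r$per_frame[7])
})

test_that("nvca filtering improves the two-region CNR", {
  np <- paper_noise()
  cl <- matrix(0.3, 24, 24)
  cl[, 1:12] <- 0.7
  s <- sample_noisy(frame_sequence(array(rep(cl, each = 30),
                                         dim = c(30, 24, 24))),
                    np, "poisson_gaussian", seed = 34)
  filt <- nvca_filter(s, filter_config(mask_spec(3, 3), 2, noise = np))
  roiA <- roi_spec(6, 2, 12, 8)
  roiB <- roi_spec(6, 14, 12, 8)
  expect_gt(cnr(filt, roiA, roiB)$cnr, cnr(s, roiA, roiB)$cnr)
})

test_that("the temporal average converges to the clean frame", {
  cl <- matrix(0.5, 12, 12)
  const <- frame_sequence(array(rep(cl, each = 8), dim = c(8, 12, 12)))
  expect_identical(reference_from_time_average(const), cl)
  np <- noise_params(0, 4e-4)  # sd 0.02
  err_rms <- function(n, seed) {
    s <- sample_noisy(frame_sequence(array(rep(cl, each = n),
                                           dim = c(n, 12, 12))),
                      np, "gaussian_approx", seed = seed)
    sqrt(mean((reference_from_time_average(s) - cl)^2))
  }
  expect_lt(err_rms(400, 35), 2 * 0.02 / sqrt(400))
  # residual noise shrinks with the number of frames
  expect_lt(err_rms(400, 36), err_rms(25, 36))
})
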