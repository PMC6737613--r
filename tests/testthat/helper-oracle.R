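# Independent brute-force reference for the conditioned average: a literal
# per-pixel transcription of the filter definition. Accumulation order
# (i, then j, then h) matches the production kernel so results are
# comparable bit for bit in double precision.
nvca_oracle <- function(frames, thresh, n_spatial, k_temporal) {
  d <- dim(frames)
  nt <- d[1]; nh <- d[2]; nw <- d[3]
  r <- (n_spatial - 1L) %/% 2L
  scalar_t <- length(thresh) == 1L
  out <- array(0, d)
  for (t in seq_len(nt)) for (y in seq_len(nh)) for (x in seq_len(nw)) {
    cc <- frames[t, y, x]
    tt <- if (scalar_t) thresh else thresh[t, y, x]
    s <- 0
    n <- 0L
    for (i in 0:(k_temporal - 1L)) {
      ti <- t - i
      if (ti < 1L) next
      for (j in (-r):r) {
        yj <- y - j
        if (yj < 1L || yj > nh) next
        for (h in (-r):r) {
          xh <- x - h
          if (xh < 1L || xh > nw) next
          v <- frames[ti, yj, xh]
          if (abs(v - cc) <= tt) {
            s <- s + (v - cc)
            n <- n + 1L
          }
        }
      }
    }
    out[t, y, x] <- cc + s / n
  }
  out
}

# Random small sequence for oracle comparisons.
random_sequence <- function(nt, nh, nw, lo = 0, hi = 1) {
  frame_sequence(array(stats::runif(nt * nh * nw, lo, hi),
                       dim = c(nt, nh, nw)))
}

# Paper-magnitude quantum-noise parameters (temporal estimate, B clamped
# to 0 for the Poisson mixture).
paper_noise <- function() noise_params(43.90e-4, 0)

# Moving-edge FWHM for one filter output of a moving-insert phantom:
# mean over 10 consecutive profiles across the insert's leading edge at
# the given frame.
moving_edge_fwhm <- function(seq, ph, frame, n_profiles = 10) {
  fwhm_over_profiles(seq, ph$edge_roi_per_frame[[frame]],
                     n_profiles = n_profiles, direction = "horizontal",
                     frame = frame)$mean_fwhm
}
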