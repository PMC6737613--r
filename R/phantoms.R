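#' Step phantom specification
#'
#' Describes a motionless step phantom for noise characterization: a set
#' of concentric, strictly nested squares of decreasing size over a
#' uniform background, each square one gray level - the digital analogue
#' of a stack of square aluminum sheets (thicker stack, darker region)
#' imaged by a fluoroscope. Every pixel of the clean frame belongs to
#' exactly one flat region, giving the multi-level flat scene that the
#' temporal expected value-variance regression needs.
#'
#' Defaults emulate the physical reference object: seven sheets with
#' side lengths in the ratio 30:26:22:18:14:10:6 (scaled into the
#' frame), frames of 328 x 333 px, 712 frames, and eight gray levels
#' (background + 7 steps) geometrically spaced in `[0.1, 0.8]` a.u.
#' Two small dark discs ("screws") can optionally be added near the
#' center; they are decorations, labeled 0 in the region map and
#' excluded from region statistics.
#'
#' @param frame_height,frame_width Frame size in pixels.
#' @param step_levels Clean gray levels of the nested squares, ordered
#'   outermost to innermost (a.u.).
#' @param step_edge_fractions Side lengths of the nested squares as
#'   fractions of `min(frame_height, frame_width)`, same order and
#'   length as `step_levels`, strictly decreasing.
#' @param background_level Clean background gray level (a.u.).
#' @param include_screws Add two dark discs near the center.
#' @param n_frames Number of frames.
#' @return An object of class `step_phantom_spec`.
#' @export
step_phantom_spec <- function(frame_height = 328L, frame_width = 333L,
                              step_levels = NULL,
                              step_edge_fractions = c(30, 26, 22, 18, 14, 10, 6) / 32,
                              background_level = NULL,
                              include_screws = FALSE,
                              n_frames = 712L) {
  if (is.null(step_levels) || is.null(background_level)) {
    # background + one level per sheet, geometric from 0.8 down to 0.1
    k <- length(step_edge_fractions)
    lv <- 0.8 * (0.1 / 0.8)^((0:k) / k)
    if (is.null(background_level)) background_level <- lv[1L]
    if (is.null(step_levels)) step_levels <- lv[-1L]
  }
  if (length(step_levels) != length(step_edge_fractions)) {
    stop("`step_levels` and `step_edge_fractions` must have equal length")
  }
  if (any(diff(step_edge_fractions) >= 0) || any(step_edge_fractions <= 0) ||
      any(step_edge_fractions > 1)) {
    stop("`step_edge_fractions` must be strictly decreasing in (0, 1]")
  }
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L) stop("`n_frames` must be >= 1")
  structure(
    list(
      frame_height = as.integer(frame_height),
      frame_width = as.integer(frame_width),
      step_levels = as.numeric(step_levels),
      step_edge_fractions = as.numeric(step_edge_fractions),
      background_level = as.numeric(background_level),
      include_screws = isTRUE(include_screws),
      n_frames = n_frames
    ),
    class = "step_phantom_spec"
  )
}

# Clean frame + integer region map for a step phantom spec.
# Region labels: 1 = background, 1 + k = k-th square (outermost first),
# 0 = screw decoration (excluded from statistics).
step_clean_frame <- function(spec) {
  h <- spec$frame_height
  w <- spec$frame_width
  img <- matrix(spec$background_level, h, w)
  map <- matrix(1L, h, w)
  base <- min(h, w)
  for (k in seq_along(spec$step_levels)) {
    side <- round(spec$step_edge_fractions[k] * base)
    top <- floor((h - side) / 2)
    left <- floor((w - side) / 2)
    rows <- (top + 1):(top + side)
    cols <- (left + 1):(left + side)
    img[rows, cols] <- spec$step_levels[k]
    map[rows, cols] <- k + 1L
  }
  if (spec$include_screws) {
    r <- max(2L, round(0.02 * base))
    cy <- round(h / 2)
    for (cx in round(w / 2) + c(-3L, 3L) * r) {
      yy <- matrix(seq_len(h), h, w)
      xx <- matrix(seq_len(w), h, w, byrow = TRUE)
      disc <- (yy - cy)^2 + (xx - cx)^2 <= r^2
      img[disc] <- 0.05
      map[disc] <- 0L
    }
  }
  list(frame = img, region_map = map)
}

#' Generate a step phantom sequence
#'
#' Renders the clean scene of a [step_phantom_spec()] (identical in every
#' frame), corrupts it with signal-dependent noise via [sample_noisy()],
#' and returns both together with an integer region map labeling each
#' flat region (1 = background, 2..k+1 = squares outermost to innermost,
#' 0 = screw decorations) for downstream ROI selection.
#'
#' @param spec A [step_phantom_spec()].
#' @param noise A [noise_params()] object; all step levels must lie in
#'   its declared range.
#' @param mode Sampling mode passed to [sample_noisy()].
#' @param seed Optional integer seed for reproducible noise.
#' @return A list with `clean` and `noisy` (`frame_sequence`s) and
#'   `region_map` (integer matrix).
#' @export
make_step_sequence <- function(spec, noise,
                               mode = c("gaussian_approx", "poisson_gaussian"),
                               seed = NULL) {
  stopifnot(inherits(spec, "step_phantom_spec"),
            inherits(noise, "noise_params"))
  mode <- match.arg(mode)
  lv <- c(spec$background_level, spec$step_levels)
  if (min(lv) < noise$level_range[1] || max(lv) > noise$level_range[2]) {
    stop("step levels fall outside the noise parameters' declared level range")
  }
  cf <- step_clean_frame(spec)
  frames <- array(rep(cf$frame, each = spec$n_frames),
                  dim = c(spec$n_frames, spec$frame_height, spec$frame_width))
  clean <- frame_sequence(frames, metadata = list(phantom = "step"))
  noisy <- sample_noisy(clean, noise, mode = mode, seed = seed)
  list(clean = clean, noisy = noisy, region_map = cf$region_map)
}

#' Moving-insert phantom specification
#'
#' Describes the fully digital motion-blur test scene: a uniform
#' background carrying a few motionless circular objects of different
#' sizes and contrasts, plus a rectangular radiopaque insert translating
#' horizontally left to right at an integer number of pixels per frame.
#' All edges are ideal - each pixel is wholly inside or outside an
#' object, with no anti-aliasing - so the ground-truth edge position is
#' exact in every frame. The insert's clean level is
#' `insert_contrast_ratio * background_level` (default 0.46, i.e. the
#' insert-to-background mean ratio is 46%).
#'
#' Only integer speeds are supported: a fractional speed would break the
#' ideal-edge construction.
#'
#' @param frame_height,frame_width Frame size in pixels.
#' @param background_level Clean background level (a.u.).
#' @param circles List of motionless discs, each
#'   `list(center = c(row, col), radius, level)` in 0-based pixel
#'   coordinates. `NULL` gives three default discs in the upper part of
#'   the frame, clear of the insert's path.
#' @param insert_size `c(height, width)` of the rectangle in pixels.
#' @param insert_contrast_ratio Clean insert mean / clean background
#'   mean.
#' @param speed Integer pixels per frame, horizontal, left to right.
#' @param start_col 0-based column of the insert's left edge at frame 1.
#' @param n_frames Number of frames.
#' @return An object of class `moving_insert_spec`.
#' @export
moving_insert_spec <- function(frame_height = 256L, frame_width = 256L,
                               background_level = 0.5,
                               circles = NULL,
                               insert_size = c(64L, 40L),
                               insert_contrast_ratio = 0.46,
                               speed = 1L, start_col = 20L,
                               n_frames = 60L) {
  if (speed != round(speed)) {
    stop("only integer speeds (px/frame) are supported: a fractional speed ",
         "would break the ideal-edge construction")
  }
  if (is.null(circles)) {
    circles <- list(
      list(center = c(40, 60), radius = 18, level = 0.75),
      list(center = c(40, 128), radius = 12, level = 0.35),
      list(center = c(40, 196), radius = 7, level = 0.62)
    )
  }
  structure(
    list(
      frame_height = as.integer(frame_height),
      frame_width = as.integer(frame_width),
      background_level = as.numeric(background_level),
      circles = circles,
      insert_size = as.integer(insert_size),
      insert_contrast_ratio = as.numeric(insert_contrast_ratio),
      speed = as.integer(speed),
      start_col = as.integer(start_col),
      n_frames = as.integer(n_frames)
    ),
    class = "moving_insert_spec"
  )
}

#' Generate a moving-insert phantom sequence
#'
#' Renders the clean digital phantom of a [moving_insert_spec()], adds
#' signal-dependent noise, and returns per-frame ROIs tracking the
#' insert's leading (right) vertical edge for FWHM evaluation. Each edge
#' ROI covers the central insert rows - the top and bottom quarters are
#' excluded to stay clear of the corners - and a band of columns
#' centered on the edge, so consecutive horizontal profiles through the
#' ROI each cross the moving edge at its exact ground-truth position.
#'
#' The default noise for this phantom elsewhere in the package is the
#' quantum-noise level estimated temporally on real fluoroscopy
#' (`A = 43.90e-4` a.u., `B = 0`).
#'
#' @param spec A [moving_insert_spec()].
#' @param noise A [noise_params()] object.
#' @param mode Sampling mode passed to [sample_noisy()].
#' @param seed Optional integer seed.
#' @return A list with `clean`, `noisy` (`frame_sequence`s),
#'   `edge_roi_per_frame` (list of [roi_spec()], one per frame),
#'   `edge_col_per_frame` (0-based column of the first background pixel
#'   right of the insert) and `geometry` (insert rows/cols per frame and
#'   background mask).
#' @export
make_moving_insert_sequence <- function(spec, noise,
                                        mode = c("poisson_gaussian",
                                                 "gaussian_approx"),
                                        seed = NULL) {
  stopifnot(inherits(spec, "moving_insert_spec"),
            inherits(noise, "noise_params"))
  mode <- match.arg(mode)
  h <- spec$frame_height
  w <- spec$frame_width
  nf <- spec$n_frames
  ih <- spec$insert_size[1L]
  iw <- spec$insert_size[2L]
  insert_level <- spec$insert_contrast_ratio * spec$background_level

  # static part: background + circles
  base <- matrix(spec$background_level, h, w)
  yy <- matrix(seq_len(h) - 1L, h, w)
  xx <- matrix(seq_len(w) - 1L, h, w, byrow = TRUE)
  circle_mask <- matrix(FALSE, h, w)
  for (ci in spec$circles) {
    disc <- (yy - ci$center[1])^2 + (xx - ci$center[2])^2 <= ci$radius^2
    base[disc] <- ci$level
    circle_mask <- circle_mask | disc
  }

  ins_top <- floor((h - ih) / 2)             # 0-based
  rows <- (ins_top + 1):(ins_top + ih)       # 1-based
  left0 <- spec$start_col                    # 0-based left edge per frame

  frames <- array(0, dim = c(nf, h, w))
  edge_rois <- vector("list", nf)
  edge_cols <- integer(nf)
  margin <- max(1L, floor(ih / 4))           # corner-row exclusion
  roi_rows <- max(10L, ih - 2L * margin)     # >= 10 profiles
  pad <- 8L                                  # columns either side of edge
  lefts <- integer(nf)
  for (f in seq_len(nf)) {
    left <- left0 + spec$speed * (f - 1L)
    right <- left + iw - 1L
    if (left < 0L || right >= w) {
      stop(sprintf("insert exits the frame at frame %d (columns %d..%d)",
                   f, left, right))
    }
    lefts[f] <- left
    fr <- base
    fr[rows, (left + 1L):(right + 1L)] <- insert_level
    frames[f, , ] <- fr
    edge_cols[f] <- right + 1L               # 0-based first background col
    roi_left <- right + 1L - pad
    roi_width <- 2L * pad
    if (roi_left < 0L || roi_left + roi_width > w) {
      stop(sprintf("edge ROI exits the frame at frame %d", f))
    }
    edge_rois[[f]] <- roi_spec(ins_top + margin, roi_left,
                               roi_rows, roi_width)
  }

  clean <- frame_sequence(frames, metadata = list(phantom = "moving_insert"))
  noisy <- sample_noisy(clean, noise, mode = mode, seed = seed)
  background_mask <- !circle_mask            # excludes circles, not insert
  list(
    clean = clean, noisy = noisy,
    edge_roi_per_frame = edge_rois,
    edge_col_per_frame = edge_cols,
    geometry = list(
      insert_rows = rows, insert_left_per_frame = lefts,
      insert_height = ih, insert_width = iw,
      insert_level = insert_level,
      circle_mask = circle_mask,
      background_mask = background_mask
    )
  )
}
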