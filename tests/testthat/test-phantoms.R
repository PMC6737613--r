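test_that("step phantom spec validates its geometry", {
  expect_error(step_phantom_spec(step_edge_fractions = c(0.5, 0.6)),
               "strictly decreasing")
  expect_error(step_phantom_spec(step_levels = c(0.5, 0.4),
                                 step_edge_fractions = c(0.5)),
               "equal length")
  expect_error(step_phantom_spec(n_frames = 0), ">= 1")
  spec <- step_phantom_spec()
  expect_equal(spec$frame_height, 328L)
  expect_equal(spec$frame_width, 333L)
  expect_equal(spec$n_frames, 712L)
  expect_length(spec$step_levels, 7)
  # background + 7 steps: geometric ladder from 0.8 down to 0.1
  lv <- c(spec$background_level, spec$step_levels)
  expect_equal(lv[1], 0.8)
  expect_equal(lv[8], 0.1)
  expect_equal(diff(log(lv)), rep(log(0.1 / 0.8) / 7, 7))
})

test_that("step phantom regions match the nested-square pixel counts", {
  spec <- step_phantom_spec(64, 80, n_frames = 1)
  ph <- make_step_sequence(spec, noise_params(0, 0), seed = 1)
  map <- ph$region_map
  expect_setequal(sort(unique(as.vector(map))), 1:8)
  sides <- round(spec$step_edge_fractions * 64)
  counts <- tabulate(map, nbins = 8)
  # innermost square is intact; each outer square is an annulus
  expect_equal(counts[8], sides[7]^2)
  for (k in 1:6) expect_equal(counts[k + 1], sides[k]^2 - sides[k + 1]^2)
  expect_equal(counts[1], 64 * 80 - sides[1]^2)
  # region map labels agree with the clean pixel values
  lv <- c(spec$background_level, spec$step_levels)
  fr <- get_frame(ph$clean, 1)
  for (k in 1:8) expect_true(all(fr[map == k] == lv[k]))
})

test_that("zero-noise step sequence reproduces the clean scene exactly", {
  ph <- make_step_sequence(step_phantom_spec(32, 32, n_frames = 4),
                           noise_params(0, 0), seed = 5)
  expect_identical(ph$noisy$frames, ph$clean$frames)
  # every frame is the same clean scene
  expect_identical(get_frame(ph$clean, 1), get_frame(ph$clean, 4))
})

test_that("noisy step regions have the specified mean and variance", {
  np <- paper_noise()
  spec <- step_phantom_spec(96, 96, n_frames = 200)
  ph <- make_step_sequence(spec, np, mode = "poisson_gaussian", seed = 9)
  lv <- c(spec$background_level, spec$step_levels)
  # time-by-pixel matrix view (column-major: t fastest)
  m <- matrix(ph$noisy$frames, nrow = spec$n_frames)
  for (k in c(1, 4, 8)) {
    px <- m[, as.vector(ph$region_map == k)]
    n <- length(px)
    v <- np$a_gain * lv[k]
    expect_lt(abs(mean(px) - lv[k]), 4 * sqrt(v / n))
    expect_lt(abs(stats::var(as.vector(px)) - v), 4 * v * sqrt(2 / n))
  }
})

test_that("step generation is deterministic in the seed", {
  np <- noise_params(2e-3, 1e-5)
  spec <- step_phantom_spec(24, 24, n_frames = 3)
  a <- make_step_sequence(spec, np, seed = 7)
  b <- make_step_sequence(spec, np, seed = 7)
  c <- make_step_sequence(spec, np, seed = 8)
  expect_identical(a$noisy$frames, b$noisy$frames)
  expect_false(identical(a$noisy$frames, c$noisy$frames))
})

test_that("step levels must lie inside the noise level range", {
  np <- noise_params(1e-3, 1e-5, level_range = c(0, 0.5))
  expect_error(make_step_sequence(step_phantom_spec(24, 24, n_frames = 2), np),
               "level range")
})

test_that("optional screws are labeled 0 and excluded from regions", {
  spec <- step_phantom_spec(64, 64, include_screws = TRUE, n_frames = 1)
  ph <- make_step_sequence(spec, noise_params(0, 0), seed = 1)
  expect_true(any(ph$region_map == 0))
  expect_true(all(get_frame(ph$clean, 1)[ph$region_map == 0] == 0.05))
})

test_that("moving insert spec rejects non-integer speeds", {
  expect_error(moving_insert_spec(speed = 1.5), "integer speeds")
  expect_s3_class(moving_insert_spec(speed = 3), "moving_insert_spec")
})

test_that("the clean insert-to-background contrast is exactly 46%", {
  spec <- moving_insert_spec(n_frames = 5)
  ph <- make_moving_insert_sequence(spec, noise_params(0, 0),
                                    mode = "gaussian_approx", seed = 1)
  g <- ph$geometry
  fr <- get_frame(ph$clean, 3)
  cols <- (g$insert_left_per_frame[3] + 1):(g$insert_left_per_frame[3] +
                                              g$insert_width)
  insert_px <- fr[g$insert_rows, cols]
  bg_px <- fr[-g$insert_rows, ][g$background_mask[-g$insert_rows, ]]
  expect_equal(mean(insert_px) / mean(bg_px), 0.46)
  expect_true(all(insert_px == 0.46 * 0.5))
  expect_true(all(bg_px == 0.5))
})

test_that("zero speed gives a static scene; speed shifts the edge exactly", {
  np <- noise_params(0, 0)
  st <- make_moving_insert_sequence(moving_insert_spec(speed = 0,
                                                       n_frames = 6),
                                    np, mode = "gaussian_approx")
  for (f in 2:6) {
    expect_identical(st$clean$frames[f, , ], st$clean$frames[1, , ])
  }
  expect_equal(st$edge_col_per_frame, rep(st$edge_col_per_frame[1], 6))
  mv <- make_moving_insert_sequence(moving_insert_spec(speed = 2,
                                                       n_frames = 10),
                                    np, mode = "gaussian_approx")
  expect_equal(diff(mv$edge_col_per_frame), rep(2, 9))
  expect_equal(diff(mv$geometry$insert_left_per_frame), rep(2L, 9))
  # frame 2 equals frame 1 shifted two columns inside the insert band
  r <- mv$geometry$insert_rows
  expect_identical(mv$clean$frames[2, r, 23:256],
                   mv$clean$frames[1, r, 21:254])
})

test_that("the insert and its edge ROI may not exit the frame", {
  # insert itself out of bounds from the first frame
  expect_error(
    make_moving_insert_sequence(moving_insert_spec(start_col = 230,
                                                   n_frames = 5),
                                noise_params(0, 0), mode = "gaussian_approx"),
    "insert exits the frame at frame 1"
  )
  # at speed 3 the edge ROI's right pad leaves the frame at frame 64
  expect_error(
    make_moving_insert_sequence(moving_insert_spec(speed = 3, n_frames = 100),
                                noise_params(0, 0), mode = "gaussian_approx"),
    "exits the frame at frame 64"
  )
})

test_that("edge ROIs track the ground-truth edge and avoid the corners", {
  spec <- moving_insert_spec(speed = 2, n_frames = 20)
  ph <- make_moving_insert_sequence(spec, noise_params(0, 0),
                                    mode = "gaussian_approx")
  g <- ph$geometry
  ins_top <- g$insert_rows[1] - 1L  # 0-based
  for (f in c(1, 10, 20)) {
    roi <- ph$edge_roi_per_frame[[f]]
    expect_gte(roi$height, 10)
    # rows strictly inside the insert, clear of both corners
    expect_gt(roi$top, ins_top)
    expect_lt(roi$top + roi$height, ins_top + g$insert_height)
    # the edge column sits inside the ROI's column span
    ec <- ph$edge_col_per_frame[f]
    expect_gte(ec, roi$left)
    expect_lt(ec, roi$left + roi$width)
    # each clean horizontal profile is an ideal step at the edge column
    block <- roi_extract(get_frame(ph$clean, f), roi)
    cols0 <- roi$left + seq_len(roi$width) - 1L  # 0-based columns
    for (r in c(1, nrow(block))) {
      expect_true(all(block[r, cols0 < ec] == g$insert_level))
      expect_true(all(block[r, cols0 >= ec] == spec$background_level))
    }
  }
})

test_that("moving-insert generation is deterministic in the seed", {
  np <- paper_noise()
  spec <- moving_insert_spec(n_frames = 4)
  a <- make_moving_insert_sequence(spec, np, seed = 3)
  b <- make_moving_insert_sequence(spec, np, seed = 3)
  expect_identical(a$noisy$frames, b$noisy$frames)
})
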