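test_that("instantaneous speed converts pixel displacement to mm/s", {
  cam <- round_cam()  # mm_per_px = 0.2434 exactly
  s <- make_series(c(100, 102, 102, 104), rep(200, 4), cam)
  expect_equal(instantaneous_speed(s, 0), 2 * 0.2434 * 30)  # 14.604
  expect_equal(instantaneous_speed(s, 1), 0)
  s2 <- make_series(c(100, 102, 104, 106), rep(200, 4), cam,
                    valid = c(TRUE, FALSE, TRUE, TRUE))
  expect_true(is.na(instantaneous_speed(s2, 0)))
  expect_true(is.na(instantaneous_speed(s2, 1)))
  expect_false(is.na(instantaneous_speed(s2, 2)))
})

test_that("segment mean speed averages defined pairs and rejects endpoints", {
  cam <- round_cam()
  v_px <- 25.7 / cam$mm_per_px / cam$fps
  s <- make_series(100 + v_px * 0:9, rep(200, 10), cam)
  seg <- make_segment("travel", 0L, 10L)
  expect_equal(segment_mean_speed(seg, s), 25.7, tolerance = 1e-12)
  expect_error(segment_mean_speed(make_segment("endpoint", 0L, 10L), s),
               "travel segments only")
  # one invalid frame: mean over the remaining defined pairs
  s3 <- make_series(c(0, 2, 4, 100, 8, 10), rep(200, 6), cam,
                    valid = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_equal(segment_mean_speed(make_segment("travel", 0L, 6L), s3),
               mean(c(2, 2, 2) * 0.2434 * 30))
})

test_that("acceleration magnitudes follow the two-speed stencil", {
  cam <- round_cam()
  # constant velocity: zero acceleration
  v_px <- 2
  s <- make_series(100 + v_px * 0:9, rep(200, 10), cam)
  expect_equal(segment_mean_acceleration(make_segment("travel", 0L, 10L), s), 0)
  # speeds 10, 20, 30 mm/s -> samples (300, 300), mean 300
  step <- c(10, 20, 30) / cam$mm_per_px / cam$fps
  xs <- c(0, cumsum(step))
  s2 <- make_series(100 + xs, rep(200, 4), cam)
  expect_equal(segment_mean_acceleration(make_segment("travel", 0L, 4L), s2),
               300, tolerance = 1e-9)
  # fewer than 4 frames: undefined
  expect_true(is.na(segment_mean_acceleration(make_segment("travel", 0L, 3L), s)))
})

test_that("mean |acceleration| of a smooth ramp matches the analytic value", {
  # full minimum-jerk movement of D mm over T s: integral of |dv/dt| is
  # 2 * v_peak, so the time-averaged |acceleration| is 3.75 * D / T^2
  cam <- ref_cam()
  D <- 100; T <- 2
  n <- T * cam$fps
  tt <- (0:n) / cam$fps
  u <- tt / T
  x_mm <- D * (10 * u^3 - 15 * u^4 + 6 * u^5)
  s <- make_series(100 + x_mm / cam$mm_per_px, rep(200, n + 1), cam)
  got <- segment_mean_acceleration(make_segment("travel", 0L, n + 1L), s)
  expect_equal(got, 3.75 * D / T^2, tolerance = 0.02)
})

test_that("percent speed error is exact and strictly increasing", {
  expect_identical(percent_speed_error(2 * 25.7), 100)
  expect_equal(percent_speed_error(51.4), 100)
  expect_identical(percent_speed_error(25.7), 0)
  expect_equal(percent_speed_error(26.985), 5)
  v <- seq(5, 150, by = 5)
  expect_true(all(diff(percent_speed_error(v)) > 0))
})

test_that("center offset is signed along the travel direction", {
  cam <- round_cam()
  proto <- protocol(cam)
  rx <- proto$right_center_px; lx <- proto$left_center_px
  # rightward approach reversing 10 px past the right center: +2.434 mm
  xs <- c(rx - 5, rx + 2, rx + 10, rx + 6, rx)
  s <- make_series(xs, rep(proto$center_y_px, 5), cam)
  seg <- make_segment("endpoint", 1L, 5L, "rightward")
  expect_equal(center_offset(seg, s, proto), 10 * 0.2434)
  # leftward approach reversing 10 px short of the left center: -2.434 mm
  xs2 <- c(lx + 30, lx + 15, lx + 10, lx + 14, lx + 20)
  s2 <- make_series(xs2, rep(proto$center_y_px, 5), cam)
  seg2 <- make_segment("endpoint", 1L, 5L, "leftward")
  expect_equal(center_offset(seg2, s2, proto), -10 * 0.2434)
  # reversal exactly at the center: 0
  xs3 <- c(rx - 8, rx - 3, rx, rx - 4, rx - 9)
  s3 <- make_series(xs3, rep(proto$center_y_px, 5), cam)
  expect_equal(center_offset(make_segment("endpoint", 1L, 5L, "rightward"),
                             s3, proto), 0)
  expect_error(center_offset(make_segment("travel", 1L, 5L), s3, proto),
               "endpoint segments only")
})

test_that("path accuracy is the inside fraction of travel frames", {
  proto <- protocol()
  roi <- region_of_interest(proto, 1)
  # 5-frame trajectory, one frame outside the corridor: 80 percent
  xs <- seq(proto$left_center_px + 60, proto$right_center_px - 60,
            length.out = 5)
  ys <- rep(proto$center_y_px, 5)
  ys[3] <- roi$ymax + 5
  s <- make_series(xs, ys)
  seg <- make_segment("travel", 0L, 5L)
  expect_equal(intertarget_path_accuracy(seg, s, proto, 1), 80)
  # all inside (one on the boundary, which counts as inside): 100
  ys2 <- rep(proto$center_y_px, 5); ys2[2] <- roi$ymax
  expect_equal(
    intertarget_path_accuracy(seg, make_series(xs, ys2), proto, 1), 100)
})

test_that("a straight noiseless trial has 100 percent path accuracy", {
  proto <- protocol()
  tr <- simulate_trial(subject_params(speed_mult = 2), proto, seed = 6)
  seg <- extract_segments(run_state_machine(tr$series, proto), tr$series)
  for (s in 1:6)
    expect_equal(intertarget_path_accuracy(seg, tr$series, proto, s), 100)
})

test_that("path accuracy falls as lateral path noise grows", {
  proto <- protocol()
  mean_ipa <- vapply(c(1, 4, 8), function(sd_mm) {
    vals <- unlist(lapply(1:3, function(i) {
      tr <- simulate_trial(subject_params(speed_mult = 2.5,
                                          path_noise_sd = sd_mm),
                           proto, seed = 100 * sd_mm + i)
      seg <- extract_segments(run_state_machine(tr$series, proto), tr$series)
      vapply(1:6, function(s)
        intertarget_path_accuracy(seg, tr$series, proto, s), numeric(1))
    }))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(mean_ipa) < 0))
})

test_that("scaling displacements scales speed and acceleration linearly", {
  cam <- ref_cam()
  set.seed(40)
  steps <- runif(20, 1, 3)
  x <- 100 + cumsum(steps)
  s1 <- make_series(x, rep(200, 20), cam)
  s2 <- make_series(100 + 2 * cumsum(steps), rep(200, 20), cam)
  seg <- make_segment("travel", 0L, 20L)
  expect_equal(segment_mean_speed(seg, s2),
               2 * segment_mean_speed(seg, s1), tolerance = 1e-12)
  expect_equal(segment_mean_acceleration(seg, s2),
               2 * segment_mean_acceleration(seg, s1), tolerance = 1e-12)
})

test_that("trial summaries aggregate segments as documented", {
  proto <- protocol()
  tr <- simulate_trial(subject_params(speed_mult = 2, overshoot_mm = 1),
                       proto, seed = 13)
  seg <- extract_segments(run_state_machine(tr$series, proto), tr$series)
  mt <- summarize_trial(tr$series, seg, proto, participant_id = 7, trial = 2)
  expect_equal(nrow(mt), 6)
  expect_equal(mt$subtask, proto$subtask_ids)
  expect_equal(mt$speed_mmps, rep(51.4, 6), tolerance = 1e-9)
  expect_equal(mt$speed_error_pct, rep(100, 6), tolerance = 1e-9)
  expect_equal(mt$center_offset_mm, rep(1, 6), tolerance = 0.02)
  expect_equal(mt$ipa_pct, rep(100, 6))
  expect_equal(mt$n_travel, rep(5L, 6))
  # hand-built two-segment toy: means equal hand arithmetic
  cam <- round_cam(); p2 <- protocol(cam)
  v1 <- 20 / cam$mm_per_px / cam$fps; v2 <- 40 / cam$mm_per_px / cam$fps
  x <- c(100 + v1 * 0:4, 200 + v2 * 0:4)
  s <- make_series(x, rep(p2$center_y_px, 10), cam)
  segs <- rbind(make_segment("travel", 0L, 5L), make_segment("travel", 5L, 10L))
  segs$subtask <- 1L
  ms <- vapply(1:2, function(r) segment_mean_speed(segs[r, ], s), numeric(1))
  expect_equal(mean(ms), 30, tolerance = 1e-9)
})
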