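proto <- protocol()

test_that("segmentation round-trips the generator's ground truth", {
  for (sp in list(subject_params(speed_mult = 2),
                  subject_params(speed_mult = 2.5, path_noise_sd = 2,
                                 overshoot_mm = 1, accel_jitter_sd = 2))) {
    tr <- simulate_trial(sp, proto, seed = 17)
    st <- run_state_machine(tr$series, proto)
    seg <- extract_segments(st, tr$series)
    cols <- c("kind", "subtask", "index", "start", "end", "direction")
    expect_equal(as.data.frame(seg[cols]),
                 as.data.frame(tr$truth[cols]),
                 ignore_attr = TRUE)
    # idempotence
    seg2 <- extract_segments(run_state_machine(tr$series, proto), tr$series)
    expect_identical(seg, seg2)
  }
})

test_that("a completed trial yields 30 alternating travel segments", {
  tr <- simulate_trial(subject_params(speed_mult = 2, path_noise_sd = 3),
                       proto, seed = 23)
  seg <- extract_segments(run_state_machine(tr$series, proto), tr$series)
  travels <- seg[seg$kind == "travel", ]
  expect_equal(nrow(travels), 30)
  expect_lte(nrow(seg[seg$kind == "endpoint" & !seg$missing, ]), 30)
  for (s in 1:6) {
    dirs <- travels$direction[travels$subtask == s]
    expect_equal(dirs, rep(c("rightward", "leftward"), length.out = 5))
  }
})

test_that("segments and gaps tile the trial's frames exactly once", {
  tr <- simulate_trial(subject_params(speed_mult = 2, path_noise_sd = 2),
                       proto, seed = 31)
  seg <- extract_segments(run_state_machine(tr$series, proto), tr$series)
  seg <- seg[seg$end > seg$start, ]
  frames <- unlist(lapply(seq_len(nrow(seg)), function(r)
    seg$start[r]:(seg$end[r] - 1L)))
  expect_equal(anyDuplicated(frames), 0)
  expect_true(all(frames >= 0 & frames < nrow(tr$series$obs)))
  # within a subtask, segment ranges are ordered travel < endpoint < travel..
  for (s in 1:6) {
    ss <- seg[seg$subtask == s, ]
    ss <- ss[order(ss$start), ]
    expect_true(all(diff(ss$start) > 0))
    expect_true(all(ss$end[-nrow(ss)] <= ss$start[-1]))
  }
})

test_that("the boundary of a target square counts as inside", {
  cam <- ref_cam()
  side <- 100
  rest <- proto$rest_center_px
  edge_x <- proto$left_center_px + side / 2  # exactly on the right edge
  n_rest <- 10 * cam$fps
  # rest, then hold exactly on the boundary: must register as the initiation
  x <- c(rep(rest[1], n_rest), rep(edge_x, 5))
  y <- rep(rest[2], length(x))
  series <- make_series(x, y, cam)
  st <- tryCatch(run_state_machine(series, proto),
                 error = function(e) conditionMessage(e))
  # trial is truncated (only initiation happened), but the arrival frame
  # proves the closed-square convention
  expect_match(st, "truncated trial")
  # direct check through a complete single-movement protocol
  p1 <- protocol(movements_per_subtask = 1L, rest_duration_s = 0.2,
                 subtask_order = "large")
  tr <- simulate_trial(subject_params(speed_mult = 2), p1, seed = 2)
  st1 <- run_state_machine(tr$series, p1)
  arr <- attr(st1, "arrivals")
  expect_equal(nrow(arr), 2)  # initiation + one movement
  f <- arr$frame[arr$movement == 1] + 1
  expect_true(st1$inside_right[f])
})

test_that("a truncated trial reports the completed subtasks", {
  tr <- simulate_trial(subject_params(speed_mult = 2), proto, seed = 3)
  st_full <- run_state_machine(tr$series, proto)
  arr <- attr(st_full, "arrivals")
  # cut the series shortly after the Medium subtask starts (subtask 5)
  cut_frame <- arr$frame[arr$subtask == 5 & arr$movement == 2]
  obs <- tr$series$obs[seq_len(cut_frame), ]
  short <- centroid_series(tr$series$camera, obs)
  err <- tryCatch(run_state_machine(short, proto),
                  error = function(e) conditionMessage(e))
  expect_match(err, "during Medium")
  expect_match(err, "Large1, Large2, Large3, Large4")
})

test_that("passing straight through a target marks the endpoint missing", {
  p1 <- protocol(movements_per_subtask = 1L, rest_duration_s = 0.2,
                 subtask_order = "large")
  cam <- p1$camera
  n_rest <- ceiling(0.2 * cam$fps) + 2
  # rest at center, glide to the left target, then sweep monotonically right
  # across the right target and beyond without reversing
  x0 <- p1$rest_center_px[1]
  xl <- p1$left_center_px
  xr <- p1$right_center_px
  x <- c(rep(x0, n_rest),
         seq(x0, xl, length.out = 40),
         rep(xl, 5),
         seq(xl, xr + 80, length.out = 120),
         rep(xr + 80, 10))
  y <- rep(p1$center_y_px, length(x))
  series <- make_series(x, y, cam)
  st <- run_state_machine(series, p1)
  seg <- extract_segments(st, series)
  ep <- seg[seg$kind == "endpoint", ]
  expect_equal(nrow(ep), 1)
  expect_true(ep$missing)
  expect_true(is.na(center_offset(ep[1, ], series, p1)))
})

test_that("recorded statuses can replay segmentation and are checked", {
  tr <- simulate_trial(subject_params(speed_mult = 2), proto, seed = 9)
  st <- run_state_machine(tr$series, proto)
  st_replay <- run_state_machine(tr$series, proto,
                                 recorded = st[, c("inside_left",
                                                   "inside_right")])
  expect_equal(attr(st_replay, "status_disagreements"), 0L)
  seg1 <- extract_segments(st, tr$series)
  seg2 <- extract_segments(st_replay, tr$series)
  expect_identical(seg1, seg2)
  # a corrupted recording is reported
  rec <- st[, c("inside_left", "inside_right")]
  rec$inside_left[100:104] <- !rec$inside_left[100:104]
  expect_message(run_state_machine(tr$series, proto, recorded = rec),
                 "disagree on 5 frame")
})

test_that("series with too many invalid frames are rejected", {
  tr <- simulate_trial(subject_params(speed_mult = 2), proto, seed = 4)
  obs <- tr$series$obs
  obs$valid[seq_len(floor(nrow(obs) * 0.15))] <- FALSE
  expect_error(run_state_machine(centroid_series(tr$series$camera, obs), proto),
               "90%")
})
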