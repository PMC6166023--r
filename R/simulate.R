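#' Per-subject generative parameters
#'
#' Knobs of the synthetic trajectory generator that encode how an individual
#' performs the reaching task: a multiplier on the trained speed, lateral
#' path jitter, signed endpoint over/underreach, and within-segment speed
#' fluctuation. \code{trial_sd} gives the between-trial (within-subject)
#' perturbation applied to each knob when the same subject performs the task
#' twice.
#'
#' @param age subject age, years.
#' @param speed_mult multiplier on the 25.7 mm/s training speed (> 0).
#' @param path_noise_sd sd of lateral (y) jitter, mm.
#' @param overshoot_mm signed endpoint offset along the travel direction,
#'   mm; positive = past the target center.
#' @param accel_jitter_sd scale of within-segment speed fluctuation, mm/s^2.
#' @param trial_sd named numeric: between-trial sd for \code{speed_mult},
#'   \code{path_noise_sd}, \code{overshoot_mm}, \code{accel_jitter_sd}.
#' @return object of class \code{subject_params}.
#' @export
subject_params <- function(age = 70, speed_mult = 2, path_noise_sd = 0,
                           overshoot_mm = 0, accel_jitter_sd = 0,
                           trial_sd = c(speed_mult = 0, path_noise_sd = 0,
                                        overshoot_mm = 0, accel_jitter_sd = 0)) {
  stopifnot(speed_mult > 0, path_noise_sd >= 0, accel_jitter_sd >= 0,
            all(trial_sd >= 0))
  structure(list(age = age, speed_mult = speed_mult,
                 path_noise_sd = path_noise_sd, overshoot_mm = overshoot_mm,
                 accel_jitter_sd = accel_jitter_sd,
                 trial_sd = trial_sd), class = "subject_params")
}

#' Cohort effect model
#'
#' Linear age effects plus variance components for the generative knobs of
#' \code{\link{subject_params}}. Each knob is drawn as
#' \code{intercept + slope * age + N(0, between_sd)} per subject, with an
#' additional \code{N(0, within_sd)} perturbation per trial. Defaults encode
#' the qualitative aging trends the task is designed to expose: speed drifts
#' up from about twice the trained speed at age 43 (about +1.1 mm/s per
#' year), lateral control degrades (driving intertarget path accuracy down),
#' and overreach grows. They are illustrative calibrations, not estimates
#' from any cohort.
#'
#' @param intercepts,slopes,between_sd,within_sd named numeric vectors over
#'   \code{speed_mult}, \code{path_noise_sd}, \code{overshoot_mm},
#'   \code{accel_jitter_sd}.
#' @param seed integer; default stream seed used when the cohort simulation
#'   is not given one explicitly.
#' @return object of class \code{effect_model}.
#' @export
effect_model <- function(
    intercepts = c(speed_mult = 0.159, path_noise_sd = 0.42,
                   overshoot_mm = -1.15, accel_jitter_sd = 0.35),
    slopes = c(speed_mult = 0.0428, path_noise_sd = 0.06,
               overshoot_mm = 0.05, accel_jitter_sd = 0.05),
    between_sd = c(speed_mult = 0.3, path_noise_sd = 0.8,
                   overshoot_mm = 0.8, accel_jitter_sd = 0.5),
    within_sd = c(speed_mult = 0.1, path_noise_sd = 0.25,
                  overshoot_mm = 0.3, accel_jitter_sd = 0.2),
    seed = 1L) {
  knobs <- c("speed_mult", "path_noise_sd", "overshoot_mm", "accel_jitter_sd")
  stopifnot(all(knobs %in% names(intercepts)), all(knobs %in% names(slopes)),
            all(between_sd >= 0), all(within_sd >= 0))
  structure(list(intercepts = intercepts[knobs], slopes = slopes[knobs],
                 between_sd = between_sd[knobs], within_sd = within_sd[knobs],
                 seed = as.integer(seed)), class = "effect_model")
}

# minimum-jerk position polynomial on u in [0, 1]
mj_pos <- function(u) 10 * u^3 - 15 * u^4 + 6 * u^5

# One horizontal movement from reversal point x_a (inside the departure
# square) to reversal point x_b (inside the arrival square):
#   half-min-jerk ramp 0 -> v ending exactly at the departure square's exit
#   edge, constant v across the corridor until one frame-travel (v*dt) past
#   the arrival square's entry edge, then half-min-jerk ramp v -> 0 ending
#   at x_b. Keeping every frame pair of the travel segment inside the
#   constant-velocity stretch makes the segment's measured mean speed equal
#   the commanded speed exactly.
movement_profile <- function(x_a, x_b, v_px, dep_cx, dep_side, arr_cx,
                             arr_side, dt) {
  d <- sign(x_b - x_a)
  stopifnot(d != 0, v_px > 0)
  edge_out <- dep_cx + d * dep_side / 2
  delta <- v_px * dt
  decel_start <- arr_cx - d * arr_side / 2 + d * delta
  d1 <- (edge_out - x_a) * d
  d2 <- (decel_start - edge_out) * d
  d3 <- (x_b - decel_start) * d
  if (d1 <= 0)
    stop("movement infeasible: reversal point lies outside the departure square")
  if (d2 <= 0 || d3 <= 0)
    stop(sprintf(paste0("movement infeasible: speed %.1f px/s too high for the ",
                        "arrival square (ramp distance %.2f px)"), v_px, d3))
  T1 <- 1.875 * d1 / v_px
  T2 <- d2 / v_px
  T3 <- 1.875 * d3 / v_px
  fn <- function(t) {
    x <- numeric(length(t))
    p1 <- t <= T1
    p2 <- t > T1 & t <= T1 + T2
    p3 <- t > T1 + T2
    x[p1] <- x_a + d * 2 * d1 * mj_pos(t[p1] / (2 * T1))
    x[p2] <- edge_out + d * v_px * (t[p2] - T1)
    x[p3] <- decel_start +
      d * (2 * d3 * mj_pos(0.5 + (t[p3] - T1 - T2) / (2 * T3)) - d3)
    x
  }
  list(fn = fn, duration = T1 + T2 + T3, direction = d,
       t_ramp_in = T1, t_decel = T1 + T2)
}

#' Simulate one full trial
#'
#' Generates the centroid series of a complete six-subtask trial at the
#' camera's frame spacing, together with the ground-truth travel/endpoint
#' segment ranges and true mean speeds. The trial follows the protocol
#' sequence: an initial rest on the central square, then per subtask an
#' initiation move to the left target followed by five movements between the
#' targets (constant commanded speed \code{training_speed * speed_mult}
#' between the squares, smooth reversals inside them), a return to the rest
#' square, and a timed rest.
#'
#' Lateral path deviation (\code{path_noise_sd}) is one smooth sinusoidal
#' bow per movement with random amplitude, the scale a hand drifts off the
#' direct path; speed fluctuation (\code{accel_jitter_sd}) perturbs x frame
#' by frame. Rest frames are stationary. With all noise at zero the measured
#' mean speed of every travel segment equals the commanded speed to
#' numerical precision.
#'
#' @param subject a \code{\link{subject_params}}.
#' @param proto a \code{\link{protocol}}.
#' @param camera a \code{\link{camera_model}}; defaults to the protocol's.
#' @param seed integer seed; the same seed reproduces the trial exactly.
#' @return object of class \code{simulated_trial}: \code{series} (a
#'   \code{\link{centroid_series}}), \code{truth} (data.frame of segments:
#'   \code{kind}, \code{subtask}, \code{index}, \code{start}, \code{end}
#'   half-open 0-based frame range, \code{direction},
#'   \code{true_mean_speed} mm/s), \code{arrivals} (data.frame of arrival
#'   frames incl. the initiation arrival, \code{movement} 0..5), and
#'   \code{subject}.
#' @export
simulate_trial <- function(subject, proto = protocol(), camera = proto$camera,
                           seed = 1L) {
  stopifnot(inherits(subject, "subject_params"), inherits(proto, "protocol"))
  fps <- camera$fps; dt <- 1 / fps
  mmpp <- camera$mm_per_px
  v_mm <- proto$training_speed * subject$speed_mult
  v_px <- v_mm / mmpp
  ov_px <- subject$overshoot_mm / mmpp
  cx <- proto$rest_center_px[1]; cy <- proto$rest_center_px[2]
  Lx <- proto$left_center_px; Rx <- proto$right_center_px
  rest_dur <- proto$rest_duration_s
  n_mov <- proto$movements_per_subtask

  # build the phase timeline: rests (stationary) and movements (profiles)
  phases <- list(); t_cur <- 0
  add <- function(ph) { phases[[length(phases) + 1L]] <<- ph; t_cur <<- ph$t_end }
  add(list(type = "rest", t_start = 0, t_end = rest_dur, x = cx))
  for (s in seq_along(proto$subtask_ids)) {
    side <- subtask_side_px(proto, s)
    x_rev_L <- Lx - ov_px; x_rev_R <- Rx + ov_px
    # initiation: rest square -> left target
    mp <- movement_profile(cx, x_rev_L, v_px, cx, proto$rest_square_px,
                           Lx, side, dt)
    add(list(type = "move", subtask = s, movement = 0L,
             t_start = t_cur, t_end = t_cur + mp$duration, profile = mp,
             arr_cx = Lx, dep_cx = cx, dep_side = proto$rest_square_px,
             side = side))
    for (m in seq_len(n_mov)) {
      right <- m %% 2L == 1L  # first movement goes left -> right
      x_a <- if (right) x_rev_L else x_rev_R
      x_b <- if (right) x_rev_R else x_rev_L
      dep <- if (right) Lx else Rx
      arr <- if (right) Rx else Lx
      mp <- movement_profile(x_a, x_b, v_px, dep, side, arr, side, dt)
      add(list(type = "move", subtask = s, movement = m,
               t_start = t_cur, t_end = t_cur + mp$duration, profile = mp,
               arr_cx = arr, dep_cx = dep, dep_side = side, side = side))
    }
    # return: last target -> rest square (odd n_mov ends on the right)
    x_last <- if (n_mov %% 2L == 1L) x_rev_R else x_rev_L
    dep <- if (n_mov %% 2L == 1L) Rx else Lx
    mp <- movement_profile(x_last, cx, v_px, dep, side, cx,
                           proto$rest_square_px, dt)
    add(list(type = "move", subtask = s, movement = n_mov + 1L,
             t_start = t_cur, t_end = t_cur + mp$duration, profile = mp,
             arr_cx = cx, dep_cx = dep, dep_side = side, side = side))
    add(list(type = "rest", t_start = t_cur, t_end = t_cur + rest_dur, x = cx))
  }

  n_frames <- floor(t_cur / dt) + 1L
  tk <- (seq_len(n_frames) - 1L) * dt
  starts <- vapply(phases, `[[`, numeric(1), "t_start")
  idx <- findInterval(tk, starts, rightmost.closed = FALSE)
  x <- numeric(n_frames); moving <- logical(n_frames)
  for (p in seq_along(phases)) {
    sel <- idx == p
    if (!any(sel)) next
    ph <- phases[[p]]
    if (ph$type == "rest") {
      x[sel] <- ph$x
    } else {
      x[sel] <- ph$profile$fn(tk[sel] - ph$t_start)
      moving[sel] <- TRUE
    }
  }
  y <- rep(cy, n_frames)

  # Lateral deviation is one smooth bow per movement (amplitude ~
  # N(0, path_noise_sd)): a rough per-frame jitter of the mm scale needed to
  # leave the intertarget corridor would add an unphysical lateral velocity
  # and swamp the speed/acceleration metrics. Speed fluctuation is additive
  # x noise scaled so the induced mean |acceleration| is about
  # accel_jitter_sd.
  noisy <- with_seed(seed, {
    for (p in seq_along(phases)) {
      ph <- phases[[p]]
      if (ph$type != "move") next
      sel <- idx == p
      if (!any(sel)) next
      if (subject$path_noise_sd > 0) {
        amp <- stats::rnorm(1, 0, subject$path_noise_sd / mmpp)
        rel <- (tk[sel] - ph$t_start) / (ph$t_end - ph$t_start)
        y[sel] <- y[sel] + amp * sin(pi * rel)
      }
      if (subject$accel_jitter_sd > 0) {
        sd_px <- subject$accel_jitter_sd / (fps^2 * sqrt(6)) / mmpp
        x[sel] <- x[sel] + stats::rnorm(sum(sel), 0, sd_px)
      }
    }
    list(x = x, y = y)
  })
  x <- noisy$x; y <- noisy$y

  obs <- data.frame(frame = seq_len(n_frames) - 1L, x = x, y = y,
                    radius = expected_radius_px(marker_spec(), camera),
                    valid = TRUE, interpolated = FALSE)
  series <- centroid_series(camera, obs)

  truth <- derive_truth(phases, x, y, proto, v_mm, n_frames, dt)
  if (any(truth$segments$kind == "travel" &
          truth$segments$end - truth$segments$start < 4))
    stop("commanded speed too high: a travel segment spans fewer than 4 frames")
  structure(list(series = series, truth = truth$segments,
                 arrivals = truth$arrivals, subject = subject,
                 protocol = proto, seed = seed),
            class = "simulated_trial")
}

# ground-truth segments from the generator's own knowledge of the movement
# windows, applying the definitional rules to the sampled (noisy) positions
derive_truth <- function(phases, x, y, proto, v_mm, n_frames, dt) {
  cy <- proto$center_y_px
  segs <- list(); arrs <- list()
  moves <- Filter(function(p) p$type == "move", phases)
  frame_of <- function(t) pmin(n_frames - 1L, pmax(0L, as.integer(ceiling(t / dt - 1e-9))))
  for (i in seq_along(moves)) {
    ph <- moves[[i]]
    if (ph$movement > proto$movements_per_subtask) next  # return move
    f0 <- frame_of(ph$t_start)
    f_end <- if (i < length(moves)) frame_of(moves[[i + 1]]$t_end)
             else n_frames - 1L
    win <- f0:f_end
    ins_arr <- inside_square(x[win + 1], y[win + 1], ph$arr_cx, cy, ph$side)
    if (!any(ins_arr)) stop("generator inconsistency: no arrival frame found")
    arrival <- win[which(ins_arr)[1]]
    arrs[[length(arrs) + 1L]] <- data.frame(
      frame = arrival, subtask = ph$subtask, movement = ph$movement,
      target = if (ph$arr_cx < proto$rest_center_px[1]) "left" else "right")
    if (ph$movement == 0L) next  # initiation: no travel/endpoint segment
    dep_win <- f0:(arrival - 1L)
    ins_dep <- inside_square(x[dep_win + 1], y[dep_win + 1], ph$dep_cx, cy,
                             ph$dep_side)
    last_in <- dep_win[max(which(ins_dep))]
    d <- ph$profile$direction
    # reversal: extreme x in the direction of travel over the contiguous
    # inside-run starting at the arrival
    run_end <- arrival
    while (run_end + 1L <= n_frames - 1L &&
           inside_square(x[run_end + 2], y[run_end + 2], ph$arr_cx, cy, ph$side))
      run_end <- run_end + 1L
    run <- arrival:run_end
    reversal <- run[which.max(d * x[run + 1])]
    segs[[length(segs) + 1L]] <- data.frame(
      kind = "travel", subtask = ph$subtask, index = ph$movement,
      start = last_in + 1L, end = arrival + 1L,
      direction = if (d > 0) "rightward" else "leftward",
      true_mean_speed = v_mm)
    segs[[length(segs) + 1L]] <- data.frame(
      kind = "endpoint", subtask = ph$subtask, index = ph$movement,
      start = arrival + 1L, end = reversal + 1L,
      direction = if (d > 0) "rightward" else "leftward",
      true_mean_speed = NA_real_)
  }
  segments <- do.call(rbind, segs)
  segments$subtask_id <- proto$subtask_ids[segments$subtask]
  list(segments = segments, arrivals = do.call(rbind, arrs))
}

#' Simulate a two-trial cohort
#'
#' Draws a cohort of subjects with ages uniform over \code{age_range},
#' subject-level generative knobs from the \code{\link{effect_model}}
#' (linear in age plus between-subject noise), and two trials per subject
#' (each adding within-subject noise to the knobs).
#'
#' Two modes: \code{"metrics"} maps each trial's knobs directly to the five
#' kinematic metrics per subtask via their generative relations (speed =
#' training speed x multiplier, speed error = 100 x (multiplier - 1),
#' center offset = overshoot, mean |acceleration| = jitter scale x
#' sqrt(2/pi), path accuracy = the Gaussian corridor-containment
#' probability), which is fast and has exact known expectations;
#' \code{"trajectories"} runs \code{\link{simulate_trial}} per subject and
#' trial so the full detection-free pipeline can be exercised end to end.
#'
#' @param n_subjects number of subjects (>= 3).
#' @param age_range length-2 numeric, years.
#' @param effects an \code{\link{effect_model}}.
#' @param seed integer master seed; every draw derives from it.
#' @param mode \code{"metrics"} or \code{"trajectories"}.
#' @param proto a \code{\link{protocol}}.
#' @return For \code{mode = "metrics"}: a data.frame metric table (class
#'   \code{metric_table}) with columns \code{participant_id}, \code{age},
#'   \code{trial}, \code{subtask}, \code{speed_mmps}, \code{accel_mmps2},
#'   \code{speed_error_pct}, \code{center_offset_mm}, \code{ipa_pct}. For
#'   \code{mode = "trajectories"}: list with \code{subjects} (data.frame
#'   id/age) and \code{trials} (list of \code{\link{simulate_trial}} results
#'   indexed by subject then trial).
#' @export
simulate_cohort <- function(n_subjects, age_range = c(43, 94),
                            effects = effect_model(), seed = effects$seed,
                            mode = c("metrics", "trajectories"),
                            proto = protocol()) {
  mode <- match.arg(mode)
  stopifnot(n_subjects >= 3, length(age_range) == 2)
  if (age_range[1] == age_range[2] && any(effects$slopes != 0))
    warning("degenerate age range with nonzero age slopes: age effects are unidentifiable")

  knobs <- names(effects$intercepts)
  draws <- with_seed(derive_seed(seed, 1), {
    ages <- stats::runif(n_subjects, age_range[1], age_range[2])
    subj <- sapply(knobs, function(kn) {
      effects$intercepts[kn] + effects$slopes[kn] * ages +
        stats::rnorm(n_subjects, 0, effects$between_sd[kn])
    })
    trial1 <- subj + sapply(knobs, function(kn)
      stats::rnorm(n_subjects, 0, effects$within_sd[kn]))
    trial2 <- subj + sapply(knobs, function(kn)
      stats::rnorm(n_subjects, 0, effects$within_sd[kn]))
    list(ages = ages, trial = list(trial1, trial2))
  })

  clip <- function(m) {
    m[, "speed_mult"] <- pmax(m[, "speed_mult"], 0.05)
    m[, "path_noise_sd"] <- pmax(m[, "path_noise_sd"], 0)
    m[, "accel_jitter_sd"] <- pmax(m[, "accel_jitter_sd"], 0)
    m
  }
  draws$trial <- lapply(draws$trial, clip)

  if (mode == "metrics") {
    rows <- list()
    for (tr in 1:2) {
      pm <- draws$trial[[tr]]
      for (s in seq_along(proto$subtask_ids)) {
        side_mm <- subtask_side_px(proto, s) * proto$camera$mm_per_px
        ipa <- ifelse(pm[, "path_noise_sd"] > 0,
                      100 * (2 * stats::pnorm((side_mm / 2) / pm[, "path_noise_sd"]) - 1),
                      100)
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = seq_len(n_subjects), age = draws$ages,
          trial = tr, subtask = proto$subtask_ids[s],
          speed_mmps = proto$training_speed * pm[, "speed_mult"],
          accel_mmps2 = pm[, "accel_jitter_sd"] * sqrt(2 / pi),
          speed_error_pct = 100 * (pm[, "speed_mult"] - 1),
          center_offset_mm = pm[, "overshoot_mm"],
          ipa_pct = ipa)
      }
    }
    tab <- do.call(rbind, rows)
    tab <- tab[order(tab$participant_id, tab$trial), ]
    rownames(tab) <- NULL
    class(tab) <- c("metric_table", "data.frame")
    return(tab)
  }

  trials <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    trials[[i]] <- lapply(1:2, function(tr) {
      pm <- draws$trial[[tr]]
      sp <- subject_params(age = draws$ages[i],
                           speed_mult = pm[i, "speed_mult"],
                           path_noise_sd = pm[i, "path_noise_sd"],
                           overshoot_mm = pm[i, "overshoot_mm"],
                           accel_jitter_sd = pm[i, "accel_jitter_sd"])
      simulate_trial(sp, proto, seed = derive_seed(seed, i, tr))
    })
  }
  list(subjects = data.frame(participant_id = seq_len(n_subjects),
                             age = draws$ages),
       trials = trials)
}

#' Simulate a subject-by-trial matrix with known variance components
#'
#' Direct metric-level generator for reliability studies:
#' \code{value[i, j] = mu + b_i + c_j + e_ij} with subject effects
#' \code{b ~ N(0, sd_subject)}, trial (column) effects
#' \code{c ~ N(0, sd_trial)}, and residuals \code{e ~ N(0, sd_resid)}. The
#' theoretical agreement ICC for the average of k trials is
#' \code{sd_subject^2 / (sd_subject^2 + (sd_trial^2 + sd_resid^2) / k)}.
#'
#' @param n_subjects rows (>= 3).
#' @param k trials/columns.
#' @param mu grand mean.
#' @param sd_subject,sd_trial,sd_resid component standard deviations.
#' @param seed integer seed.
#' @return numeric \code{n_subjects x k} matrix.
#' @export
simulate_metric_matrix <- function(n_subjects, k = 2, mu = 0, sd_subject = 1,
                                   sd_trial = 0, sd_resid = 1, seed = 1L) {
  stopifnot(n_subjects >= 3, k >= 2, sd_subject >= 0, sd_trial >= 0,
            sd_resid >= 0)
  with_seed(seed, {
    b <- stats::rnorm(n_subjects, 0, sd_subject)
    cc <- stats::rnorm(k, 0, sd_trial)
    mu + outer(b, cc, `+`) +
      matrix(stats::rnorm(n_subjects * k, 0, sd_resid), n_subjects, k)
  })
}
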