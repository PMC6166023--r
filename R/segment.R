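#' Replay the target-square state machine over a centroid series
#'
#' Recomputes, from centroid geometry alone, the per-frame target status the
#' acquisition software tracked online: whether the centroid is inside the
#' left/right target square of the active subtask (closed squares: the
#' boundary counts as inside), which target is active, and the subtask
#' label. A subtask starts with an initiation arrival at the left target;
#' every arrival at the active target flips activity to the opposite target;
#' after \code{movements_per_subtask} post-initiation arrivals the subtask
#' is complete and the machine returns to rest until the next initiation
#' arrival at the left target.
#'
#' When per-frame status flags recorded at acquisition time are supplied via
#' \code{recorded}, the machine replays those inside flags instead of
#' recomputing them from geometry (they were evaluated online against the
#' then-active square), and reports how many frames disagree with the
#' geometric recomputation.
#'
#' @param series a \code{\link{centroid_series}} with valid observations for
#'   at least 90 percent of frames.
#' @param proto the \code{\link{protocol}} in force.
#' @param recorded optional data.frame with \code{inside_left},
#'   \code{inside_right} per frame (e.g. from \code{\link{read_trial_file}});
#'   selects the replay source.
#' @return data.frame of class \code{target_status} with one row per frame:
#'   \code{frame}, \code{inside_left}, \code{inside_right},
#'   \code{active_target} (\code{"left"}, \code{"right"} or \code{"rest"}),
#'   \code{subtask_id} (a protocol label or \code{"rest"}). Attribute
#'   \code{arrivals}: data.frame \code{frame}, \code{subtask},
#'   \code{movement} (0 = initiation), \code{target}. When \code{recorded}
#'   is supplied, attribute \code{status_disagreements}: number of frames
#'   whose recorded inside flags differ from the geometric recomputation.
#' @export
run_state_machine <- function(series, proto = protocol(), recorded = NULL) {
  stopifnot(inherits(series, "centroid_series"))
  obs <- series$obs
  n <- nrow(obs)
  if (mean(obs$valid) < 0.9)
    stop("series has valid observations for fewer than 90% of frames")
  n_sub <- length(proto$subtask_ids)
  n_mov <- proto$movements_per_subtask
  cy <- proto$center_y_px
  x <- obs$x; y <- obs$y; ok <- obs$valid & !is.na(obs$x)

  # inside flags per size class, vectorized once
  sides <- proto$target_side_px[unique(proto$subtask_order)]
  in_l <- lapply(sides, function(s)
    ok & inside_square(x, y, proto$left_center_px, cy, s))
  in_r <- lapply(sides, function(s)
    ok & inside_square(x, y, proto$right_center_px, cy, s))
  disagreements <- NA_integer_
  if (!is.null(recorded)) {
    stopifnot(nrow(recorded) == n,
              all(c("inside_left", "inside_right") %in% names(recorded)))
    rl <- recorded$inside_left; rr <- recorded$inside_right
  }

  inside_left <- logical(n); inside_right <- logical(n)
  active <- character(n); subtask <- character(n)
  s_idx <- 1L; phase <- "rest"; act <- "left"; done_mov <- 0L
  arr <- vector("list", n_sub * (n_mov + 1L)); n_arr <- 0L

  for (i in seq_len(n)) {
    if (s_idx > n_sub) {            # trial complete
      inside_left[i] <- FALSE; inside_right[i] <- FALSE
      active[i] <- "rest"; subtask[i] <- "rest"
      next
    }
    cls <- proto$subtask_order[s_idx]
    il <- in_l[[cls]][i]; ir <- in_r[[cls]][i]
    if (!is.null(recorded)) {
      if (is.na(disagreements)) disagreements <- 0L
      if (xor(rl[i], il) || xor(rr[i], ir)) disagreements <- disagreements + 1L
      il <- rl[i]; ir <- rr[i]
    }
    inside_left[i] <- il; inside_right[i] <- ir
    if (phase == "rest") {
      active[i] <- "rest"; subtask[i] <- "rest"
      if (il) {                     # initiation arrival at the left target
        phase <- "active"; act <- "right"; done_mov <- 0L
        n_arr <- n_arr + 1L
        arr[[n_arr]] <- data.frame(frame = obs$frame[i], subtask = s_idx,
                                   movement = 0L, target = "left")
        active[i] <- "right"; subtask[i] <- proto$subtask_ids[s_idx]
      }
    } else {
      subtask[i] <- proto$subtask_ids[s_idx]
      hit <- (act == "left" && il) || (act == "right" && ir)
      if (hit) {
        done_mov <- done_mov + 1L
        n_arr <- n_arr + 1L
        arr[[n_arr]] <- data.frame(frame = obs$frame[i], subtask = s_idx,
                                   movement = done_mov, target = act)
        if (done_mov >= n_mov) {    # subtask complete
          s_idx <- s_idx + 1L; phase <- "rest"; act <- "left"
        } else {
          act <- if (act == "left") "right" else "left"
        }
      }
      active[i] <- if (phase == "active") act else "rest"
    }
  }

  if (s_idx <= n_sub) {
    completed <- if (s_idx > 1) proto$subtask_ids[seq_len(s_idx - 1L)] else character(0)
    stop(sprintf("truncated trial: series ended during %s; completed subtasks: %s",
                 proto$subtask_ids[s_idx],
                 if (length(completed)) paste(completed, collapse = ", ") else "none"))
  }

  statuses <- data.frame(frame = obs$frame, inside_left = inside_left,
                         inside_right = inside_right, active_target = active,
                         subtask_id = subtask)
  attr(statuses, "arrivals") <- do.call(rbind, arr[seq_len(n_arr)])
  attr(statuses, "protocol") <- proto
  if (!is.null(recorded)) {
    attr(statuses, "status_disagreements") <- disagreements
    if (!is.na(disagreements) && disagreements > 0)
      message(sprintf("recorded and recomputed target statuses disagree on %d frame(s)",
                      disagreements))
  }
  class(statuses) <- c("target_status", "data.frame")
  statuses
}

#' Cut a centroid series into travel and endpoint segments
#'
#' Applies the segment definitions to the arrivals found by
#' \code{\link{run_state_machine}}. A travel segment spans the frames
#' strictly after the last frame inside the departure square up to and
#' including the arrival frame (half-open range \code{[start, arrival + 1)}).
#' An endpoint segment spans the frames after the arrival up to and
#' including the frame of horizontal direction reversal, i.e. the extreme-x
#' frame in the travel direction within the contiguous run of frames inside
#' the target (zero-displacement frames are absorbed; the search includes
#' the arrival frame itself, which is assigned to the travel segment). If
#' the centroid leaves the target square without reversing, that endpoint is
#' marked missing.
#'
#' @param statuses a \code{\link{run_state_machine}} result.
#' @param series the same \code{\link{centroid_series}}.
#' @return data.frame of class \code{segment_table}: \code{kind}
#'   (\code{"travel"}/\code{"endpoint"}), \code{subtask} (index),
#'   \code{subtask_id}, \code{index} (movement 1..5), \code{start},
#'   \code{end} (half-open 0-based frame range), \code{direction},
#'   \code{missing} (endpoint without reversal).
#' @export
extract_segments <- function(statuses, series) {
  stopifnot(inherits(statuses, "target_status"),
            inherits(series, "centroid_series"))
  proto <- attr(statuses, "protocol")
  arrivals <- attr(statuses, "arrivals")
  obs <- series$obs
  x <- obs$x; y <- obs$y
  cy <- proto$center_y_px
  n <- nrow(obs)
  rows <- list()

  for (s in seq_along(proto$subtask_ids)) {
    sub_arr <- arrivals[arrivals$subtask == s, ]
    sub_arr <- sub_arr[order(sub_arr$movement), ]
    side <- subtask_side_px(proto, s)
    for (m in seq_len(proto$movements_per_subtask)) {
      a_prev <- sub_arr$frame[sub_arr$movement == m - 1L]
      a_cur <- sub_arr$frame[sub_arr$movement == m]
      tgt <- sub_arr$target[sub_arr$movement == m]
      tgt_cx <- if (tgt == "left") proto$left_center_px else proto$right_center_px
      dep_cx <- if (tgt == "left") proto$right_center_px else proto$left_center_px
      dep_side <- side
      if (m == 1L) { dep_cx <- proto$left_center_px }  # departure = left target
      d <- if (tgt == "right") 1 else -1

      dep_win <- a_prev:(a_cur - 1L)
      ins_dep <- inside_square(x[dep_win + 1], y[dep_win + 1], dep_cx, cy,
                               dep_side)
      start <- dep_win[max(which(ins_dep))] + 1L

      rows[[length(rows) + 1L]] <- data.frame(
        kind = "travel", subtask = s, subtask_id = proto$subtask_ids[s],
        index = m, start = start, end = a_cur + 1L,
        direction = if (d > 0) "rightward" else "leftward", missing = FALSE)

      # contiguous inside-run from the arrival
      run_end <- a_cur
      while (run_end + 1L <= n - 1L &&
             inside_square(x[run_end + 2], y[run_end + 2], tgt_cx, cy, side))
        run_end <- run_end + 1L
      run <- a_cur:run_end
      rev_rel <- which.max(d * x[run + 1])
      # exited still moving in the travel direction: no reversal inside
      miss <- (rev_rel == length(run)) && run_end < n - 1L &&
        d * x[run_end + 2] > d * x[run_end + 1]
      reversal <- run[rev_rel]
      if (reversal == a_cur) miss <- TRUE  # no frames after arrival to reverse in
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "endpoint", subtask = s, subtask_id = proto$subtask_ids[s],
        index = m, start = a_cur + 1L, end = reversal + 1L,
        direction = if (d > 0) "rightward" else "leftward", missing = miss)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("segment_table", "data.frame")
  out
}
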