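#' Instantaneous speed between consecutive frames
#'
#' Euclidean displacement of the centroid between frames \code{i} and
#' \code{i + 1}, converted to mm via the camera scale and multiplied by the
#' frame rate. Undefined (NA) when either frame is invalid; interpolated
#' frames count as valid.
#'
#' @param series a \code{\link{centroid_series}}.
#' @param i 0-based frame index (vectorized).
#' @return speed in mm/s (NA where undefined).
#' @export
instantaneous_speed <- function(series, i) {
  obs <- series$obs
  stopifnot(all(i >= 0), all(i + 2 <= nrow(obs)))
  a <- i + 1L; b <- i + 2L
  sp <- sqrt((obs$x[b] - obs$x[a])^2 + (obs$y[b] - obs$y[a])^2) *
    series$camera$mm_per_px * series$camera$fps
  sp[!(obs$valid[a] & obs$valid[b])] <- NA_real_
  sp
}

# speeds for all frame pairs of a half-open segment [start, end)
segment_speeds <- function(segment, series) {
  if (segment$end - segment$start < 2) return(numeric(0))
  instantaneous_speed(series, segment$start:(segment$end - 2L))
}

#' Mean speed of a travel segment
#'
#' Arithmetic mean of the defined instantaneous speeds over the segment's
#' consecutive frame pairs. Only travel segments carry a speed metric;
#' passing an endpoint segment is a contract violation.
#'
#' @param segment one row of a \code{\link{extract_segments}} table (or any
#'   list with \code{kind}, \code{start}, \code{end}).
#' @param series the \code{\link{centroid_series}}.
#' @return mean speed, mm/s (NA if no defined pair).
#' @export
segment_mean_speed <- function(segment, series) {
  if (segment$kind != "travel")
    stop("segment_mean_speed is defined for travel segments only")
  sp <- segment_speeds(segment, series)
  if (all(is.na(sp)) || length(sp) == 0) return(NA_real_)
  mean(sp, na.rm = TRUE)
}

#' Mean absolute acceleration of a travel segment
#'
#' Instantaneous acceleration at frame \code{i} is the difference of
#' consecutive instantaneous speeds times the frame rate,
#' \code{(v[i+1] - v[i]) * fps}, so each acceleration sample draws on the
#' centroid at four frame slots. The segment value is the mean of the
#' absolute acceleration samples: over a segment that starts and stops, a
#' signed mean would cancel to about zero, while the magnitude tracks how
#' unsteady the motion is.
#'
#' @inheritParams segment_mean_speed
#' @return mean |acceleration|, mm/s^2 (NA if the segment has fewer than 4
#'   frames or no defined sample).
#' @export
segment_mean_acceleration <- function(segment, series) {
  if (segment$kind != "travel")
    stop("segment_mean_acceleration is defined for travel segments only")
  if (segment$end - segment$start < 4) return(NA_real_)
  sp <- segment_speeds(segment, series)
  acc <- diff(sp) * series$camera$fps
  if (all(is.na(acc))) return(NA_real_)
  mean(abs(acc), na.rm = TRUE)
}

#' Percent speed error
#'
#' Signed percent deviation of a measured mean speed from the trained target
#' speed: \code{100 * (mean_speed - training_speed) / training_speed}.
#' Moving at exactly twice the trained speed gives +100.
#'
#' @param mean_speed measured mean speed, mm/s.
#' @param training_speed trained speed, mm/s (default 25.7).
#' @return percent error (vectorized).
#' @export
percent_speed_error <- function(mean_speed, training_speed = 25.7) {
  stopifnot(training_speed > 0)
  100 * (mean_speed - training_speed) / training_speed
}

#' Center offset of an endpoint segment
#'
#' Horizontal distance between the farthest point reached inside the target
#' and the target's center, projected on the travel direction and converted
#' to mm: positive = overreach (past the center), negative = underreach
#' (reversed short of the center), for either approach direction.
#'
#' @param segment an endpoint-segment row from \code{\link{extract_segments}}.
#' @param series the \code{\link{centroid_series}}.
#' @param proto the \code{\link{protocol}}.
#' @return signed offset in mm; NA for a missing endpoint.
#' @export
center_offset <- function(segment, series, proto = protocol()) {
  if (segment$kind != "endpoint")
    stop("center_offset is defined for endpoint segments only")
  if (isTRUE(segment$missing) || segment$end <= segment$start) return(NA_real_)
  d <- if (segment$direction == "rightward") 1 else -1
  tgt_cx <- if (d > 0) proto$right_center_px else proto$left_center_px
  frames <- segment$start:(segment$end - 1L)
  xs <- series$obs$x[frames + 1L]
  xs <- xs[series$obs$valid[frames + 1L]]
  if (length(xs) == 0) return(NA_real_)
  extreme <- xs[which.max(d * xs)]
  d * (extreme - tgt_cx) * series$camera$mm_per_px
}

#' Intertarget path accuracy of a subtask
#'
#' Percentage of travel-segment frames whose centroid lies inside the
#' intertarget corridor (see \code{\link{region_of_interest}}); the boundary
#' counts as inside. Normalizing by the subtask's own frame count removes
#' the effect of travel speed. Only travel frames enter the measure:
#' endpoint frames sit inside a target square, hence inside the corridor by
#' construction.
#'
#' @param segments the \code{\link{extract_segments}} table.
#' @param series the \code{\link{centroid_series}}.
#' @param proto the \code{\link{protocol}}.
#' @param subtask subtask index (1-based) or id label.
#' @return percentage in [0, 100]; NA if the subtask has no valid travel
#'   frame.
#' @export
intertarget_path_accuracy <- function(segments, series, proto = protocol(),
                                      subtask = 1L) {
  if (is.character(subtask)) subtask <- match(subtask, proto$subtask_ids)
  roi <- region_of_interest(proto, subtask)
  tr <- segments[segments$kind == "travel" & segments$subtask == subtask, ]
  if (nrow(tr) == 0) return(NA_real_)
  frames <- unlist(lapply(seq_len(nrow(tr)), function(r)
    if (tr$end[r] > tr$start[r]) tr$start[r]:(tr$end[r] - 1L) else integer(0)))
  obs <- series$obs[frames + 1L, ]
  obs <- obs[obs$valid, ]
  if (nrow(obs) == 0) return(NA_real_)
  inside <- obs$x >= roi$xmin & obs$x <= roi$xmax &
    obs$y >= roi$ymin & obs$y <= roi$ymax
  100 * mean(inside)
}

#' Per-subtask kinematic summary of one trial
#'
#' Aggregates segment-level metrics to one record per subtask: mean over the
#' subtask's travel segments for speed, |acceleration| and percent speed
#' error (the error of each segment's mean speed, then averaged); mean over
#' its non-missing endpoint segments for center offset; path accuracy over
#' the pooled travel frames.
#'
#' @param series a \code{\link{centroid_series}}.
#' @param segments its \code{\link{extract_segments}} table.
#' @param proto the \code{\link{protocol}}.
#' @param participant_id,trial identifiers copied into the records.
#' @param age subject age copied into the records (NA if unknown).
#' @return data.frame of class \code{metric_table}, one row per subtask:
#'   \code{participant_id}, \code{age}, \code{trial}, \code{subtask},
#'   \code{speed_mmps}, \code{accel_mmps2}, \code{speed_error_pct},
#'   \code{center_offset_mm}, \code{ipa_pct}, \code{n_travel},
#'   \code{n_endpoint}, \code{missing} (no usable segment).
#' @export
summarize_trial <- function(series, segments, proto = protocol(),
                            participant_id = 1L, trial = 1L, age = NA_real_) {
  rows <- lapply(seq_along(proto$subtask_ids), function(s) {
    tr <- segments[segments$kind == "travel" & segments$subtask == s, ]
    ep <- segments[segments$kind == "endpoint" & segments$subtask == s &
                     !segments$missing, ]
    speeds <- vapply(seq_len(nrow(tr)), function(r)
      segment_mean_speed(tr[r, ], series), numeric(1))
    accels <- vapply(seq_len(nrow(tr)), function(r)
      segment_mean_acceleration(tr[r, ], series), numeric(1))
    offsets <- vapply(seq_len(nrow(ep)), function(r)
      center_offset(ep[r, ], series, proto), numeric(1))
    data.frame(
      participant_id = participant_id, age = age, trial = trial,
      subtask = proto$subtask_ids[s],
      speed_mmps = if (all(is.na(speeds))) NA_real_ else mean(speeds, na.rm = TRUE),
      accel_mmps2 = if (all(is.na(accels))) NA_real_ else mean(accels, na.rm = TRUE),
      speed_error_pct = if (all(is.na(speeds))) NA_real_ else
        mean(percent_speed_error(speeds[!is.na(speeds)], proto$training_speed)),
      center_offset_mm = if (length(offsets) == 0 || all(is.na(offsets)))
        NA_real_ else mean(offsets, na.rm = TRUE),
      ipa_pct = intertarget_path_accuracy(segments, series, proto, s),
      n_travel = nrow(tr), n_endpoint = nrow(ep),
      missing = nrow(tr) == 0)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("metric_table", "data.frame")
  out
}
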