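#' Per-trial centroid series
#'
#' Container for the per-frame fiducial observations of one trial: the raw
#' output of the tracking stage and the input to segmentation. Frames are
#' 0-based and consecutive; the time of frame \code{i} is \code{i / fps}.
#'
#' @param camera the \code{\link{camera_model}} that produced the frames.
#' @param obs data.frame with columns \code{frame} (0-based integer),
#'   \code{x}, \code{y} (px; NA when invalid), \code{radius} (px),
#'   \code{valid} (logical), \code{interpolated} (logical).
#' @return object of class \code{centroid_series}.
#' @export
centroid_series <- function(camera, obs) {
  need <- c("frame", "x", "y", "radius", "valid", "interpolated")
  stopifnot(inherits(camera, "camera_model"), all(need %in% names(obs)))
  obs <- obs[need]
  if (nrow(obs) > 1 && !all(diff(obs$frame) == 1))
    stop("frame indices must increase by exactly 1")
  structure(list(camera = camera, obs = obs), class = "centroid_series")
}

#' @export
print.centroid_series <- function(x, ...) {
  cat(sprintf("<centroid_series> %d frames (%.1f s at %g fps), %d valid, %d interpolated\n",
              nrow(x$obs), nrow(x$obs) / x$camera$fps, x$camera$fps,
              sum(x$obs$valid), sum(x$obs$interpolated)))
  invisible(x)
}

# connected-component candidates of a binary mask: area, equivalent radius,
# circularity 4*pi*A/P^2 (perimeter = closed boundary chain length), and the
# intensity-weighted centroid. Only components passing the area and radius
# gates get a contour (the expensive step).
component_candidates <- function(frame, mask, expected_radius_px,
                                 radius_tol = 0.4, circularity_min = 0.8) {
  if (is.logical(mask)) mask <- mask + 0
  lab <- EBImage::bwlabel(mask)
  nlab <- as.integer(max(lab))
  if (nlab == 0) return(NULL)
  areas <- tabulate(lab[lab > 0L], nbins = nlab)
  eq_r <- sqrt(areas / pi)
  min_area <- pi * (0.5 * expected_radius_px)^2
  keep <- which(areas >= min_area &
                abs(eq_r - expected_radius_px) <= radius_tol * expected_radius_px)
  if (length(keep) == 0) return(NULL)
  contours <- EBImage::ocontour(lab)
  out <- lapply(keep, function(id) {
    ctr <- contours[[id]]
    seg <- ctr - ctr[c(2:nrow(ctr), 1), , drop = FALSE]
    per <- sum(sqrt(rowSums(seg^2)))
    circ <- if (per > 0) 4 * pi * areas[id] / per^2 else 0
    idx <- which(lab == id, arr.ind = TRUE)
    w <- frame[idx]
    if (sum(w) <= 0) w <- rep(1, nrow(idx))
    list(area = areas[id], radius = eq_r[id], circularity = circ,
         x = sum(w * idx[, 2]) / sum(w), y = sum(w * idx[, 1]) / sum(w))
  })
  out <- out[vapply(out, function(c) c$circularity >= circularity_min, logical(1))]
  if (length(out) == 0) NULL else out
}

#' Calibrate the detection threshold from a single frame
#'
#' Re-creates the calibration step performed at the start of every trial:
#' with the marker held still, every candidate gray threshold is tried and a
#' threshold is valid when binarizing the frame at it yields exactly one
#' circle-like component (area, circularity and equivalent-radius gates)
#' whose radius is within \code{radius_tol} of the expected circle radius.
#' The stored operating threshold is the median of the contiguous valid
#' range.
#'
#' @param calibration_frame numeric gray matrix (0..255), e.g. from
#'   \code{\link{render_frame}} or \code{\link{read_frame_png}}.
#' @param expected_radius_px expected circle radius in px (see
#'   \code{\link{expected_radius_px}}).
#' @param radius_tol relative radius tolerance for a valid component.
#' @param circularity_min minimum isoperimetric circularity.
#' @return object of class \code{calibration_result}: \code{threshold},
#'   \code{min_valid_threshold}, \code{max_valid_threshold},
#'   \code{expected_radius_px}, \code{radius_tol}, \code{circularity_min}.
#' @export
calibrate_threshold <- function(calibration_frame, expected_radius_px,
                                radius_tol = 0.4, circularity_min = 0.8) {
  stopifnot(is.matrix(calibration_frame), expected_radius_px > 0)
  thresholds <- seq(0L, 254L)
  ok <- vapply(thresholds, function(t) {
    cand <- component_candidates(calibration_frame, calibration_frame > t,
                                 expected_radius_px, radius_tol,
                                 circularity_min)
    length(cand) == 1L
  }, logical(1))
  if (!any(ok))
    stop("calibration failure: no threshold detects exactly one fiducial circle")
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  iv <- which(runs$values)
  best <- iv[which.max(runs$lengths[iv])]
  lo <- thresholds[starts[best]]; hi <- thresholds[ends[best]]
  structure(list(threshold = (lo + hi) / 2,
                 min_valid_threshold = lo,
                 max_valid_threshold = hi,
                 expected_radius_px = expected_radius_px,
                 radius_tol = radius_tol,
                 circularity_min = circularity_min),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> threshold %.1f (valid %d..%d), expected radius %.2f px\n",
              x$threshold, x$min_valid_threshold, x$max_valid_threshold,
              x$expected_radius_px))
  invisible(x)
}

#' Detect the circle fiducial in one frame
#'
#' Binarizes at the calibrated threshold, labels connected components, and
#' discriminates the fiducial circle from artifacts: components must exceed
#' a minimum area (a disc of half the expected radius), have equivalent
#' radius within the calibration's radius tolerance, and isoperimetric
#' circularity \code{4*pi*A/P^2} at or above the cutoff. Among survivors the
#' most circular wins (ties broken by area). The reported centroid is the
#' intensity-weighted centroid of the component's pixels (sub-pixel); the
#' radius is the equivalent-area radius. Absence of a detectable marker is
#' not an error: an invalid observation is returned.
#'
#' @param frame numeric gray matrix.
#' @param calib a \code{\link{calibrate_threshold}} result.
#' @param frame_index 0-based frame index recorded in the observation.
#' @return one-row data.frame: \code{frame}, \code{x}, \code{y},
#'   \code{radius}, \code{valid}, \code{interpolated}.
#' @export
detect_fiducial <- function(frame, calib, frame_index = 0L) {
  stopifnot(inherits(calib, "calibration_result"))
  cand <- component_candidates(frame, frame > calib$threshold,
                               calib$expected_radius_px, calib$radius_tol,
                               calib$circularity_min)
  if (is.null(cand)) {
    return(data.frame(frame = as.integer(frame_index), x = NA_real_,
                      y = NA_real_, radius = NA_real_, valid = FALSE,
                      interpolated = FALSE))
  }
  circ <- vapply(cand, `[[`, numeric(1), "circularity")
  area <- vapply(cand, `[[`, numeric(1), "area")
  best <- cand[[order(-circ, -area)[1]]]
  data.frame(frame = as.integer(frame_index), x = best$x, y = best$y,
             radius = best$radius, valid = TRUE, interpolated = FALSE)
}

#' Track the fiducial across an ordered stack of frames
#'
#' Runs \code{\link{detect_fiducial}} on every frame and fills short dropout
#' runs (at most \code{max_gap} consecutive invalid frames bracketed by
#' valid ones) by linear interpolation of the centroid, flagging those
#' observations as interpolated. Longer runs stay invalid.
#'
#' @param frames list of numeric gray matrices, in acquisition order.
#' @param calib a \code{\link{calibrate_threshold}} result.
#' @param camera the \code{\link{camera_model}} of the acquisition.
#' @param max_gap longest dropout run (frames) to interpolate across.
#' @return a \code{\link{centroid_series}}.
#' @export
track_frames <- function(frames, calib, camera = camera_model(), max_gap = 3L) {
  stopifnot(length(frames) >= 1)
  obs <- do.call(rbind, lapply(seq_along(frames), function(i) {
    detect_fiducial(frames[[i]], calib, frame_index = i - 1L)
  }))
  if (!any(obs$valid)) stop("tracking failure: no frame contains a detectable fiducial")
  obs <- interpolate_gaps(obs, max_gap)
  centroid_series(camera, obs)
}

# linear interpolation of invalid runs of length <= max_gap with valid
# neighbours on both sides
interpolate_gaps <- function(obs, max_gap) {
  inv <- which(!obs$valid)
  if (length(inv) == 0 || max_gap < 1) return(obs)
  runs <- split(inv, cumsum(c(1, diff(inv) != 1)))
  for (run in runs) {
    a <- min(run) - 1L; b <- max(run) + 1L
    if (length(run) > max_gap) next
    if (a < 1 || b > nrow(obs)) next
    if (!obs$valid[a] || !obs$valid[b]) next
    t <- (run - a) / (b - a)
    obs$x[run] <- obs$x[a] + t * (obs$x[b] - obs$x[a])
    obs$y[run] <- obs$y[a] + t * (obs$y[b] - obs$y[a])
    obs$radius[run] <- obs$radius[a] + t * (obs$radius[b] - obs$radius[a])
    obs$valid[run] <- TRUE
    obs$interpolated[run] <- TRUE
  }
  obs
}
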