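#' Write a trial file
#'
#' Serializes a centroid series plus (optionally) its per-frame target
#' statuses to the plain-text trial dialect: '#'-prefixed \code{key: value}
#' header lines carrying the camera parameters and identifiers, then one
#' tab-separated record per frame. Numeric fields are written with full
#' (17 significant digit) precision so that \code{read(write(x)) == x}.
#'
#' @param series a \code{\link{centroid_series}}.
#' @param statuses optional \code{\link{run_state_machine}} result aligned
#'   with the series.
#' @param path output file path.
#' @param participant_id,trial identifiers stored in the header.
#' @param timestamp ISO-8601 string stored in the header.
#' @return \code{path}, invisibly.
#' @export
write_trial_file <- function(series, statuses = NULL, path,
                             participant_id = 1L, trial = 1L,
                             timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ",
                                                tz = "UTC")) {
  stopifnot(inherits(series, "centroid_series"))
  obs <- series$obs
  cam <- series$camera
  if (!is.null(statuses)) {
    stopifnot(nrow(statuses) == nrow(obs))
    il <- statuses$inside_left; ir <- statuses$inside_right
    at <- statuses$active_target; si <- statuses$subtask_id
  } else {
    il <- rep(NA, nrow(obs)); ir <- rep(NA, nrow(obs))
    at <- rep(NA_character_, nrow(obs)); si <- rep(NA_character_, nrow(obs))
  }
  num <- function(v) ifelse(is.na(v), "NA", sprintf("%.17g", v))
  hdr <- c("# reachtrack trial file v1",
           sprintf("# participant_id: %s", participant_id),
           sprintf("# trial: %s", trial),
           sprintf("# timestamp: %s", timestamp),
           sprintf("# image_width_px: %d", cam$image_width_px),
           sprintf("# image_height_px: %d", cam$image_height_px),
           sprintf("# fov_width_mm: %.17g", cam$fov_width_mm),
           sprintf("# fps: %.17g", cam$fps))
  cols <- c("frame_index", "time_s", "centroid_x_px", "centroid_y_px",
            "radius_px", "valid", "interpolated", "inside_left",
            "inside_right", "active_target", "subtask_id")
  body <- paste(obs$frame, num(obs$frame / cam$fps), num(obs$x), num(obs$y),
                num(obs$radius), as.integer(obs$valid),
                as.integer(obs$interpolated),
                ifelse(is.na(il), "NA", as.integer(il)),
                ifelse(is.na(ir), "NA", as.integer(ir)),
                ifelse(is.na(at), "NA", at), ifelse(is.na(si), "NA", si),
                sep = "\t")
  writeLines(c(hdr, paste(cols, collapse = "\t"), body), path)
  invisible(path)
}

#' Read a trial file
#'
#' Parses the dialect written by \code{\link{write_trial_file}}. Header keys
#' sufficient to rebuild the camera model are required; a malformed record
#' fails with its line number.
#'
#' @param path trial file path.
#' @return list: \code{series} (a \code{\link{centroid_series}}),
#'   \code{statuses} (data.frame with the stored status columns, or NULL if
#'   none were recorded), \code{header} (named list of header values).
#' @export
read_trial_file <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) stop(sprintf("%s: empty trial file", path))
  hdr_idx <- grep("^#", lines)
  if (length(hdr_idx) == 0 || length(lines) <= length(hdr_idx) + 1)
    stop(sprintf("%s: no data records", path))
  kv <- regmatches(lines[hdr_idx],
                   regexec("^#\\s*([A-Za-z0-9_]+):\\s*(.*)$", lines[hdr_idx]))
  header <- list()
  for (m in kv) if (length(m) == 3) header[[m[2]]] <- m[3]
  for (key in c("image_width_px", "image_height_px", "fov_width_mm", "fps"))
    if (is.null(header[[key]]))
      stop(sprintf("%s: missing header key '%s'", path, key))

  col_line <- length(hdr_idx) + 1L
  cols <- strsplit(lines[col_line], "\t", fixed = TRUE)[[1]]
  expect <- c("frame_index", "time_s", "centroid_x_px", "centroid_y_px",
              "radius_px", "valid", "interpolated", "inside_left",
              "inside_right", "active_target", "subtask_id")
  if (!identical(cols, expect))
    stop(sprintf("%s: unexpected column header at line %d", path, col_line))
  body <- lines[(col_line + 1L):length(lines)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != length(expect))
  if (length(bad))
    stop(sprintf("%s: malformed record at line %d (expected %d fields, got %d)",
                 path, col_line + bad[1], length(expect),
                 lengths(parts)[bad[1]]))
  m <- do.call(rbind, parts)
  suppress_na <- function(v) suppressWarnings(as.numeric(v))
  camera <- camera_model(as.integer(header$image_width_px),
                         as.integer(header$image_height_px),
                         as.numeric(header$fov_width_mm),
                         as.numeric(header$fps))
  obs <- data.frame(frame = as.integer(m[, 1]),
                    x = suppress_na(m[, 3]), y = suppress_na(m[, 4]),
                    radius = suppress_na(m[, 5]),
                    valid = m[, 6] == "1", interpolated = m[, 7] == "1")
  series <- centroid_series(camera, obs)
  statuses <- NULL
  if (!all(m[, 8] == "NA")) {
    statuses <- data.frame(frame = obs$frame,
                           inside_left = m[, 8] == "1",
                           inside_right = m[, 9] == "1",
                           active_target = m[, 10],
                           subtask_id = m[, 11])
  }
  list(series = series, statuses = statuses, header = header)
}

#' Write and read gray frames as PNG
#'
#' Frame stacks are exchanged as directories of numbered 8-bit grayscale
#' PNGs (frame order = file name order). Color PNGs are converted to
#' luminance with the ITU-R BT.601 weights on reading.
#'
#' @param frames list of numeric gray matrices (0..255).
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return character vector of file paths (write) / list of matrices (read).
#' @export
write_frames_png <- function(frames, dir, prefix = "frame") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, sprintf("%s_%06d.png", prefix, seq_along(frames)))
  for (i in seq_along(frames))
    png::writePNG(pmin(pmax(frames[[i]] / 255, 0), 1), paths[i])
  invisible(paths)
}

#' @rdname write_frames_png
#' @param path a single PNG file path.
#' @export
read_frame_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) {
    if (dim(img)[3] >= 3)
      img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    else img <- img[, , 1]
  }
  img * 255
}

#' @rdname write_frames_png
#' @export
read_frames_png <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) stop(sprintf("%s: no PNG frames found", dir))
  lapply(files, read_frame_png)
}

#' Write a long metric table as CSV
#'
#' Fixed-schema CSV emitter for metric tables (the column set is stable so
#' downstream tooling can rely on it).
#'
#' @param metric_table a \code{metric_table}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_metric_csv <- function(metric_table, path) {
  cols <- c("participant_id", "age", "trial", "subtask", "speed_mmps",
            "accel_mmps2", "speed_error_pct", "center_offset_mm", "ipa_pct")
  utils::write.csv(as.data.frame(metric_table)[, cols], path,
                   row.names = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' Validated bundle of pipeline settings with defaults equal to the standard
#' acquisition constants (183-mm field of view at 752 x 480 and 30 fps,
#' 25.7 mm/s training speed, 100/62/50-px targets 138 mm apart, 10-s rests).
#' Unknown keys are rejected.
#'
#' @param ... overrides; see Details for keys.
#' @details Keys: \code{image_width_px}, \code{image_height_px},
#'   \code{fov_width_mm}, \code{fps}; \code{training_speed},
#'   \code{center_to_center_mm}, \code{rest_duration_s};
#'   \code{radius_tol}, \code{circularity_min}, \code{max_gap};
#'   \code{icc_form} ("2k"/"3k"), \code{stratify_subtask},
#'   \code{status_source} ("geometry"/"recorded"); \code{seed},
#'   \code{n_subjects}, \code{age_min}, \code{age_max}, \code{out_dir}.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(...) {
  defaults <- list(
    image_width_px = 752L, image_height_px = 480L, fov_width_mm = 183,
    fps = 30, training_speed = 25.7, center_to_center_mm = 138,
    rest_duration_s = 10, radius_tol = 0.4, circularity_min = 0.8,
    max_gap = 3L, icc_form = "2k", stratify_subtask = FALSE,
    status_source = "geometry", seed = 1L, n_subjects = 20L,
    age_min = 43, age_max = 94, out_dir = "reachtrack-out")
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, overrides)
  stopifnot(cfg$icc_form %in% c("2k", "3k"),
            cfg$status_source %in% c("geometry", "recorded"))
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path YAML file of overrides.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(run_config, vals)
}

#' Camera and protocol objects from a run configuration
#' @param cfg a \code{\link{run_config}}.
#' @return list with \code{camera} and \code{protocol}.
#' @export
config_objects <- function(cfg) {
  cam <- camera_model(cfg$image_width_px, cfg$image_height_px,
                      cfg$fov_width_mm, cfg$fps)
  list(camera = cam,
       protocol = protocol(cam, training_speed = cfg$training_speed,
                           center_to_center_mm = cfg$center_to_center_mm,
                           rest_duration_s = cfg$rest_duration_s))
}
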