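#' Pipeline stages
#'
#' Batch recast of the acquisition system's runtime loops as file-to-file
#' stages under one output directory:
#' \describe{
#'   \item{simulate}{write a synthetic cohort as trial files plus the
#'     ground-truth knob table (\code{trials/}, \code{cohort_truth.csv}).}
#'   \item{detect}{track a directory of PNG frames into a trial file.}
#'   \item{metrics}{segment every trial file and write the long metric
#'     table (\code{metrics.csv}).}
#'   \item{reliability}{ICC/LCC and age-trend tables plus a text report and
#'     figure panels (\code{reliability.csv}, \code{age_trends.csv},
#'     \code{report.txt}, \code{figures/}).}
#' }
#' Each stage checks that its input stage has run and fails with a
#' dependency error otherwise. Runs are deterministic given the seed.
#'
#' @param cfg a \code{\link{run_config}}.
#' @return the output paths written, invisibly (stage functions); the config
#'   for \code{run_pipeline}.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
pipeline_simulate <- function(cfg = run_config()) {
  obj <- config_objects(cfg)
  dir.create(file.path(cfg$out_dir, "trials"), showWarnings = FALSE,
             recursive = TRUE)
  cohort <- simulate_cohort(cfg$n_subjects, c(cfg$age_min, cfg$age_max),
                            seed = cfg$seed, mode = "trajectories",
                            proto = obj$protocol)
  paths <- character(0); truth <- list()
  for (i in seq_len(cfg$n_subjects)) {
    for (tr in 1:2) {
      sim <- cohort$trials[[i]][[tr]]
      st <- run_state_machine(sim$series, obj$protocol)
      p <- file.path(cfg$out_dir, "trials",
                     sprintf("P%03d_T%d.tsv", i, tr))
      write_trial_file(sim$series, st, p, participant_id = i, trial = tr,
                       timestamp = "1970-01-01T00:00:00Z")
      paths <- c(paths, p)
      sj <- sim$subject
      truth[[length(truth) + 1L]] <- data.frame(
        participant_id = i, age = cohort$subjects$age[i], trial = tr,
        true_speed_mmps = obj$protocol$training_speed * sj$speed_mult,
        true_speed_error_pct = 100 * (sj$speed_mult - 1),
        true_overshoot_mm = sj$overshoot_mm,
        true_path_noise_sd_mm = sj$path_noise_sd,
        true_accel_jitter_sd = sj$accel_jitter_sd)
    }
  }
  utils::write.csv(do.call(rbind, truth),
                   file.path(cfg$out_dir, "cohort_truth.csv"),
                   row.names = FALSE)
  invisible(c(paths, file.path(cfg$out_dir, "cohort_truth.csv")))
}

#' @rdname pipeline
#' @param frames_dir directory of numbered PNG frames.
#' @param calibration_frame_path PNG of the calibration frame (marker held
#'   still); defaults to the first frame in \code{frames_dir}.
#' @param participant_id,trial identifiers for the output trial file.
#' @export
pipeline_detect <- function(cfg = run_config(), frames_dir,
                            calibration_frame_path = NULL,
                            participant_id = 1L, trial = 1L) {
  # detection needs only the camera, not the task geometry, so any sensor
  # crop can be processed even if the full target layout would not fit it
  camera <- camera_model(cfg$image_width_px, cfg$image_height_px,
                         cfg$fov_width_mm, cfg$fps)
  frames <- read_frames_png(frames_dir)
  calib_frame <- if (is.null(calibration_frame_path)) frames[[1]]
                 else read_frame_png(calibration_frame_path)
  calib <- calibrate_threshold(calib_frame,
                               expected_radius_px(marker_spec(), camera),
                               radius_tol = cfg$radius_tol,
                               circularity_min = cfg$circularity_min)
  series <- track_frames(frames, calib, camera, max_gap = cfg$max_gap)
  dir.create(file.path(cfg$out_dir, "trials"), showWarnings = FALSE,
             recursive = TRUE)
  p <- file.path(cfg$out_dir, "trials",
                 sprintf("P%03d_T%d.tsv", participant_id, trial))
  write_trial_file(series, NULL, p, participant_id, trial,
                   timestamp = "1970-01-01T00:00:00Z")
  invisible(p)
}

#' @rdname pipeline
#' @export
pipeline_metrics <- function(cfg = run_config()) {
  obj <- config_objects(cfg)
  trial_dir <- file.path(cfg$out_dir, "trials")
  files <- sort(list.files(trial_dir, pattern = "\\.tsv$", full.names = TRUE))
  if (length(files) == 0)
    stop(sprintf("dependency error: no trial files in %s; run the simulate or detect stage first",
                 trial_dir))
  truth_path <- file.path(cfg$out_dir, "cohort_truth.csv")
  ages <- NULL
  if (file.exists(truth_path)) {
    tt <- utils::read.csv(truth_path)
    ages <- tt[!duplicated(tt$participant_id),
               c("participant_id", "age")]
  }
  tabs <- lapply(files, function(f) {
    tf <- read_trial_file(f)
    recorded <- if (cfg$status_source == "recorded") tf$statuses else NULL
    st <- run_state_machine(tf$series, obj$protocol, recorded = recorded)
    seg <- extract_segments(st, tf$series)
    pid <- as.integer(tf$header$participant_id)
    age <- if (!is.null(ages)) ages$age[match(pid, ages$participant_id)]
           else NA_real_
    summarize_trial(tf$series, seg, obj$protocol, participant_id = pid,
                    trial = as.integer(tf$header$trial), age = age)
  })
  out <- do.call(rbind, tabs)
  p <- file.path(cfg$out_dir, "metrics.csv")
  write_metric_csv(out, p)
  invisible(p)
}

#' @rdname pipeline
#' @export
pipeline_reliability <- function(cfg = run_config()) {
  p_metrics <- file.path(cfg$out_dir, "metrics.csv")
  if (!file.exists(p_metrics))
    stop("dependency error: metrics.csv not found; run the metrics stage first")
  mt <- utils::read.csv(p_metrics)
  rel <- reliability_table(mt, stratify_subtask = cfg$stratify_subtask)
  if (cfg$icc_form == "3k") {
    rel$icc_reported <- rel$icc3k
  } else rel$icc_reported <- rel$icc
  trends <- age_trend_table(mt)
  utils::write.csv(rel, file.path(cfg$out_dir, "reliability.csv"),
                   row.names = FALSE)
  utils::write.csv(trends, file.path(cfg$out_dir, "age_trends.csv"),
                   row.names = FALSE)

  fig_dir <- file.path(cfg$out_dir, "figures")
  dir.create(fig_dir, showWarnings = FALSE, recursive = TRUE)
  figs <- character(0)
  for (metric in unique(rel$metric)) {
    f <- file.path(fig_dir, paste0(metric, "_trial1_vs_trial2.png"))
    plot_trial_vs_trial(mt, metric, file = f)
    figs <- c(figs, f)
  }

  rp <- file.path(cfg$out_dir, "report.txt")
  con <- file(rp, "w"); on.exit(close(con))
  writeLines(c("reachtrack reliability report",
               sprintf("seed: %s", cfg$seed),
               sprintf("config: %s", config_digest(cfg)),
               sprintf("package version: %s",
                       as.character(utils::packageVersion("reachtrack"))),
               "", "Test-retest reliability (subtask-averaged values):"), con)
  utils::capture.output(print(rel, digits = 3), file = con, append = TRUE)
  writeLines(c("", "Age trends (trial-averaged values):"), con)
  utils::capture.output(print(trends, digits = 3), file = con, append = TRUE)
  invisible(c(file.path(cfg$out_dir, c("reliability.csv", "age_trends.csv")),
              rp, figs))
}

#' @rdname pipeline
#' @export
run_pipeline <- function(cfg = run_config()) {
  pipeline_simulate(cfg)
  pipeline_metrics(cfg)
  pipeline_reliability(cfg)
  invisible(cfg)
}

# short stable digest of the configuration for the report log
config_digest <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(v) paste(format(v), collapse = ","),
                                character(1)), sep = "=", collapse = ";")
  sprintf("%d keys, sum %.0f", length(cfg),
          sum(utf8ToInt(s) * seq_along(utf8ToInt(s))))
}

#' Trial-1 versus trial-2 scatter panels
#'
#' One scatter panel per subtask of per-subject trial-1 vs trial-2 values
#' for a metric, with the least-squares line and the identity for reference.
#'
#' @param metric_table long metric table.
#' @param metric metric column name.
#' @param file optional PNG path; when given the plot is written there.
#' @return invisibly, the per-subtask \code{\link{trial_vs_trial}} results.
#' @export
plot_trial_vs_trial <- function(metric_table, metric, file = NULL) {
  subs <- unique(metric_table$subtask)
  mats <- subject_trial_matrix(metric_table, metric, stratify_subtask = TRUE)
  if (!is.null(file)) {
    grDevices::png(file, width = 1200, height = 800, res = 120)
    on.exit(grDevices::dev.off())
  }
  old <- graphics::par(mfrow = c(2, ceiling(length(subs) / 2)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old), add = TRUE, after = FALSE)
  results <- list()
  for (s in subs) {
    m <- mats[[s]]
    tv <- tryCatch(trial_vs_trial(m), error = function(e) NULL)
    results[[s]] <- tv
    title <- if (is.null(tv)) sprintf("%s: %s (r undefined)", s, metric)
             else sprintf("%s: %s (r = %.2f)", s, metric, tv$lcc)
    graphics::plot(m[, 1], m[, 2], pch = 19, col = "steelblue",
                   xlab = "trial 1", ylab = "trial 2", main = title)
    if (!is.null(tv))
      graphics::abline(tv$intercept, tv$slope, col = "firebrick", lwd = 2)
    graphics::abline(0, 1, lty = 3, col = "gray50")
  }
  invisible(results)
}
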