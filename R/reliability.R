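#' Subject-by-trial matrix for one metric
#'
#' Pools a long metric table to one value per subject and trial by averaging
#' the subtask means (pre-averaging across the six subtasks), then drops
#' subjects with any missing cell listwise (with a message naming how many).
#' With \code{stratify_subtask = TRUE} a matrix is returned per subtask
#' instead.
#'
#' @param metric_table a \code{metric_table} data.frame (see
#'   \code{\link{summarize_trial}} / \code{\link{simulate_cohort}}).
#' @param metric column name, e.g. \code{"speed_mmps"}.
#' @param stratify_subtask return a list of per-subtask matrices.
#' @return numeric matrix \code{n x k} with attribute \code{ages} (per
#'   subject), or a named list of such matrices.
#' @export
subject_trial_matrix <- function(metric_table, metric,
                                 stratify_subtask = FALSE) {
  stopifnot(metric %in% names(metric_table))
  if (stratify_subtask) {
    subs <- unique(metric_table$subtask)
    out <- lapply(subs, function(s)
      subject_trial_matrix(metric_table[metric_table$subtask == s, ], metric))
    names(out) <- subs
    return(out)
  }
  agg <- stats::aggregate(metric_table[[metric]],
                          by = list(participant_id = metric_table$participant_id,
                                    trial = metric_table$trial),
                          FUN = mean)
  wide <- stats::reshape(agg, idvar = "participant_id", timevar = "trial",
                         direction = "wide")
  ages <- metric_table$age[match(wide$participant_id,
                                 metric_table$participant_id)]
  m <- as.matrix(wide[, -1, drop = FALSE])
  keep <- stats::complete.cases(m)
  if (any(!keep))
    message(sprintf("%s: dropped %d subject(s) with missing trial values",
                    metric, sum(!keep)))
  m <- m[keep, , drop = FALSE]
  colnames(m) <- paste0("trial", seq_len(ncol(m)))
  rownames(m) <- wide$participant_id[keep]
  attr(m, "ages") <- ages[keep]
  m
}

#' Two-way ANOVA without replication
#'
#' Mean squares of the subjects-by-trials decomposition
#' \code{SS_total = SS_rows + SS_cols + SS_error} with degrees of freedom
#' \code{n - 1}, \code{k - 1}, \code{(n - 1)(k - 1)}; the building block of
#' the intraclass correlation. Fitted via \code{stats::aov}.
#'
#' @param m complete numeric matrix, subjects in rows, trials in columns,
#'   \code{n >= 3}, \code{k >= 2}.
#' @return list: \code{MSR} (rows/subjects), \code{MSC} (columns/trials),
#'   \code{MSE} (residual), \code{n}, \code{k}, and the df triple.
#' @export
anova_two_way_no_rep <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m))
    stop("matrix has missing cells; exclude incomplete subjects upstream")
  n <- nrow(m); k <- ncol(m)
  stopifnot(n >= 3, k >= 2)
  long <- data.frame(value = as.vector(m),
                     subject = factor(rep(seq_len(n), k)),
                     trial = factor(rep(seq_len(k), each = n)))
  tab <- summary(stats::aov(value ~ subject + trial, data = long))[[1]]
  ms <- tab[["Mean Sq"]]
  list(MSR = ms[1], MSC = ms[2], MSE = ms[3], n = n, k = k,
       df = c(rows = n - 1L, cols = k - 1L, error = (n - 1L) * (k - 1L)))
}

#' Intraclass correlation ICC(2,k) with confidence interval
#'
#' Agreement ICC for the average of k measurements under the two-way model,
#' \code{ICC(2,k) = (MSR - MSE) / (MSR + (MSC - MSE)/n)}, with a 95 percent
#' confidence interval by the Shrout-Fleiss F-based procedure (the
#' single-rater bounds converted to average-measure form by the
#' Spearman-Brown step-up). The consistency form
#' \code{ICC(3,k) = (MSR - MSE)/MSR} is reported as a secondary value.
#'
#' @param m complete numeric matrix, subjects in rows, trials in columns.
#' @param conf confidence level.
#' @return list of class \code{icc_result}: \code{icc} (the 2,k form),
#'   \code{icc_ci95}, \code{icc3k}, \code{icc3k_ci95}, \code{icc_single}
#'   (the single-measure ICC(2,1), the quantity a Pearson trial-1/trial-2
#'   correlation estimates when there is no systematic trial shift),
#'   \code{n}, \code{k}, and the mean squares.
#' @export
icc_2k <- function(m, conf = 0.95) {
  a <- anova_two_way_no_rep(m)
  n <- a$n; k <- a$k
  MSR <- a$MSR; MSC <- a$MSC; MSE <- a$MSE
  alpha <- 1 - conf
  # treat FP-level row variance (e.g. a constant matrix through aov) as zero
  ms_tol <- 1e-12 * max(1, abs(mean(m)))^2
  if (MSR <= ms_tol) {
    warning("no between-subject variance; ICC reported as 0")
    return(structure(list(icc = 0, icc_ci95 = c(0, 0), icc3k = 0,
                          icc3k_ci95 = c(0, 0), icc_single = 0, n = n,
                          k = k, MSR = MSR, MSC = MSC, MSE = MSE),
                     class = "icc_result"))
  }

  icc2k <- (MSR - MSE) / (MSR + (MSC - MSE) / n)
  icc21 <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)

  # Shrout-Fleiss CI for the single-rater ICC(2,1), then Spearman-Brown
  Fj <- MSC / MSE
  vn <- (k - 1) * (n - 1) *
    (k * icc21 * Fj + n * (1 + (k - 1) * icc21) - k * icc21)^2
  vd <- (n - 1) * k^2 * icc21^2 * Fj^2 +
    (n * (1 + (k - 1) * icc21) - k * icc21)^2
  v <- vn / vd
  FU <- stats::qf(1 - alpha / 2, n - 1, v)
  FL <- stats::qf(1 - alpha / 2, v, n - 1)
  L21 <- n * (MSR - FU * MSE) /
    (FU * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  U21 <- n * (FL * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * FL * MSR)
  sb <- function(r1) k * r1 / (1 + (k - 1) * r1)
  ci2k <- sort(c(sb(L21), sb(U21)))

  icc3k <- (MSR - MSE) / MSR
  F3 <- MSR / MSE
  df2 <- (n - 1) * (k - 1)
  lo3 <- 1 - 1 / (F3 / stats::qf(1 - alpha / 2, n - 1, df2))
  hi3 <- 1 - 1 / (F3 * stats::qf(1 - alpha / 2, df2, n - 1))
  structure(list(icc = icc2k, icc_ci95 = ci2k, icc3k = icc3k,
                 icc3k_ci95 = sort(c(lo3, hi3)), icc_single = icc21,
                 n = n, k = k, MSR = MSR, MSC = MSC, MSE = MSE),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(2,k) = %.3f (95%% CI %.3f-%.3f); ICC(3,k) = %.3f (%.3f-%.3f); n = %d, k = %d\n",
              x$icc, x$icc_ci95[1], x$icc_ci95[2], x$icc3k,
              x$icc3k_ci95[1], x$icc3k_ci95[2], x$n, x$k))
  invisible(x)
}

#' Pearson correlation between trials with Fisher-z interval
#'
#' Linear correlation coefficient between the trial-1 and trial-2 columns,
#' with the standard Fisher z-transform 95 percent confidence interval
#' (via \code{stats::cor.test}).
#'
#' @param m numeric matrix with at least two columns; the first two are
#'   correlated.
#' @param conf confidence level.
#' @return list of class \code{lcc_result}: \code{lcc}, \code{lcc_ci95},
#'   \code{p_value}, \code{n}.
#' @export
lcc <- function(m, conf = 0.95) {
  m <- as.matrix(m)
  stopifnot(nrow(m) >= 3, ncol(m) >= 2)
  if (stats::sd(m[, 1]) == 0 || stats::sd(m[, 2]) == 0)
    stop("a trial column has zero variance; correlation undefined")
  ct <- stats::cor.test(m[, 1], m[, 2], conf.level = conf)
  structure(list(lcc = unname(ct$estimate), lcc_ci95 = as.numeric(ct$conf.int),
                 p_value = ct$p.value, n = nrow(m)),
            class = "lcc_result")
}

#' @export
print.lcc_result <- function(x, ...) {
  cat(sprintf("LCC = %.3f (95%% CI %.3f-%.3f), p = %.3g, n = %d\n",
              x$lcc, x$lcc_ci95[1], x$lcc_ci95[2], x$p_value, x$n))
  invisible(x)
}

#' Ordinary least-squares age regression
#'
#' Linear trend of a per-subject metric value against age, with the
#' two-sided p-value for a nonzero slope. Values are normally the mean of
#' the two trials (or a single trial's values, as configured upstream).
#'
#' @param values per-subject metric values.
#' @param ages per-subject ages, years.
#' @return list of class \code{age_regression}: \code{slope} (metric units
#'   per year), \code{intercept}, \code{slope_se}, \code{p_value}, \code{n}.
#' @export
age_regression <- function(values, ages) {
  stopifnot(length(values) == length(ages))
  keep <- stats::complete.cases(values, ages)
  values <- values[keep]; ages <- ages[keep]
  if (length(values) < 3) stop("need at least 3 complete observations")
  if (stats::sd(ages) == 0) stop("ages are constant; slope unidentifiable")
  fit <- stats::lm(values ~ ages)
  sm <- summary(fit)$coefficients
  structure(list(slope = sm["ages", "Estimate"],
                 intercept = sm["(Intercept)", "Estimate"],
                 slope_se = sm["ages", "Std. Error"],
                 p_value = sm["ages", "Pr(>|t|)"],
                 n = length(values)), class = "age_regression")
}

#' Trial-1 versus trial-2 association
#'
#' The scatter-panel statistics: Pearson correlation (with Fisher-z CI)
#' plus the least-squares line of trial 2 on trial 1.
#'
#' @param m subject-by-trial matrix (two columns used).
#' @return list of class \code{trial_vs_trial}: \code{lcc} result fields
#'   plus \code{slope}, \code{intercept} of trial2 ~ trial1.
#' @export
trial_vs_trial <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 3) stop("need at least 3 subjects")
  r <- lcc(m)
  fit <- stats::lm(m[, 2] ~ m[, 1])
  structure(c(unclass(r),
              list(slope = unname(stats::coef(fit)[2]),
                   intercept = unname(stats::coef(fit)[1]))),
            class = "trial_vs_trial")
}

#' Reliability summary across metrics
#'
#' ICC(2,k) and LCC with 95 percent intervals for every kinematic metric in
#' a long metric table, each computed on the subject-by-trial matrix of
#' subtask-averaged values.
#'
#' @param metric_table long metric table.
#' @param metrics metric column names to summarize.
#' @param stratify_subtask if TRUE, one row per metric and subtask.
#' @return data.frame: \code{metric} (and \code{subtask} when stratified),
#'   \code{icc}, \code{icc_lo}, \code{icc_hi}, \code{icc3k}, \code{lcc},
#'   \code{lcc_lo}, \code{lcc_hi}, \code{lcc_p}, \code{n}.
#' @export
reliability_table <- function(metric_table,
                              metrics = c("speed_mmps", "accel_mmps2",
                                          "center_offset_mm", "ipa_pct",
                                          "speed_error_pct"),
                              stratify_subtask = FALSE) {
  one <- function(m, metric, subtask = NA_character_) {
    ic <- icc_2k(m); lc <- lcc(m)
    data.frame(metric = metric, subtask = subtask, icc = ic$icc,
               icc_lo = ic$icc_ci95[1], icc_hi = ic$icc_ci95[2],
               icc3k = ic$icc3k, lcc = lc$lcc, lcc_lo = lc$lcc_ci95[1],
               lcc_hi = lc$lcc_ci95[2], lcc_p = lc$p_value, n = ic$n)
  }
  rows <- list()
  for (metric in metrics) {
    if (stratify_subtask) {
      ms <- subject_trial_matrix(metric_table, metric, stratify_subtask = TRUE)
      for (s in names(ms))
        rows[[length(rows) + 1L]] <- one(ms[[s]], metric, s)
    } else {
      rows[[length(rows) + 1L]] <-
        one(subject_trial_matrix(metric_table, metric), metric)
    }
  }
  out <- do.call(rbind, rows)
  if (!stratify_subtask) out$subtask <- NULL
  rownames(out) <- NULL
  out
}

#' Age-trend summary across metrics and subtasks
#'
#' Per metric and subtask, the OLS slope (metric units per year) and p-value
#' of the trial-averaged subject values against age.
#'
#' @param metric_table long metric table with an \code{age} column.
#' @param metrics metric column names.
#' @return data.frame: \code{metric}, \code{subtask}, \code{slope},
#'   \code{p_value}, \code{n}.
#' @export
age_trend_table <- function(metric_table,
                            metrics = c("speed_mmps", "accel_mmps2",
                                        "center_offset_mm", "ipa_pct",
                                        "speed_error_pct")) {
  rows <- list()
  for (metric in metrics) {
    for (s in unique(metric_table$subtask)) {
      sub <- metric_table[metric_table$subtask == s, ]
      agg <- stats::aggregate(sub[[metric]],
                              by = list(participant_id = sub$participant_id),
                              FUN = mean)
      ages <- sub$age[match(agg$participant_id, sub$participant_id)]
      ar <- age_regression(agg$x, ages)
      rows[[length(rows) + 1L]] <- data.frame(
        metric = metric, subtask = s, slope = ar$slope,
        p_value = ar$p_value, n = ar$n)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
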