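# 4x2 worked matrix: row means 1.5/3.5/5.5/7.5, column means 4/5, grand 4.5
# SS_rows = 2*(9+1+1+9) = 40 -> MSR = 40/3; SS_cols = 4*(0.25+0.25) = 2 ->
# MSC = 2; residuals all zero -> MSE = 0.
worked <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8), ncol = 2, byrow = TRUE)

test_that("two-way ANOVA mean squares match hand arithmetic", {
  a <- anova_two_way_no_rep(worked)
  expect_equal(a$MSR, 40 / 3, tolerance = 1e-12)
  expect_equal(a$MSC, 2, tolerance = 1e-12)
  expect_equal(a$MSE, 0, tolerance = 1e-12)
  expect_equal(unname(a$df), c(3L, 1L, 3L))

  ident <- cbind(1:3, 1:3)
  ai <- anova_two_way_no_rep(ident)
  expect_equal(ai$MSC, 0, tolerance = 1e-12)
  expect_equal(ai$MSE, 0, tolerance = 1e-12)

  # exchangeability: permuting subjects leaves the mean squares unchanged
  ap <- anova_two_way_no_rep(worked[c(3, 1, 4, 2), ])
  expect_equal(ap[c("MSR", "MSC", "MSE")], a[c("MSR", "MSC", "MSE")])

  expect_error(anova_two_way_no_rep(rbind(worked, c(NA, 1))), "missing cells")
})

test_that("ICC(2,k) matches the plug-in formula and its reference values", {
  # hand plug-in on the worked matrix: (40/3 - 0)/(40/3 + (2 - 0)/4)
  ic <- icc_2k(worked)
  expect_equal(ic$icc, (40 / 3) / (40 / 3 + 0.5), tolerance = 1e-12)
  expect_equal(ic$icc3k, 1, tolerance = 1e-12)

  # identical columns: perfect agreement
  m <- cbind(c(4, 9, 2, 7), c(4, 9, 2, 7))
  expect_equal(icc_2k(m)$icc, 1)

  # frozen reference (independent implementation, same 8x2 matrix)
  m8 <- matrix(c(10.2, 11.0, 9.1, 9.5, 12.3, 12.8, 8.7, 9.9,
                 11.5, 11.1, 10.0, 10.9, 9.8, 9.2, 12.9, 13.5),
               ncol = 2, byrow = TRUE)
  ic8 <- icc_2k(m8)
  expect_equal(ic8$icc, 0.9415758156623133, tolerance = 1e-12)
  expect_equal(round(ic8$icc_ci95, 2), c(0.68, 0.99))
  expect_equal(ic8$icc3k, 0.9556582360570682, tolerance = 1e-12)
  expect_equal(round(ic8$icc3k_ci95, 2), c(0.78, 0.99))

  # no subject variance: 0 with a warning
  expect_warning(z <- icc_2k(matrix(5, 4, 2)), "ICC reported as 0")
  expect_equal(z$icc, 0)
})

test_that("the estimator recovers a known variance-component ICC", {
  theta <- 1 / (1 + 0.84^2 / 2)  # sd_subject 1, sd_resid 0.84 -> ~0.739
  est <- vapply(1:40, function(r) {
    icc_2k(simulate_metric_matrix(200, 2, 0, 1, 0, 0.84, seed = 500 + r))$icc
  }, numeric(1))
  expect_lt(abs(mean(est) - theta), 0.05)
})

test_that("consistency ICC dominates agreement ICC under a trial shift", {
  for (r in 1:10) {
    m <- simulate_metric_matrix(50, 2, 0, 1, sd_trial = 0.6, sd_resid = 0.5,
                                seed = 700 + r)
    ic <- icc_2k(m)
    if (ic$MSC > ic$MSE) expect_gte(ic$icc3k, ic$icc)
  }
})

test_that("Pearson trial correlation behaves at the anchors", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4)
  expect_equal(lcc(cbind(x, x))$lcc, 1)
  expect_equal(lcc(cbind(x, -x))$lcc, -1)
  expect_error(lcc(cbind(x, rep(1, 5))), "zero variance")
})

test_that("lcc estimates the single-measure ICC absent a trial shift", {
  for (r in 1:10) {
    m <- simulate_metric_matrix(111, 2, 0, 1, sd_trial = 0, sd_resid = 0.6,
                                seed = 900 + r)
    expect_lt(abs(icc_2k(m)$icc_single - lcc(m)$lcc), 0.02)
  }
})

test_that("age regression recovers exact and null trends", {
  ages <- seq(43, 94, length.out = 30)
  ar <- suppressWarnings(age_regression(2 * ages, ages))  # exact fit
  expect_equal(ar$slope, 2, tolerance = 1e-10)
  expect_lt(ar$p_value, 1e-12)
  expect_error(age_regression(rnorm(10), rep(50, 10)), "constant")
  # null simulations reject at about the nominal 5 percent rate
  set.seed(61)
  rej <- mean(replicate(400, {
    age_regression(rnorm(40), seq(43, 94, length.out = 40))$p_value < 0.05
  }))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
})

test_that("trial-vs-trial panels report attenuation and degenerate input", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4)
  tv <- trial_vs_trial(cbind(x, x))
  expect_equal(tv$slope, 1, tolerance = 1e-12)
  expect_equal(tv$lcc, 1)
  expect_error(trial_vs_trial(cbind(x[1:2], x[1:2])), "at least 3")
  # within-subject noise attenuates the slope toward sb^2/(sb^2 + sw^2)
  m <- simulate_metric_matrix(2000, 2, 0, 1, 0, 1, seed = 77)
  expect_equal(trial_vs_trial(m)$slope, 0.5, tolerance = 0.06)
})

test_that("confidence intervals bracket the estimate and tighten with n", {
  m_small <- simulate_metric_matrix(15, 2, 0, 1, 0, 0.6, seed = 5)
  m_big <- simulate_metric_matrix(400, 2, 0, 1, 0, 0.6, seed = 5)
  for (m in list(m_small, m_big)) {
    ic <- icc_2k(m); lc <- lcc(m)
    expect_true(ic$icc_ci95[1] <= ic$icc && ic$icc <= ic$icc_ci95[2])
    expect_true(lc$lcc_ci95[1] <= lc$lcc && lc$lcc <= lc$lcc_ci95[2])
  }
  expect_lt(diff(icc_2k(m_big)$icc_ci95), diff(icc_2k(m_small)$icc_ci95))
  expect_lt(diff(lcc(m_big)$lcc_ci95), diff(lcc(m_small)$lcc_ci95))
})

test_that("reliability and age-trend tables cover every metric", {
  mt <- simulate_cohort(40, c(43, 94), seed = 3, mode = "metrics")
  rel <- reliability_table(mt)
  expect_equal(nrow(rel), 5)
  expect_true(all(rel$icc_lo <= rel$icc & rel$icc <= rel$icc_hi))
  trends <- age_trend_table(mt)
  expect_equal(nrow(trends), 30)  # 5 metrics x 6 subtasks
  expect_true(all(trends$p_value > 0 & trends$p_value <= 1))
  # speed rises and path accuracy falls with age under the default model
  expect_true(all(trends$slope[trends$metric == "speed_mmps"] > 0))
  expect_true(all(trends$slope[trends$metric == "ipa_pct"] < 0))
  # stratified mode returns one row per metric and subtask
  rel_s <- reliability_table(mt, metrics = "speed_mmps",
                             stratify_subtask = TRUE)
  expect_equal(nrow(rel_s), 6)
})
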