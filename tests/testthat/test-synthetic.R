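# Synthetic cohort generators: variance structure, moment targets,
# step-stream feasibility, determinism, end-to-end parameter recovery.

test_that("the ICC target controls the within-subject noise exactly at its limits", {
  spec1 <- cohort_spec(n_subjects = 25, conditions = "PWS", target_icc = 1,
                       seed = 2)
  sim1 <- simulate_metric_cohort(spec1)
  pairs <- metric_values_wide(sim1$metrics, "vel", "PWS")
  expect_equal(pairs$walk1, pairs$walk2)

  spec0 <- cohort_spec(n_subjects = 5000, conditions = "PWS", target_icc = 0,
                       seed = 3,
                       calibration = vestibular_cohort_defaults("PWS")[1, ])
  sim0 <- simulate_metric_cohort(spec0)
  pairs0 <- metric_values_wide(sim0$metrics, "vel", "PWS")
  fit <- icc(as.matrix(pairs0[, c("walk1", "walk2")]))
  expect_lt(abs(fit$icc), 0.03)
})

test_that("between- plus within-subject variance reconstructs the population SD", {
  cal <- vestibular_cohort_defaults("PWS")
  cal <- cal[cal$metric %in% c("vel", "swing_cv", "swidth"), ]
  spec <- cohort_spec(n_subjects = 4000, conditions = "PWS",
                      calibration = cal, seed = 8)
  sim <- simulate_metric_cohort(spec)
  for (m in cal$metric) {
    pairs <- metric_values_wide(sim$metrics, m, "PWS")
    x <- as.matrix(pairs[, c("walk1", "walk2")])
    between <- var(rowMeans(x)) - var(x[, 1] - x[, 2]) / 4
    within <- var(x[, 1] - x[, 2]) / 2
    total_sd <- sqrt(between + within)
    expect_lt(abs(total_sd - cal$sd[cal$metric == m]) / cal$sd[cal$metric == m],
              0.06)
    expect_lt(abs(between / (between + within) - cal$icc[cal$metric == m]),
              0.03)
  }
})

test_that("anchor scores stay in range and correlate with gait as designed", {
  spec <- cohort_spec(n_subjects = 400, conditions = "PWS", seed = 21)
  sim <- simulate_metric_cohort(spec)
  a <- sim$anchors
  expect_true(all(a$fga >= 0 & a$fga <= 30 & a$fga == round(a$fga)))
  expect_true(all(a$fes_i >= 16 & a$fes_i <= 64))
  # worse latent mobility: lower FGA, higher FES-I, lower PCS-12
  expect_lt(cor(sim$latent$z, a$fga), -0.5)
  expect_gt(cor(sim$latent$z, a$fes_i), 0.5)
  expect_lt(cor(sim$latent$z, a$pcs12), -0.5)
  # metric-anchor correlations land in the designed moderate band
  vel <- subject_mean_values(sim$metrics, "vel", "PWS", a$subject_id)
  r <- cor(vel, a$fga)
  expect_gt(r, 0.3); expect_lt(r, 0.75)
})

test_that("step streams realize their targets and reject infeasible ones", {
  # deterministic gait is recovered exactly
  tgt <- c(slen = 100, stime = 1.0, swing = 36, swidth = 12)
  gm <- extract_one(synthesize_step_stream(tgt, n_cycles = 20, seed = 1))
  expect_equal(unname(gm["vel"]), 100, tolerance = 1e-10)
  expect_equal(unname(gm["slen"]), 100, tolerance = 1e-10)
  expect_equal(unname(gm["stime"]), 1, tolerance = 1e-10)
  expect_equal(unname(gm["swing"]), 36, tolerance = 1e-10)
  expect_equal(unname(gm["dsupp"]), 28, tolerance = 1e-10)
  expect_equal(unname(gm["swidth"]), 12, tolerance = 1e-10)

  # stride-length CV target at 200 cycles
  t2 <- pws_targets()
  gm2 <- extract_one(synthesize_step_stream(t2, n_cycles = 200, seed = 4))
  expect_gt(unname(gm2["slen_cv"]), 2.99)
  expect_lt(unname(gm2["slen_cv"]), 3.99)

  # zero-asymmetry feet with identical distributions: extracted asymmetry
  # vanishes (moment-matched draws make it exact, not just consistent)
  t3 <- t2
  t3[c("slen_asym", "stime_asym", "swing_asym")] <- 0
  gm3 <- extract_one(synthesize_step_stream(t3, n_cycles = 500, seed = 5))
  expect_lt(unname(gm3["slen_asym"]), 0.3)
  expect_lt(unname(gm3["swing_asym"]), 0.3)
  # moment matching leaves only the tiny progression-axis tilt residual
  expect_lt(unname(gm3["slen_asym"]), 1e-5)

  # swing beyond half the cycle implies negative double support
  expect_error(synthesize_step_stream(
    c(slen = 100, stime = 1, swing = 55, swidth = 10), 20),
    "negative double support")
  expect_error(synthesize_step_stream(
    c(slen = 100, stime = 1, swing = 36, swidth = 10, swing_cv = 12), 20),
    "infeasible")
})

test_that("a full study is deterministic under its seed and structurally complete", {
  spec <- cohort_spec(n_subjects = 4, conditions = "PWS", n_controls = 2,
                      seed = 77)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_full_study(spec, d1)
  simulate_full_study(spec, d2)
  for (f in c("footfalls_patients.csv", "footfalls_controls.csv",
              "anchors.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  spec_b <- cohort_spec(n_subjects = 4, conditions = "PWS", n_controls = 2,
                        seed = 78)
  d3 <- withr::local_tempdir()
  simulate_full_study(spec_b, d3)
  expect_false(identical(readLines(file.path(d1, "footfalls_patients.csv")),
                         readLines(file.path(d3, "footfalls_patients.csv"))))
})

test_that("a cohort-scale study has the full trial structure and recovers its targets end to end", {
  elapsed <- system.time({
    spec <- cohort_spec(n_subjects = 60, seed = 11)
    dir <- withr::local_tempdir()
    sim <- simulate_full_study(spec, dir, controls = FALSE)
    ff <- read_footfalls(sim$paths$footfalls)

    # bookkeeping round trip: parsed events match the generator's count
    expect_equal(nrow(ff), sim$events_patients)

    # 60 subjects x 3 conditions x 4 trials present
    blocks <- unique(ff[, c("subject_id", "condition", "trial_index")])
    expect_equal(nrow(blocks), 60L * 3L * 4L)

    # cycles per pooled walk near the per-condition target
    plan <- sim$cycle_plan
    expect_lt(abs(mean(plan$n_cycles[plan$condition == "PWS"]) - 21.8), 3)
    expect_lt(abs(mean(plan$n_cycles[plan$condition == "SWS"]) - 29.2), 3)

    # end-to-end: extracted-metric reliability CIs cover the generating
    # ICC targets for at least 11 of 13 metrics at preferred speed
    mets <- suppressWarnings(extract_metrics(ff))
    rel <- reliability_table(mets[mets$condition == "PWS", ])
    cal <- vestibular_cohort_defaults("PWS")
    merged <- merge(as.data.frame(rel), cal, by = c("condition", "metric"))
    covered <- merged$ci_low <= merged$icc.y & merged$icc.y <= merged$ci_high
    expect_gte(sum(covered), 11L)

    # anchor regressions recover qualifying correlations
    anchors <- read_anchors(sim$paths$anchors)
    tab <- build_mcid_table(mets[mets$condition == "PWS", ], anchors)
    expect_equal(nrow(tab), 13L)
    expect_gt(sum(is.finite(tab$mcid_fga)), 5)
  })["elapsed"]
  # the stated pipeline-scale budget
  expect_lt(elapsed, 120)
})
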