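# SEM/MDC95, distribution-based, anchor-based and triangulated MCIDs.

test_that("SEM and MDC95 follow their closed forms and limits", {
  expect_equal(sem_mdc(1, 1)$mdc95, 0)
  expect_equal(sem_mdc(1, 1)$sem, 0)
  expect_equal(sem_mdc(1, 0)$mdc95, 1.96 * sqrt(2))
  expect_equal(sem_mdc(21.27, 0.992)$mdc95,
               1.96 * sqrt(2) * 21.27 * sqrt(0.008))
  expect_equal(round(sem_mdc(21.27, 0.992)$mdc95, 1), 5.3)
  # strictly decreasing in ICC at fixed SD
  iccs <- seq(0, 1, by = 0.05)
  mdcs <- sapply(iccs, function(r) sem_mdc(10, r)$mdc95)
  expect_true(all(diff(mdcs) < 0))
  expect_error(sem_mdc(10, 1.2), "<= 1")
  expect_error(sem_mdc(0, 0.5), "positive")
})

test_that("distribution-based MCIDs are effect size times SD", {
  expect_equal(distribution_mcid(21.27, 0.5), 10.635)
  expect_equal(distribution_mcid(4.04, 0.8), 3.232)
  expect_equal(distribution_mcid(1, 0.2), 0.2)
  expect_error(distribution_mcid(0, 0.5), "positive")
  expect_error(distribution_mcid(10, -1), "positive")
})

test_that("anchor-based MCID multiplies the regression slope by the anchor's meaningful change", {
  # exact linear relation with slope 2.0 cm/s per FGA point
  fga <- rep(10:29, 2)
  vel <- 60 + 2.0 * fga
  res <- anchor_mcid(vel, fga, "FGA")
  expect_equal(res$b, 2.0)
  expect_equal(res$estimate, 8.0)
  expect_equal(res$reason, "ok")

  # FES-I improvement is a decrease: negative slope yields a positive
  # velocity MCID through the signed anchor change
  set.seed(2)
  fes <- round(runif(40, 20, 60))
  vel2 <- 120 - 1.5 * fes + rnorm(40, 0, 5)
  res2 <- anchor_mcid(vel2, fes, "FES_I")
  expect_lt(res2$b, 0)
  expect_gt(res2$estimate, 0)
  expect_equal(res2$estimate, res2$b * -8)

  # degenerate anchor: absent with reason
  res3 <- anchor_mcid(vel, rep(20, length(vel)), "FGA")
  expect_true(is.na(res3$estimate))
  expect_equal(res3$reason, "degenerate_anchor")

  # below the correlation gate: absent
  set.seed(5)
  res4 <- anchor_mcid(rnorm(200), round(runif(200, 0, 30)), "FGA")
  expect_true(is.na(res4$estimate))
  expect_equal(res4$reason, "low_correlation")

  # too few pairs: absent
  res5 <- anchor_mcid(vel[1:5], fga[1:5], "FGA")
  expect_equal(res5$reason, "too_few_pairs")
})

test_that("anchor-based MCID recovers a planted slope and obeys equivariance", {
  set.seed(14)
  n <- 2000
  z <- rnorm(n)
  fga <- pmin(30, pmax(0, round(18 + 4 * z)))
  bstar <- 1.8
  vel <- 90 + bstar * fga + rnorm(n, 0, 12.5)  # r around 0.5
  res <- anchor_mcid(vel, fga, "FGA")
  expect_gt(abs(res$r), 0.3)
  expect_lt(abs(res$estimate - bstar * 4) / (bstar * 4), 0.05)
  # metric rescaling scales B and the estimate
  res_c <- anchor_mcid(vel * 2.54, fga, "FGA")
  expect_equal(res_c$b, res$b * 2.54, tolerance = 1e-12)
  expect_equal(res_c$estimate, res$estimate * 2.54, tolerance = 1e-12)
  # consistent anchor rescaling leaves the estimate unchanged
  res_a <- anchor_mcid(vel, fga * 10,
                       list(anchor = "FGA", mcid = 40, improvement = 1))
  expect_equal(res_a$estimate, res$estimate, tolerance = 1e-12)
})

test_that("triangulation averages the available estimates", {
  expect_equal(round(triangulate_mcid(10.64, c(7.18, 7.49, 11.02))$triangulated, 2),
               9.08)
  # fewer than four available: average over those present
  two <- triangulate_mcid(5.34, c(NA, NA, 3.27))
  expect_equal(gaitmcid:::round_half_away(two$triangulated, 2), 4.31)
  expect_equal(two$n_contributors, 2L)
  # identity on a single value
  expect_equal(triangulate_mcid(2.5)$triangulated, 2.5)
  expect_equal(triangulate_mcid(NA_real_, c(NA, NA, NA))$n_contributors, 0L)
  # permutation invariance and boundedness
  set.seed(4)
  for (i in 1:20) {
    vals <- rnorm(4)
    t1 <- triangulate_mcid(vals[1], vals[2:4])$triangulated
    p <- sample(4)
    t2 <- triangulate_mcid(vals[p][1], vals[p][2:4])$triangulated
    expect_equal(t1, t2)
    expect_gte(t1, min(vals))
    expect_lte(t1, max(vals))
  }
})

test_that("the MCID table has the right shape, signs and error-floor flags", {
  # planted contrast: a high-reliability pace metric and a low-reliability
  # asymmetry metric
  cal <- vestibular_cohort_defaults("PWS")
  cal <- cal[cal$metric %in% c("vel", "slen_asym"), ]
  cal$icc[cal$metric == "vel"] <- 0.97
  cal$icc[cal$metric == "slen_asym"] <- 0.2
  spec <- cohort_spec(n_subjects = 60, conditions = "PWS",
                      calibration = cal, seed = 31)
  sim <- simulate_metric_cohort(spec)
  tab <- build_mcid_table(sim$metrics, sim$anchors)
  expect_s3_class(tab, "mcid_table")
  expect_equal(nrow(tab), 2L)
  vel <- tab[tab$metric == "vel", ]
  asym <- tab[tab$metric == "slen_asym", ]
  # improvement signs: velocity up, asymmetry down
  expect_gt(vel$dist_medium, 0)
  expect_lt(asym$dist_medium, 0)
  expect_gt(vel$mdc95, 0)
  expect_lt(asym$mdc95, 0)
  # only the unreliable asymmetry metric collapses below measurement error
  expect_false(vel$below_mdc)
  expect_true(asym$below_mdc)
  # qualifying anchors contribute to the triangulated average
  est_cols <- c("dist_medium", "mcid_fga", "mcid_fes_i", "mcid_pcs12")
  avail <- unlist(vel[, est_cols])
  expect_equal(vel$triangulated, mean(avail[is.finite(avail)]))
  expect_equal(vel$n_contributors, sum(is.finite(avail)))
  # every reported anchor estimate passed the correlation gate
  for (a in c("fga", "fes_i", "pcs12")) {
    reported <- is.finite(tab[[paste0("mcid_", a)]])
    expect_true(all(abs(tab[[paste0("r_", a)]][reported]) > 0.3))
  }
})

test_that("full-cohort MCID tables cover all metrics and bracket anchor estimates", {
  spec <- cohort_spec(n_subjects = 60, seed = 13)
  sim <- simulate_metric_cohort(spec)
  tab <- build_mcid_table(sim$metrics, sim$anchors)
  expect_equal(nrow(tab), 13L * 3L)
  info <- gait_metrics_info()
  merged <- merge(tab, info, by = "metric")
  # distribution-based estimates carry the metric improvement direction
  expect_true(all(sign(merged$dist_medium) == merged$improvement))
  expect_true(all(sign(merged$dist_small) == sign(merged$dist_large)))
  # moderate planted correlations keep anchor-based MCIDs mostly inside the
  # small-to-large distribution envelope
  anchor_cols <- c("mcid_fga", "mcid_fes_i", "mcid_pcs12")
  vals <- abs(as.matrix(merged[, anchor_cols]))
  lo <- abs(merged$dist_small); hi <- abs(merged$dist_large)
  inside <- vals >= lo & vals <= hi
  expect_gt(mean(inside[is.finite(vals)]), 0.8)
})
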