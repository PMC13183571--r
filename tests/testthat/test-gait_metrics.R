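# Stride segmentation and metric extraction: hand-computable cases,
# invariance properties, outlier rule, normality wrapper.

test_that("stride segmentation reproduces hand-computed stride and swing times", {
  # L(0), R(0.5), L(1.0), R(1.5), L(2.0), lift at contact + 0.64 s:
  # left stride times {1.0, 1.0}, swing times 0.36 s (36% of the cycle)
  ev <- toy_footfalls(times = c(0, 0.5, 1.0, 1.5, 2.0),
                      feet = c("left", "right", "left", "right", "left"),
                      ys = c(0, 50, 100, 150, 200),
                      xs = c(-6, 6, -6, 6, -6), stance = 0.64)
  w <- as_walk(ev, trial_pair = c(1L, 1L))
  st <- segment_strides(w, min_events = 2L)
  left <- st[st$foot == "left", ]
  expect_equal(left$stride_time, c(1, 1))
  expect_equal(left$swing_time, c(0.36, 0.36))
  expect_equal(left$swing_pct, c(36, 36))
  expect_equal(left$stride_length, c(100, 100))
  # too few events per foot is an error naming the walk
  expect_error(segment_strides(w, min_events = 3L), "T1")
})

test_that("asymmetry follows the symmetry-index formula on a two-foot toy", {
  # left stride lengths {100, 102}, right {98, 100}:
  # slen = 100, slen_asym = 100 * |101 - 99| / 100 = 2.0
  ev1 <- toy_footfalls(times = c(0, 0.5, 1, 1.5, 2, 2.5),
                       feet = rep(c("left", "right"), 3),
                       ys = c(0, 49, 100, 147, 202, 247),
                       xs = rep(c(-6, 6), 3), trial = 1L)
  ev2 <- ev1; ev2$trial_index <- 2L
  w <- as_walk(validate_footfalls(rbind(ev1, ev2)))
  gm <- suppressWarnings(
    compute_metrics(segment_strides(w), w, min_strides = 2L))
  expect_equal(unname(gm["slen"]), 100)
  expect_equal(unname(gm["slen_asym"]), 2.0)
  expect_equal(unname(gm["stime"]), 1.0)
  # log-ratio alternative: 100 * |log(101/99)|
  gm_lr <- suppressWarnings(
    compute_metrics(segment_strides(w), w, min_strides = 2L,
                    asym_form = "log_ratio"))
  expect_equal(unname(gm_lr["slen_asym"]), 100 * log(101 / 99))
})

test_that("perfectly regular symmetric gait has zero variability and asymmetry", {
  tgt <- c(slen = 100, stime = 1.0, swing = 36, swidth = 12)
  gm <- extract_one(synthesize_step_stream(tgt, n_cycles = 20, seed = 1))
  expect_equal(unname(gm[c("slen_cv", "stime_cv", "swing_cv", "swidth_cv")]),
               rep(0, 4), tolerance = 1e-10)
  expect_equal(unname(gm[c("slen_asym", "stime_asym", "swing_asym")]),
               rep(0, 3), tolerance = 1e-10)
})

test_that("lengths scale equivariantly; phase and relative metrics are scale-free", {
  for (seed in 1:3) {
    ev <- synthesize_step_stream(pws_targets(), n_cycles = 60, seed = seed)
    gm <- extract_one(ev)
    ev2 <- ev
    ev2$heel_x <- ev2$heel_x * 2.5
    ev2$heel_y <- ev2$heel_y * 2.5
    gm2 <- extract_one(ev2)
    scaled <- c("vel", "slen", "swidth")
    free <- setdiff(gait_metric_names(), c(scaled, "stime"))
    expect_equal(unclass(gm2[scaled]), unclass(gm[scaled]) * 2.5,
                 tolerance = 1e-9)
    expect_equal(unclass(gm2[c(free, "stime")]),
                 unclass(gm[c(free, "stime")]), tolerance = 1e-9)
  }
})

test_that("metrics are invariant to walking-direction reversal and foot relabelling", {
  ev <- synthesize_step_stream(pws_targets(), n_cycles = 60, seed = 9)
  gm <- extract_one(ev)
  # reverse the progression direction
  rev <- ev; rev$heel_y <- -rev$heel_y
  expect_equal(unclass(extract_one(rev)), unclass(gm), tolerance = 1e-9)
  # swap foot labels (asymmetry uses the absolute difference)
  swap <- ev
  swap$foot <- ifelse(swap$foot == "left", "right", "left")
  gms <- extract_one(swap)
  rel <- c("slen_cv", "stime_cv", "swing_cv", "slen_asym", "stime_asym",
           "swing_asym", "swidth", "swidth_cv")
  expect_equal(unclass(gms[rel]), unclass(gm[rel]), tolerance = 1e-9)
})

test_that("stride counts match the generator's bookkeeping", {
  ev <- synthesize_step_stream(pws_targets(), n_cycles = 88, seed = 5)
  planned <- attr(ev, "planned")
  w <- pool_trials(ev, c(1, 2))
  st <- segment_strides(w)
  counts <- table(st$foot, st$trial_index)
  expect_true(all(abs(counts - planned$strides_per_foot_per_trial) <= 1))
  expect_equal(nrow(st), planned$n_cycles)
})

test_that("below the stride floor, variability metrics propagate as missing", {
  ev <- synthesize_step_stream(pws_targets(), n_cycles = 12, seed = 2)
  gm <- extract_one(ev, min_strides = 4L)   # 3 strides per foot per trial
  expect_true(all(is.finite(gm[c("vel", "slen", "stime", "swing", "dsupp",
                                 "swidth")])))
  # 6 strides per foot across the walk: above the floor
  expect_true(all(is.finite(gm)))
  gm2 <- extract_one(ev, min_strides = 7L)
  expect_true(all(is.na(gm2[c("slen_cv", "slen_asym", "swing_asym")])))
  # fewer than 15 cycles triggers the stability warning
  w <- pool_trials(ev, c(1, 2))
  expect_warning(compute_metrics(segment_strides(w), w), "15")
})

test_that("pairwise outlier rule removes exactly the planted subject", {
  set.seed(42)
  pairs <- data.frame(subject_id = sprintf("P%02d", 1:60),
                      walk1 = rnorm(60, 100, 10), walk2 = rnorm(60, 100, 10))
  # everything within 3 SD: nothing removed
  res0 <- remove_outliers(pairs)
  expect_length(res0$removed, 0)
  expect_identical(res0$kept, pairs)
  # plant a single extreme value in walk1 of subject 17
  pairs$walk1[17] <- mean(pairs$walk1) + 5 * sd(pairs$walk1)
  res <- remove_outliers(pairs)
  expect_equal(res$removed, "P17")
  expect_false("P17" %in% res$kept$subject_id)
  expect_equal(res$fraction, 1 / 60)
  expect_error(remove_outliers(pairs[1:2, ]), ">= 3")
})

test_that("Shapiro-Wilk wrapper matches stats and rejects degenerate input", {
  set.seed(1)
  x <- rnorm(100)
  sw <- shapiro_normality(x)
  ref <- shapiro.test(x)
  expect_equal(sw$statistic, unname(ref$statistic))
  expect_equal(sw$p, ref$p.value)
  expect_error(shapiro_normality(c(1, 2)), "n >= 3")
  expect_error(shapiro_normality(rep(1, 10)), "constant",
               class = "gaitmcid_degenerate")
  # size and power at n = 500 (a few replicates; distributional property)
  set.seed(10)
  p_norm <- replicate(20, shapiro_normality(rnorm(500))$p)
  p_exp <- replicate(20, shapiro_normality(rexp(500))$p)
  expect_gte(mean(p_norm > 0.01), 0.9)
  expect_equal(mean(p_exp < 0.01), 1)
})
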