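# Seeded synthetic gait cohorts, at two levels:
#  * metric level — per-subject, per-condition, per-walk metric values with a
#    controlled between/within-subject variance split (hence controlled
#    test-retest ICC) and clinical anchors linear in a latent mobility
#    factor;
#  * footfall-event level — step streams whose extracted metrics hit
#    per-walk targets, via moment-matched per-stride draws.

#' Specification of a synthetic gait cohort
#'
#' Bundles every generator parameter: cohort size, walking conditions,
#' per-metric population means/SDs and target test–retest ICCs (defaulting
#' to [vestibular_cohort_defaults()], a chronic-vestibulopathy calibration),
#' the per-condition target number of gait cycles per pooled walk, the
#' latent-mobility loading that induces metric–anchor correlations, and the
#' anchor measurement models.
#'
#' The anchor model makes the Functional Gait Assessment decrease, the
#' FES-I increase and the PCS-12 decrease with worse latent mobility; slopes
#' and residual SDs default to values giving metric–anchor correlations of
#' roughly 0.4–0.6, comfortably above the |r| > 0.3 gate used by
#' anchor-based MCID estimation.
#'
#' @param n_subjects Number of patients (default 60).
#' @param conditions Subset of [gait_conditions()].
#' @param calibration Data.frame with columns `condition`, `metric`, `mean`,
#'   `sd`, `icc` (defaults to [vestibular_cohort_defaults()]).
#' @param target_icc Optional named override: single value recycled to all
#'   metrics/conditions, or a data.frame `condition`/`metric`/`icc`.
#' @param cycle_targets Data.frame `condition`/`mean`/`sd` of gait cycles
#'   per pooled walk (defaults 21.8 ± 4.5 at preferred speed, 29.2 ± 4.8
#'   slow, 30.4 ± 8.5 eyes closed).
#' @param latent_loading Loading of each metric's subject-level deviation on
#'   the latent mobility factor (default 0.6).
#' @param anchor_model Data.frame `anchor`/`intercept`/`slope`/`resid_sd`;
#'   slope is per unit of the latent impairment factor (higher = worse
#'   mobility).
#' @param n_controls Number of healthy controls for [simulate_full_study()].
#' @param seed Integer seed; part of the specification so every dataset is
#'   reproducible.
#' @return A validated list of class `cohort_spec`.
#' @examples
#' spec <- cohort_spec(n_subjects = 10, conditions = "PWS", seed = 42)
#' @export
cohort_spec <- function(n_subjects = 60L,
                        conditions = gait_conditions(),
                        calibration = vestibular_cohort_defaults(),
                        target_icc = NULL,
                        cycle_targets = NULL,
                        latent_loading = 0.6,
                        anchor_model = NULL,
                        n_controls = 30L,
                        seed = 1L) {
  conditions <- match.arg(conditions, gait_conditions(), several.ok = TRUE)
  if (!is_count(n_subjects) || n_subjects < 1)
    stop_gait("n_subjects must be a positive integer")
  cal <- as.data.frame(calibration)
  need <- c("condition", "metric", "mean", "sd", "icc")
  if (!all(need %in% names(cal)))
    stop_gait("calibration needs columns: %s", paste(need, collapse = ", "))
  cal <- cal[cal$condition %in% conditions, , drop = FALSE]
  if (!is.null(target_icc)) {
    if (is.data.frame(target_icc)) {
      for (i in seq_len(nrow(target_icc))) {
        sel <- cal$condition == target_icc$condition[i] &
          cal$metric == target_icc$metric[i]
        cal$icc[sel] <- target_icc$icc[i]
      }
    } else cal$icc <- as.numeric(target_icc)
  }
  if (any(cal$sd <= 0)) stop_gait("calibration SDs must be positive")
  if (any(cal$icc < 0 | cal$icc > 1))
    stop_gait("target ICCs must lie in [0, 1]")
  if (is.null(cycle_targets)) cycle_targets <- .cycle_targets()
  if (is.null(anchor_model))
    anchor_model <- data.frame(
      anchor = c("FGA", "FES_I", "PCS12", "MCS12"),
      intercept = c(18, 32, 38, 50),
      slope = c(-5, 7, -6, 0),
      resid_sd = c(3.5, 5, 5, 9),
      stringsAsFactors = FALSE)
  if (latent_loading < 0 || latent_loading > 1)
    stop_gait("latent_loading must lie in [0, 1]")
  structure(list(n_subjects = as.integer(n_subjects),
                 conditions = conditions, calibration = cal,
                 cycle_targets = cycle_targets,
                 latent_loading = latent_loading,
                 anchor_model = anchor_model,
                 n_controls = as.integer(n_controls),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %d patients (+%d controls), conditions %s, seed %d\n",
              x$n_subjects, x$n_controls,
              paste(x$conditions, collapse = "/"), x$seed))
  invisible(x)
}

#' Simulate a metric-level cohort with controlled test-retest reliability
#'
#' For each metric with population mean \eqn{\mu}, SD \eqn{\sigma} and
#' target ICC \eqn{\rho}, subject-level true values are drawn with variance
#' \eqn{\rho\sigma^2} and each walk adds independent noise with variance
#' \eqn{(1-\rho)\sigma^2}, so the expected single-measure ICC of the two
#' walks equals \eqn{\rho} and the marginal per-walk variance is
#' \eqn{\sigma^2}. A share `latent_loading` of each subject-level deviation
#' is carried by a standard-normal latent mobility-impairment factor (signed
#' so that worse mobility worsens the metric), and anchors are linear in the
#' same factor plus noise — which induces the metric–anchor correlations
#' exploited by anchor-based MCID estimation. FGA and FES-I scores are
#' rounded and clipped to their legal ranges.
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional override of `spec$seed`; `NA` leaves the RNG state
#'   untouched (for use inside larger simulations).
#' @return List with `metrics` (long data.frame: `subject_id`, `condition`,
#'   `walk` ∈ {1,2}, `metric`, `value`), `anchors` (one row per subject),
#'   `latent` (`subject_id`, `z`), and `spec`.
#' @export
simulate_metric_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed) && !is.na(seed)) set.seed(seed)
  n <- spec$n_subjects
  ids <- sprintf("P%03d", seq_len(n))
  z <- stats::rnorm(n)
  lam <- spec$latent_loading
  info <- gait_metrics_info()
  cal <- spec$calibration
  rows <- vector("list", nrow(cal))
  for (i in seq_len(nrow(cal))) {
    mu <- cal$mean[i]; sdv <- cal$sd[i]; rho <- cal$icc[i]
    sgn <- -info$improvement[info$metric == cal$metric[i]] # impairment dir
    eta <- stats::rnorm(n)
    subj <- mu + sqrt(rho) * sdv * (lam * sgn * z + sqrt(1 - lam^2) * eta)
    w1 <- subj + stats::rnorm(n, 0, sqrt(1 - rho) * sdv)
    w2 <- subj + stats::rnorm(n, 0, sqrt(1 - rho) * sdv)
    rows[[i]] <- data.frame(
      subject_id = rep(ids, 2L),
      condition = cal$condition[i],
      walk = rep(c(1L, 2L), each = n),
      metric = cal$metric[i],
      value = c(w1, w2), stringsAsFactors = FALSE)
  }
  metrics <- do.call(rbind, rows)
  am <- spec$anchor_model
  a_draw <- function(name) {
    j <- match(name, am$anchor)
    am$intercept[j] + am$slope[j] * z + stats::rnorm(n, 0, am$resid_sd[j])
  }
  anchors <- data.frame(
    subject_id = ids,
    fga = pmin(30, pmax(0, round(a_draw("FGA")))),
    fes_i = pmin(64, pmax(16, round(a_draw("FES_I")))),
    pcs12 = a_draw("PCS12"),
    mcs12 = a_draw("MCS12"),
    stringsAsFactors = FALSE)
  list(metrics = metrics, anchors = anchors,
       latent = data.frame(subject_id = ids, z = z), spec = spec)
}

# feasibility checks for step-stream targets
check_step_targets <- function(t) {
  if (t$swing >= 50)
    stop_gait("infeasible target: swing %.1f%% >= 50%% implies negative double support", t$swing)
  if (t$swing <= 0 || t$slen <= 0 || t$stime <= 0 || t$swidth <= 0)
    stop_gait("infeasible target: slen, stime, swing, swidth must be positive")
  w <- t$swing / 100; wsd <- t$swing_cv / 100 * w
  if (w + 4 * wsd >= 0.5)
    stop_gait("infeasible target: swing distribution reaches 50%% of the cycle")
  if (t$stime_cv / 100 * 5 >= 1)
    stop_gait("infeasible target: stride-time CV admits non-positive stride times")
  if (t$slen_cv / 100 * 5 >= 1)
    stop_gait("infeasible target: stride-length CV admits non-positive lengths")
  invisible(TRUE)
}

#' Synthesize a footfall step stream realizing target gait metrics
#'
#' Generates footfall events for one pooled walk (two trials) whose
#' extracted metrics ([segment_strides()] + [compute_metrics()]) match the
#' targets: stride length, stride time and swing phase are drawn per foot
#' with moment-matched samples (exact sample means and pooled SDs, hence
#' exact extracted means, CVs and asymmetries); gait velocity and the
#' double-support phase are emergent (`vel = slen/stime`,
#' `dsupp = 100 − swing_L − swing_R`); the base-of-support noise scale is
#' calibrated against the package's own extraction so the extracted stride
#' width mean and CV match their targets.
#'
#' Stride-time asymmetry deserves a note: over a long walk both feet must
#' share the trial's total duration, so a persistent left–right stride-time
#' difference is not structurally sustainable. It is realized here as a
#' bounded linear phase drift between the feet within each trial (the
#' cumulated drift is capped so the inter-foot phase stays inside the
#' double-support band); for very long trials the realized stride-time
#' asymmetry therefore saturates below large targets (the realized value is
#' recorded in the `planned` attribute).
#'
#' @param target Named numeric vector or list: `slen` (cm), `stime` (s),
#'   `swing` (% of cycle), `swidth` (cm) required; `slen_cv`, `stime_cv`,
#'   `swing_cv`, `swidth_cv`, `slen_asym`, `stime_asym`, `swing_asym` (all
#'   %) default to 0. `vel` and `dsupp` entries are accepted but ignored
#'   (emergent).
#' @param n_cycles Total gait cycles (both feet) for the pooled walk;
#'   divided evenly over two trials and two feet.
#' @param seed Integer seed, or `NA` to use the current RNG state.
#' @param subject_id,condition Labels stamped on the emitted events.
#' @param trial_indices The two trial indices to emit (default 1:2).
#' @return A `footfall_table` data.frame; attribute `planned` records the
#'   per-foot, per-trial stride counts and the realized asymmetry offsets.
#' @examples
#' ev <- synthesize_step_stream(
#'   c(slen = 112, stime = 1.16, swing = 36.4, swidth = 11.5),
#'   n_cycles = 20, seed = 7)
#' w <- pool_trials(ev, c(1, 2))
#' compute_metrics(segment_strides(w), w)
#' @export
synthesize_step_stream <- function(target, n_cycles, seed = NA,
                                   subject_id = "S1", condition = "PWS",
                                   trial_indices = c(1L, 2L)) {
  if (!is.null(seed) && !is.na(seed)) set.seed(seed)
  t <- as.list(target)
  for (nm in c("slen_cv", "stime_cv", "swing_cv", "swidth_cv",
               "slen_asym", "stime_asym", "swing_asym"))
    t[[nm]] <- t[[nm]] %||% 0
  for (nm in c("slen", "stime", "swing", "swidth"))
    if (is.null(t[[nm]])) stop_gait("step-stream target needs '%s'", nm)
  check_step_targets(t)
  m <- max(2L, as.integer(round(n_cycles / 4)))  # strides per foot per trial
  nf <- 2L * m                                   # strides per foot per walk
  # stride times: per-foot means realize (capped) asymmetry. The right
  # foot's contacts follow the left foot's through a deterministic linear
  # phase schedule (per trial), so the inter-foot phase stays inside the
  # double-support band instead of random-walking out of it; per-foot
  # marginal sample moments remain exact (T_R is a constant shift of T_L).
  d_t <- min(t$stime_asym / 100, 0.24 / m)
  mtL <- t$stime * (1 + d_t / 2); mtR <- t$stime * (1 - d_t / 2)
  s_t <- within_sd_for_pooled(t$stime_cv / 100 * t$stime, mtL, mtR, nf)
  if (is.na(s_t))
    stop_gait("infeasible target: stride-time CV below its asymmetry component")
  T_L <- rnorm_exact(nf, mtL, s_t)
  T_R <- T_L - d_t * t$stime
  if (any(c(T_L, T_R) <= 0)) stop_gait("infeasible stride-time draw")
  # stride lengths
  d_l <- t$slen_asym / 100
  mlL <- t$slen * (1 + d_l / 2); mlR <- t$slen * (1 - d_l / 2)
  s_l <- within_sd_for_pooled(t$slen_cv / 100 * t$slen, mlL, mlR, nf)
  if (is.na(s_l))
    stop_gait("infeasible target: stride-length CV below its asymmetry component")
  S_L <- rnorm_exact(nf, mlL, s_l); S_R <- rnorm_exact(nf, mlR, s_l)
  if (any(c(S_L, S_R) <= 0)) stop_gait("infeasible stride-length draw")
  # swing fractions
  wbar <- t$swing / 100; d_w <- t$swing_asym / 100
  mwL <- wbar * (1 + d_w / 2); mwR <- wbar * (1 - d_w / 2)
  s_w <- within_sd_for_pooled(t$swing_cv / 100 * wbar, mwL, mwR, nf)
  if (is.na(s_w))
    stop_gait("infeasible target: swing CV below its asymmetry component")
  W_L <- rnorm_exact(nf, mwL, s_w); W_R <- rnorm_exact(nf, mwR, s_w)
  if (any(c(W_L, W_R) <= 0.02) || any(c(W_L, W_R) >= 0.5))
    stop_gait("infeasible swing-fraction draw (outside (2%%, 50%%) of cycle)")
  # lateral noise (unit scale, calibrated below)
  e_L <- stats::rnorm(2L * (m + 1L)); e_R <- stats::rnorm(2L * (m + 1L))
  s_bos <- t$swidth_cv / 100 * t$swidth
  build <- function(w_base, alpha) {
    evs <- vector("list", 2L)
    for (k in 1:2) {
      idx <- ((k - 1L) * m + 1L):(k * m)       # stride draws for this trial
      idxe <- ((k - 1L) * (m + 1L) + 1L):(k * (m + 1L)) # contact noise
      tl <- T_L[idx]; tr <- T_R[idx]
      sl <- S_L[idx]; sr <- S_R[idx]
      wl <- W_L[idx]; wr <- W_R[idx]
      cl <- c(0, cumsum(tl))
      # linear phase schedule centered on half a stride time
      phi <- 0.5 * t$stime + ((m + 2) / 2 - seq_len(m + 1L)) * d_t * t$stime
      cr <- cl + phi
      yl <- c(0, cumsum(sl))
      yr <- 0.5 * t$slen + c(0, cumsum(sr))
      xl <- -w_base / 2 + alpha * e_L[idxe]
      xr <- +w_base / 2 + alpha * e_R[idxe]
      # toe-off: next same-foot contact minus the cycle's swing time
      ll <- c(cl[-1] - wl * tl, cl[m + 1L] + (1 - wbar) * t$stime)
      lr <- c(cr[-1] - wr * tr, cr[m + 1L] + (1 - wbar) * t$stime)
      ev <- data.frame(
        subject_id = subject_id, condition = condition,
        trial_index = trial_indices[k],
        foot = rep(c("left", "right"), each = m + 1L),
        contact_time = c(cl, cr), lift_time = c(ll, lr),
        heel_x = c(xl, xr), heel_y = c(yl, yr),
        stringsAsFactors = FALSE)
      evs[[k]] <- ev[order(ev$contact_time), ]
    }
    out <- do.call(rbind, evs)
    rownames(out) <- NULL
    out
  }
  extract_bos <- function(ev) {
    w <- structure(list(subject_id = subject_id, condition = condition,
                        trial_pair = as.integer(trial_indices), events = ev),
                   class = "walk")
    st <- segment_strides(w)
    st$base_of_support[is.finite(st$base_of_support)]
  }
  w_base <- t$swidth; alpha <- 0
  if (s_bos > 0) {
    alpha <- s_bos / sqrt(1.5)
    for (it in 1:2) { # extraction is ~linear in (w_base, alpha): fixed point
      b <- extract_bos(build(w_base, alpha))
      alpha <- alpha * s_bos / stats::sd(b)
      b <- extract_bos(build(w_base, alpha))
      w_base <- w_base - (mean(b) - t$swidth)
    }
  }
  ev <- build(w_base, alpha)
  attr(ev, "planned") <- list(
    strides_per_foot_per_trial = m, n_cycles = 4L * m,
    stime_asym_realized = 100 * d_t,
    events_emitted = nrow(ev))
  class(ev) <- c("footfall_table", "data.frame")
  ev
}

#' Simulate a complete on-disk gait study
#'
#' Composes [simulate_metric_cohort()] (cohort structure, anchors) with
#' [synthesize_step_stream()] (per-walk footfall events at the cohort's
#' per-walk metric targets) and writes the walkway-format dataset: patient
#' footfalls, healthy-control footfalls, the clinical-anchor table, and a
#' JSON manifest of the generating parameters. Deterministic for a fixed
#' spec seed: the same spec writes byte-identical files.
#'
#' Healthy controls are generated from the patient calibration shifted
#' toward normal gait (faster, longer strides, less variable, less
#' asymmetric, narrower base of support); they exercise the group-comparison
#' stage and carry no anchors.
#'
#' @param spec A [cohort_spec()].
#' @param dir Output directory (created if needed).
#' @param controls Generate the control cohort too? (default TRUE)
#' @return Invisibly, a list with file paths and bookkeeping: per-block
#'   event counts, total events emitted, and the per-walk cycle plan.
#' @export
simulate_full_study <- function(spec, dir, controls = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)
  cohort <- simulate_metric_cohort(spec, seed = NA)
  pat_ff <- .cohort_footfalls(cohort$metrics, spec)
  paths <- list(footfalls = file.path(dir, "footfalls_patients.csv"),
                anchors = file.path(dir, "anchors.csv"),
                manifest = file.path(dir, "manifest.json"))
  utils::write.csv(pat_ff$events, paths$footfalls, row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(cohort$anchors, paths$anchors, row.names = FALSE,
                   quote = FALSE)
  ctl_ff <- NULL
  if (controls && spec$n_controls > 0) {
    ctl_spec <- cohort_spec(
      n_subjects = spec$n_controls, conditions = spec$conditions,
      calibration = control_calibration(spec$calibration),
      cycle_targets = spec$cycle_targets,
      latent_loading = spec$latent_loading,
      anchor_model = spec$anchor_model, n_controls = 0L, seed = spec$seed)
    ctl_cohort <- simulate_metric_cohort(ctl_spec, seed = NA)
    ctl_cohort$metrics$subject_id <- sub("^P", "C", ctl_cohort$metrics$subject_id)
    ctl_ff <- .cohort_footfalls(ctl_cohort$metrics, ctl_spec)
    paths$controls <- file.path(dir, "footfalls_controls.csv")
    utils::write.csv(ctl_ff$events, paths$controls, row.names = FALSE,
                     quote = FALSE)
  }
  manifest <- list(
    generator = "gaitmcid::simulate_full_study",
    seed = spec$seed, n_subjects = spec$n_subjects,
    n_controls = if (controls) spec$n_controls else 0L,
    conditions = spec$conditions,
    events_patients = nrow(pat_ff$events),
    events_controls = if (is.null(ctl_ff)) 0L else nrow(ctl_ff$events))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             paths$manifest)
  invisible(list(paths = paths,
                 events_patients = nrow(pat_ff$events),
                 events_controls = if (is.null(ctl_ff)) 0L
                                   else nrow(ctl_ff$events),
                 cycle_plan = pat_ff$cycle_plan,
                 cohort = cohort))
}

# per-walk step-stream synthesis for a metric-level cohort
.cohort_footfalls <- function(metrics, spec) {
  evs <- list(); plan <- list()
  for (sid in unique(metrics$subject_id)) {
    for (cond in spec$conditions) {
      ct <- spec$cycle_targets[spec$cycle_targets$condition == cond, ]
      for (wk in 1:2) {
        sel <- metrics$subject_id == sid & metrics$condition == cond &
          metrics$walk == wk
        tv <- stats::setNames(metrics$value[sel], metrics$metric[sel])
        tgt <- sanitize_step_targets(tv)
        n_cyc <- max(16L, as.integer(round(stats::rnorm(1, ct$mean, ct$sd))))
        ev <- synthesize_step_stream(
          tgt, n_cycles = n_cyc, seed = NA, subject_id = sid,
          condition = cond, trial_indices = c(2L * wk - 1L, 2L * wk))
        evs[[length(evs) + 1L]] <- ev
        plan[[length(plan) + 1L]] <- data.frame(
          subject_id = sid, condition = cond, walk = wk,
          n_cycles = attr(ev, "planned")$n_cycles,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(events = do.call(rbind, evs), cycle_plan = do.call(rbind, plan))
}

# clamp cohort-drawn per-walk targets into the generator's feasible region
sanitize_step_targets <- function(tv) {
  t <- as.list(tv)
  for (nm in c("slen_cv", "stime_cv", "swing_cv", "swidth_cv"))
    t[[nm]] <- max(0.1, t[[nm]] %||% 0)
  for (nm in c("slen_asym", "stime_asym", "swing_asym"))
    t[[nm]] <- max(0, t[[nm]] %||% 0)
  t$swing <- min(t$swing, 47)
  t$swidth <- max(t$swidth, 1)
  wbar <- t$swing / 100
  caps <- c(slen = 18, stime = 18,
            swing = 100 * (0.495 - wbar) / (4.2 * wbar))
  for (nm in names(caps)) {
    cvn <- paste0(nm, "_cv"); asn <- paste0(nm, "_asym")
    # pooled CV must carry the between-feet spread the asymmetry implies,
    # while staying inside the generator's feasible region
    t[[cvn]] <- max(t[[cvn]], 0.52 * t[[asn]] + 0.05)
    if (t[[cvn]] > caps[nm]) {
      t[[cvn]] <- caps[nm]
      t[[asn]] <- min(t[[asn]], max(0, 1.85 * (caps[nm] - 0.06)))
    }
  }
  t
}

# healthy-control calibration: patient means shifted toward normal gait
control_calibration <- function(cal) {
  out <- cal
  for (i in seq_len(nrow(out))) {
    m <- out$metric[i]
    out$mean[i] <- switch(m,
      vel = out$mean[i] * 1.15, slen = out$mean[i] * 1.10,
      stime = out$mean[i] * 0.95,
      swing = out$mean[i] + 1.5, dsupp = out$mean[i] - 2.5,
      swidth = out$mean[i] * 0.75,
      out$mean[i] * 0.55) # variability / asymmetry markers shrink
    if (m %in% c("swidth_cv")) out$mean[i] <- cal$mean[i] * 0.7
    out$sd[i] <- out$sd[i] * 0.8
  }
  out
}
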