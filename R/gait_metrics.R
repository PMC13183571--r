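# Stride segmentation and the thirteen spatiotemporal gait metrics.
#
# A gait cycle (stride) is the interval between two successive contacts of
# the same foot. Strides are segmented per trial (never across the pooled
# trial boundary). The progression axis is re-estimated per walk as the
# principal axis of the per-foot mean-centered heel positions: centering
# each foot's point cloud before the eigen-decomposition removes the
# constant lateral offset between the two feet, so for noise-free straight
# walking the estimated axis is exactly the walking direction.

# principal progression axis (unit vector) from walk events
progression_axis <- function(events) {
  xs <- split(seq_len(nrow(events)), events$foot)
  pts <- do.call(rbind, lapply(xs, function(idx) {
    p <- cbind(events$heel_x[idx], events$heel_y[idx])
    sweep(p, 2, colMeans(p))
  }))
  cv <- crossprod(pts) / max(1, nrow(pts) - 1)
  ax <- eigen(cv, symmetric = TRUE)$vectors[, 1]
  # orient along net displacement (first to last event of each foot)
  disp <- c(0, 0)
  for (idx in xs) {
    n <- length(idx)
    disp <- disp + c(events$heel_x[idx[n]] - events$heel_x[idx[1]],
                     events$heel_y[idx[n]] - events$heel_y[idx[1]])
  }
  if (sum(disp * ax) < 0) ax <- -ax
  ax
}

# perpendicular distance from point p to the line through a and b
point_line_distance <- function(p, a, b) {
  d <- b - a
  nrm <- sqrt(sum(d^2))
  if (nrm < 1e-12) return(sqrt(sum((p - a)^2)))
  abs(d[1] * (p[2] - a[2]) - d[2] * (p[1] - a[1])) / nrm
}

#' Segment a walk into stride records
#'
#' Builds one record per complete same-foot gait cycle within a trial. For
#' each stride the record holds the stride (cycle) time, the stride length
#' along the walk's estimated progression axis, the swing time (toe-off to
#' next same-foot heel strike), the double-support time (time within the
#' cycle during which both feet are on the ground; `NA` when the opposite
#' foot's contact history does not cover the cycle start), and the base of
#' support (perpendicular distance from the stride's initial heel point to
#' the line through the opposite foot's two temporally flanking heel
#' points; `NA` when no flanking pair exists).
#'
#' @param walk A `walk` object from [pool_trials()].
#' @param min_events Minimum footfall events per foot per trial (default 3).
#' @return A data.frame of stride records with columns `trial_index`,
#'   `foot`, `stride_time`, `stride_length`, `swing_time`, `swing_pct`,
#'   `double_support_time`, `dsupp_pct`, `base_of_support`.
#' @export
segment_strides <- function(walk, min_events = 3L) {
  if (!inherits(walk, "walk")) stop_gait("segment_strides expects a walk object")
  ev <- walk$events
  ax <- progression_axis(ev)
  ev$proj <- ev$heel_x * ax[1] + ev$heel_y * ax[2]
  out <- list()
  for (tr in unique(ev$trial_index)) {
    trev <- ev[ev$trial_index == tr, , drop = FALSE]
    for (ft in c("left", "right")) {
      own <- trev[trev$foot == ft, , drop = FALSE]
      opp <- trev[trev$foot != ft, , drop = FALSE]
      if (nrow(own) < min_events || nrow(opp) < min_events)
        stop_gait("walk %s/%s trial %d: fewer than %d events per foot",
                  walk$subject_id, walk$condition, tr, min_events)
      own <- own[order(own$contact_time), ]
      opp <- opp[order(opp$contact_time), ]
      n <- nrow(own)
      ns <- n - 1L
      c0 <- own$contact_time[-n]; c1 <- own$contact_time[-1L]
      l0 <- own$lift_time[-n]
      stride_time <- c1 - c0
      swing_time <- c1 - l0
      stride_length <- own$proj[-1L] - own$proj[-n]
      keep <- swing_time > 0 & swing_time < stride_time
      if (any(!keep))
        warning(sprintf("dropping %d inconsistent stride(s) (%s trial %d)",
                        sum(!keep), ft, tr))
      # double support: own stance [c0, l0] overlapped with the opposite
      # foot's stance intervals; NA when the opposite contact history does
      # not cover the cycle start
      opp_ct <- opp$contact_time; opp_lt <- opp$lift_time
      covered <- opp_ct[1] <= c0 & max(opp_lt) >= l0
      ds <- rep(0, ns)
      j0 <- findInterval(c0, opp_ct)
      for (off in -1:2) {
        j <- j0 + off
        ok <- j >= 1L & j <= length(opp_ct)
        ov <- rep(0, ns)
        ov[ok] <- pmax(0, pmin(opp_lt[j[ok]], l0[ok]) -
                          pmax(opp_ct[j[ok]], c0[ok]))
        ds <- ds + ov
      }
      ds[!covered] <- NA_real_
      # base of support at the stride's initial heel point: perpendicular
      # distance to the line through the temporally flanking opposite heels
      jb <- j0; ja <- j0 + 1L
      has_flank <- jb >= 1L & ja <= length(opp_ct)
      bos <- rep(NA_real_, ns)
      if (any(has_flank)) {
        axp <- opp$heel_x[jb[has_flank]]; ayp <- opp$heel_y[jb[has_flank]]
        bxp <- opp$heel_x[ja[has_flank]]; byp <- opp$heel_y[ja[has_flank]]
        px <- own$heel_x[-n][has_flank]; py <- own$heel_y[-n][has_flank]
        dx <- bxp - axp; dy <- byp - ayp
        nrm <- sqrt(dx^2 + dy^2)
        d <- abs(dx * (py - ayp) - dy * (px - axp)) / nrm
        d[nrm < 1e-12] <- sqrt((px - axp)^2 + (py - ayp)^2)[nrm < 1e-12]
        bos[has_flank] <- d
      }
      if (any(keep))
        out[[length(out) + 1L]] <- data.frame(
          trial_index = tr, foot = ft,
          stride_time = stride_time[keep], stride_length = stride_length[keep],
          swing_time = swing_time[keep],
          swing_pct = 100 * swing_time[keep] / stride_time[keep],
          double_support_time = ds[keep],
          dsupp_pct = 100 * ds[keep] / stride_time[keep],
          base_of_support = bos[keep], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    stop_gait("walk %s/%s yielded no complete strides",
              walk$subject_id, walk$condition)
  strides <- do.call(rbind, out)
  rownames(strides) <- NULL
  strides
}

cv_pct <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  100 * stats::sd(x) / mean(x)
}

asym_pct <- function(x, foot) {
  ok <- is.finite(x)
  x <- x[ok]; foot <- foot[ok]
  ml <- mean(x[foot == "left"]); mr <- mean(x[foot == "right"])
  if (!is.finite(ml) || !is.finite(mr)) return(NA_real_)
  100 * abs(ml - mr) / (0.5 * (ml + mr))
}

#' Compute the thirteen spatiotemporal gait metrics for a walk
#'
#' Pace domain: gait velocity `vel` (cm/s; total progression distance over
#' total ambulation time, computed per trial and combined across the pooled
#' trial pair so the spatial reset between trials does not bias it), mean
#' stride length `slen` (cm) and stride time `stime` (s). Phase domain: mean
#' swing `swing` and double-support `dsupp` phases (% of each stride's cycle
#' time, then averaged). Variability domain: coefficients of variation (100
#' × SD/mean, strides of both feet pooled) of stride length, stride time and
#' swing phase. Asymmetry domain: symmetry-index form 100 × |mean_L −
#' mean_R| / (0.5 × (mean_L + mean_R)) of the same three quantities (a
#' log-ratio alternative, 100 × |log(mean_L/mean_R)|, is available via
#' `asym_form = "log_ratio"`). Postural-control domain: mean and CV of the
#' per-stride base of support.
#'
#' Variability and asymmetry metrics require at least `min_strides` strides
#' per foot; below that they are returned as `NA` (missing, not zero). A
#' warning is emitted when a walk has fewer than 15 total cycles, the
#' commonly recommended minimum for stable variability and asymmetry
#' estimates.
#'
#' @param strides Stride records from [segment_strides()].
#' @param walk The `walk` the strides came from (used for velocity and
#'   labelling).
#' @param min_strides Minimum strides per foot for variability/asymmetry
#'   metrics (default 4).
#' @param asym_form `"symmetry_index"` (default) or `"log_ratio"`.
#' @return A named numeric vector of the 13 metrics (class `gait_metrics`)
#'   with attributes `subject_id`, `condition`, `walk`, `n_strides`.
#' @export
compute_metrics <- function(strides, walk, min_strides = 4L,
                            asym_form = c("symmetry_index", "log_ratio")) {
  asym_form <- match.arg(asym_form)
  ev <- walk$events
  ax <- progression_axis(ev)
  proj <- ev$heel_x * ax[1] + ev$heel_y * ax[2]
  # velocity: distance/time per trial, combined as total distance over
  # total time (equivalently duration-weighted mean of trial velocities)
  dist_tot <- 0; time_tot <- 0
  for (tr in unique(ev$trial_index)) {
    sel <- ev$trial_index == tr
    tt <- ev$contact_time[sel]
    o <- order(tt)
    d <- proj[sel][o[length(o)]] - proj[sel][o[1]]
    tm <- tt[o[length(o)]] - tt[o[1]]
    if (tm <= 0) stop_gait("degenerate trial duration in walk %s/%s",
                           walk$subject_id, walk$condition)
    dist_tot <- dist_tot + abs(d); time_tot <- time_tot + tm
  }
  n_left <- sum(strides$foot == "left")
  n_right <- sum(strides$foot == "right")
  if (nrow(strides) < 15)
    warning(sprintf(
      "walk %s/%s has %d cycles; at least 15 are recommended for stable variability/asymmetry estimates",
      walk$subject_id, walk$condition, nrow(strides)))
  enough <- min(n_left, n_right) >= min_strides
  asymf <- if (asym_form == "symmetry_index") asym_pct else function(x, foot) {
    ok <- is.finite(x)
    ml <- mean(x[ok & foot == "left"]); mr <- mean(x[ok & foot == "right"])
    if (!is.finite(ml) || !is.finite(mr) || ml <= 0 || mr <= 0) return(NA_real_)
    100 * abs(log(ml / mr))
  }
  vals <- c(
    vel = dist_tot / time_tot,
    slen = mean(strides$stride_length),
    stime = mean(strides$stride_time),
    swing = mean(strides$swing_pct),
    dsupp = mean(strides$dsupp_pct, na.rm = TRUE),
    slen_cv = if (enough) cv_pct(strides$stride_length) else NA_real_,
    stime_cv = if (enough) cv_pct(strides$stride_time) else NA_real_,
    swing_cv = if (enough) cv_pct(strides$swing_pct) else NA_real_,
    slen_asym = if (enough) asymf(strides$stride_length, strides$foot) else NA_real_,
    stime_asym = if (enough) asymf(strides$stride_time, strides$foot) else NA_real_,
    swing_asym = if (enough) asymf(strides$swing_pct, strides$foot) else NA_real_,
    swidth = mean(strides$base_of_support, na.rm = TRUE),
    swidth_cv = if (enough) cv_pct(strides$base_of_support) else NA_real_
  )
  structure(vals, class = "gait_metrics",
            subject_id = walk$subject_id, condition = walk$condition,
            walk = as.integer(ceiling(walk$trial_pair[1] / 2)),
            n_strides = c(left = n_left, right = n_right))
}

#' @export
print.gait_metrics <- function(x, digits = 3, ...) {
  cat(sprintf("<gait_metrics> subject %s, condition %s, walk %d (%d L / %d R strides)\n",
              attr(x, "subject_id"), attr(x, "condition"), attr(x, "walk"),
              attr(x, "n_strides")[1], attr(x, "n_strides")[2]))
  print(round(unclass(x), digits))
  invisible(x)
}

#' Extract the full metric table from a footfall table
#'
#' Convenience wrapper: for every subject × condition, pools the trial pairs
#' into walks, segments strides and computes the metric set per walk.
#'
#' @param footfalls A validated footfall table.
#' @param trial_pairs List of trial-index pairs defining the walks (default
#'   trials (1,2) and (3,4) in recording order).
#' @inheritParams compute_metrics
#' @return Long data.frame with columns `subject_id`, `condition`, `walk`,
#'   `metric`, `value`.
#' @export
extract_metrics <- function(footfalls, trial_pairs = list(c(1L, 2L), c(3L, 4L)),
                            min_strides = 4L,
                            asym_form = c("symmetry_index", "log_ratio")) {
  asym_form <- match.arg(asym_form)
  df <- as.data.frame(footfalls)
  sets <- list()
  for (sid in unique(df$subject_id)) {
    for (cond in unique(df$condition[df$subject_id == sid])) {
      sub <- df[df$subject_id == sid & df$condition == cond, , drop = FALSE]
      for (tp in trial_pairs) {
        if (!all(tp %in% sub$trial_index)) next
        w <- pool_trials(sub, tp)
        st <- segment_strides(w)
        gm <- suppressWarnings(
          compute_metrics(st, w, min_strides = min_strides,
                          asym_form = asym_form))
        sets[[length(sets) + 1L]] <- gm
      }
    }
  }
  as_metric_table(sets)
}

#' Pairwise 3-SD outlier removal across a cohort
#'
#' For one metric × condition, removes a subject's walk pair when either walk
#' value lies beyond `threshold` standard deviations from the cohort mean of
#' that walk ("pairwise": both walks of the subject are excluded together,
#' for this metric and condition only). Means and SDs are computed once on
#' the full cohort (non-iterative).
#'
#' @param pairs A data.frame with columns `subject_id`, `walk1`, `walk2`
#'   (one row per subject), or an n × 2 numeric matrix.
#' @param threshold SD multiple defining an outlier (default 3).
#' @return A list with `kept` (filtered data.frame), `removed` (subject ids),
#'   and `fraction` (share of subjects removed).
#' @export
remove_outliers <- function(pairs, threshold = 3) {
  if (is.matrix(pairs))
    pairs <- data.frame(subject_id = seq_len(nrow(pairs)),
                        walk1 = pairs[, 1], walk2 = pairs[, 2])
  if (nrow(pairs) < 3) stop_gait("outlier removal needs >= 3 subjects")
  flag <- rep(FALSE, nrow(pairs))
  for (col in c("walk1", "walk2")) {
    v <- pairs[[col]]
    m <- mean(v, na.rm = TRUE); s <- stats::sd(v, na.rm = TRUE)
    if (is.finite(s) && s > 0)
      flag <- flag | (is.finite(v) & abs(v - m) > threshold * s)
  }
  flag <- flag | !is.finite(pairs$walk1) | !is.finite(pairs$walk2)
  list(kept = pairs[!flag, , drop = FALSE],
       removed = pairs$subject_id[flag],
       fraction = mean(flag))
}

#' Shapiro–Wilk normality test
#'
#' Thin wrapper around [stats::shapiro.test()] with explicit degenerate-input
#' handling (constant vectors are rejected with an informative error rather
#' than an opaque one).
#'
#' @param values Numeric vector, `3 <= length <= 5000`.
#' @return List with `statistic` and `p`.
#' @export
shapiro_normality <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3) stop_gait("Shapiro-Wilk requires n >= 3")
  if (stats::sd(values) == 0)
    stop_gait("Shapiro-Wilk undefined for a constant vector",
              class = "gaitmcid_degenerate")
  ht <- stats::shapiro.test(values)
  list(statistic = unname(ht$statistic), p = unname(ht$p.value))
}
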