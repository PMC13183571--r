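# Standard error of measurement, minimal detectable change, and minimal
# clinically important difference estimation (distribution-based,
# anchor-based, triangulated).

#' Standard error of measurement and minimal detectable change
#'
#' \eqn{SEM = SD \times \sqrt{1 - ICC}} and
#' \eqn{MDC_{95} = 1.96 \times \sqrt{2} \times SEM}: the smallest change
#' exceeding measurement error at 95% confidence for a test-retest design.
#'
#' @param sd Cohort standard deviation of the metric (> 0).
#' @param icc Reliability of the metric (<= 1).
#' @return List with `sem` and `mdc95`, in metric units.
#' @examples
#' sem_mdc(sd = 21.27, icc = 0.98)
#' @export
sem_mdc <- function(sd, icc) {
  if (!is.finite(sd) || sd <= 0) stop_gait("sd must be positive")
  if (!is.finite(icc) || icc > 1) stop_gait("icc must be <= 1")
  sem <- sd * sqrt(1 - icc)
  list(sem = sem, mdc95 = 1.96 * sqrt(2) * sem)
}

#' Distribution-based MCID
#'
#' Effect-size-based threshold: `effect_size * sd`, with the conventional
#' small/medium/large effect sizes 0.2, 0.5 and 0.8.
#'
#' @param sd Cohort standard deviation of the metric (> 0).
#' @param effect_size One of 0.2, 0.5, 0.8 (other positive values allowed).
#' @return The unsigned estimate in metric units (sign it with the metric's
#'   improvement direction for reporting; [build_mcid_table()] does this).
#' @examples
#' distribution_mcid(21.27, 0.5)
#' @export
distribution_mcid <- function(sd, effect_size) {
  if (!is.finite(sd) || sd <= 0) stop_gait("sd must be positive")
  if (!is.finite(effect_size) || effect_size <= 0)
    stop_gait("effect_size must be positive")
  effect_size * sd
}

#' Anchor-based MCID for one metric/anchor pair
#'
#' Regresses the metric (per-subject values, typically the mean of the two
#' walks) on the clinical anchor. The anchor qualifies only when the Pearson
#' correlation satisfies |r| > `r_gate` (default 0.3) and at least
#' `min_pairs` complete pairs are available; otherwise the estimate is
#' absent (`NA`) with the reason recorded. When the anchor qualifies, the
#' MCID is the unstandardized regression coefficient B multiplied by the
#' anchor's established meaningful change, signed by the anchor's
#' improvement direction (e.g. FES-I improvement is a decrease of 8 points),
#' so the product carries the metric's own improvement direction.
#'
#' @param metric_values Per-subject metric values.
#' @param anchor_values Per-subject anchor scores, same order.
#' @param anchor One row of [anchor_specs()] (or a list with `mcid` and
#'   `improvement`), or an anchor name (`"FGA"`, `"FES_I"`, `"PCS12"`).
#' @param r_gate Minimum |Pearson r| for the anchor to qualify.
#' @param min_pairs Minimum complete pairs (default 10).
#' @return List with `r`, `b` (slope, metric units per anchor point),
#'   `estimate` (`b * improvement * mcid`, `NA` when the anchor does not
#'   qualify), `n`, and `reason` (`"ok"`, `"low_correlation"`,
#'   `"too_few_pairs"`, `"degenerate_anchor"`).
#' @examples
#' # the canonical worked example: slope 2.0 cm/s per FGA point, FGA MCID 4
#' fga <- 10:29
#' vel <- 60 + 2.0 * fga
#' anchor_mcid(vel, fga, "FGA")$estimate # 8 cm/s
#' @export
anchor_mcid <- function(metric_values, anchor_values, anchor,
                        r_gate = 0.3, min_pairs = 10L) {
  spec <- resolve_anchor(anchor)
  ok <- is.finite(metric_values) & is.finite(anchor_values)
  x <- anchor_values[ok]; y <- metric_values[ok]
  n <- length(x)
  absent <- function(reason, r = NA_real_, b = NA_real_)
    list(r = r, b = b, estimate = NA_real_, n = n, reason = reason)
  if (n < min_pairs) return(absent("too_few_pairs"))
  if (stats::sd(x) == 0) return(absent("degenerate_anchor"))
  if (stats::sd(y) == 0) return(absent("degenerate_metric"))
  r <- stats::cor(x, y)
  b <- stats::cov(x, y) / stats::var(x)
  if (!is.finite(r) || abs(r) <= r_gate)
    return(absent("low_correlation", r = r, b = b))
  list(r = r, b = b, estimate = b * spec$improvement * spec$mcid, n = n,
       reason = "ok")
}

resolve_anchor <- function(anchor) {
  specs <- anchor_specs()
  if (is.character(anchor)) {
    i <- match(anchor, specs$anchor)
    if (is.na(i)) stop_gait("unknown anchor: %s", anchor)
    return(as.list(specs[i, ]))
  }
  anchor <- as.list(anchor)
  if (is.null(anchor$mcid) || anchor$mcid <= 0)
    stop_gait("anchor mcid must be positive")
  anchor$improvement <- anchor$improvement %||% 1
  anchor
}

#' Triangulated MCID
#'
#' Arithmetic mean of the available members of the estimate set: the
#' medium-effect distribution-based value and up to three anchor-based
#' values. Missing members are simply left out; with fewer than four
#' available the average is over those present.
#'
#' @param dist_medium Medium-effect (0.5 × SD) distribution-based estimate,
#'   signed.
#' @param anchor_estimates Numeric vector of up to three anchor-based
#'   estimates (may contain `NA`).
#' @return List with `triangulated` (`NA` when no estimate is available) and
#'   `n_contributors`.
#' @examples
#' triangulate_mcid(10.64, c(7.18, 7.49, 11.02))$triangulated # 9.08
#' @export
triangulate_mcid <- function(dist_medium, anchor_estimates = numeric(0)) {
  vals <- c(dist_medium, anchor_estimates)
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0)
    return(list(triangulated = NA_real_, n_contributors = 0L))
  list(triangulated = mean(vals), n_contributors = length(vals))
}

#' Full MDC/MCID table for a cohort
#'
#' For every metric × condition: applies the pairwise outlier rule to the
#' walk pairs, computes the cohort SD (pooled over both walks after
#' removal), fits the ICC, derives SEM and MDC95, the three
#' distribution-based MCIDs (signed by the metric's improvement direction),
#' the anchor-based MCIDs for each qualifying anchor (metric entered as the
#' per-subject mean of the two walks), and the triangulated MCID. Rows where
#' the triangulated MCID does not exceed the MDC95 in magnitude are flagged
#' (`below_mdc`): for those metrics clinically meaningful change is not
#' separable from measurement error.
#'
#' @inheritParams reliability_table
#' @param anchors Anchor table (columns `subject_id`, `fga`, `fes_i`,
#'   `pcs12`), or `NULL` to skip anchor-based estimation.
#' @param r_gate,min_pairs Passed to [anchor_mcid()].
#' @return Data.frame of class `mcid_table`: one row per condition × metric
#'   with MDC, distribution-based, per-anchor and triangulated estimates
#'   (`mdc95` signed by improvement direction; `sem` unsigned), plus
#'   correlation/slope diagnostics per anchor.
#' @export
build_mcid_table <- function(metric_table, anchors = NULL,
                             form = c("absolute_agreement", "consistency"),
                             outlier_threshold = 3, r_gate = 0.3,
                             min_pairs = 10L) {
  form <- match.arg(form)
  info <- gait_metrics_info()
  if (!is.null(anchors)) anchors <- validate_anchors(as.data.frame(anchors))
  specs <- anchor_specs()
  out <- list()
  for (cond in intersect(gait_conditions(), unique(metric_table$condition))) {
    for (m in intersect(info$metric, unique(metric_table$metric))) {
      pairs <- metric_pairs(metric_table, m, cond)
      if (is.null(pairs) || nrow(pairs) < 3) next
      filt <- if (is.finite(outlier_threshold))
        remove_outliers(pairs, outlier_threshold)
      else list(kept = pairs, removed = character(0), fraction = 0)
      mat <- as.matrix(filt$kept[, c("walk1", "walk2")])
      if (nrow(mat) < 3) next
      sgn <- info$improvement[info$metric == m]
      pooled_sd <- stats::sd(c(mat))
      fit <- suppressMessages(icc(mat, form = form))
      sm <- sem_mdc(pooled_sd, min(1, fit$icc))
      row <- data.frame(
        condition = cond, domain = info$domain[info$metric == m], metric = m,
        n = nrow(mat), n_removed = length(filt$removed),
        sd = pooled_sd, icc = fit$icc, sem = sm$sem,
        mdc95 = sgn * sm$mdc95,
        dist_small = sgn * distribution_mcid(pooled_sd, 0.2),
        dist_medium = sgn * distribution_mcid(pooled_sd, 0.5),
        dist_large = sgn * distribution_mcid(pooled_sd, 0.8),
        stringsAsFactors = FALSE)
      anchor_est <- rep(NA_real_, nrow(specs))
      for (j in seq_len(nrow(specs))) {
        col_r <- paste0("r_", tolower(specs$anchor[j]))
        col_b <- paste0("b_", tolower(specs$anchor[j]))
        col_e <- paste0("mcid_", tolower(specs$anchor[j]))
        if (is.null(anchors)) {
          row[[col_r]] <- NA_real_; row[[col_b]] <- NA_real_
          row[[col_e]] <- NA_real_
          next
        }
        subj_mean <- data.frame(subject_id = filt$kept$subject_id,
                                value = rowMeans(mat))
        merged <- merge(subj_mean, anchors, by = "subject_id")
        am <- anchor_mcid(merged$value, merged[[specs$column[j]]],
                          as.list(specs[j, ]), r_gate = r_gate,
                          min_pairs = min_pairs)
        row[[col_r]] <- am$r; row[[col_b]] <- am$b; row[[col_e]] <- am$estimate
        anchor_est[j] <- am$estimate
      }
      tri <- triangulate_mcid(row$dist_medium, anchor_est)
      row$triangulated <- tri$triangulated
      row$n_contributors <- tri$n_contributors
      row$below_mdc <- is.finite(row$triangulated) &
        abs(row$triangulated) <= abs(row$mdc95)
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("mcid_table", "data.frame")
  res
}

#' @export
print.mcid_table <- function(x, digits = 2, ...) {
  cat("MDC and MCID estimates (signed by improvement direction)\n")
  df <- as.data.frame(x)
  num <- c("mdc95", "dist_small", "dist_medium", "dist_large",
           "mcid_fga", "mcid_fes_i", "mcid_pcs12", "triangulated")
  for (col in intersect(num, names(df)))
    df[[col]] <- round_half_away(df[[col]], digits)
  df$flag <- ifelse(df$below_mdc, "*", "")
  print(df[, c("condition", "domain", "metric", "mdc95", "dist_small",
               "dist_medium", "dist_large",
               intersect(c("mcid_fga", "mcid_fes_i", "mcid_pcs12"), names(df)),
               "triangulated", "flag")], row.names = FALSE)
  cat("* triangulated MCID within measurement error (|MCID| <= |MDC95|)\n")
  invisible(x)
}
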