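# Patient vs healthy-control comparison per metric and condition.

#' Compare patients with healthy controls on one metric
#'
#' Two-sided independent-samples t-test (Welch by default; Student available
#' by switch), with Shapiro–Wilk normality flags per group attached.
#'
#' @param patient_values,control_values Numeric vectors (each n >= 3).
#' @param variant `"welch"` (default, unequal variances) or `"student"`
#'   (pooled variance).
#' @param alpha Significance level used for the normality flags.
#' @return List of class `group_comparison` with `n_patients`, `n_controls`,
#'   `mean_diff` (patients − controls), `t_stat`, `df`, `p`, `variant`, and
#'   `normality` (per-group Shapiro–Wilk p-values and flags; `NA` for
#'   degenerate groups).
#' @examples
#' compare_groups(rnorm(60, 1), rnorm(30))
#' @export
compare_groups <- function(patient_values, control_values,
                           variant = c("welch", "student"), alpha = 0.05) {
  variant <- match.arg(variant)
  p <- patient_values[is.finite(patient_values)]
  ctrl <- control_values[is.finite(control_values)]
  if (length(p) < 3 || length(ctrl) < 3)
    stop_gait("each group needs n >= 3")
  if (stats::sd(p) == 0 && stats::sd(ctrl) == 0 && mean(p) == mean(ctrl))
    stop_gait("degenerate: both groups constant and equal")
  ht <- stats::t.test(p, ctrl, var.equal = (variant == "student"))
  sw <- function(v) {
    out <- tryCatch(shapiro_normality(v), error = function(e) NULL)
    if (is.null(out)) c(p = NA_real_, normal = NA)
    else c(p = out$p, normal = out$p > alpha)
  }
  structure(list(
    n_patients = length(p), n_controls = length(ctrl),
    mean_diff = mean(p) - mean(ctrl),
    t_stat = unname(ht$statistic), df = unname(ht$parameter),
    p = ht$p.value, variant = variant,
    normality = list(patients = sw(p), controls = sw(ctrl))),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s t-test: t(%.1f) = %.3f, p = %.3g; mean difference %.3f (n = %d vs %d)\n",
              x$variant, x$df, x$t_stat, x$p, x$mean_diff,
              x$n_patients, x$n_controls))
  invisible(x)
}

#' Patient-vs-control comparison table
#'
#' Runs [compare_groups()] for every metric × condition, using per-subject
#' condition means (average of the two walks). The `direction` column gives
#' the sign of the patient-minus-control difference, yielding the
#' sign-plus-significance matrix used to summarize group contrasts.
#'
#' @param patient_metrics,control_metrics Long metric tables.
#' @inheritParams compare_groups
#' @return Data.frame of class `compare_table` with one row per condition ×
#'   metric: `n_patients`, `n_controls`, `mean_patients`, `mean_controls`,
#'   `mean_diff`, `t_stat`, `df`, `p`, `direction`, `significant`,
#'   normality flags.
#' @export
compare_table <- function(patient_metrics, control_metrics,
                          variant = c("welch", "student"), alpha = 0.05) {
  variant <- match.arg(variant)
  info <- gait_metrics_info()
  out <- list()
  for (cond in intersect(gait_conditions(),
                         unique(patient_metrics$condition))) {
    for (m in intersect(info$metric, unique(patient_metrics$metric))) {
      pv <- subject_means(patient_metrics, m, cond)
      cv <- subject_means(control_metrics, m, cond)
      if (length(pv) < 3 || length(cv) < 3) next
      cmp <- compare_groups(pv, cv, variant = variant, alpha = alpha)
      out[[length(out) + 1L]] <- data.frame(
        condition = cond, domain = info$domain[info$metric == m], metric = m,
        n_patients = cmp$n_patients, n_controls = cmp$n_controls,
        mean_patients = mean(pv), mean_controls = mean(cv),
        mean_diff = cmp$mean_diff, t_stat = cmp$t_stat, df = cmp$df,
        p = cmp$p, variant = variant, direction = sign(cmp$mean_diff),
        significant = cmp$p < alpha,
        normal_patients = unname(cmp$normality$patients["normal"]) == 1,
        normal_controls = unname(cmp$normality$controls["normal"]) == 1,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("compare_table", "data.frame")
  res
}

# per-subject mean of the two walks for one metric x condition
subject_means <- function(metric_table, metric, condition) {
  sel <- metric_table$metric == metric & metric_table$condition == condition
  df <- metric_table[sel, , drop = FALSE]
  if (nrow(df) == 0) return(numeric(0))
  tapply(df$value, df$subject_id, mean, na.rm = TRUE)
}

#' @export
print.compare_table <- function(x, ...) {
  cat("Patient vs control comparison (", x$variant[1], " t-test)\n", sep = "")
  df <- as.data.frame(x)
  df$p <- ifelse(df$p < 0.001, "<0.001", sprintf("%.3f", df$p))
  df$sig <- ifelse(df$significant, ifelse(df$direction > 0, "+", "-"), "")
  print(df[, c("condition", "metric", "mean_patients", "mean_controls",
               "t_stat", "p", "sig")], digits = 4, row.names = FALSE)
  invisible(x)
}
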