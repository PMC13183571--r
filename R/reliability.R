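# Test-retest reliability: two-way ANOVA mean squares, single-measure
# intraclass correlation (consistency and absolute-agreement forms),
# F test, confidence intervals and interpretation bands.

#' Two-way ANOVA mean squares for a subjects x measurements matrix
#'
#' Balanced two-way decomposition with rows = subjects and columns = repeated
#' measurements (walks). Subjects with any missing cell are dropped
#' (complete-case, listwise per matrix) with a message. The sums of squares
#' partition the total sum of squares exactly.
#'
#' @param x Numeric matrix, n subjects × k measurements (k >= 2, n >= 3 after
#'   dropping incomplete rows).
#' @return List with `ms_rows`, `ms_cols`, `ms_error`, `ss_rows`, `ss_cols`,
#'   `ss_error`, `ss_total`, `n`, `k`, `n_dropped`.
#' @export
anova_mean_squares <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop_gait("need k >= 2 repeated measurements")
  complete <- stats::complete.cases(x)
  n_dropped <- sum(!complete)
  x <- x[complete, , drop = FALSE]
  n <- nrow(x); k <- ncol(x)
  if (n < 3) stop_gait("need n >= 3 complete subjects (have %d)", n)
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_total <- sum((x - grand)^2)
  ss_error <- ss_total - ss_rows - ss_cols
  list(ms_rows = ss_rows / (n - 1),
       ms_cols = ss_cols / (k - 1),
       ms_error = ss_error / ((n - 1) * (k - 1)),
       ss_rows = ss_rows, ss_cols = ss_cols, ss_error = ss_error,
       ss_total = ss_total, n = n, k = k, n_dropped = n_dropped)
}

#' Single-measure intraclass correlation (two-way model)
#'
#' Fits the two-way single-measure ICC used for test–retest reliability of
#' gait metrics across repeated walks. Two forms are available:
#' \describe{
#'   \item{consistency}{\eqn{(MS_R - MS_E) / (MS_R + (k-1) MS_E)} — the
#'     classic two-way mixed-effects, single-measure, consistency ICC.}
#'   \item{absolute_agreement}{\eqn{(MS_R - MS_E) / (MS_R + (k-1) MS_E +
#'     (k/n)(MS_C - MS_E))} — penalizes systematic differences between
#'     walks.}
#' }
#' The F statistic is \eqn{MS_R / MS_E} with \eqn{(n-1, (n-1)(k-1))} degrees
#' of freedom and an upper-tail p-value. Confidence intervals: exact F-based
#' for the consistency form; McGraw–Wong approximation with Satterthwaite
#' degrees of freedom for absolute agreement. ICC values are interpreted as
#' poor (< 0.5), moderate (0.5–0.75), good (0.75–0.9) or excellent (> 0.9).
#'
#' @param x n × k numeric matrix (subjects × walks), or a list of mean
#'   squares as returned by [anova_mean_squares()].
#' @param form `"absolute_agreement"` (default) or `"consistency"`.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return An object of class `gait_icc`: list with `icc`, `ci_low`,
#'   `ci_high`, `f_stat`, `df1`, `df2`, `p`, `band`, `form`, `n`, `k`,
#'   `ms_rows`, `ms_cols`, `ms_error`, `conf_level`.
#' @examples
#' x <- cbind(c(1, 2, 3, 4, 5), c(1.1, 2.0, 3.2, 3.9, 5.1))
#' icc(x, form = "consistency")
#' @export
icc <- function(x, form = c("absolute_agreement", "consistency"),
                conf_level = 0.95) {
  form <- match.arg(form)
  ms <- if (is.list(x) && !is.data.frame(x)) x else anova_mean_squares(x)
  res <- icc_from_mean_squares(ms$ms_rows, ms$ms_cols, ms$ms_error,
                               ms$n, ms$k, form = form)
  ci <- icc_confidence_interval(res, level = conf_level)
  res$ci_low <- ci[1]; res$ci_high <- ci[2]
  res$conf_level <- conf_level
  res$band <- classify_band(res$icc)
  res
}

#' ICC point estimate, F statistic and p-value from mean squares
#'
#' @param ms_rows,ms_cols,ms_error Two-way ANOVA mean squares (subjects,
#'   measurements, residual).
#' @param n,k Numbers of subjects and repeated measurements.
#' @inheritParams icc
#' @return A `gait_icc` object without confidence limits (see [icc()] for
#'   the full fit).
#' @export
icc_from_mean_squares <- function(ms_rows, ms_cols, ms_error, n, k,
                                  form = c("absolute_agreement",
                                           "consistency")) {
  form <- match.arg(form)
  if (any(c(ms_rows, ms_cols, ms_error) < -1e-12))
    stop_gait("mean squares must be non-negative")
  df1 <- n - 1; df2 <- (n - 1) * (k - 1)
  denom <- if (form == "consistency") {
    ms_rows + (k - 1) * ms_error
  } else {
    ms_rows + (k - 1) * ms_error + (k / n) * (ms_cols - ms_error)
  }
  est <- if (denom <= 0) 1 else (ms_rows - ms_error) / denom
  if (ms_error <= 0) {
    # perfect within-subject consistency: F degenerates
    f <- Inf
    p <- 0
    message("ms_error = 0: p-value below machine precision")
  } else {
    f <- ms_rows / ms_error
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  structure(list(icc = est, f_stat = f, df1 = df1, df2 = df2, p = p,
                 form = form, n = n, k = k,
                 ms_rows = ms_rows, ms_cols = ms_cols, ms_error = ms_error),
            class = "gait_icc")
}

#' Confidence interval for a single-measure ICC
#'
#' Consistency form: exact interval from the F distribution of
#' \eqn{MS_R/MS_E}. Absolute-agreement form: McGraw–Wong approximate
#' interval with Satterthwaite denominator degrees of freedom.
#'
#' @param result A `gait_icc` object.
#' @param level Confidence level (default 0.95).
#' @return Numeric vector `c(ci_low, ci_high)`.
#' @export
icc_confidence_interval <- function(result, level = 0.95) {
  n <- result$n; k <- result$k
  msr <- result$ms_rows; msc <- result$ms_cols; mse <- result$ms_error
  alpha <- 1 - level
  if (mse <= 0) {
    if (result$form == "consistency" || msc <= 0 || result$icc >= 1)
      return(c(1, 1))
    # absolute agreement with a pure walk offset: CI from the F ratio of
    # the between-walk to between-subject spread
    f_l <- stats::qf(1 - alpha / 2, n - 1, k - 1)
    f_u <- stats::qf(1 - alpha / 2, k - 1, n - 1)
    lo <- n * msr / (f_l * k * msc + n * msr)
    hi <- n * f_u * msr / (k * msc + n * f_u * msr)
    return(c(max(-1, min(lo, hi)), min(1, max(lo, hi))))
  }
  if (result$form == "consistency") {
    fobs <- msr / mse
    fl <- fobs / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    fu <- fobs * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    lo <- (fl - 1) / (fl + k - 1)
    hi <- (fu - 1) / (fu + k - 1)
  } else {
    est <- result$icc
    a <- (k * est) / (n * (1 - est))
    b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  }
  c(max(-1, lo), min(1, hi))
}

#' @export
confint.gait_icc <- function(object, parm, level = 0.95, ...) {
  ci <- icc_confidence_interval(object, level = level)
  out <- matrix(ci, nrow = 1,
                dimnames = list("icc", sprintf("%g %%", c((1 - level) / 2,
                                                          1 - (1 - level) / 2) * 100)))
  out
}

#' Interpretation band for an ICC value
#'
#' Cut-points: below 0.5 poor, 0.5 to 0.75 moderate, 0.75 to 0.9 good,
#' above 0.9 excellent. Values exactly at a boundary are assigned to the
#' higher band, except 0.9 itself which is good (the excellent band is
#' strictly above 0.9).
#'
#' @param icc Finite ICC value (vectorized).
#' @return Factor with levels poor, moderate, good, excellent.
#' @examples
#' classify_band(c(0.49, 0.5, 0.75, 0.9, 0.98))
#' @export
classify_band <- function(icc) {
  stopifnot(all(is.finite(icc)))
  bands <- ifelse(icc < 0.5, "poor",
           ifelse(icc < 0.75, "moderate",
           ifelse(icc <= 0.9, "good", "excellent")))
  factor(bands, levels = c("poor", "moderate", "good", "excellent"))
}

#' @export
print.gait_icc <- function(x, digits = 3, ...) {
  cat(sprintf("Single-measure ICC (%s form), n = %d subjects, k = %d\n",
              x$form, x$n, x$k))
  cat(sprintf("  ICC = %.*f", digits, x$icc))
  if (!is.null(x$ci_low))
    cat(sprintf("  %g%% CI [%.*f, %.*f]", 100 * (x$conf_level %||% 0.95),
                digits, x$ci_low, digits, x$ci_high))
  cat("\n")
  cat(sprintf("  F(%d, %d) = %.4g, p = %.3g\n", x$df1, x$df2, x$f_stat, x$p))
  if (!is.null(x$band)) cat(sprintf("  reliability: %s\n", as.character(x$band)))
  invisible(x)
}

#' Cohort reliability table
#'
#' For each metric × condition: applies the pairwise outlier rule, fits the
#' ICC across the two walks, and reports mean ± SD (pooled over both walks
#' after removal), the ICC with confidence interval, F statistic, p-value
#' and interpretation band.
#'
#' @param metric_table Long metric table (columns `subject_id`, `condition`,
#'   `walk`, `metric`, `value`), e.g. from [extract_metrics()] or
#'   [simulate_metric_cohort()].
#' @param form ICC form (see [icc()]).
#' @param outlier_threshold SD multiple for [remove_outliers()]; `Inf`
#'   disables removal.
#' @param conf_level Confidence level.
#' @return Data.frame of class `reliability_table`: one row per condition ×
#'   metric with columns `condition`, `domain`, `metric`, `n`, `n_removed`,
#'   `mean`, `sd`, `icc`, `ci_low`, `ci_high`, `f_stat`, `p`, `band`,
#'   `form`.
#' @export
reliability_table <- function(metric_table, form = c("absolute_agreement",
                                                     "consistency"),
                              outlier_threshold = 3, conf_level = 0.95) {
  form <- match.arg(form)
  info <- gait_metrics_info()
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
      fit <- suppressMessages(icc(mat, form = form, conf_level = conf_level))
      pooled <- c(mat)
      out[[length(out) + 1L]] <- data.frame(
        condition = cond, domain = info$domain[info$metric == m], metric = m,
        n = nrow(mat), n_removed = length(filt$removed),
        mean = mean(pooled), sd = stats::sd(pooled),
        icc = fit$icc, ci_low = fit$ci_low, ci_high = fit$ci_high,
        f_stat = fit$f_stat, p = fit$p, band = as.character(fit$band),
        form = form, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("reliability_table", "data.frame")
  res
}

# reshape long metric table into subject x (walk1, walk2) pairs for one
# metric and condition
metric_pairs <- function(metric_table, metric, condition) {
  sel <- metric_table$metric == metric & metric_table$condition == condition
  df <- metric_table[sel, , drop = FALSE]
  if (nrow(df) == 0) return(NULL)
  w1 <- df[df$walk == 1, c("subject_id", "value")]
  w2 <- df[df$walk == 2, c("subject_id", "value")]
  names(w1)[2] <- "walk1"; names(w2)[2] <- "walk2"
  merged <- merge(w1, w2, by = "subject_id")
  merged[order(merged$subject_id), , drop = FALSE]
}

#' @export
print.reliability_table <- function(x, digits = 2, ...) {
  cat("Test-retest reliability (", x$form[1], " ICC)\n", sep = "")
  df <- as.data.frame(x)
  df$mean_sd <- sprintf("%.2f ± %.2f", df$mean, df$sd)
  df$ci <- sprintf("[%.2f, %.2f]", df$ci_low, df$ci_high)
  df$icc <- round_half_away(df$icc, digits)
  df$f_stat <- signif(df$f_stat, 4)
  df$p <- ifelse(df$p < 0.001, "<0.001", sprintf("%.3f", df$p))
  print(df[, c("condition", "domain", "metric", "n", "mean_sd", "icc",
               "ci", "f_stat", "p", "band")], row.names = FALSE)
  invisible(x)
}
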