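# Metric catalogue, walking conditions and clinical-anchor constants.

#' The thirteen spatiotemporal gait metrics
#'
#' Catalogue of the gait metrics computed by [compute_metrics()], grouped into
#' the five established domains of spatiotemporal gait analysis. The
#' `improvement` column gives the direction of clinically meaningful change:
#' `+1` when a larger value reflects better gait (velocity, stride length,
#' swing phase), `-1` when a smaller value does (stride time, double support,
#' all variability and asymmetry markers, base of support and its
#' variability).
#'
#' @return A data.frame with columns `metric`, `domain`, `units`,
#'   `improvement`.
#' @examples
#' gait_metrics_info()
#' @export
gait_metrics_info <- function() {
  data.frame(
    metric = c("vel", "slen", "stime",
               "swing", "dsupp",
               "slen_cv", "stime_cv", "swing_cv",
               "slen_asym", "stime_asym", "swing_asym",
               "swidth", "swidth_cv"),
    domain = c(rep("pace", 3), rep("phase", 2), rep("variability", 3),
               rep("asymmetry", 3), rep("postural_control", 2)),
    units = c("cm/s", "cm", "s", "%", "%", "%", "%", "%", "%", "%", "%",
              "cm", "%"),
    improvement = c(1, 1, -1, 1, -1, -1, -1, -1, -1, -1, -1, -1, -1),
    stringsAsFactors = FALSE
  )
}

#' @rdname gait_metrics_info
#' @export
gait_metric_names <- function() gait_metrics_info()$metric

#' Walking conditions
#'
#' The three walking conditions supported by the pipeline: preferred walking
#' speed (`PWS`), slow walking speed (`SWS`) and eyes-closed walking (`EC`).
#'
#' @return Character vector of condition codes.
#' @export
gait_conditions <- function() c("PWS", "SWS", "EC")

#' Clinical anchor specifications
#'
#' The three clinical anchors used for anchor-based MCID estimation, with
#' their literature-established minimal clinically important differences and
#' improvement directions: Functional Gait Assessment (FGA, 0–30, +4 points
#' meaningful), Falls Efficacy Scale–International (FES-I, 16–64, −8 points
#' meaningful), and the SF-12 Physical Component Score (PCS-12, +10 points
#' meaningful).
#'
#' @return A data.frame with columns `anchor`, `column`, `mcid`,
#'   `improvement` (`+1` = meaningful change is an increase, `-1` a
#'   decrease), and `delta` (= `improvement * mcid`, the signed anchor change
#'   used when converting regression slopes into metric-scale MCIDs).
#' @examples
#' anchor_specs()
#' @export
anchor_specs <- function() {
  out <- data.frame(
    anchor = c("FGA", "FES_I", "PCS12"),
    column = c("fga", "fes_i", "pcs12"),
    mcid = c(4, 8, 10),
    improvement = c(1, -1, 1),
    stringsAsFactors = FALSE
  )
  out$delta <- out$mcid * out$improvement
  out
}

# Default per-metric population calibration for a chronic-vestibulopathy
# cohort (means, SDs and test-retest ICCs per condition), used as generator
# defaults. One row per condition x metric, ordered as gait_metric_names().
.cohort_calibration <- function() {
  m <- gait_metric_names()
  pws <- data.frame(
    condition = "PWS", metric = m,
    mean = c(98.27, 112.52, 1.16, 36.45, 26.96, 3.49, 3.17, 5.61,
             0.71, 0.91, 3.81, 11.48, 23.80),
    sd = c(21.27, 20.49, 0.09, 1.94, 4.04, 1.49, 1.28, 2.74,
           0.30, 0.52, 2.26, 3.67, 13.82),
    icc = c(0.98, 0.99, 0.92, 0.95, 0.97, 0.65, 0.60, 0.83,
            0.32, 0.51, 0.55, 0.94, 0.75))
  sws <- data.frame(
    condition = "SWS", metric = m,
    mean = c(53.29, 83.83, 1.61, 31.79, 36.27, 5.44, 4.94, 11.66,
             0.90, 0.71, 6.65, 13.50, 18.92),
    sd = c(10.68, 13.09, 0.23, 2.14, 4.15, 2.08, 2.01, 4.92,
           0.52, 0.43, 4.56, 4.32, 13.29),
    icc = c(0.86, 0.93, 0.95, 0.86, 0.86, 0.47, 0.66, 0.81,
            0.65, 0.34, 0.64, 0.97, 0.89))
  ec <- data.frame(
    condition = "EC", metric = m,
    mean = c(73.14, 84.75, 1.18, 34.27, 31.52, 9.96, 6.96, 14.53,
             1.49, 1.26, 7.18, 14.94, 27.04),
    sd = c(18.43, 18.73, 0.13, 2.96, 6.15, 3.72, 2.84, 5.39,
           0.81, 0.94, 5.48, 5.16, 15.39),
    icc = c(0.88, 0.92, 0.91, 0.90, 0.94, 0.53, 0.76, 0.80,
            0.16, 0.78, 0.66, 0.92, 0.87))
  rbind(pws, sws, ec)
}

#' Default cohort calibration for a chronic-vestibulopathy population
#'
#' Per-metric, per-condition population means, standard deviations and target
#' test–retest ICCs emulating a cohort of patients with chronic peripheral
#' vestibular failure walking at preferred speed, slowly, and with eyes
#' closed. These values parameterize the synthetic-cohort generators (see
#' [cohort_spec()]).
#'
#' @param conditions Subset of [gait_conditions()] to return.
#' @return A data.frame with columns `condition`, `metric`, `mean`, `sd`,
#'   `icc`.
#' @examples
#' head(vestibular_cohort_defaults())
#' @export
vestibular_cohort_defaults <- function(conditions = gait_conditions()) {
  conditions <- match.arg(conditions, gait_conditions(), several.ok = TRUE)
  cal <- .cohort_calibration()
  cal[cal$condition %in% conditions, , drop = FALSE]
}

# Average number of gait cycles per pooled walk (mean, SD) per condition.
.cycle_targets <- function() {
  data.frame(condition = c("PWS", "SWS", "EC"),
             mean = c(21.8, 29.2, 30.4),
             sd = c(4.5, 4.8, 8.5),
             stringsAsFactors = FALSE)
}
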