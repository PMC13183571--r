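# Pipeline orchestration: synthetic or on-disk study -> metric extraction ->
# reliability, MDC/MCID and group-comparison tables + run manifest.

#' Pipeline run configuration
#'
#' Aggregates every switch of the analysis: input paths (or a synthetic
#' cohort spec), ICC form, t-test variant, asymmetry formula, outlier
#' threshold, anchor MCID constants, rounding, seed and output directory.
#'
#' @param footfalls,anchors,controls Paths to the patient footfall CSV, the
#'   anchor CSV and (optionally) the control footfall CSV; leave `NULL` and
#'   supply `synthetic` to simulate instead.
#' @param synthetic A [cohort_spec()] used when no input paths are given.
#' @param conditions Conditions to analyze (default: all present).
#' @param icc_form `"absolute_agreement"` (default) or `"consistency"`.
#' @param t_variant `"welch"` (default) or `"student"`.
#' @param asym_form `"symmetry_index"` (default) or `"log_ratio"`.
#' @param outlier_threshold SD multiple for pairwise outlier removal
#'   (default 3; `Inf` disables).
#' @param rounding Decimal places for rendered tables (default 2, half away
#'   from zero).
#' @param seed Seed for the synthetic path.
#' @param output_dir Where `run_pipeline()` writes its files.
#' @return List of class `run_config`.
#' @export
run_config <- function(footfalls = NULL, anchors = NULL, controls = NULL,
                       synthetic = NULL, conditions = NULL,
                       icc_form = c("absolute_agreement", "consistency"),
                       t_variant = c("welch", "student"),
                       asym_form = c("symmetry_index", "log_ratio"),
                       outlier_threshold = 3, rounding = 2L,
                       seed = 1L, output_dir = tempfile("gaitmcid_run_")) {
  icc_form <- match.arg(icc_form)
  t_variant <- match.arg(t_variant)
  asym_form <- match.arg(asym_form)
  if (is.null(footfalls) && is.null(synthetic))
    synthetic <- cohort_spec(seed = seed)
  if (!is.null(conditions))
    conditions <- match.arg(conditions, gait_conditions(), several.ok = TRUE)
  structure(list(footfalls = footfalls, anchors = anchors,
                 controls = controls, synthetic = synthetic,
                 conditions = conditions, icc_form = icc_form,
                 t_variant = t_variant, asym_form = asym_form,
                 outlier_threshold = outlier_threshold,
                 rounding = as.integer(rounding), seed = as.integer(seed),
                 output_dir = output_dir),
            class = "run_config")
}

#' Run the full gait reliability/MCID pipeline
#'
#' Stages: (1) obtain footfall data — either read from the configured paths
#' or simulate the configured synthetic study; (2) extract the per-walk
#' metric table; (3) reliability table (ICC per metric × condition); (4)
#' MDC/MCID table (SEM, MDC95, distribution-/anchor-based and triangulated
#' MCIDs); (5) patient-vs-control comparison (when controls are available);
#' (6) write all tables as CSV plus a JSON manifest recording every switch,
#' per-cell subject counts and the outlier-removal log. Deterministic for
#' fixed inputs and seed.
#'
#' @param config A [run_config()].
#' @return An object of class `gait_study`: list with `metrics`,
#'   `reliability`, `mcid`, `comparison` (or `NULL`), `config`, `manifest`,
#'   and `files` (paths written).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(label, expr) {
    tryCatch(expr, error = function(e)
      stop_gait("pipeline stage '%s' failed: %s", label, conditionMessage(e)))
  }
  ctl_metrics <- NULL
  if (!is.null(config$footfalls)) {
    ff <- stage("read", read_footfalls(config$footfalls))
    anchors <- if (!is.null(config$anchors))
      stage("read", read_anchors(config$anchors)) else NULL
    if (!is.null(config$controls)) {
      cff <- stage("read", read_footfalls(config$controls))
      ctl_metrics <- stage("extract",
                           extract_metrics(cff, asym_form = config$asym_form))
    }
    metrics <- stage("extract",
                     extract_metrics(ff, asym_form = config$asym_form))
  } else {
    spec <- config$synthetic
    sim_dir <- file.path(config$output_dir, "synthetic_data")
    sim <- stage("simulate", simulate_full_study(spec, sim_dir))
    ff <- stage("read", read_footfalls(sim$paths$footfalls))
    anchors <- stage("read", read_anchors(sim$paths$anchors))
    metrics <- stage("extract",
                     extract_metrics(ff, asym_form = config$asym_form))
    if (!is.null(sim$paths$controls)) {
      cff <- stage("read", read_footfalls(sim$paths$controls))
      ctl_metrics <- stage("extract",
                           extract_metrics(cff, asym_form = config$asym_form))
    }
  }
  if (!is.null(config$conditions)) {
    metrics <- metrics[metrics$condition %in% config$conditions, ]
    if (!is.null(ctl_metrics))
      ctl_metrics <- ctl_metrics[ctl_metrics$condition %in% config$conditions, ]
  }
  rel <- stage("reliability",
               reliability_table(metrics, form = config$icc_form,
                                 outlier_threshold = config$outlier_threshold))
  mcid <- stage("mcid",
                build_mcid_table(metrics, anchors, form = config$icc_form,
                                 outlier_threshold = config$outlier_threshold))
  cmp <- if (!is.null(ctl_metrics))
    stage("compare", compare_table(metrics, ctl_metrics,
                                   variant = config$t_variant)) else NULL
  files <- list(metrics = file.path(config$output_dir, "metrics.csv"),
                reliability = file.path(config$output_dir, "reliability.csv"),
                mcid = file.path(config$output_dir, "mcid.csv"),
                manifest = file.path(config$output_dir, "manifest.json"))
  write_metrics(metrics, files$metrics)
  utils::write.csv(as.data.frame(rel), files$reliability, row.names = FALSE)
  utils::write.csv(as.data.frame(mcid), files$mcid, row.names = FALSE)
  if (!is.null(cmp)) {
    files$comparison <- file.path(config$output_dir, "comparison.csv")
    utils::write.csv(as.data.frame(cmp), files$comparison, row.names = FALSE)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("gaitmcid")),
    seed = config$seed, icc_form = config$icc_form,
    t_variant = config$t_variant, asym_form = config$asym_form,
    outlier_threshold = config$outlier_threshold,
    rounding = config$rounding,
    anchor_mcids = stats::setNames(as.list(anchor_specs()$mcid),
                                   anchor_specs()$anchor),
    n_per_cell = stats::setNames(as.list(rel$n),
                                 paste(rel$condition, rel$metric, sep = ".")),
    removed_per_cell = stats::setNames(as.list(rel$n_removed),
                                       paste(rel$condition, rel$metric,
                                             sep = ".")),
    config_hash = config_hash(config))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             files$manifest)
  structure(list(metrics = metrics, control_metrics = ctl_metrics,
                 reliability = rel, mcid = mcid, comparison = cmp,
                 config = config, manifest = manifest, files = files),
            class = "gait_study")
}

# stable hash of the configuration switches (order-independent content hash)
config_hash <- function(config) {
  keep <- config[setdiff(names(config), "output_dir")]
  txt <- paste(deparse(keep[order(names(keep))]), collapse = "")
  # small polynomial rolling hash; enough to fingerprint a config
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 1000000007
  sprintf("%09d", h)
}

#' @export
print.gait_study <- function(x, ...) {
  cat("<gait_study>\n")
  cat(sprintf("  %d metric values, %d reliability rows, %d MCID rows%s\n",
              nrow(x$metrics), nrow(x$reliability), nrow(x$mcid),
              if (is.null(x$comparison)) ""
              else sprintf(", %d comparison rows", nrow(x$comparison))))
  cat("  output:", x$config$output_dir, "\n")
  invisible(x)
}

#' @export
summary.gait_study <- function(object, ...) {
  print(object$reliability)
  cat("\n")
  print(object$mcid)
  if (!is.null(object$comparison)) {
    cat("\n")
    print(object$comparison)
  }
  invisible(object)
}
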