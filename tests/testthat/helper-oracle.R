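# Independent oracles and small data builders shared across tests.

# Brute-force ICC oracle: mean squares from stats::aov on the long layout,
# converted to variance components, then the definitional ratios. This is an
# independent route from the package's closed-form balanced-design sums.
oracle_icc <- function(x, form = c("consistency", "absolute_agreement")) {
  form <- match.arg(form)
  n <- nrow(x); k <- ncol(x)
  long <- data.frame(y = as.vector(x),
                     s = factor(rep(seq_len(n), times = k)),
                     w = factor(rep(seq_len(k), each = n)))
  tab <- summary(stats::aov(y ~ s + w, data = long))[[1]]
  msr <- tab["s", "Mean Sq"]; msc <- tab["w", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  var_r <- (msr - mse) / k
  var_c <- (msc - mse) / n
  if (form == "consistency") var_r / (var_r + mse)
  else var_r / (var_r + var_c + mse)
}

# n x 2 test-retest matrix with true (consistency) ICC rho
make_pair_matrix <- function(n, rho, sigma = 1, mu = 0, col_offset = 0) {
  b <- stats::rnorm(n, 0, sqrt(rho) * sigma)
  x <- mu + b + matrix(stats::rnorm(2 * n, 0, sqrt(1 - rho) * sigma), n, 2)
  x[, 2] <- x[, 2] + col_offset
  x
}

# hand-built footfall table: alternating left/right contacts at the given
# times/positions, lift at contact + stance
toy_footfalls <- function(times, feet, ys, xs, stance = 0.64,
                          subject = "T1", condition = "PWS", trial = 1L) {
  data.frame(subject_id = subject, condition = condition, trial_index = trial,
             foot = feet, contact_time = times, lift_time = times + stance,
             heel_x = xs, heel_y = ys, stringsAsFactors = FALSE)
}

# walk object straight from an events data.frame
as_walk <- function(events, trial_pair = c(1L, 2L)) {
  structure(list(subject_id = events$subject_id[1],
                 condition = events$condition[1],
                 trial_pair = as.integer(trial_pair), events = events),
            class = "walk")
}

pws_targets <- function() {
  cal <- vestibular_cohort_defaults("PWS")
  stats::setNames(cal$mean, cal$metric)
}

extract_one <- function(ev, trial_pair = c(1, 2), ...) {
  w <- pool_trials(ev, trial_pair)
  suppressWarnings(compute_metrics(segment_strides(w), w, ...))
}

# long metric table -> subject x (walk1, walk2) for one metric/condition
metric_values_wide <- function(metrics, metric, condition) {
  sel <- metrics$metric == metric & metrics$condition == condition
  df <- metrics[sel, ]
  w1 <- df[df$walk == 1, c("subject_id", "value")]
  w2 <- df[df$walk == 2, c("subject_id", "value")]
  names(w1)[2] <- "walk1"; names(w2)[2] <- "walk2"
  merge(w1, w2, by = "subject_id")
}

subject_mean_values <- function(metrics, metric, condition, ids) {
  sel <- metrics$metric == metric & metrics$condition == condition
  df <- metrics[sel, ]
  tapply(df$value, df$subject_id, mean)[ids]
}
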