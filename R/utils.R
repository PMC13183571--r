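# Small internal helpers shared across modules.

# round half away from zero at `digits` decimals (report convention; base
# round() rounds half to even)
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_gait <- function(fmt, ..., class = "gaitmcid_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error")))
}

# draw n values with exact sample mean m and exact sample sd s
# (moment-matched normal draws; n == 1 returns m, s ignored)
rnorm_exact <- function(n, m, s) {
  if (n == 1L || s <= 0) return(rep(m, n))
  z <- stats::rnorm(n)
  zs <- stats::sd(z)
  if (zs < 1e-12) z <- seq(-1, 1, length.out = n) # degenerate draw guard
  z <- (z - mean(z)) / stats::sd(z)
  m + s * z
}

# within-group sd such that the pooled (combined) sample of two groups of
# size n each, with exact group means m1, m2 and common within sd, has exact
# combined sample sd `target`. Returns NA if infeasible.
within_sd_for_pooled <- function(target, m1, m2, n) {
  if (n <= 1L) return(if (abs(m1 - m2) > 0) NA_real_ else target)
  g <- (m1 + m2) / 2
  num <- (2 * n - 1) * target^2 - n * ((m1 - g)^2 + (m2 - g)^2)
  if (num < 0) return(NA_real_)
  sqrt(num / (2 * (n - 1)))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L &&
  is.finite(x) && x == round(x) && x >= 0
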