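# Noncentral-t power and sample size for detecting a fractional change
# in a metric's mean (two-sided one-sample t test).

#' Power of the two-sided one-sample t test
#'
#' Exact power via the noncentral t distribution:
#' `power = P(|T'| > t_{1-alpha/2, n-1})` with noncentrality
#' `ncp = sqrt(n) * delta / sd`.  At `delta = 0` the power equals the
#' size `alpha` of the test.
#'
#' @param delta absolute change in the mean to detect (metric units).
#' @param sd standard deviation of the metric (same units).
#' @param n sample size (`>= 2`).
#' @param alpha two-sided significance level.
#' @return power in (0, 1), vectorised over the arguments.
#' @export
power_one_sample_t <- function(delta, sd, n, alpha = 0.05) {
  if (any(sd <= 0)) stop("`sd` must be > 0")
  if (any(n < 2)) stop("`n` must be >= 2")
  if (any(alpha <= 0 | alpha >= 1)) stop("`alpha` must be in (0, 1)")
  df <- n - 1
  tc <- qt(1 - alpha / 2, df)
  ncp <- sqrt(n) * abs(delta) / sd
  (1 - pt(tc, df, ncp)) + pt(-tc, df, ncp)
}

#' Smallest sample size reaching a target power
#'
#' Minimal integer `n >= 2` with
#' `power_one_sample_t(delta, sd, n, alpha) >= target_power`, found by
#' an upward search from the normal-approximation start
#' `n0 = ((z_{1-alpha/2} + z_{power}) * sd / delta)^2` (power is
#' strictly increasing in `n`, so the first hit is the argmin).
#'
#' @inheritParams power_one_sample_t
#' @param target_power required power.
#' @return smallest sufficient integer sample size.
#' @export
n_one_sample_t <- function(delta, sd, alpha = 0.05,
                           target_power = 0.8) {
  if (delta <= 0) stop("`delta` must be > 0")
  if (target_power <= alpha || target_power >= 1)
    stop("`target_power` must be in (alpha, 1)")
  n0 <- ceiling(((qnorm(1 - alpha / 2) + qnorm(target_power)) *
                   sd / delta)^2)
  n <- max(2, n0 - 2)
  while (power_one_sample_t(delta, sd, n, alpha) < target_power)
    n <- n + 1
  # step back in case the start overshot the argmin
  while (n > 2 &&
         power_one_sample_t(delta, sd, n - 1, alpha) >= target_power)
    n <- n - 1
  as.integer(n)
}

#' Power / sample-size report for metric summaries
#'
#' For each metric summary (mean, sd, n) and each effect fraction,
#' computes the absolute change `effect_fraction * |mean|`, the power of
#' the current design to detect it, and the sample size required to
#' reach `target_power`.
#'
#' @param summaries data frame with columns `metric`, `dose` (or any
#'   label columns), `mean`, `sd`, `n`.
#' @param effect_fractions fractional changes in the mean to detect.
#' @param alpha two-sided significance level.
#' @param target_power required power for the sample-size column.
#' @return data frame, one row per summary x effect fraction: inputs
#'   plus `delta`, `power_pct` (percent, one decimal), `n_required`;
#'   rows with `n < 2` or non-finite sd are flagged (`computable =
#'   FALSE`) and carry NAs.
#' @export
power_table <- function(summaries, effect_fractions = c(0.2, 0.5),
                        alpha = 0.05, target_power = 0.8) {
  need <- c("mean", "sd", "n")
  missing <- setdiff(need, names(summaries))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  out <- do.call(rbind, lapply(effect_fractions, function(f) {
    df <- summaries
    df$effect_fraction <- f
    df$delta <- f * abs(df$mean)
    ok <- is.finite(df$delta) & df$delta > 0 & is.finite(df$sd) &
      df$sd > 0 & !is.na(df$n) & df$n >= 2
    df$computable <- ok
    df$power_pct <- NA_real_
    df$n_required <- NA_integer_
    if (any(ok)) {
      df$power_pct[ok] <- round_half_up(
        100 * power_one_sample_t(df$delta[ok], df$sd[ok], df$n[ok],
                                 alpha), 1)
      df$n_required[ok] <- vapply(which(ok), function(i)
        n_one_sample_t(df$delta[i], df$sd[i], alpha, target_power),
        integer(1))
    }
    df
  }))
  rownames(out) <- NULL
  out
}
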