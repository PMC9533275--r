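#' Power of a fixed-model regression coefficient F-test
#'
#' Noncentral-F tail probability beyond the central-F critical value, with
#' the G*Power noncentrality convention lambda = f2 * N (not f2 * (df2 + 1)).
#'
#' @param n total sample size.
#' @param predictors total number of predictors in the model (default 3:
#'   age, education, gender).
#' @param tested number of tested predictors (numerator df, default 1 —
#'   a single-coefficient test).
#' @param alpha type-I level.
#' @param f2 Cohen's effect size f-squared (> 0 for a noncentral test).
#' @return achieved power.
#' @export
power_at <- function(n, f2, predictors = 3, tested = 1, alpha = 0.05) {
  stopifnot(n > predictors + 1, alpha > 0, alpha < 1, tested <= predictors,
            f2 >= 0)
  df1 <- tested
  df2 <- n - predictors - 1
  crit <- stats::qf(1 - alpha, df1, df2)
  stats::pf(crit, df1, df2, ncp = f2 * n, lower.tail = FALSE)
}

#' Sensitivity power analysis: minimal detectable f-squared
#'
#' Solves for the effect size f2 at which the noncentral-F test of a
#' regression coefficient (numerator df = `tested`, denominator df =
#' N - `predictors` - 1, noncentrality lambda = f2 * N) attains the target
#' power at level alpha. Power is strictly increasing in f2, so a monotone
#' bisection converges to |power - target| < `tol`.
#'
#' @param n total sample size.
#' @param predictors total predictors (default 3).
#' @param tested tested predictors / numerator df (default 1).
#' @param alpha type-I level (default 0.05).
#' @param power target power (default 0.80).
#' @param tol solver tolerance on power.
#' @return list: `f2` (unrounded), `f2_display` (3 decimals), `lambda`,
#'   `df1`, `df2`, `critical_value`, `power`.
#' @export
sensitivity_f2 <- function(n, predictors = 3, tested = 1, alpha = 0.05,
                           power = 0.80, tol = 1e-10) {
  stopifnot(n > predictors + 1, alpha > 0, alpha < 1, power > 0, power < 1)
  if (power <= alpha) stop("target power must exceed alpha")
  lo <- 0; hi <- 1
  while (power_at(n, hi, predictors, tested, alpha) < power) {
    hi <- hi * 2
    if (hi > 1e6) stop("failed to bracket the target power")
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    p <- power_at(n, mid, predictors, tested, alpha)
    if (abs(p - power) < tol) break
    if (p < power) lo <- mid else hi <- mid
  }
  df1 <- tested; df2 <- n - predictors - 1
  list(f2 = mid, f2_display = round_half_away(mid, 3), lambda = mid * n,
       df1 = df1, df2 = df2,
       critical_value = stats::qf(1 - alpha, df1, df2),
       power = power_at(n, mid, predictors, tested, alpha))
}
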