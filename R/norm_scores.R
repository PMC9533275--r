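#' Non-parametric tolerance limits on the 5th centile
#'
#' Order-statistic tolerance limits for the lower p-th population centile at
#' confidence gamma, computed from the exact binomial distribution (no normal
#' approximation). The outer limit (OTL) is the r-th order statistic with r
#' the largest integer such that P(Binomial(n, p) <= r - 1) <= 1 - gamma; it
#' is the conservative lower bound defining Equivalent Score 0. The inner
#' limit (ITL) is the s-th order statistic with s the smallest integer such
#' that P(Binomial(n, p) <= s - 1) >= gamma.
#'
#' @param adjusted numeric sample of adjusted scores.
#' @param p centile level (default 0.05).
#' @param conf confidence gamma (default 0.95).
#' @return object of class `tolerance_limits`: `otl`, `itl`, `outer_rank`,
#'   `inner_rank`, `n`, `p`, `conf`.
#' @export
tolerance_limits <- function(adjusted, p = 0.05, conf = 0.95) {
  x <- sort(adjusted[!is.na(adjusted)])
  n <- length(x)
  n_min <- ceiling(log(1 - conf) / log(1 - p))
  if (stats::pbinom(0, n, p) > 1 - conf) {
    stop(sprintf("n = %d too small for a valid outer rank at p = %g, conf = %g; minimum n is %d",
                 n, p, conf, n_min))
  }
  k <- 0:n
  cdf <- stats::pbinom(k, n, p)
  r <- max(k[cdf <= 1 - conf]) + 1L      # largest r with F(r-1) <= 1-gamma
  s <- min(k[cdf >= conf]) + 1L          # smallest s with F(s-1) >= gamma
  stopifnot(r >= 1, s <= n, r <= s)
  structure(list(otl = x[r], itl = x[s], outer_rank = r, inner_rank = s,
                 n = n, p = p, conf = conf),
            class = "tolerance_limits")
}

#' Equivalent Score thresholds
#'
#' ES = 0 is bounded above by the OTL and ES = 4 begins above the sample
#' median; the intermediate bands (ES 1, 2, 3) partition the observations
#' strictly between OTL and median into three consecutive rank groups of as
#' equal size as possible (remainders to the lower bands first), each band's
#' upper cutoff being the maximum observed value of its group.
#'
#' @param adjusted numeric sample of adjusted scores.
#' @param limits optional precomputed [tolerance_limits()] on the same sample.
#' @return object of class `es_thresholds`: `test` (NA unless set by caller),
#'   `cutoffs` (c0..c3), `median`, `limits`, `degenerate` flag.
#' @export
es_thresholds <- function(adjusted, limits = tolerance_limits(adjusted)) {
  x <- sort(adjusted[!is.na(adjusted)])
  med <- stats::median(x)
  c0 <- limits$otl
  region <- x[x > c0 & x < med]
  k <- length(region)
  degenerate <- FALSE
  if (k < 3) {
    warning("fewer than 3 observations between OTL and median; ES bands collapsed")
    degenerate <- TRUE
    c1 <- if (k >= 1) region[min(1, k)] else c0
    c2 <- if (k >= 2) region[min(2, k)] else c1
  } else {
    n1 <- ceiling(k / 3)
    n2 <- ceiling((k - n1) / 2)
    c1 <- region[n1]
    c2 <- region[n1 + n2]
  }
  cutoffs <- c(c0 = c0, c1 = c1, c2 = c2, c3 = med)
  if (any(diff(cutoffs) <= 0)) {
    warning("tied ES cutoffs collapsed; bands are degenerate")
    degenerate <- TRUE
  }
  structure(list(test = NA_character_, cutoffs = cutoffs, median = med,
                 limits = limits, degenerate = degenerate),
            class = "es_thresholds")
}

#' Assign an Equivalent Score
#'
#' Band convention with inclusive upper bounds: ES 0 iff x <= c0, ES k iff
#' c(k-1) < x <= ck for k in 1..3, ES 4 iff x > c3. Monotone non-decreasing
#' in x.
#'
#' @param x adjusted score(s).
#' @param th an [es_thresholds()].
#' @return integer ES in 0..4, vectorised over `x`.
#' @export
assign_es <- function(x, th) {
  cf <- th$cutoffs
  as.integer((x > cf[1]) + (x > cf[2]) + (x > cf[3]) + (x > cf[4]))
}

#' Percentile lookup table
#'
#' Empirical quantiles of the adjusted scores at the standard normative level
#' set, using linear interpolation of order statistics (the type 7
#' convention, recorded in the output). Values are reported unrounded with a
#' 1-decimal display column.
#'
#' @param adjusted numeric sample.
#' @param levels percentile levels (default 99, 95, 90, ..., 5, 4, 3, 2, 1).
#' @param type quantile convention passed to [stats::quantile()].
#' @return data.frame (`percentile_table`): `level`, `value`, `display`.
#' @export
percentile_table <- function(adjusted,
                             levels = c(99, seq(95, 5, by = -5), 4, 3, 2, 1),
                             type = 7) {
  x <- adjusted[!is.na(adjusted)]
  stopifnot(length(x) > 0)
  q <- stats::quantile(x, probs = levels / 100, type = type, names = FALSE)
  out <- data.frame(level = levels, value = q, display = round_half_away(q, 1))
  attr(out, "quantile_type") <- type
  class(out) <- c("percentile_table", "data.frame")
  out
}

#' Serialise / deserialise ES thresholds as JSON
#'
#' @param th an `es_thresholds`.
#' @param path file path.
#' @return reader returns the thresholds; writer returns `path` invisibly.
#' @export
write_thresholds_json <- function(th, path) {
  obj <- list(test = th$test, cutoffs = as.list(th$cutoffs), median = th$median,
              degenerate = th$degenerate,
              limits = list(otl = th$limits$otl, itl = th$limits$itl,
                            outer_rank = th$limits$outer_rank,
                            inner_rank = th$limits$inner_rank,
                            n = th$limits$n, p = th$limits$p,
                            conf = th$limits$conf))
  write_json_file(obj, path)
  invisible(path)
}

#' @rdname write_thresholds_json
#' @export
read_thresholds_json <- function(path) {
  obj <- read_json_file(path)
  lim <- structure(obj$limits[c("otl", "itl", "outer_rank", "inner_rank",
                                "n", "p", "conf")],
                   class = "tolerance_limits")
  lim$outer_rank <- as.integer(lim$outer_rank)
  lim$inner_rank <- as.integer(lim$inner_rank)
  lim$n <- as.integer(lim$n)
  structure(list(test = if (is.null(obj$test)) NA_character_ else obj$test,
                 cutoffs = unlist(obj$cutoffs), median = obj$median,
                 limits = lim, degenerate = obj$degenerate),
            class = "es_thresholds")
}

#' @export
print.es_thresholds <- function(x, ...) {
  cf <- x$cutoffs
  cat(sprintf("Equivalent Score thresholds%s\n",
              if (is.na(x$test)) "" else sprintf(" for '%s'", x$test)))
  cat(sprintf("  ES 0: <= %.2f (OTL)\n", cf[1]))
  cat(sprintf("  ES 1: %.2f - %.2f\n", cf[1], cf[2]))
  cat(sprintf("  ES 2: %.2f - %.2f\n", cf[2], cf[3]))
  cat(sprintf("  ES 3: %.2f - %.2f (median)\n", cf[3], cf[4]))
  cat(sprintf("  ES 4: > %.2f\n", cf[4]))
  cat(sprintf("  OTL = %.2f (rank %d), ITL = %.2f (rank %d), n = %d\n",
              x$limits$otl, x$limits$outer_rank, x$limits$itl,
              x$limits$inner_rank, x$limits$n))
  invisible(x)
}
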