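#' Round half away from zero
#'
#' Commercial rounding used for all display values (correction grids,
#' thresholds): ties go away from zero, unlike [base::round()]'s banker's
#' rounding. Internal arithmetic is never rounded.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Named per-stage substream: one global seed drives every stage, each stage
# gets its own reproducible stream. Kept below 2^31 - 1 (R integers).
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 7919 + h * 104729) %% (.Machine$integer.max - 1L))
}

# Quantile of a normal truncated to [lo, hi] (standardised internally).
qtruncnorm <- function(u, mean, sd, lo, hi) {
  a <- stats::pnorm((lo - mean) / sd)
  b <- stats::pnorm((hi - mean) / sd)
  stats::qnorm(a + u * (b - a)) * sd + mean
}

# Mean and SD of a Normal(mu, sigma) truncated to [lo, hi].
truncnorm_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  Z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  m <- mu + sigma * (da - db) / Z
  v <- sigma^2 * (1 + (a * da - b * db) / Z - ((da - db) / Z)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# Parent (mu, sigma) such that the truncation to [lo, hi] has the target
# mean exactly and an SD as close to the target as the family allows on
# those bounds (asymmetric truncation otherwise biases the realised
# moments). Two-stage solve: the truncated mean is strictly increasing in
# mu, so mu is found by uniroot for each candidate sigma; sigma then
# minimises the SD mismatch over a numerically stable range.
truncnorm_params <- function(mean, sd, lo, hi) {
  stopifnot(mean > lo, mean < hi, sd > 0)
  solve_mu <- function(sigma) {
    f <- function(mu) truncnorm_moments(mu, sigma, lo, hi)["mean"] - mean
    stats::uniroot(f, c(lo - 6 * sigma, hi + 6 * sigma), tol = 1e-10)$root
  }
  sd_err <- function(sigma) {
    mu <- solve_mu(sigma)
    abs(truncnorm_moments(mu, sigma, lo, hi)["sd"] - sd)
  }
  opt <- stats::optimize(sd_err, c(0.3 * sd, 6 * sd), tol = 1e-8)
  sigma <- opt$minimum
  list(mu = solve_mu(sigma), sigma = sigma)
}

# 17 significant digits so doubles survive the round trip bit-exactly
write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
}

read_json_file <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
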