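# Brute-force oracles, kept deliberately independent of the package's
# implementation paths.

# Binomial CDF by direct log-space summation of the mass function.
oracle_binom_cdf <- function(k, n, p) {
  if (k < 0) return(0)
  j <- 0:k
  sum(exp(lchoose(n, j) + j * log(p) + (n - j) * log(1 - p)))
}

# Tolerance-limit ranks by enumeration over all candidate ranks.
oracle_tolerance_ranks <- function(n, p = 0.05, conf = 0.95) {
  cdf <- vapply(0:n, oracle_binom_cdf, numeric(1), n = n, p = p)
  r <- max(which(cdf <= 1 - conf))          # index i corresponds to k = i - 1
  s <- min(which(cdf >= conf))
  c(outer = r, inner = s)                   # ranks r, s (k + 1 with 1-based which)
}

# Cohen's kappa and Gwet's AC1 evaluated directly from the four counts.
oracle_kappa <- function(a, b, c, d) {
  n <- a + b + c + d
  p_o <- (a + d) / n
  p_e <- ((a + b) / n) * ((a + c) / n) + ((c + d) / n) * ((b + d) / n)
  if (1 - p_e <= 0) return(NA_real_)
  (p_o - p_e) / (1 - p_e)
}

oracle_ac1 <- function(a, b, c, d) {
  n <- a + b + c + d
  p_o <- (a + d) / n
  pi_bar <- ((a + b) / n + (a + c) / n) / 2
  p_g <- 2 * pi_bar * (1 - pi_bar)
  if (1 - p_g <= 0) return(NA_real_)
  (p_o - p_g) / (1 - p_g)
}

# AUC by exhaustive pair counting (lower score predicts impairment).
oracle_auc <- function(scores, ref) {
  imp <- scores[ref == 1]; nor <- scores[ref == 0]
  if (length(imp) == 0 || length(nor) == 0) return(NA_real_)
  tot <- 0
  for (x in imp) for (y in nor) {
    tot <- tot + (x < y) + 0.5 * (x == y)
  }
  tot / (length(imp) * length(nor))
}

# Build flag vectors realising a 2x2 table (ref x pred).
flags_from_table <- function(a, b, c, d) {
  list(ref  = rep(c(1, 1, 0, 0), times = c(a, b, c, d)),
       pred = rep(c(1, 0, 1, 0), times = c(a, b, c, d)))
}

# Simple demographics for synthetic fitting cohorts (uniform, independent).
make_demo_cohort <- function(n, seed) {
  set.seed(seed)
  out <- data.frame(
    id = seq_len(n),
    age = sample(18:84, n, replace = TRUE),
    education = sample(5:26, n, replace = TRUE),
    gender = rbinom(n, 1, 0.6))
  class(out) <- c("cohort_table", "data.frame")
  out
}
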