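#' Score catalog for the five verbal memory tests
#'
#' Admissible score ranges and granularity: Digit Span Forward/Backward are
#' the longest span recalled (0-9, integer), Rey Auditory Verbal Learning
#' immediate recall sums five trials (0-75), delayed recall one trial (0-15),
#' and Verbal Paired Associates Learning awards half points for easy pairs
#' (0-22.5 in steps of 0.5).
#'
#' @return data.frame with columns `test`, `min`, `max`, `step`.
#' @export
test_catalog <- function() {
  data.frame(
    test = c("dsf", "dsb", "ravl_i", "ravl_d", "vpal"),
    min  = c(0, 0, 0, 0, 0),
    max  = c(9, 9, 75, 15, 22.5),
    step = c(1, 1, 1, 1, 0.5),
    stringsAsFactors = FALSE
  )
}

#' Demographic and correlation targets of the normative sample
#'
#' Published descriptives of the healthy videoconference cohort (N = 204,
#' 127 female / 77 male) used to calibrate the synthetic generator: means and
#' SDs of age, education and the five test scores, together with the full
#' correlation matrix over (gender, age, education, scores). Gender is coded
#' 0 = male, 1 = female, so gender correlations are point-biserial.
#'
#' @return list with `means`, `sds`, `bounds` (2-row matrix), `p_female`,
#'   and `corr` (8 x 8 correlation matrix).
#' @export
table1_targets <- function() {
  vars <- c("gender", "age", "education", "dsf", "dsb", "ravl_i", "ravl_d", "vpal")
  R <- matrix(c(
    1.00,  0.06,  0.00, -0.21, -0.12,  0.24,  0.32,  0.10,
    0.06,  1.00, -0.49, -0.21, -0.29, -0.46, -0.41, -0.55,
    0.00, -0.49,  1.00,  0.14,  0.22,  0.39,  0.38,  0.40,
   -0.21, -0.21,  0.14,  1.00,  0.52,  0.28,  0.21,  0.32,
   -0.12, -0.29,  0.22,  0.52,  1.00,  0.31,  0.28,  0.32,
    0.24, -0.46,  0.39,  0.28,  0.31,  1.00,  0.78,  0.65,
    0.32, -0.41,  0.38,  0.21,  0.28,  0.78,  1.00,  0.57,
    0.10, -0.55,  0.40,  0.32,  0.32,  0.65,  0.57,  1.00
  ), nrow = 8, dimnames = list(vars, vars))
  means <- c(age = 44.33, education = 14.98, dsf = 6.40, dsb = 5.01,
             ravl_i = 54.09, ravl_d = 11.82, vpal = 16.60)
  sds <- c(age = 18.51, education = 3.85, dsf = 1.15, dsb = 1.26,
           ravl_i = 9.12, ravl_d = 2.65, vpal = 4.25)
  cat <- test_catalog()
  bounds <- cbind(
    age = c(18, 84), education = c(5, 26),
    vapply(cat$test, function(t) c(cat$min[cat$test == t], cat$max[cat$test == t]),
           numeric(2))
  )
  rownames(bounds) <- c("min", "max")
  list(means = means, sds = sds, bounds = bounds,
       p_female = 127 / 204, corr = R)
}

#' Specification of a synthetic cohort
#'
#' Bundles everything the generators need: cohort size, marginal targets
#' (means, SDs, bounds, gender split), the target correlation matrix, and the
#' seed. `simulate_healthy_cohort()` uses the full correlation matrix;
#' `simulate_patient_cohort()` uses per-test clinical means/SDs plus a target
#' age-education correlation.
#'
#' @param n cohort size (>= 2).
#' @param means named numeric vector of marginal means.
#' @param sds named numeric vector of marginal SDs.
#' @param bounds 2 x p matrix (rows `min`, `max`) of marginal bounds.
#' @param p_female target proportion of females.
#' @param corr target correlation matrix (healthy cohorts).
#' @param age_edu_r target age-education Pearson correlation (patient cohorts).
#' @param age_edu_tol tolerance on the realised age-education correlation.
#' @param seed integer seed; identical specs give identical cohorts.
#' @return object of class `simulation_spec`.
#' @export
simulation_spec <- function(n, means, sds, bounds, p_female = 0.5,
                            corr = NULL, age_edu_r = NULL,
                            age_edu_tol = 0.02, seed = 1L) {
  stopifnot(n >= 2, length(means) == length(sds))
  if (!is.null(corr)) {
    if (!isSymmetric(unname(corr)) || any(abs(corr) > 1) ||
        any(abs(diag(corr) - 1) > 1e-12)) {
      stop("target correlation matrix must be symmetric with unit diagonal and entries in [-1, 1]")
    }
  }
  structure(list(n = as.integer(n), means = means, sds = sds, bounds = bounds,
                 p_female = p_female, corr = corr, age_edu_r = age_edu_r,
                 age_edu_tol = age_edu_tol, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Default spec for the healthy normative cohort
#'
#' @param n cohort size (default 204, the published sample).
#' @param seed integer seed.
#' @return `simulation_spec` at the published calibration targets.
#' @export
healthy_spec <- function(n = 204, seed = 1L) {
  t1 <- table1_targets()
  simulation_spec(n = n, means = t1$means, sds = t1$sds, bounds = t1$bounds,
                  p_female = t1$p_female, corr = t1$corr, seed = seed)
}

#' Default spec for the simulated aMCI patient cohort
#'
#' The published comparison drew patient score distributions from external
#' Italian norms whose means/SDs are not reprinted here; these defaults are
#' SYNTHETIC STAND-INS at clinically plausible magnitudes for amnestic Mild
#' Cognitive Impairment (clearly below the healthy means, large memory
#' deficits on recall tests, mild ones on spans). Age and education are
#' generated to realise the stated negative correlation r = -0.22.
#'
#' @param n cohort size (default 100).
#' @param score_means,score_sds named per-test clinical means and SDs
#'   (synthetic stand-in defaults).
#' @param seed integer seed.
#' @return `simulation_spec` for a patient cohort.
#' @export
patient_spec <- function(n = 100,
                         score_means = c(dsf = 5.2, dsb = 3.6, ravl_i = 28.5,
                                         ravl_d = 4.0, vpal = 7.5),
                         score_sds = c(dsf = 1.1, dsb = 1.2, ravl_i = 8.0,
                                       ravl_d = 2.8, vpal = 3.5),
                         seed = 1L) {
  means <- c(age = 72, education = 9, score_means)
  sds <- c(age = 6.5, education = 4, score_sds)
  cat <- test_catalog()
  # ages capped at 84, the upper end the norms were built for
  bounds <- cbind(
    age = c(55, 84), education = c(3, 25),
    vapply(names(score_means), function(t)
      c(cat$min[cat$test == t], cat$max[cat$test == t]), numeric(2))
  )
  rownames(bounds) <- c("min", "max")
  simulation_spec(n = n, means = means, sds = sds, bounds = bounds,
                  p_female = 0.5, age_edu_r = -0.22, seed = seed)
}

# Repair a nearly-PSD correlation matrix by clipping small negative
# eigenvalues; refuse if the deficit is material.
repair_corr <- function(R, max_deficit = 0.05) {
  e <- eigen(R, symmetric = TRUE)
  lam <- e$values
  if (min(lam) < -max_deficit) {
    stop(sprintf("correlation matrix is not positive semidefinite after repair (eigenvalue %.4f)",
                 min(lam)))
  }
  if (min(lam) < 1e-10) {
    lam <- pmax(lam, 1e-8)
    R <- e$vectors %*% diag(lam) %*% t(e$vectors)
    d <- sqrt(diag(R))
    R <- R / tcrossprod(d)
  }
  (R + t(R)) / 2
}

round_to_step <- function(x, step) round_half_away(x / step, 0) * step

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# The deterministic monotone map from the latent standard normal to each
# emitted variable (truncated-normal quantile map + rounding + clipping for
# continuous variables; threshold at the split quantile for gender).
marginal_maps <- function(spec, vars) {
  cat0 <- test_catalog()
  maps <- list()
  for (v in vars) {
    if (v == "gender") {
      q <- stats::qnorm(1 - spec$p_female)
      maps[[v]] <- local({
        q0 <- q
        function(z) as.numeric(z > q0)
      })
    } else {
      lo <- spec$bounds["min", v]; hi <- spec$bounds["max", v]
      par <- truncnorm_params(spec$means[v], spec$sds[v], lo, hi)
      step <- if (v %in% cat0$test) cat0$step[cat0$test == v] else 1
      maps[[v]] <- local({
        mu <- par$mu; sigma <- par$sigma; l <- lo; h <- hi; s <- step
        function(z) clip(round_to_step(qtruncnorm(stats::pnorm(z), mu, sigma, l, h), s), l, h)
      })
    }
  }
  maps
}

# Calibrate the latent Gaussian correlation matrix so that, after each
# variable's monotone output map, the population Pearson correlations equal
# the targets (the NORTA problem). Each map g is expanded in orthonormal
# Hermite polynomials, g(Z) = sum_k a_k He_k(Z)/sqrt(k!), whence
# cor(g1(Z1), g2(Z2)) = sum_{k>=1} a1_k a2_k rho^k / (s1 s2) - a polynomial
# in the latent rho, inverted per pair by monotone root finding.
calibrate_latent_corr <- function(R, maps, K = 30L, grid_n = 4001L) {
  vars <- names(maps)
  z <- seq(-8, 8, length.out = grid_n)
  w <- stats::dnorm(z) * (z[2] - z[1])
  # orthonormal Hermite basis on the grid, normalised three-term recurrence
  H <- matrix(0, grid_n, K + 1)
  H[, 1] <- 1
  H[, 2] <- z
  for (k in 2:K) {
    H[, k + 1] <- (z * H[, k] - sqrt(k - 1) * H[, k - 1]) / sqrt(k)
  }
  A <- vapply(vars, function(v) {
    g <- maps[[v]](z)
    as.numeric(crossprod(H, g * w))
  }, numeric(K + 1))
  # exact marginal SDs from the grid: the truncated series misses the
  # high-order variance that rounding steps inject, the covariance does not
  # (cross terms decay geometrically in rho)
  sds <- vapply(vars, function(v) {
    g <- maps[[v]](z)
    m <- sum(g * w)
    sqrt(max(sum(g^2 * w) - m^2, 1e-12))
  }, numeric(1))
  out <- diag(length(vars))
  dimnames(out) <- dimnames(R)
  for (i in seq_along(vars)[-1]) {
    for (j in seq_len(i - 1)) {
      target <- R[i, j]
      if (target == 0) next
      coef <- A[-1, i] * A[-1, j]
      r_out <- function(rho) sum(coef * rho^seq_len(K)) / (sds[i] * sds[j])
      lohi <- sort(c(r_out(-0.999), r_out(0.999)))
      if (target <= lohi[1] || target >= lohi[2]) {
        out[i, j] <- out[j, i] <- sign(target) * 0.999
        next
      }
      out[i, j] <- out[j, i] <-
        stats::uniroot(function(rho) r_out(rho) - target,
                       c(-0.999, 0.999), tol = 1e-8)$root
    }
  }
  out
}

#' Simulate a healthy normative cohort
#'
#' Gaussian copula: draws a latent multivariate normal with the target
#' correlation matrix, thresholds the gender component at the target split
#' quantile (so point-biserial targets are approximately honoured), and
#' quantile-maps the continuous components to truncated-normal marginals with
#' the target means/SDs and bounds. Ages and educations are rounded to whole
#' years, scores to each test's granularity, after the copula mapping (which
#' preserves correlation targets better than rounding before).
#'
#' @param spec a [simulation_spec()] carrying a full correlation matrix.
#' @return data.frame (`cohort_table`) with columns `id`, `age`, `education`,
#'   `gender` (0 = male, 1 = female) and one column per test.
#' @export
simulate_healthy_cohort <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"), !is.null(spec$corr))
  R <- repair_corr(spec$corr)
  vars <- colnames(spec$corr)
  cont <- setdiff(vars, "gender")
  missing_targets <- setdiff(cont, names(spec$means))
  if (length(missing_targets) > 0) {
    stop("no marginal targets for: ", paste(missing_targets, collapse = ", "))
  }
  for (v in cont) {
    lo <- spec$bounds["min", v]; hi <- spec$bounds["max", v]
    if (spec$means[v] - spec$sds[v] > hi || spec$means[v] + spec$sds[v] < lo) {
      warning(sprintf("bounds for '%s' inconsistent with mean +/- SD; clipping", v))
    }
  }
  # The output maps (truncated-normal quantile map, rounding, gender
  # threshold) attenuate Pearson correlations relative to the latent
  # Gaussian; calibrate the latent matrix so the population correlations of
  # the *transformed* variables equal the targets (Hermite expansion, see
  # calibrate_latent_corr), then re-repair PSD.
  R <- calibrate_latent_corr(R, marginal_maps(spec, vars))
  R <- repair_corr(R)
  set.seed(spec$seed)
  Z <- matrix(stats::rnorm(spec$n * ncol(R)), spec$n) %*% chol(R)
  colnames(Z) <- vars
  out <- data.frame(id = seq_len(spec$n))
  # latent upper tail -> female, preserving the sign of gender correlations
  out$gender <- as.integer(Z[, "gender"] > stats::qnorm(1 - spec$p_female))
  cat <- test_catalog()
  for (v in cont) {
    u <- stats::pnorm(Z[, v])
    # parent parameters moment-matched so the truncated marginal hits the
    # target mean/SD despite asymmetric truncation
    par <- truncnorm_params(spec$means[v], spec$sds[v],
                            spec$bounds["min", v], spec$bounds["max", v])
    x <- qtruncnorm(u, par$mu, par$sigma,
                    spec$bounds["min", v], spec$bounds["max", v])
    step <- if (v %in% cat$test) cat$step[cat$test == v] else 1
    out[[v]] <- clip(round_to_step(x, step),
                     spec$bounds["min", v], spec$bounds["max", v])
  }
  out <- out[, c("id", "age", "education", "gender",
                 intersect(cat$test, names(out)))]
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Simulate an impaired patient cohort
#'
#' Test scores are drawn independently Normal(mean, SD) per test, clipped to
#' catalog bounds and rounded to the test's granularity. Age and education are
#' drawn from a bivariate Gaussian copula whose latent correlation is adjusted
#' iteratively until the realised Pearson correlation of the rounded values
#' hits the target within `age_edu_tol`.
#'
#' @param spec a [simulation_spec()] carrying per-test means/SDs and a target
#'   age-education correlation (`age_edu_r`).
#' @param max_iter maximum latent-correlation adjustment iterations.
#' @return data.frame (`cohort_table`) as in [simulate_healthy_cohort()].
#' @export
simulate_patient_cohort <- function(spec, max_iter = 200L) {
  stopifnot(inherits(spec, "simulation_spec"), !is.null(spec$age_edu_r))
  target <- spec$age_edu_r
  tol <- spec$age_edu_tol
  set.seed(spec$seed)
  cat <- test_catalog()
  tests <- intersect(cat$test, names(spec$means))

  par_age <- truncnorm_params(spec$means["age"], spec$sds["age"],
                              spec$bounds["min", "age"], spec$bounds["max", "age"])
  par_edu <- truncnorm_params(spec$means["education"], spec$sds["education"],
                              spec$bounds["min", "education"],
                              spec$bounds["max", "education"])
  draw_demo <- function(rho) {
    z1 <- stats::rnorm(spec$n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(spec$n)
    age <- qtruncnorm(stats::pnorm(z1), par_age$mu, par_age$sigma,
                      spec$bounds["min", "age"], spec$bounds["max", "age"])
    edu <- qtruncnorm(stats::pnorm(z2), par_edu$mu, par_edu$sigma,
                      spec$bounds["min", "education"], spec$bounds["max", "education"])
    age <- clip(round_to_step(age, 1), spec$bounds["min", "age"], spec$bounds["max", "age"])
    edu <- clip(round_to_step(edu, 1), spec$bounds["min", "education"], spec$bounds["max", "education"])
    list(age = age, education = edu, r = stats::cor(age, edu))
  }

  rho <- clip(target, -0.99, 0.99)
  demo <- draw_demo(rho)
  it <- 0L
  while (abs(demo$r - target) > tol) {
    it <- it + 1L
    if (it > max_iter) {
      stop(sprintf("target age-education correlation %.3f unattainable within %d iterations (last realised %.3f)",
                   target, max_iter, demo$r))
    }
    rho <- clip(rho + (target - demo$r), -0.99, 0.99)
    demo <- draw_demo(rho)
  }

  out <- data.frame(id = seq_len(spec$n), age = demo$age,
                    education = demo$education,
                    gender = as.integer(stats::runif(spec$n) < spec$p_female))
  for (t in tests) {
    x <- stats::rnorm(spec$n, spec$means[t], spec$sds[t])
    lo <- cat$min[cat$test == t]; hi <- cat$max[cat$test == t]
    out[[t]] <- clip(round_to_step(x, cat$step[cat$test == t]), lo, hi)
  }
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Write / read a cohort CSV
#'
#' Gender is written as `m`/`f` for readability and mapped back to the 0/1
#' internal coding (0 = male, 1 = female) on read.
#'
#' @param cohort a `cohort_table` data.frame.
#' @param path file path.
#' @return `read_cohort_csv` returns a `cohort_table`; writer returns `path`
#'   invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- as.data.frame(cohort)
  out$gender <- c("m", "f")[out$gender + 1L]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.character(out$gender)) {
    out$gender <- as.integer(out$gender == "f")
  }
  cat <- test_catalog()
  for (t in intersect(cat$test, names(out))) {
    hi <- cat$max[cat$test == t]
    if (any(out[[t]] > hi, na.rm = TRUE)) {
      warning(sprintf("'%s' has scores above the catalog maximum %.1f", t, hi))
    }
  }
  class(out) <- c("cohort_table", "data.frame")
  out
}
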