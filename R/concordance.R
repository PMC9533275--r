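#' A normative scoring system
#'
#' Pairs an adjustment equation with an impairment rule: a participant is
#' impaired when the adjusted score falls at or below the cutoff (the outer
#' tolerance limit, i.e. Equivalent Score 0, unless another cutoff is
#' supplied).
#'
#' @param name system label.
#' @param equation an `adjustment_equation`.
#' @param cutoff impairment cutoff in adjusted-score units; defaults to the
#'   OTL of `thresholds` when given.
#' @param thresholds optional `es_thresholds` (provides the default cutoff
#'   and ES assignment).
#' @return object of class `normative_system`.
#' @export
normative_system <- function(name, equation, cutoff = NULL, thresholds = NULL) {
  stopifnot(inherits(equation, "adjustment_equation"))
  if (is.null(cutoff)) {
    if (is.null(thresholds)) stop("supply a cutoff or es_thresholds")
    cutoff <- thresholds$limits$otl
  }
  structure(list(name = name, equation = equation, cutoff = cutoff,
                 thresholds = thresholds),
            class = "normative_system")
}

#' Classify a cohort under a normative system
#'
#' Adjusts each row's raw score with the system's equation and flags
#' impairment (adjusted <= cutoff). Rows with missing demographics are
#' excluded with a message.
#'
#' @param cohort a `cohort_table` containing the test column.
#' @param system a [normative_system()].
#' @return data.frame: `id`, `adjusted`, `impaired` (0/1), and `es` when the
#'   system carries thresholds.
#' @export
classify_cohort <- function(cohort, system) {
  eq <- system$equation
  need <- unique(c("age", vapply(eq$terms, function(tm) tm$transform$covariate,
                                 character(1))))
  need <- intersect(need, names(cohort))
  ok <- stats::complete.cases(cohort[c(eq$test, need)])
  if (any(!ok)) {
    message(sprintf("%d row(s) excluded for missing demographics", sum(!ok)))
  }
  dat <- cohort[ok, ]
  adjusted <- suppressWarnings(adjust_cohort(eq, dat))
  out <- data.frame(id = dat$id, adjusted = adjusted,
                    impaired = as.integer(adjusted <= system$cutoff))
  if (!is.null(system$thresholds)) {
    out$es <- assign_es(adjusted, system$thresholds)
  }
  out
}

#' Cross-tabulate two binary classifications
#'
#' @param ref reference impairment flags (0/1).
#' @param pred predicted impairment flags (0/1).
#' @return object of class `confusion_matrix` with counts `a` (both
#'   impaired), `b` (ref impaired, pred normal), `c` (ref normal, pred
#'   impaired), `d` (both normal), and `n`.
#' @export
cross_tabulate <- function(ref, pred) {
  if (length(ref) != length(pred)) stop("ref and pred must have equal length")
  stopifnot(all(ref %in% 0:1), all(pred %in% 0:1))
  structure(list(a = sum(ref == 1 & pred == 1),
                 b = sum(ref == 1 & pred == 0),
                 c = sum(ref == 0 & pred == 1),
                 d = sum(ref == 0 & pred == 0),
                 n = length(ref)),
            class = "confusion_matrix")
}

# Mann-Whitney AUC oriented so LOWER scores predict impairment; ties count
# half. ref: 0/1 impairment flags; scores: continuous adjusted scores.
auc_rank <- function(scores, ref) {
  n1 <- sum(ref == 1); n0 <- sum(ref == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  # W counts pairs (impaired, normal) with score_impaired < score_normal
  (n1 * n0 + n1 * (n1 + 1) / 2 - sum(r[ref == 1])) / (n1 * n0)
}

# DeLong variance of the AUC via placement values.
auc_delong_ci <- function(scores, ref, conf = 0.95) {
  x1 <- scores[ref == 1]; x0 <- scores[ref == 0]
  n1 <- length(x1); n0 <- length(x0)
  auc <- auc_rank(scores, ref)
  if (n1 < 2 || n0 < 2) return(c(NA_real_, NA_real_))
  # placement of each impaired score among normals (low impaired = concordant)
  v10 <- vapply(x1, function(xi) mean((xi < x0) + 0.5 * (xi == x0)), numeric(1))
  v01 <- vapply(x0, function(xj) mean((x1 < xj) + 0.5 * (x1 == xj)), numeric(1))
  se <- sqrt(stats::var(v10) / n1 + stats::var(v01) / n0)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  c(max(0, auc - z * se), min(1, auc + z * se))
}

auc_boot_ci <- function(scores, ref, conf = 0.95, reps = 2000L, seed = 1L) {
  set.seed(seed)
  n <- length(scores)
  stat <- replicate(reps, {
    i <- sample.int(n, n, replace = TRUE)
    auc_rank(scores[i], ref[i])
  })
  unname(stats::quantile(stat, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                         na.rm = TRUE, type = 7))
}

# Gwet's AC1 with its linearised two-rater variance (binary categories).
ac1_stats <- function(a, b, c, d, conf = 0.95) {
  n <- a + b + c + d
  p_o <- (a + d) / n
  p1 <- (a + b) / n            # rater 1 (reference) impaired proportion
  p2 <- (a + c) / n            # rater 2 (prediction) impaired proportion
  pi_bar <- (p1 + p2) / 2
  p_g <- 2 * pi_bar * (1 - pi_bar)
  if (1 - p_g <= 0) return(list(ac1 = NA_real_, se = NA_real_, ci = c(NA, NA)))
  ac1 <- (p_o - p_g) / (1 - p_g)
  # subject-level linearisation: per-cell agreement indicator and per-item
  # chance term sum_k (r_ik / 2) * (1 - pi_k), k in {impaired, normal}
  cells <- c(a = a, b = b, c = c, d = d)
  agree <- c(1, 0, 0, 1)
  pi_i_imp <- c(1, 0.5, 0.5, 0)   # share of the two raters calling the item impaired
  p_gi <- pi_i_imp * (1 - pi_bar) + (1 - pi_i_imp) * pi_bar
  ac1_i <- (agree - p_g) / (1 - p_g) -
    2 * (1 - ac1) * (p_gi - p_g) / (1 - p_g)
  mean_i <- sum(cells * ac1_i) / n
  var_i <- sum(cells * (ac1_i - mean_i)^2) / (n * (n - 1))
  se <- sqrt(var_i)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(ac1 = ac1, se = se,
       ci = c(max(-1, ac1 - z * se), min(1, ac1 + z * se)))
}

kappa_stats <- function(a, b, c, d, conf = 0.95) {
  n <- a + b + c + d
  p_o <- (a + d) / n
  p1 <- (a + b) / n; p2 <- (a + c) / n
  p_e <- p1 * p2 + (1 - p1) * (1 - p2)
  if (1 - p_e <= 0) return(list(kappa = NA_real_, se = NA_real_, ci = c(NA, NA)))
  kap <- (p_o - p_e) / (1 - p_e)
  se <- sqrt(p_o * (1 - p_o) / (n * (1 - p_e)^2))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(kappa = kap, se = se,
       ci = c(max(-1, kap - z * se), min(1, kap + z * se)))
}

#' Agreement statistics between two classification systems
#'
#' Accuracy, Cohen's kappa (product-of-marginals chance correction), Gwet's
#' AC1 (chance correction robust to marginal imbalance), and the
#' Mann-Whitney AUC of the continuous predictor score against the reference
#' flag, oriented so that lower scores predict impairment (ties count half).
#' Kappa and AC1 CIs use the standard large-sample variance estimators; the
#' AUC CI uses DeLong by default or a seeded percentile bootstrap.
#'
#' @param cm a [cross_tabulate()] confusion matrix.
#' @param ref reference impairment flags used to build `cm`.
#' @param predictor_scores continuous adjusted scores from the predicting
#'   system (for the AUC); may be `NULL` to skip the AUC.
#' @param conf confidence level for all intervals.
#' @param auc_ci `"delong"` (default) or `"bootstrap"`.
#' @param boot_reps,boot_seed bootstrap resamples and seed.
#' @return object of class `agreement_stats`: accuracy, kappa/AC1/AUC with
#'   CIs, and the confusion matrix.
#' @export
agreement_stats <- function(cm, ref = NULL, predictor_scores = NULL,
                            conf = 0.95, auc_ci = c("delong", "bootstrap"),
                            boot_reps = 2000L, boot_seed = 1L) {
  stopifnot(inherits(cm, "confusion_matrix"))
  auc_ci <- match.arg(auc_ci)
  if (!is.null(ref) && length(ref) != cm$n) {
    stop("ref length inconsistent with the confusion matrix")
  }
  acc <- (cm$a + cm$d) / cm$n
  kap <- kappa_stats(cm$a, cm$b, cm$c, cm$d, conf)
  ac1 <- ac1_stats(cm$a, cm$b, cm$c, cm$d, conf)
  if (is.na(kap$kappa) || is.na(ac1$ac1)) {
    warning("degenerate marginals: chance agreement is 1; kappa/AC1 undefined")
  }
  auc <- NA_real_; auc_int <- c(NA_real_, NA_real_)
  if (!is.null(predictor_scores) && !is.null(ref)) {
    auc <- auc_rank(predictor_scores, ref)
    auc_int <- if (auc_ci == "delong") {
      auc_delong_ci(predictor_scores, ref, conf)
    } else {
      auc_boot_ci(predictor_scores, ref, conf, boot_reps, boot_seed)
    }
  }
  structure(list(accuracy = acc,
                 kappa = kap$kappa, kappa_ci = kap$ci,
                 ac1 = ac1$ac1, ac1_ci = ac1$ci,
                 auc = auc, auc_ci = auc_int, auc_ci_method = auc_ci,
                 cm = cm, conf = conf),
            class = "agreement_stats")
}

# ROC curve points: sweep the impairment cutoff over the observed scores.
roc_points <- function(scores, ref) {
  th <- c(-Inf, sort(unique(scores)), Inf)
  do.call(rbind, lapply(th, function(t) {
    pred <- as.integer(scores <= t)
    data.frame(threshold = t,
               tpr = if (sum(ref == 1) > 0) mean(pred[ref == 1] == 1) else NA,
               fpr = if (sum(ref == 0) > 0) mean(pred[ref == 0] == 1) else NA)
  }))
}

#' Compare two normative systems on a patient cohort
#'
#' For each requested test: the reference system supplies the baseline
#' impairment classification, the new system the predicted one; a 2x2
#' confusion matrix, accuracy, AUC (continuous adjusted score of the new
#' system as predictor), Cohen's kappa and Gwet's AC1 are computed, and ROC
#' points exported. Tests missing from either system are skipped with a
#' warning.
#'
#' @param patients a `cohort_table` of patients.
#' @param systems_new,systems_ref named lists of [normative_system()]s, one
#'   per test (names = test names).
#' @param tests test names to compare.
#' @param conf confidence level.
#' @param auc_ci AUC CI method, see [agreement_stats()].
#' @param seed seed used for any bootstrap resampling.
#' @return named list per test: `stats` (`agreement_stats`), `cm`, `roc`.
#' @export
run_comparison <- function(patients, systems_new, systems_ref,
                           tests = names(systems_new), conf = 0.95,
                           auc_ci = "delong", seed = 1L) {
  out <- list()
  for (t in tests) {
    if (is.null(systems_new[[t]]) || is.null(systems_ref[[t]]) ||
        !t %in% names(patients)) {
      warning(sprintf("test '%s' missing from a system or the cohort; skipped", t))
      next
    }
    cls_ref <- classify_cohort(patients, systems_ref[[t]])
    cls_new <- classify_cohort(patients, systems_new[[t]])
    m <- merge(cls_ref[c("id", "impaired")], cls_new[c("id", "impaired", "adjusted")],
               by = "id", suffixes = c("_ref", "_new"))
    cm <- cross_tabulate(m$impaired_ref, m$impaired_new)
    st <- agreement_stats(cm, ref = m$impaired_ref,
                          predictor_scores = m$adjusted, conf = conf,
                          auc_ci = auc_ci,
                          boot_seed = substream_seed(seed, paste0("auc_", t)))
    out[[t]] <- list(stats = st, cm = cm, roc = roc_points(m$adjusted, m$impaired_ref))
  }
  out
}

#' @export
print.agreement_stats <- function(x, ...) {
  fmt_ci <- function(v) sprintf("(%.2f-%.2f)", v[1], v[2])
  cat(sprintf("accuracy %.2f; AUC %.2f %s; kappa %.2f %s; AC1 %.2f %s\n",
              x$accuracy, x$auc, fmt_ci(x$auc_ci), x$kappa, fmt_ci(x$kappa_ci),
              x$ac1, fmt_ci(x$ac1_ci)))
  invisible(x)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, byrow = TRUE,
              dimnames = list(reference = c("impaired", "normal"),
                              predicted = c("impaired", "normal")))
  print(m)
  invisible(x)
}
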