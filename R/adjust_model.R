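#' Covariate transformation specification
#'
#' One candidate functional form for a demographic covariate in the norming
#' regression. Supported forms: `identity`, `cube` (x^3), `sqrt`,
#' `reciprocal` (1/x), and `shifted_log` (log(c - x), natural log), the
#' forms used in published correction equations for these tests.
#'
#' @param covariate one of `"age"`, `"education"`, `"gender"`.
#' @param form one of `"identity"`, `"cube"`, `"sqrt"`, `"reciprocal"`,
#'   `"shifted_log"`.
#' @param offset shift constant c for `shifted_log`; must exceed the maximum
#'   observed covariate value.
#' @return object of class `transform_spec`.
#' @export
transform_spec <- function(covariate, form, offset = NULL) {
  covariate <- match.arg(covariate, c("age", "education", "gender"))
  form <- match.arg(form, c("identity", "cube", "sqrt", "reciprocal", "shifted_log"))
  if (form == "shifted_log" && is.null(offset)) {
    stop("shifted_log requires an offset constant")
  }
  structure(list(covariate = covariate, form = form, offset = offset),
            class = "transform_spec")
}

#' Apply a covariate transformation
#'
#' @param ts a [transform_spec()].
#' @param x numeric covariate values.
#' @return transformed values.
#' @export
apply_transform <- function(ts, x) {
  switch(ts$form,
    identity    = x,
    cube        = x^3,
    sqrt        = { if (any(x < 0)) stop("sqrt requires non-negative covariate"); sqrt(x) },
    reciprocal  = { if (any(x <= 0)) stop("reciprocal requires strictly positive covariate"); 1 / x },
    shifted_log = {
      if (ts$offset <= max(x)) {
        stop(sprintf("shifted_log offset %.2f must exceed the covariate maximum %.2f",
                     ts$offset, max(x)))
      }
      log(ts$offset - x)
    }
  )
}

transform_label <- function(ts) {
  switch(ts$form,
    identity    = ts$covariate,
    cube        = sprintf("%s^3", ts$covariate),
    sqrt        = sprintf("sqrt(%s)", ts$covariate),
    reciprocal  = sprintf("1/%s", ts$covariate),
    shifted_log = sprintf("log(%g-%s)", ts$offset, ts$covariate)
  )
}

# Complexity order used only to break exact R^2 ties (simpler form wins).
form_complexity <- c(identity = 0, sqrt = 1, cube = 2, reciprocal = 3, shifted_log = 4)

#' Descriptive screen of a cohort
#'
#' Per-variable mean, SD, range, adjusted Fisher-Pearson standardised
#' skewness, excess kurtosis, and a normality flag (abnormal iff |skewness|
#' > 1 or |excess kurtosis| > 3), plus the full correlation matrix: Pearson r
#' for continuous pairs; with 0/1-coded gender this is algebraically the
#' point-biserial correlation.
#'
#' @param cohort a `cohort_table`.
#' @return list with `summary` (data.frame) and `corr` (matrix).
#' @export
descriptive_screen <- function(cohort) {
  vars <- setdiff(names(cohort), "id")
  stopifnot(all(vapply(cohort[vars], function(v) sum(!is.na(v)) >= 3, logical(1))))
  smry <- do.call(rbind, lapply(vars, function(v) {
    x <- cohort[[v]][!is.na(cohort[[v]])]
    if (stats::sd(x) == 0) {
      sk <- NA_real_; ku <- NA_real_
    } else {
      sk <- e1071::skewness(x, type = 2)       # adjusted Fisher-Pearson G1
      ku <- e1071::kurtosis(x, type = 2)       # excess kurtosis G2
    }
    data.frame(variable = v, n = length(x), mean = mean(x), sd = stats::sd(x),
               min = min(x), max = max(x), skewness = sk, kurtosis = ku,
               abnormal = is.na(sk) || abs(sk) > 1 || abs(ku) > 3)
  }))
  constant <- vars[vapply(cohort[vars], function(v) stats::sd(v, na.rm = TRUE) == 0, logical(1))]
  if (length(constant) > 0) {
    warning("zero-variance variables, correlations undefined: ",
            paste(constant, collapse = ", "))
  }
  corr <- suppressWarnings(stats::cor(cohort[vars], use = "pairwise.complete.obs"))
  list(summary = smry, corr = corr)
}

#' Default transformation candidate set
#'
#' Age: identity, cube, square root, shifted log (offset = observed max + 4);
#' education: identity, reciprocal; gender: identity only — the forms
#' appearing in published correction equations for these tests, plus identity.
#'
#' @param cohort a `cohort_table` (used to set the shifted-log offset).
#' @return named list of lists of [transform_spec()]s.
#' @export
default_candidates <- function(cohort) {
  list(
    age = list(
      transform_spec("age", "identity"),
      transform_spec("age", "cube"),
      transform_spec("age", "sqrt"),
      transform_spec("age", "shifted_log", offset = max(cohort$age) + 4)
    ),
    education = list(
      transform_spec("education", "identity"),
      transform_spec("education", "reciprocal")
    ),
    gender = list(transform_spec("gender", "identity"))
  )
}

#' Screen candidate transformations by bivariate fit
#'
#' Fits each candidate form in a one-predictor least-squares regression of
#' the raw score and ranks candidates by R^2 within covariate (exact ties go
#' to the simpler form). Candidates invalid on the observed range (e.g. a
#' shifted-log offset not exceeding the maximum) are skipped with a warning.
#'
#' @param cohort a `cohort_table`.
#' @param test test name (column of `cohort`).
#' @param candidates named list of candidate [transform_spec()]s per
#'   covariate; defaults to [default_candidates()].
#' @return list with `ranking` (data.frame: covariate, form, r_squared, rank)
#'   and `best` (named list of the winning `transform_spec` per covariate).
#' @export
screen_transforms <- function(cohort, test, candidates = default_candidates(cohort)) {
  stopifnot(test %in% names(cohort), length(candidates) > 0)
  y <- cohort[[test]]
  rows <- list(); specs <- list()
  for (cov in names(candidates)) {
    for (ts in candidates[[cov]]) {
      g <- tryCatch(apply_transform(ts, cohort[[cov]]), error = function(e) {
        warning(sprintf("skipping %s: %s", transform_label(ts), conditionMessage(e)))
        NULL
      })
      if (is.null(g)) next
      fit <- stats::lm(y ~ g)
      r2 <- summary(fit)$r.squared
      rows[[length(rows) + 1L]] <- data.frame(
        covariate = cov, form = ts$form, label = transform_label(ts),
        r_squared = r2, complexity = form_complexity[[ts$form]])
      specs[[length(specs) + 1L]] <- ts
    }
  }
  ranking <- do.call(rbind, rows)
  ord <- order(ranking$covariate, -ranking$r_squared, ranking$complexity)
  ranking <- ranking[ord, ]
  ranking$rank <- stats::ave(seq_len(nrow(ranking)), ranking$covariate, FUN = seq_along)
  best <- lapply(split(seq_along(specs)[ord], ranking$covariate),
                 function(i) specs[[i[1]]])
  rownames(ranking) <- NULL
  list(ranking = ranking[, c("covariate", "form", "label", "r_squared", "rank")],
       best = best)
}

#' Fit the demographic adjustment equation by stepwise regression
#'
#' Bidirectional p-value stepwise least squares over the (at most three)
#' best-transformed covariates: a covariate enters when its partial t-test
#' p-value is below `alpha_enter` and leaves when it rises above
#' `alpha_remove`. Retained covariates and the outcome are then expressed as
#' deviations from their sample means and refit; the resulting coefficients
#' are stored sign-reversed together with the centering constants, so that
#' adding the correction term removes the demographic variation from a raw
#' score. If no covariate enters, the equation is empty (adjusted = raw).
#'
#' @param cohort a `cohort_table`, complete for `test` and the covariates.
#' @param test test name.
#' @param best_forms named list of [transform_spec()]s per covariate (e.g.
#'   `screen_transforms(...)$best`).
#' @param alpha_enter,alpha_remove stepwise entry/removal p-value thresholds.
#' @return object of class `adjustment_equation`: `test`, `terms` (each with
#'   `transform`, `beta` sign-reversed, `center`, observed covariate `range`),
#'   diagnostics (`r_squared`, `adj_r_squared`, `rmse`), and fitting `n`.
#' @export
stepwise_fit <- function(cohort, test, best_forms,
                         alpha_enter = 0.05, alpha_remove = 0.05) {
  keep <- stats::complete.cases(cohort[c(test, names(best_forms))])
  dat <- cohort[keep, ]
  y <- dat[[test]]
  G <- vapply(best_forms, function(ts) apply_transform(ts, dat[[ts$covariate]]),
              numeric(nrow(dat)))
  G <- as.matrix(G)
  colnames(G) <- names(best_forms)

  pvals_of <- function(members) {
    fit <- stats::lm(y ~ G[, members, drop = FALSE])
    p <- summary(fit)$coefficients[-1, 4]
    stats::setNames(p, members)
  }

  included <- character(0)
  excluded <- names(best_forms)
  repeat {
    changed <- FALSE
    if (length(excluded) > 0) {
      p_add <- vapply(excluded, function(v) {
        utils::tail(pvals_of(c(included, v)), 1)
      }, numeric(1))
      if (min(p_add) < alpha_enter) {
        v <- excluded[which.min(p_add)]
        included <- c(included, v)
        excluded <- setdiff(excluded, v)
        changed <- TRUE
      }
    }
    if (length(included) > 1) {
      p_cur <- pvals_of(included)
      if (max(p_cur) > alpha_remove) {
        v <- included[which.max(p_cur)]
        included <- setdiff(included, v)
        excluded <- c(excluded, v)
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  if (length(included) == 0) {
    message(sprintf("'%s': no covariate entered; adjusted score = raw score", test))
    eq <- structure(list(test = test, terms = list(),
                         diagnostics = list(r_squared = 0, adj_r_squared = 0,
                                            rmse = stats::sd(y)),
                         n = length(y)),
                    class = "adjustment_equation")
    return(eq)
  }

  # mean-deviation refit: centering leaves slopes unchanged but makes the
  # correction vanish exactly at the sample means of the transformed covariates
  Gc <- scale(G[, included, drop = FALSE], center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  fit <- stats::lm(yc ~ Gc - 1)
  betas <- stats::coef(fit)
  full <- stats::lm(y ~ G[, included, drop = FALSE])
  s <- summary(full)
  rmse <- sqrt(mean(stats::residuals(full)^2))

  terms <- lapply(seq_along(included), function(i) {
    v <- included[i]
    ts <- best_forms[[v]]
    list(transform = ts,
         beta = -unname(betas[i]),              # sign-reversed correction slope
         center = mean(G[, v]),
         range = range(dat[[ts$covariate]]))
  })
  names(terms) <- included
  structure(list(test = test, terms = terms,
                 diagnostics = list(r_squared = s$r.squared,
                                    adj_r_squared = s$adj.r.squared,
                                    rmse = rmse),
                 n = length(y)),
            class = "adjustment_equation")
}

#' Construct an adjustment equation from known coefficients
#'
#' Builds an `adjustment_equation` directly from published (or otherwise
#' known) sign-reversed coefficients and centering constants, bypassing the
#' fitting path. Used for the shipped published equations.
#'
#' @param test test name.
#' @param terms list of `list(transform =, beta =, center =, range =)` items.
#' @param diagnostics optional list (`r_squared`, `adj_r_squared`, `rmse`).
#' @param n fitting-sample size, if known.
#' @return `adjustment_equation`.
#' @export
adjustment_equation <- function(test, terms, diagnostics = NULL, n = NA_integer_) {
  for (tm in terms) {
    stopifnot(inherits(tm$transform, "transform_spec"),
              is.numeric(tm$beta), is.numeric(tm$center))
  }
  names(terms) <- vapply(terms, function(tm) tm$transform$covariate, character(1))
  if (anyDuplicated(names(terms))) stop("each covariate may appear at most once")
  structure(list(test = test, terms = terms, diagnostics = diagnostics, n = n),
            class = "adjustment_equation")
}

# Correction term of an equation at given demographics (vectorised).
correction_term <- function(eq, age, education = NULL, gender = NULL) {
  demo <- list(age = age, education = education, gender = gender)
  corr <- 0
  for (tm in eq$terms) {
    cov <- tm$transform$covariate
    x <- demo[[cov]]
    if (is.null(x) || anyNA(x)) {
      stop(sprintf("demographic '%s' required by the '%s' equation is missing", cov, eq$test))
    }
    if (!is.null(tm$range) && !all(is.na(tm$range)) &&
        any(x < tm$range[1] | x > tm$range[2])) {
      warning(sprintf("'%s' outside the fitting range [%g, %g]; extrapolating",
                      cov, tm$range[1], tm$range[2]))
    }
    corr <- corr + tm$beta * (apply_transform(tm$transform, x) - tm$center)
  }
  corr
}

#' Adjust a raw score for demographics
#'
#' adjusted = raw + sum over terms of beta * (g(covariate) - centering
#' constant). The correction is exactly zero when every transformed covariate
#' sits at its centering constant. The unrounded value is returned; display
#' rounding is separate.
#'
#' @param eq an `adjustment_equation`.
#' @param raw raw score(s).
#' @param age,education,gender demographics (vectorised; gender 0 = male,
#'   1 = female).
#' @return adjusted score(s), unrounded.
#' @export
adjust_score <- function(eq, raw, age, education = NULL, gender = NULL) {
  raw + correction_term(eq, age, education, gender)
}

#' Adjust every row of a cohort
#'
#' @param eq an `adjustment_equation`.
#' @param cohort a `cohort_table` containing the test column.
#' @return numeric vector of adjusted scores, one per row.
#' @export
adjust_cohort <- function(eq, cohort) {
  adjust_score(eq, cohort[[eq$test]], cohort$age, cohort$education, cohort$gender)
}

#' Tabulate the clinical correction grid
#'
#' Evaluates the correction term on the standard age lattice, crossed with
#' the education lattice when education is in the equation and stratified by
#' gender when gender is, rounded half-away-from-zero to 2 decimals — the
#' grid a clinician adds to a raw score.
#'
#' @param eq an `adjustment_equation`.
#' @param ages age lattice.
#' @param educations education lattice (used only when education is a term).
#' @return data.frame (`correction_grid`): `test`, `gender` (`m`/`f` or `""`),
#'   `education` (NA when absent), `age`, `correction`.
#' @export
build_grid <- function(eq,
                       ages = c(18, 22, 27, 32, 37, 42, 47, 52, 57, 62, 67, 72, 77, 82, 84),
                       educations = c(5, 8, 13, 16, 18, 21)) {
  has_edu <- "education" %in% names(eq$terms)
  has_gen <- "gender" %in% names(eq$terms)
  edus <- if (has_edu) educations else NA_real_
  gens <- if (has_gen) c(1, 0) else NA_integer_   # female rows first, as printed
  cells <- expand.grid(age = ages, education = edus, gender = gens,
                       KEEP.OUT.ATTRS = FALSE)
  corr <- suppressWarnings(correction_term(
    eq, cells$age,
    education = if (has_edu) cells$education else NULL,
    gender = if (has_gen) cells$gender else NULL))
  if (length(eq$terms) == 0) corr <- rep(0, nrow(cells))
  out <- data.frame(
    test = eq$test,
    gender = if (has_gen) c("m", "f")[cells$gender + 1L] else "",
    education = cells$education,
    age = cells$age,
    correction = round_half_away(corr, 2))
  class(out) <- c("correction_grid", "data.frame")
  out
}

#' Serialise / deserialise an adjustment equation as JSON
#'
#' @param eq an `adjustment_equation`.
#' @param path file path.
#' @return `read_equation_json` returns the equation; the writer returns
#'   `path` invisibly.
#' @export
write_equation_json <- function(eq, path) {
  obj <- list(
    test = eq$test,
    terms = lapply(unname(eq$terms), function(tm) list(
      covariate = tm$transform$covariate,
      form = tm$transform$form,
      offset = tm$transform$offset,
      beta = tm$beta, center = tm$center, range = tm$range)),
    diagnostics = eq$diagnostics, n = eq$n)
  write_json_file(obj, path)
  invisible(path)
}

#' @rdname write_equation_json
#' @export
read_equation_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  terms <- lapply(obj$terms, function(tm) list(
    transform = transform_spec(tm$covariate, tm$form, offset = tm$offset),
    beta = tm$beta, center = tm$center,
    range = if (is.null(tm$range)) NULL else unlist(tm$range)))
  adjustment_equation(obj$test, terms, diagnostics = obj$diagnostics,
                      n = if (is.null(obj$n)) NA_integer_ else obj$n)
}

#' @export
print.adjustment_equation <- function(x, ...) {
  cat(sprintf("Adjustment equation for '%s' (n = %s)\n", x$test, x$n))
  if (length(x$terms) == 0) {
    cat("  adjusted score = raw score (no demographic term retained)\n")
  } else {
    parts <- vapply(x$terms, function(tm)
      sprintf("%+g*(%s - %g)", tm$beta, transform_label(tm$transform), tm$center),
      character(1))
    cat("  adjusted score = raw score ", paste(parts, collapse = " "), "\n", sep = "")
  }
  if (!is.null(x$diagnostics)) {
    cat(sprintf("  R^2 = %.3f, adj R^2 = %.3f, RMSE = %.3f\n",
                x$diagnostics$r_squared, x$diagnostics$adj_r_squared,
                x$diagnostics$rmse))
  }
  invisible(x)
}
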