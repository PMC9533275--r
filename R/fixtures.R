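#' Published adjustment equations for the five tests
#'
#' The demographic correction equations published with the remote-setting
#' norms, transcribed with their sign-reversed coefficients and centering
#' constants (gender coded 0 = male, 1 = female; natural log in the shifted
#' log):
#' \itemize{
#'   \item DSF: raw + 0.0000017*(Age^3 - 128919) + 0.472*(Gender - 0.618)
#'   \item DSB: raw + 0.02*(Age - 43.62)
#'   \item RAVL-I: raw - 6.72*(log(88 - Age) - 3.769)
#'     + 106.06*(1/Education - 0.0697) - 4.214*(Gender - 0.6)
#'   \item RAVL-D: raw + 0.0481*(Age - 40.8)
#'     + 28.678*(1/Education - 0.0697) - 1.635*(Gender - 0.6)
#'   \item VPAL: raw + 1.357*(sqrt(Age) - 6.514)
#'     + 35.603*(1/Education - 0.0733) - 1.106*(Gender - 0.6)
#' }
#'
#' @return named list of `adjustment_equation`s.
#' @export
published_equations <- function() {
  term <- function(cov, form, beta, center, offset = NULL) {
    list(transform = transform_spec(cov, form, offset = offset),
         beta = beta, center = center, range = NULL)
  }
  list(
    dsf = adjustment_equation("dsf", list(
      term("age", "cube", 0.0000017, 128919),
      term("gender", "identity", 0.472, 0.618)), n = 199L),
    dsb = adjustment_equation("dsb", list(
      term("age", "identity", 0.02, 43.62)), n = 199L),
    ravl_i = adjustment_equation("ravl_i", list(
      term("age", "shifted_log", -6.72, 3.769, offset = 88),
      term("education", "reciprocal", 106.06, 0.0697),
      term("gender", "identity", -4.214, 0.6)), n = 180L),
    ravl_d = adjustment_equation("ravl_d", list(
      term("age", "identity", 0.0481, 40.8),
      term("education", "reciprocal", 28.678, 0.0697),
      term("gender", "identity", -1.635, 0.6)), n = 180L),
    vpal = adjustment_equation("vpal", list(
      term("age", "sqrt", 1.357, 6.514),
      term("education", "reciprocal", 35.603, 0.0733),
      term("gender", "identity", -1.106, 0.6)), n = 204L)
  )
}

#' Published correction grid (long form)
#'
#' The printed clinical correction grid shipped as a plain-text fixture:
#' corrections on the age lattice 18..84, crossed with education rows for
#' the tests whose equations include education, stratified by gender where
#' gender enters. Values are exactly as printed (some cells at 1 decimal).
#'
#' @return data.frame: `test`, `gender` (`m`/`f`/`""`), `education`, `age`,
#'   `correction`.
#' @export
published_grid <- function() {
  path <- system.file("extdata", "published_correction_grid.csv",
                      package = "memnorms", mustWork = TRUE)
  wide <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(gender = "character"))
  ages <- as.numeric(sub("^a", "", names(wide)[-(1:3)]))
  long <- do.call(rbind, lapply(seq_len(nrow(wide)), function(i) {
    vals <- as.numeric(wide[i, -(1:3)])
    # printed decimal places, for per-cell comparison tolerance
    dp <- vapply(as.character(unlist(wide[i, -(1:3)])), function(s) {
      if (grepl("\\.", s)) nchar(sub("^[^.]*\\.", "", s)) else 0L
    }, integer(1))
    data.frame(test = wide$test[i], gender = wide$gender[i],
               education = wide$education[i], age = ages,
               correction = vals, printed_dp = dp, row.names = NULL)
  }))
  long
}

#' Published Equivalent Score cutoffs and tolerance limits
#'
#' The printed ES bands (upper cutoffs c0..c3) and outer/inner tolerance
#' limits per test. These are plausibility fixtures, not recomputable
#' targets (the underlying participant data are unavailable). The printed
#' VPAL row is numerically identical to the DSF row — almost certainly a
#' typesetting duplication — and is flagged `suspect_duplicate`; it must not
#' be treated as ground truth.
#'
#' @return data.frame: `test`, `c0`..`c3`, `otl`, `itl`, `suspect_duplicate`.
#' @export
published_es_table <- function() {
  data.frame(
    test = c("dsf", "dsb", "ravl_i", "ravl_d", "vpal"),
    c0 = c(4.02, 2.79, 35.62, 6.24, 4.02),
    c1 = c(5.52, 3.79, 47.19, 9.99, 5.52),
    c2 = c(5.99, 4.57, 51.26, 11.23, 5.99),
    c3 = c(6.19, 4.81, 54.34, 12.15, 6.19),
    otl = c(4.02, 2.79, 35.62, 6.24, 4.02),
    itl = c(4.97, 3.45, 43.79, 8.62, 4.97),
    suspect_duplicate = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Validate the shipped fixtures
#'
#' Recomputes every published correction-grid cell from the published
#' equations and reports the maximum absolute deviation from the printed
#' value. A cell fails when its deviation exceeds half a unit in the last
#' printed decimal place plus 0.005 rounding slack at 2 decimals.
#'
#' @param equations named list of equations (default [published_equations()]).
#' @param grid printed grid (default [published_grid()]).
#' @return list: `max_deviation`, `n_cells`, `failures` (data.frame of
#'   offending cells, empty when all pass), `ok`.
#' @export
validate_fixtures <- function(equations = published_equations(),
                              grid = published_grid()) {
  computed <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    eq <- equations[[grid$test[i]]]
    g <- if (grid$gender[i] == "") NULL else as.integer(grid$gender[i] == "f")
    e <- if (is.na(grid$education[i])) NULL else grid$education[i]
    computed[i] <- correction_term(eq, grid$age[i], education = e, gender = g)
  }
  dev <- abs(computed - grid$correction)
  # printed 2-dp cells must agree to 0.005; coarser cells to their half-ulp
  tol <- pmax(0.005, 0.5 * 10^(-grid$printed_dp) + 1e-9)
  bad <- dev > tol
  failures <- cbind(grid[bad, c("test", "gender", "education", "age", "correction")],
                    computed = computed[bad], deviation = dev[bad])
  list(max_deviation = max(dev), n_cells = nrow(grid),
       failures = failures, ok = !any(bad))
}

#' Synthetic stand-in reference normative systems
#'
#' The comparison of the remote norms against norms developed decades
#' earlier in face-to-face settings requires those older systems' adjustment
#' equations and cutoffs, which are not reprinted here. These stand-ins are
#' SYNTHETIC: simple age/education corrections of the same functional family
#' with deliberately different coefficients, and impairment cutoffs placed
#' near plausible older ES-0 limits. They exercise the comparison machinery;
#' they are not the historical norms.
#'
#' @return named list of [normative_system()]s per test.
#' @export
standin_reference_systems <- function() {
  term <- function(cov, form, beta, center, offset = NULL) {
    list(transform = transform_spec(cov, form, offset = offset),
         beta = beta, center = center, range = NULL)
  }
  eqs <- list(
    dsf = adjustment_equation("dsf", list(
      term("age", "identity", 0.015, 45))),
    dsb = adjustment_equation("dsb", list(
      term("age", "identity", 0.025, 45),
      term("education", "identity", -0.04, 11))),
    ravl_i = adjustment_equation("ravl_i", list(
      term("age", "identity", 0.25, 45),
      term("education", "identity", -0.8, 11))),
    ravl_d = adjustment_equation("ravl_d", list(
      term("age", "identity", 0.06, 45),
      term("education", "identity", -0.15, 11))),
    vpal = adjustment_equation("vpal", list(
      term("age", "identity", 0.10, 45),
      term("education", "identity", -0.25, 11)))
  )
  cutoffs <- c(dsf = 3.75, dsb = 2.65, ravl_i = 28.53, ravl_d = 4.69,
               vpal = 6.0)
  lapply(stats::setNames(names(eqs), names(eqs)), function(t) {
    normative_system(paste0("standin_", t), eqs[[t]], cutoff = cutoffs[[t]])
  })
}

#' Normative systems of the present (remote) norms
#'
#' Builds one [normative_system()] per test from the published equations and
#' the published ES-0 cutoffs (outer tolerance limits).
#'
#' @return named list of `normative_system`s.
#' @export
published_systems <- function() {
  eqs <- published_equations()
  es <- published_es_table()
  lapply(stats::setNames(es$test, es$test), function(t) {
    normative_system(paste0("remote_", t), eqs[[t]],
                     cutoff = es$otl[es$test == t])
  })
}
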