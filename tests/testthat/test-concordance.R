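test_that("cross tabulation counts the four cells correctly", {
  cm <- cross_tabulate(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(c(cm$a, cm$b, cm$c, cm$d), c(1, 1, 1, 1))
  same <- cross_tabulate(rep(c(1, 0), each = 25), rep(c(1, 0), each = 25))
  expect_equal(c(same$b, same$c), c(0, 0))
  comp <- cross_tabulate(c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_equal(c(comp$a, comp$d), c(0, 0))
  expect_error(cross_tabulate(c(1, 0), c(1, 0, 1)), "equal length")
})

test_that("perfect, chance and mixed tables give the expected agreement", {
  fl <- flags_from_table(50, 0, 0, 50)
  scores <- c(rep(0, 50), rep(1, 50))        # separable, low = impaired
  st <- agreement_stats(cross_tabulate(fl$ref, fl$pred), ref = fl$ref,
                        predictor_scores = scores)
  expect_equal(st$accuracy, 1)
  expect_equal(st$kappa, 1)
  expect_equal(st$ac1, 1)
  expect_equal(st$auc, 1)

  st2 <- agreement_stats(cross_tabulate(
    flags_from_table(25, 25, 25, 25)$ref, flags_from_table(25, 25, 25, 25)$pred))
  expect_equal(st2$kappa, 0)

  fl3 <- flags_from_table(45, 5, 15, 35)
  st3 <- agreement_stats(cross_tabulate(fl3$ref, fl3$pred))
  expect_equal(st3$accuracy, 0.80)
  expect_equal(st3$kappa, 0.60, tolerance = 1e-12)
  expect_equal(st3$ac1, (0.80 - 0.495) / (1 - 0.495), tolerance = 1e-12)
  expect_equal(round(st3$ac1, 3), 0.604)
})

test_that("degenerate marginals yield missing kappa/AC1 with a warning", {
  fl <- flags_from_table(40, 0, 0, 0)
  expect_warning(st <- agreement_stats(cross_tabulate(fl$ref, fl$pred)),
                 "degenerate")
  expect_true(is.na(st$kappa))
})

test_that("kappa and AC1 match direct-formula oracles on all tables up to n = 40", {
  tabs <- expand.grid(a = 0:40, b = 0:40, c = 0:40, d = 0:40)
  tabs <- tabs[rowSums(tabs) >= 2 & rowSums(tabs) <= 40, ]
  got_k <- mapply(function(a, b, c, d) memnorms:::kappa_stats(a, b, c, d)$kappa,
                  tabs$a, tabs$b, tabs$c, tabs$d)
  got_g <- mapply(function(a, b, c, d) memnorms:::ac1_stats(a, b, c, d)$ac1,
                  tabs$a, tabs$b, tabs$c, tabs$d)
  exp_k <- mapply(oracle_kappa, tabs$a, tabs$b, tabs$c, tabs$d)
  exp_g <- mapply(oracle_ac1, tabs$a, tabs$b, tabs$c, tabs$d)
  expect_equal(got_k, exp_k, tolerance = 1e-12)
  expect_equal(got_g, exp_g, tolerance = 1e-12)
})

test_that("AC1 exceeds kappa under imbalanced marginals at fixed agreement", {
  fl <- flags_from_table(90, 4, 4, 2)        # strong imbalance
  st <- agreement_stats(cross_tabulate(fl$ref, fl$pred))
  expect_gt(st$ac1, st$kappa)
})

test_that("the rank AUC equals exhaustive pair counting, ties counted half", {
  # first two rows impaired: one discordant pair (0.4 vs 0.35) of four
  scores <- c(0.1, 0.4, 0.35, 0.8)
  ref <- c(1, 1, 0, 0)
  expect_equal(memnorms:::auc_rank(scores, ref), 0.75)
  expect_equal(oracle_auc(scores, ref), 0.75)
  # impaired strictly lowest -> AUC 1
  expect_equal(memnorms:::auc_rank(scores, c(1, 0, 1, 0)), 1)
  set.seed(31)
  for (i in 1:50) {
    n <- sample(4:40, 1)
    ref_i <- rbinom(n, 1, 0.4)
    if (length(unique(ref_i)) < 2) next
    s <- sample(seq(0, 5, by = 0.5), n, replace = TRUE)  # ties likely
    expect_equal(memnorms:::auc_rank(s, ref_i), oracle_auc(s, ref_i))
  }
})

test_that("AUC is invariant to strictly monotone score transforms", {
  set.seed(12)
  s <- rnorm(60)
  ref <- rbinom(60, 1, 0.5)
  a0 <- memnorms:::auc_rank(s, ref)
  expect_equal(memnorms:::auc_rank(exp(s), ref), a0)
  expect_equal(memnorms:::auc_rank(3 * s - 7, ref), a0)
})

test_that("DeLong intervals agree with the pROC reference implementation", {
  set.seed(21)
  scores <- c(rnorm(40, 0), rnorm(60, 1.2))
  ref <- c(rep(1, 40), rep(0, 60))
  st <- agreement_stats(cross_tabulate(ref, as.integer(scores < 0.5)),
                        ref = ref, predictor_scores = scores)
  ro <- pROC::roc(ref, scores, direction = ">", levels = c(0, 1), quiet = TRUE)
  ci <- as.numeric(pROC::ci.auc(ro, method = "delong"))
  expect_equal(st$auc, as.numeric(pROC::auc(ro)), tolerance = 1e-12)
  expect_equal(st$auc_ci[1], ci[1], tolerance = 1e-6)
  expect_equal(st$auc_ci[2], ci[3], tolerance = 1e-6)
})

test_that("classification respects the cutoff semantics", {
  pp <- simulate_patient_cohort(patient_spec(seed = 4))
  sys <- published_systems()$dsb
  # vacuous rule: cutoff -Inf classifies nobody impaired
  sys_none <- normative_system("none", sys$equation, cutoff = -Inf)
  expect_equal(sum(classify_cohort(pp, sys_none)$impaired), 0)
  # scores centred at the cutoff split about half/half
  set.seed(9)
  ch <- data.frame(id = 1:400, age = rep(43.62, 400),
                   dsb = rnorm(400, mean = sys$cutoff, sd = 0.3))
  class(ch) <- c("cohort_table", "data.frame")
  frac <- mean(classify_cohort(ch, sys)$impaired)
  expect_lt(abs(frac - 0.5), 0.1)
})

test_that("run_comparison is reproducible and self-comparison is perfect", {
  pp <- simulate_patient_cohort(patient_spec(seed = 6))
  new_sys <- published_systems()
  out <- run_comparison(pp, new_sys, new_sys, tests = c("dsf", "ravl_i"))
  for (t in names(out)) {
    expect_equal(out[[t]]$stats$accuracy, 1)
    expect_equal(out[[t]]$stats$kappa, 1)
  }
  ref_sys <- standin_reference_systems()
  a <- run_comparison(pp, new_sys, ref_sys, seed = 11)
  b <- run_comparison(pp, new_sys, ref_sys, seed = 11)
  expect_identical(a, b)
  # orientation convention keeps every AUC at or above chance
  expect_true(all(vapply(a, function(x) x$stats$auc, numeric(1)) >= 0.5))
})

test_that("a vacuously strict new system degrades accuracy to the reference-normal rate", {
  pp <- simulate_patient_cohort(patient_spec(seed = 8))
  ref_sys <- standin_reference_systems()
  lax <- published_systems()
  lax$ravl_d <- normative_system("lax", lax$ravl_d$equation, cutoff = -1e9)
  out <- run_comparison(pp, lax, ref_sys, tests = "ravl_d")
  ref_normal <- 1 - mean(classify_cohort(pp, ref_sys$ravl_d)$impaired)
  expect_equal(out$ravl_d$stats$accuracy, ref_normal)
})

test_that("tests missing from a system are skipped with a warning", {
  pp <- simulate_patient_cohort(patient_spec(seed = 10))
  new_sys <- published_systems()
  ref_sys <- standin_reference_systems()
  expect_warning(out <- run_comparison(pp, new_sys, ref_sys,
                                       tests = c("dsf", "nonexistent")),
                 "skipped")
  expect_named(out, "dsf")
})
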