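test_that("descriptive screen flags non-normal and degenerate variables", {
  ch <- make_demo_cohort(50, seed = 1)
  ch$dsf <- rep(5, 50)                       # constant column
  expect_warning(scr <- descriptive_screen(ch), "zero-variance")
  row <- scr$summary[scr$summary$variable == "dsf", ]
  expect_true(is.na(row$skewness))
  expect_true(row$abnormal)
  expect_true(all(is.na(scr$corr["dsf", setdiff(colnames(scr$corr), "dsf")])))

  # symmetric two-point sample has zero skewness, not flagged on skewness
  sym <- data.frame(id = 1:4, age = c(-1, -1, 1, 1))
  class(sym) <- c("cohort_table", "data.frame")
  s2 <- descriptive_screen(sym)
  expect_equal(s2$summary$skewness[s2$summary$variable == "age"], 0)
})

test_that("gender point-biserial correlation matches the calibrated target", {
  ch <- simulate_healthy_cohort(healthy_spec(seed = 1))
  scr <- descriptive_screen(ch)
  expect_lt(abs(scr$corr["gender", "ravl_d"] - 0.32), 0.15)
  # point-biserial is algebraically Pearson on the 0/1 coding
  expect_equal(scr$corr["gender", "ravl_d"], cor(ch$gender, ch$ravl_d))
})

test_that("transform screening recovers an exact generative form with R^2 = 1", {
  ch <- make_demo_cohort(200, seed = 2)
  ch$score <- 2 + 3e-5 * ch$age^3            # exact cube relationship, no noise
  scr <- suppressWarnings(screen_transforms(ch, "score"))
  age_rank <- scr$ranking[scr$ranking$covariate == "age", ]
  expect_equal(age_rank$form[age_rank$rank == 1], "cube")
  expect_equal(age_rank$r_squared[age_rank$rank == 1], 1)
  expect_equal(scr$best$age$form, "cube")
})

test_that("screening under the null keeps R^2 at noise level", {
  ch <- make_demo_cohort(500, seed = 3)
  set.seed(99)
  ch$score <- rnorm(500)                     # independent of all demographics
  scr <- screen_transforms(ch, "score")
  edu <- scr$ranking[scr$ranking$covariate == "education", ]
  expect_true(all(edu$r_squared <= 0.02))
})

test_that("a shifted-log generative age effect outranks the identity form", {
  wins <- vapply(1:20, function(s) {
    ch <- make_demo_cohort(300, seed = 100 + s)
    set.seed(200 + s)
    ch$score <- 80 - 6.72 * log(88 - ch$age) + rnorm(300, sd = 2)
    rk <- screen_transforms(ch, "score")$ranking
    rk <- rk[rk$covariate == "age", ]
    rk$rank[rk$form == "shifted_log"] < rk$rank[rk$form == "identity"]
  }, logical(1))
  expect_gte(mean(wins), 0.90)
})

test_that("invalid shifted-log candidates are skipped with a warning", {
  ch <- make_demo_cohort(100, seed = 4)
  ch$score <- ch$age + rnorm(100)
  cands <- list(age = list(transform_spec("age", "identity"),
                           transform_spec("age", "shifted_log", offset = 50)))
  expect_warning(scr <- screen_transforms(ch, "score", cands), "skipping")
  expect_false("shifted_log" %in% scr$ranking$form)
})

test_that("stepwise fit recovers a known age slope and rejects null covariates", {
  # generative model mirrors the span-backward equation: a pure age slope
  recovered <- vapply(1:20, function(s) {
    ch <- make_demo_cohort(2000, seed = 300 + s)
    set.seed(400 + s)
    ch$score <- 5 - 0.02 * (ch$age - mean(ch$age)) + rnorm(2000, sd = 0.5)
    forms <- list(age = transform_spec("age", "identity"),
                  education = transform_spec("education", "identity"),
                  gender = transform_spec("gender", "identity"))
    eq <- stepwise_fit(ch, "score", forms)
    ok_beta <- "age" %in% names(eq$terms) &&
      abs(eq$terms$age$beta - 0.02) < 0.005
    c(ok_beta && length(eq$terms) == 1, ok_beta)
  }, logical(2))
  expect_gte(mean(recovered[2, ]), 0.95)     # sign-reversed slope recovered
  expect_gte(mean(recovered[1, ]), 0.80)     # and no spurious extra term
})

test_that("stepwise fit on pure noise usually returns an empty equation", {
  empties <- vapply(1:20, function(s) {
    ch <- make_demo_cohort(500, seed = 500 + s)
    set.seed(600 + s)
    ch$score <- rnorm(500)
    forms <- list(age = transform_spec("age", "identity"),
                  education = transform_spec("education", "identity"),
                  gender = transform_spec("gender", "identity"))
    eq <- suppressMessages(stepwise_fit(ch, "score", forms))
    length(eq$terms) == 0
  }, logical(1))
  # per-covariate entry at alpha = 0.05 over three covariates implies an
  # empty equation in about 0.95^3 = 86% of draws
  expect_gte(mean(empties), 14 / 20)
})

test_that("an exact linear outcome gives one term, R^2 = 1 and RMSE 0", {
  ch <- make_demo_cohort(100, seed = 5)
  ch$score <- ch$age
  forms <- list(age = transform_spec("age", "identity"),
                education = transform_spec("education", "identity"))
  eq <- suppressWarnings(stepwise_fit(ch, "score", forms))
  expect_equal(names(eq$terms), "age")
  expect_equal(eq$diagnostics$r_squared, 1)
  expect_equal(eq$diagnostics$rmse, 0, tolerance = 1e-8)
  expect_equal(eq$terms$age$beta, -1, tolerance = 1e-10)
})

test_that("published equations adjust scores to the printed values", {
  eqs <- published_equations()
  # correction vanishes exactly at the centering constant
  expect_identical(adjust_score(eqs$dsb, 5, age = 43.62), 5)
  expect_equal(round_half_away(adjust_score(eqs$dsb, 5, age = 18), 2), 4.49)
  expect_equal(round_half_away(
    adjust_score(eqs$ravl_i, 50, age = 18, education = 5, gender = 1), 2),
    58.91)
})

test_that("adjustment is exact at centering constants and mean-invariant", {
  ch <- simulate_healthy_cohort(healthy_spec(seed = 6))
  scr <- screen_transforms(ch, "ravl_d")
  eq <- stepwise_fit(ch, "ravl_d", scr$best)
  # centering identity: raw returned exactly at the transformed-covariate means
  if (length(eq$terms) > 0) {
    demo <- list(age = NA, education = NA, gender = NA)
    for (tm in eq$terms) {
      cov <- tm$transform$covariate
      g_inv <- switch(tm$transform$form,
        identity = tm$center, cube = tm$center^(1/3), sqrt = tm$center^2,
        reciprocal = 1 / tm$center, shifted_log = tm$transform$offset - exp(tm$center))
      demo[[cov]] <- g_inv
    }
    got <- suppressWarnings(adjust_score(eq, 10, demo$age, demo$education, demo$gender))
    expect_equal(got, 10, tolerance = 1e-9)
  }
  # cohort mean of adjusted equals cohort mean of raw under the own fit
  adj <- adjust_cohort(eq, ch)
  expect_equal(mean(adj), mean(ch$ravl_d), tolerance = 1e-9)
})

test_that("coefficient estimates converge to truth as n grows", {
  err_at <- function(n) {
    ch <- make_demo_cohort(n, seed = 700 + n)
    set.seed(800 + n)
    ch$score <- 12 - 0.05 * ch$age + 0.2 * ch$education + rnorm(n, sd = 1.5)
    forms <- list(age = transform_spec("age", "identity"),
                  education = transform_spec("education", "identity"))
    eq <- stepwise_fit(ch, "score", forms)
    abs(eq$terms$age$beta - 0.05) + abs(eq$terms$education$beta - (-0.2))
  }
  expect_lt(err_at(2000), err_at(200))
  expect_lt(err_at(2000), 0.01)
})

test_that("missing demographics raise an error and extrapolation warns", {
  eqs <- published_equations()
  expect_error(adjust_score(eqs$ravl_i, 50, age = 30), "education")
  ch <- make_demo_cohort(100, seed = 8)
  ch$score <- 5 + 0.1 * ch$age + rnorm(100, sd = 0.1)
  eq <- stepwise_fit(ch, "score", list(age = transform_spec("age", "identity")))
  expect_warning(adjust_score(eq, 5, age = 110), "extrapolating")
})

test_that("correction grids reproduce every printed cell", {
  v <- validate_fixtures()
  expect_true(v$ok)
  expect_equal(nrow(v$failures), 0)
  # spot values straight from build_grid
  eqs <- published_equations()
  g_dsf <- build_grid(eqs$dsf)
  expect_equal(g_dsf$correction[g_dsf$gender == "m" & g_dsf$age == 18], -0.50)
  g_vpal <- build_grid(eqs$vpal)
  expect_equal(g_vpal$correction[g_vpal$gender == "f" & g_vpal$education == 5 &
                                 g_vpal$age == 18], 0.99)
  # corrections monotone along age for a monotone age transform
  for (edu in unique(g_vpal$education)) {
    for (gen in c("m", "f")) {
      col <- g_vpal$correction[g_vpal$education == edu & g_vpal$gender == gen]
      expect_true(all(diff(col) >= 0))
    }
  }
})

test_that("an empty equation yields an all-zero grid", {
  eq <- adjustment_equation("dsb", list())
  g <- build_grid(eq)
  expect_true(all(g$correction == 0))
  expect_equal(adjust_score(eq, 7, age = 50), 7)
})

test_that("equations survive a JSON round trip exactly", {
  eqs <- published_equations()
  f <- tempfile(fileext = ".json")
  write_equation_json(eqs$ravl_i, f)
  back <- read_equation_json(f)
  expect_equal(back$terms$age$beta, eqs$ravl_i$terms$age$beta)
  expect_equal(back$terms$education$center, eqs$ravl_i$terms$education$center)
  expect_equal(adjust_cohort(back, data.frame(ravl_i = 50, age = 30,
                                              education = 13, gender = 0)),
               adjust_cohort(eqs$ravl_i, data.frame(ravl_i = 50, age = 30,
                                                    education = 13, gender = 0)))
})
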