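test_that("the unconstrained full fit equals the normal-equation solution", {
  prep <- make_prepared(n = 250, seed = 31)
  cat19 <- build_catalog(prep)
  f <- fit_spec(cat19[["Full Model"]], prep)
  ols <- ols_oracle(prep)
  expect_lt(max(abs(unname(coef(ols)) - unname(f$coefficients))), 1e-6)
  expect_equal(f$LL, as.numeric(logLik(ols)), tolerance = 1e-8)
  expect_length(f$active_constraints, 0L)
  expect_true(f$converged)
})

test_that("the null fit recovers the outcome mean and ML variance", {
  prep <- make_prepared(n = 120, seed = 32)
  cat19 <- build_catalog(prep)
  f <- fit_spec(cat19[["Null Model"]], prep)
  y <- prep$L1
  expect_equal(unname(f$coefficients["b0"]), mean(y))
  expect_equal(f$sigma2, mean((y - mean(y))^2))
})

test_that("inactive constraints leave the estimate at the OLS optimum", {
  # generate from a saturating-extraversion surface; its own spec's
  # constraints hold at the truth, so the constrained and unconstrained
  # estimates agree when the OLS solution happens to be feasible
  m <- "Saturating Effect of Extraversion Model"
  prep <- make_prepared(n = 1500, model = m, seed = 33)
  cat19 <- build_catalog(prep)
  f <- fit_spec(cat19[[m]], prep)
  df <- as.data.frame(prep)
  ols <- lm(L1 ~ E + E2, data = df)
  if (length(f$active_constraints) == 0L) {
    expect_lt(max(abs(unname(coef(ols)) -
                        unname(f$coefficients[c("b0", "b1", "b3")]))), 1e-6)
  }
  # either way the estimate satisfies the spec's constraint system
  expect_true(shape_predicate(cat19[[m]], f$coefficients, tol = 1e-6)$satisfied)
})

test_that("violated constraints project onto the feasible boundary", {
  # data with a clearly positive quadratic trend in E; the
  # exponential-extraversion spec demands nonpositive curvature, so its fit
  # must pin b3 at zero and collapse to the linear-extraversion solution
  set.seed(34)
  n <- 400
  E <- rnorm(n); N <- rnorm(n)
  L <- 3 - 0.4 * E + 0.3 * E^2 + rnorm(n, sd = 0.5)
  coh <- cohort(data.frame(E = E + 4, N = N + 4, L1 = pmin(pmax(L, 1), 7)),
                scales = list(E = NULL, N = NULL, L = c(1, 7)))
  prep <- build_design(coh)
  cat19 <- build_catalog(prep)
  fexp <- fit_spec(cat19[["Exponential Effect of Extraversion Model"]], prep)
  expect_gt(length(fexp$active_constraints), 0L)
  flin <- fit_spec(cat19[["Linear Main Effect of Extraversion Model"]], prep)
  expect_equal(unname(fexp$coefficients["b3"]), 0, tolerance = 1e-8)
  expect_equal(fexp$LL, flin$LL, tolerance = 1e-6)
})

test_that("log-likelihood is monotone under nesting across the catalogue", {
  prep <- make_prepared(n = 200, model = "Full Model", seed = 35)
  cat19 <- build_catalog(prep)
  fits <- fit_catalog(cat19, prep)
  M <- nesting(cat19)$matrix
  LL <- vapply(fits, `[[`, numeric(1), "LL")
  for (a in rownames(M)) for (b in colnames(M)) if (M[a, b])
    expect_lte(LL[[a]], LL[[b]] + 1e-6)
})

test_that("parameters of a constraint-satisfying generator are recovered", {
  m <- "Saturating Effect of Extraversion Model"
  gen <- generating_coefficients(m)
  errs <- t(vapply(1:30, function(r) {
    prep <- make_prepared(n = 2000, model = m, seed = 100 + r)
    f <- fit_spec(build_catalog(prep)[[m]], prep)
    f$coefficients[c("b1", "b3")] - gen[c("b1", "b3")]
  }, numeric(2)))
  # bias within 3 Monte-Carlo standard errors of zero
  for (j in 1:2) {
    mc_se <- sd(errs[, j]) / sqrt(nrow(errs))
    expect_lt(abs(mean(errs[, j])), 3 * mc_se + 1e-3)
  }
})

test_that("with no missing follow-up the longitudinal fit is complete-case OLS", {
  prep <- make_prepared(n = 200, seed = 36, t2_missing_rate = 0)
  expect_false(anyNA(prep$L2))
  catL <- build_catalog(prep, longitudinal = TRUE)
  f <- fit_spec(catL[["Full Model"]], prep, outcome = "L2")
  ols <- ols_oracle(prep, outcome = "L2", covariate = TRUE)
  expect_equal(unname(coef(ols)),
               unname(f$coefficients[c("b0", "b1", "b2", "b3", "b4", "b5", "c_cov")]),
               tolerance = 1e-9)
  expect_equal(f$n_complete, f$n_obs)
})

test_that("missing follow-up rows stay in n_obs but not in the likelihood", {
  prep <- make_prepared(n = 300, seed = 37, t2_missing_rate = 0.4)
  catL <- build_catalog(prep, longitudinal = TRUE)
  f <- fit_spec(catL[["Full Model"]], prep, outcome = "L2")
  expect_equal(f$n_obs, 300L)
  expect_equal(f$n_complete, sum(!is.na(prep$L2)))
  expect_lt(f$n_complete, f$n_obs)
  # the conditional likelihood equals the complete-case one
  ols <- ols_oracle(prep, outcome = "L2", covariate = TRUE)
  expect_equal(f$LL, as.numeric(logLik(ols)), tolerance = 1e-8)
})

test_that("the LR gate separates signal from pure noise", {
  prep <- make_prepared(n = 300, seed = 38)
  cat19 <- build_catalog(prep)
  full <- fit_spec(cat19[["Full Model"]], prep)
  null <- fit_spec(cat19[["Null Model"]], prep)
  g <- lr_gate(full, null)
  expect_equal(g$df, 5L)
  expect_true(g$proceed)
  expect_equal(g$statistic, 2 * (full$LL - null$LL))
  # identical fits: zero statistic, no proceed
  g0 <- lr_gate(null, null)
  expect_equal(g0$statistic, 0)
  expect_false(g0$proceed)
  # internal-consistency guard
  fake_full <- list(LL = -10, K = 7, n_complete = 300)
  fake_null <- list(LL = -5, K = 2, n_complete = 300)
  expect_error(lr_gate(fake_full, fake_null), "inconsistency")
})

test_that("adjusted R2 follows the complete-case formula", {
  expect_equal(adjusted_r2(0.5, n_complete = 100, p = 5), 0.4734, tolerance = 5e-5)
  expect_lte(adjusted_r2(0, n_complete = 50, p = 3), 0)
  expect_equal(adjusted_r2(1, n_complete = 50, p = 3), 1)
  expect_true(is.na(adjusted_r2(0.5, n_complete = 6, p = 5)))
  # from a fit: perfect noiseless data
  set.seed(39)
  E <- rnorm(60); N <- rnorm(60)
  L <- 3 - 0.3 * E + 0.2 * N
  coh <- cohort(data.frame(E = E, N = N, L1 = L),
                scales = list(E = NULL, N = NULL, L = NULL))
  prep <- build_design(coh)
  f <- fit_spec(build_catalog(prep)[["Linear Main Effects Model"]], prep)
  expect_equal(f$adj_R2, 1, tolerance = 1e-10)
})

test_that("zero-residual points do not perturb noiseless estimates", {
  set.seed(40)
  E <- rnorm(80); N <- rnorm(80)
  L <- 3 - 0.3 * E + 0.2 * N
  mk <- function(idx) {
    coh <- cohort(data.frame(E = E[idx], N = N[idx], L1 = L[idx]),
                  scales = list(E = NULL, N = NULL, L = NULL))
    prep <- build_design(coh)
    fit_spec(build_catalog(prep)[["Linear Main Effects Model"]], prep)$coefficients
  }
  b_all <- mk(1:80)
  b_m1 <- mk(1:79)
  expect_lt(max(abs(b_all[c("b1", "b2")] - b_m1[c("b1", "b2")])), 1e-8)
})
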