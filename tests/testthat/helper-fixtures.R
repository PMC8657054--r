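# Shared fixtures: all synthetic, built in code.

# symmetric unit-free range box used by arithmetic-level catalogue tests
square_box <- function(half = 2) {
  c(e_lo = -half, e_hi = half, n_lo = -half, n_hi = half)
}

# small prepared dataset generated from a named catalogue model
make_prepared <- function(n = 300, model = "Linear Main Effects Model",
                          coef = NULL, seed = 1, resid_sd = 0.8,
                          clip = FALSE, ...) {
  if (is.null(coef)) coef <- generating_coefficients(model)
  cfg <- synth_config(n = n, model = model, coef = coef,
                      resid_sd = resid_sd, clip = clip, seed = seed, ...)
  build_design(generate_cohort(cfg))
}

# complete-case OLS of the full polynomial, the closed-form oracle for the
# unconstrained fit
ols_oracle <- function(prepared, outcome = "L1", covariate = FALSE) {
  df <- as.data.frame(prepared)
  df$y <- df[[outcome]]
  df <- df[!is.na(df$y), ]
  fm <- if (covariate) y ~ E + N + E2 + EN + N2 + L1 else y ~ E + N + E2 + EN + N2
  stats::lm(fm, data = df)
}
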