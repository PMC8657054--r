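test_that("POMS rescaling maps instrument bounds onto the target range", {
  expect_equal(poms_rescale(1, 1, 5), 1)
  expect_equal(poms_rescale(5, 1, 5), 7)
  expect_equal(poms_rescale(3, 1, 5), 4)
  # linear and order-preserving
  x <- c(1.2, 2.7, 4.9, 3.3)
  y <- poms_rescale(x, 1, 5)
  expect_equal(order(y), order(x))
  expect_equal(diff(y) / diff(x), rep(6 / 4, 3))
  expect_error(poms_rescale(6, 1, 5), "outside")
  expect_error(poms_rescale(1, 5, 5), "strictly less")
})

test_that("centering removes the mean and retains it", {
  expect_equal(center_scores(c(2, 4))$values, c(-1, 1))
  expect_equal(center_scores(c(3, 3, 3))$values, c(0, 0, 0))
  x <- rnorm(50, mean = 10)
  cs <- center_scores(x)
  expect_lt(abs(mean(cs$values)), 1e-10)
  expect_equal(cs$values + cs$mean, x)
  expect_error(center_scores(c(NA_real_, NA_real_)), "non-missing")
})

test_that("build_design rescales, centers and derives second-order terms", {
  set.seed(11)
  raw <- data.frame(E = runif(40, 1, 5), N = runif(40, 1, 5),
                    L1 = runif(40, 1, 5))
  coh <- cohort(raw, scales = list(E = c(1, 5), N = c(1, 5), L = c(1, 5)))
  prep <- build_design(coh)
  expect_lt(abs(mean(prep$E)), 1e-10)
  expect_lt(abs(mean(prep$N)), 1e-10)
  expect_equal(prep$E2, prep$E^2)
  expect_equal(prep$EN, prep$E * prep$N)
  expect_equal(prep$N2, prep$N^2)
  # outcome is rescaled to 1-7 but not centered
  expect_true(all(prep$L1 >= 1 & prep$L1 <= 7))
  expect_equal(prep$L1, poms_rescale(raw$L1, 1, 5))
  rb <- attr(prep, "range_box")
  expect_lt(rb["e_lo"], rb["e_hi"])
  expect_lt(rb["n_lo"], rb["n_hi"])
  expect_error(build_design(cohort(raw[1:5, ],
                                   scales = list(E = c(1, 5), N = c(1, 5), L = c(1, 5)))),
               "fewer than 10")
})

test_that("POMS-plus-centering is affine: fit statistics are scale-free", {
  set.seed(21)
  n <- 120
  E5 <- runif(n, 1, 5); N5 <- runif(n, 1, 5)
  L5 <- 3 - 0.3 * E5 + 0.4 * N5 + rnorm(n, sd = 0.5)
  L5 <- pmin(pmax(L5, 1), 5)
  sc5 <- list(E = c(1, 5), N = c(1, 5), L = c(1, 5))
  sc7 <- list(E = c(1, 7), N = c(1, 7), L = c(1, 7))
  prep_a <- build_design(cohort(data.frame(E = E5, N = N5, L1 = L5), sc5))
  # same data pre-transformed onto 1-7 by hand
  prep_b <- build_design(cohort(data.frame(E = poms_rescale(E5, 1, 5),
                                           N = poms_rescale(N5, 1, 5),
                                           L1 = poms_rescale(L5, 1, 5)), sc7))
  ca <- build_catalog(prep_a); cb <- build_catalog(prep_b)
  fa <- fit_spec(ca[["Full Model"]], prep_a)
  fb <- fit_spec(cb[["Full Model"]], prep_b)
  na <- fit_spec(ca[["Null Model"]], prep_a)
  nb <- fit_spec(cb[["Null Model"]], prep_b)
  expect_equal(fa$R2, fb$R2, tolerance = 1e-10)
  expect_equal(lr_gate(fa, na)$statistic, lr_gate(fb, nb)$statistic,
               tolerance = 1e-8)
})

test_that("rows with missing baseline values are dropped with counts", {
  raw <- data.frame(E = c(2, NA, 3, 4, 2.5), N = c(3, 3, NA, 2, 3.5),
                    L1 = c(2, 3, 3, NA, 4), L2 = c(NA, 2, 3, 3, 2))
  coh <- cohort(raw, scales = list(E = c(1, 5), N = c(1, 5), L = c(1, 5)))
  expect_equal(nrow(coh), 2L)           # rows 2,3 (missing E/N) and 4 (missing L1) dropped
  expect_equal(unname(attr(coh, "dropped")["missing_L1"]), 1L)
  expect_equal(unname(attr(coh, "dropped")["missing_EN"]), 2L)
  expect_true(is.na(coh$L2[1]))         # follow-up may stay missing
})

test_that("cohort CSV round-trips through the configured reader", {
  cfg <- synth_config(n = 60, seed = 4)
  coh <- generate_cohort(cfg)
  csv <- file.path(tempdir(), "cohort.csv")
  write_cohort(coh, csv)
  back <- read_cohort(csv)
  expect_equal(back$E, coh$E)
  expect_equal(back$L2, coh$L2)         # NAs encoded as empty cells
  # custom column mapping and scales via YAML config
  df <- data.frame(id = 1:30, extra = runif(30, 1, 5), neuro = runif(30, 1, 5),
                   lone_t1 = runif(30, 1, 5))
  csv2 <- file.path(tempdir(), "cohort2.csv")
  write.csv(df, csv2, row.names = FALSE)
  yml <- file.path(tempdir(), "map.yaml")
  yaml::write_yaml(list(columns = list(E = "extra", N = "neuro",
                                       L1 = "lone_t1", person_id = "id"),
                        scales = list(E = c(1, 5), N = c(1, 5), L = c(1, 5))),
                   yml)
  coh2 <- read_cohort(csv2, yml)
  expect_equal(coh2$E, df$extra)
  expect_equal(attr(coh2, "scales")$E, c(1, 5))
})

test_that("influence screen flags a planted outlier but not clean data", {
  prep <- make_prepared(n = 300, seed = 8)
  rep0 <- flag_influential(prep)
  # hat values sum to the number of design columns and lie in [0, 1]
  expect_equal(sum(rep0$hat), 6, tolerance = 1e-8)
  expect_true(all(rep0$hat >= 0 & rep0$hat <= 1))
  # clean Gaussian data: flagged fraction below 5%
  expect_lt(mean(rep0$flagged), 0.05)

  # plant one case at an extreme predictor point with a 10-residual-SD shift
  df <- as.data.frame(prep)
  resid_sd <- summary(lm(L1 ~ E + N + E2 + EN + N2, df))$sigma
  ex <- df[1, ]
  ex$E <- max(df$E) * 1.6; ex$N <- min(df$N) * 1.6
  ex$E2 <- ex$E^2; ex$EN <- ex$E * ex$N; ex$N2 <- ex$N^2
  ex$L1 <- mean(df$L1) + 10 * resid_sd
  ex$person_id <- 99999
  df2 <- rbind(df, ex)
  attributes(df2)[c("range_box", "class")] <- attributes(prep)[c("range_box", "class")]
  rep1 <- flag_influential(df2)
  expect_true(rep1$flagged[rep1$person_id == 99999])

  # a duplicate of an interior point has low leverage
  mid <- df[which.min(abs(df$E) + abs(df$N)), ]
  df3 <- rbind(df, mid)
  attributes(df3)[c("range_box", "class")] <- attributes(prep)[c("range_box", "class")]
  rep2 <- flag_influential(df3)
  expect_lt(rep2$hat[nrow(rep2)], attr(rep2, "cutoffs")["hat"])
})

test_that("degenerate designs are rejected with advice", {
  df <- data.frame(person_id = 1:30, E = rep(0, 30), N = rnorm(30),
                   L1 = rnorm(30, 3))
  df$E2 <- 0; df$EN <- 0; df$N2 <- df$N^2; df$L2 <- NA_real_
  class(df) <- c("prepared_data", "data.frame")
  expect_error(flag_influential(df), "singular")
})
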