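# Log-cost regression, Duan smearing, dollar-scale effects, CPI inflation.

test_that("the smearing factor follows its definition", {
  expect_identical(smear_factor(c(0, 0, 0)), 1)
  expect_equal(smear_factor(c(log(2), log(0.5))), 1.25)
})

test_that("beta and smear match a hand-computed OLS on a 6-record cohort", {
  toy <- toy_cost_cohort()
  X <- cbind(1, toy$exposure, toy$age)
  beta <- ols_oracle(X, log(toy$cost_total))
  resid <- log(toy$cost_total) - X %*% beta
  fit <- fit_log_cost(toy, c("exposure", "age"), n_boot = 0)
  expect_lt(abs(fit$estimates$beta_log[1] - beta[2]), 1e-8)
  expect_lt(abs(fit$estimates$beta_log[2] - beta[3]), 1e-8)
  expect_lt(abs(fit$smear - mean(exp(resid))), 1e-8)
})

test_that("a noise-free cohort gives smear 1 and exact dollar differences", {
  x <- rep(c(0, 1), each = 10)
  cost <- exp(8 + 0.4 * x)
  d <- data.frame(cost_total = cost, x = x)
  # summary.lm warns about the (intentionally) perfect fit
  fit <- suppressWarnings(fit_log_cost(d, "x", n_boot = 0))
  expect_equal(fit$smear, 1, tolerance = 1e-10)
  expect_equal(fit$estimates$dollar_change[1], exp(8.4) - exp(8),
               tolerance = 1e-6)
  # with a single binary covariate the at-means effect coincides
  fit_am <- suppressWarnings(fit_log_cost(d, "x", n_boot = 0,
                                          dollar_scale = "at-means"))
  expect_equal(fit_am$estimates$dollar_change[1],
               fit$estimates$dollar_change[1], tolerance = 1e-8)
})

test_that("dollar effects scale with the currency and keep the beta sign", {
  co <- generate_cohort(cohort_config(n = 1500, emit_codes = FALSE), seed = 2)
  f1 <- fit_log_cost(co, c("morb_hypertension", "age"), n_boot = 50)
  co2 <- co
  co2$cost_total <- co2$cost_total * 3
  f2 <- fit_log_cost(co2, c("morb_hypertension", "age"), n_boot = 0)
  expect_equal(f2$estimates$dollar_change, 3 * f1$estimates$dollar_change,
               tolerance = 1e-8)
  expect_equal(f2$estimates$beta_log, f1$estimates$beta_log,
               tolerance = 1e-8)
  expect_identical(sign(f1$estimates$dollar_change),
                   sign(f1$estimates$beta_log))
  expect_true(all(f1$estimates$ci_low <= f1$estimates$dollar_change &
                    f1$estimates$dollar_change <= f1$estimates$ci_high))
})

test_that("mean smeared fitted cost matches mean observed cost (Duan)", {
  # well-specified log-scale model; the agreement is statistical (the
  # smeared mean is consistent, not an algebraic identity), so use a large
  # sample and a 1% margin
  set.seed(12)
  n <- 40000
  x <- runif(n) < 0.4
  age <- runif(n, 40, 95)
  d <- data.frame(cost_total = exp(8 + 0.5 * x + 0.005 * age +
                                     rnorm(n, 0, 0.9)),
                  x = x, age = age)
  fit <- fit_log_cost(d, c("x", "age"), n_boot = 0)
  expect_rel(fit$mean_smeared_fitted, fit$mean_observed, 0.01, "Duan")
})

test_that("degenerate designs and outcomes are rejected with names", {
  co <- generate_cohort(cohort_config(n = 200, emit_codes = FALSE), seed = 1)
  co$dup <- co$morb_hypertension
  expect_error(fit_log_cost(co, c("morb_hypertension", "dup"), n_boot = 0),
               "rank deficient")
  co$bad <- co$cost_total
  co$bad[5] <- -1
  expect_error(fit_log_cost(co, "age", outcome = "bad"), "positive")
  expect_error(fit_log_cost(co, "nope", n_boot = 0), "not found")
})

test_that("association_test needs two exposure levels and detects effects", {
  co <- generate_cohort(cohort_config(n = 5000, emit_codes = FALSE), seed = 4)
  co$all_one <- TRUE
  expect_error(association_test(co, "all_one"), "single level")
  # a planted strong effect is detected at large n
  expect_lt(association_test(co, "morb_hypertension"), 1e-3)
})

test_that("per-added-morbidity model reports the count effect first", {
  co <- generate_cohort(cohort_config(n = 3000, emit_codes = FALSE), seed = 6)
  fit <- fit_morbidity_count_cost(co, n_boot = 0)
  expect_identical(fit$estimates$covariate[1], "morb_count")
  expect_gt(fit$estimates$dollar_change[1], 0)
})

test_that("CPI inflation is a ratio and chains across years", {
  cpi <- cpi_series(2005:2015, c(100, 102, 104, 107, 107, 109, 112, 113,
                                 114, 116, 118))
  expect_equal(inflate(100, 2008, 2008, cpi), 100)
  expect_equal(inflate(100, 2005, 2010, cpi), 109)
  direct <- inflate(250, 2006, 2014, cpi)
  chained <- inflate(inflate(250, 2006, 2011, cpi), 2011, 2014, cpi)
  expect_equal(direct, chained, tolerance = 1e-12)
  expect_error(inflate(100, 1998, 2015, cpi), "absent")
  expect_error(cpi_series(2001:2002, c(1, -3)), "positive")
  tmp <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(year = 2005:2015, index = unclass(cpi)), tmp,
            row.names = FALSE)
  expect_equal(unclass(read_cpi_series(tmp)), unclass(cpi))
})
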