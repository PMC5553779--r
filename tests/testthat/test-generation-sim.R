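# Generational Monte Carlo simulation and Welch comparison.

test_that("cohort_size follows the geometric-growth closed form", {
  expect_identical(cohort_size(1e6, 0, 12 / 1e5, 10), 1200)
  expect_identical(cohort_size(2.5e6, 0, 12 / 1e5, 1), 300)
  # loop-based oracle
  oracle <- function(bp, g, h, yrs) round(sum(bp * h * (1 + g)^(0:(yrs - 1))))
  set.seed(5)
  for (i in 1:5) {
    bp <- runif(1, 1e5, 5e7); g <- runif(1, 0, 0.03); yrs <- sample(2:120, 1)
    expect_identical(cohort_size(bp, g, 12e-5, yrs), oracle(bp, g, 12e-5, yrs))
  }
  # the default demographic scenario accumulates ~717,727 admissions
  cfg <- gen_sim_config()
  expect_rel(cohort_size(cfg$base_population, cfg$growth_rate, cfg$hosp_rate,
                         cfg$years), 717727, 0.005, "100-year cohort")
  # monotone in every argument
  base <- cohort_size(1e6, 0.01, 1e-4, 50)
  expect_gt(cohort_size(2e6, 0.01, 1e-4, 50), base)
  expect_gt(cohort_size(1e6, 0.02, 1e-4, 50), base)
  expect_gt(cohort_size(1e6, 0.01, 2e-4, 50), base)
  expect_gt(cohort_size(1e6, 0.01, 1e-4, 60), base)
})

test_that("simulated demographics respect bounds and moments", {
  cfg <- gen_sim_config(per_replicate_n = 40000, seed = 3)
  set.seed(cfg$seed)
  demo <- draw_generation_cohort(cfg)
  expect_true(all(demo$age >= 18 & demo$age <= 126))
  # truncated-normal mean oracle: mu + sd*(phi(a)-phi(b))/(Phi(b)-Phi(a))
  a <- (18 - 70) / 13; b <- (126 - 70) / 13
  mu_tr <- 70 + 13 * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  expect_lt(abs(mean(demo$age) - mu_tr), 0.25)
  expect_lt(abs(mean(demo$hypertension) - 0.77), 0.01)
  cfg0 <- gen_sim_config(hyp_prev = 0, per_replicate_n = 500)
  expect_false(any(draw_generation_cohort(cfg0)$hypertension))
})

test_that("welch_test matches its closed form and conventions", {
  w <- welch_test(10, 10, 40, 10, 10, 40)
  expect_equal(w$t, 0)
  expect_equal(w$p_value, 1)
  # equal n, equal variances: reduces to the Student statistic
  ws <- welch_test(10, 4, 30, 12, 4, 30)
  t_student <- (10 - 12) / sqrt(4 * (1 / 30 + 1 / 30))
  expect_equal(ws$t, t_student, tolerance = 1e-12)
  expect_equal(ws$df, 58, tolerance = 1e-9)
  # frozen values from the closed form: se2 = 4/30 + 9/40, t = -2/sqrt(se2),
  # df = se2^2 / ((4/30)^2/29 + (9/40)^2/39)
  w2 <- welch_test(10, 4, 30, 12, 9, 40)
  expect_equal(w2$t, -3.341076, tolerance = 1e-5)
  expect_equal(w2$df, 67.1878, tolerance = 1e-4)
  expect_equal(w2$p_value, 0.0013659, tolerance = 1e-3)
  # degenerate variance conventions
  expect_equal(welch_test(5, 0, 10, 5, 0, 10)$p_value, 1)
  expect_equal(welch_test(5, 0, 10, 6, 0, 10)$p_value, 0)
})

test_that("welch p-values agree with a numerical integration oracle", {
  set.seed(99)
  for (i in 1:100) {
    w <- welch_test(rnorm(1), runif(1, 0.5, 9), sample(5:200, 1),
                    rnorm(1), runif(1, 0.5, 9), sample(5:200, 1))
    p_oracle <- 2 * integrate(function(x) dt(x, w$df), abs(w$t), Inf,
                              rel.tol = 1e-12, abs.tol = 1e-14)$value
    expect_lt(abs(w$p_value - p_oracle), 1e-6)
  }
})

test_that("the simulation is reproducible and rejects bad references", {
  ref <- generate_cohort(cohort_config(n = 400), seed = 10)
  cfg <- gen_sim_config(n_replicates = 8, per_replicate_n = 1500, seed = 21)
  r1 <- run_generation_sim(cfg, ref, n_boot_primary = 30)
  r2 <- run_generation_sim(cfg, ref, n_boot_primary = 30)
  expect_identical(r1$replicate_estimates, r2$replicate_estimates)
  expect_identical(r1$welch$p_value, r2$welch$p_value)
  ref_onestratum <- ref[ref$morb_hypertension, ]
  expect_error(run_generation_sim(cfg, ref_onestratum, n_boot_primary = 0),
               "stratum")
  expect_error(run_generation_sim(cfg, ref[, c("age", "cost_total")]),
               "lacks columns")
})

test_that("a null reference mechanism gives a near-zero dollar effect", {
  set.seed(13)
  n <- 3000
  ref <- data.frame(
    age = round(runif(n, 30, 95)),
    morb_hypertension = runif(n) < 0.5,
    cost_total = exp(rnorm(n, 9, 0.6))
  )
  cfg <- gen_sim_config(n_replicates = 25, per_replicate_n = 5000, seed = 31)
  res <- run_generation_sim(cfg, ref, n_boot_primary = 0)
  expect_lt(abs(res$mean_dollar_increase), 0.05 * mean(ref$cost_total))
})

test_that("the replicate estimator is consistent for the planted effect", {
  ref <- generate_cohort(cohort_config(), seed = 55)
  cfg <- gen_sim_config(n_replicates = 40, per_replicate_n = 20000, seed = 7)
  res <- run_generation_sim(cfg, ref, n_boot_primary = 0)
  truth <- gen_sim_planted_effect(ref, cfg)
  expect_rel(res$mean_dollar_increase, truth, 0.03, "planted effect")
})
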