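# Synthetic cohort generator: reproducibility, marginal structure, code
# round-trip, and calibration on stripped-down targets.

test_that("generation is reproducible bit-for-bit under a fixed seed", {
  cfg <- cohort_config(n = 300)
  a <- generate_cohort(cfg, seed = 7)
  b <- generate_cohort(cfg, seed = 7)
  attr(a, "config") <- attr(b, "config") <- NULL
  expect_identical(a, b)
  c2 <- generate_cohort(cfg, seed = 8)
  expect_false(identical(a$cost_total, c2$cost_total))
})

test_that("degenerate prevalences give morbidity-free cohorts", {
  cfg <- cohort_config(n = 150)
  cfg$morbidity_prev[] <- 0
  cfg$htn_assoc_rr[] <- 1
  co <- generate_cohort(cfg, seed = 3)
  expect_true(all(co$morb_count == 0))
  expect_false(any(co$morb_any))
})

test_that("structural invariants hold on a default cohort", {
  co <- generate_cohort(cohort_config(), seed = 5)
  expect_identical(nrow(co), 987L)
  expect_true(all(co$age >= 18 & co$age <= 99))
  expect_true(all(co$los_days >= 1 & co$los_days <= 190))
  expect_true(all(co$cost_total > 0))
  expect_true(all(abs(co$cost_total - (co$cost_diagnostic + co$cost_acute +
                                         co$cost_rehab)) < 0.02))
  expect_true(all(co$cost_year == 2015L))
  expect_identical(co$morb_count, rowSums(co[, paste0("morb_", morb_ids())]))
  # severity fields only in the clinical subgroup
  expect_true(mean(!is.na(co$nihss_ge15)) > 0.08)
  expect_true(mean(!is.na(co$nihss_ge15)) < 0.25)
  expect_true(all(is.na(co$mrs_poor[co$died])))
})

test_that("marginals track the configured prevalences at n = 987", {
  # average over seeds; binomial 3*SE at n=987*5 is ~2 points
  ms <- sapply(1:5, function(s) {
    co <- generate_cohort(cohort_config(), seed = 20 + s)
    c(htn = mean(co$morb_hypertension), male = mean(co$sex == "M"),
      died = mean(co$died), surg = mean(co$surgery),
      diab = mean(co$morb_diabetes))
  })
  m <- rowMeans(ms)
  expect_lt(abs(m[["htn"]] - 0.67), 0.02)
  expect_lt(abs(m[["male"]] - 0.55), 0.025)
  expect_lt(abs(m[["died"]] - 0.28), 0.025)
  expect_lt(abs(m[["surg"]] - 0.18), 0.02)
  expect_lt(abs(m[["diab"]] - 0.15), 0.02)
})

test_that("hypertension clustering preserves marginal prevalences", {
  cfg <- cohort_config(n = 40000, emit_codes = FALSE)
  co <- generate_cohort(cfg, seed = 9)
  for (j in c("secondary_cerebrovascular", "diabetes", "renal")) {
    expect_lt(abs(mean(co[[paste0("morb_", j)]]) -
                    cfg$morbidity_prev[[j]]), 0.006)
  }
  # and the clustering is real: higher prevalence among hypertensives
  scvd <- co$morb_secondary_cerebrovascular
  expect_gt(mean(scvd[co$morb_hypertension]),
            mean(scvd[!co$morb_hypertension]) * 1.5)
})

test_that("generated codes round-trip through the classifier", {
  co <- generate_cohort(cohort_config(), seed = 31)
  expect_true(all(round_trip_codes(co)))
  # wiping the codes breaks the round trip unless the profile was empty
  co2 <- co
  co2$codes <- vapply(co$codes, function(s) strsplit(s, ";")[[1]][1],
                      character(1))
  rt <- round_trip_codes(co2)
  expect_identical(rt, co$morb_count == 0)
})

test_that("invalid configurations are rejected before sampling", {
  expect_error(cohort_config(n = 0), "n must be")
  expect_error(cohort_config(male_frac = 1.2), "proportions")
  cfg <- cohort_config()
  cfg$morbidity_prev[["diabetes"]] <- 1.4
  expect_error(validate_cohort_config(cfg), "prevalences")
  cfg2 <- cohort_config()
  cfg2$cost_los_link$values <- rev(cfg2$cost_los_link$values)
  expect_error(validate_cohort_config(cfg2), "non-decreasing")
})

test_that("calibration recovers a null planted effect and a median target", {
  cfg <- null_config(n = 987)
  cal <- calibrate_generator(cfg,
    targets = list(htn_dollar_age_adj = 0, median_cost = 9000),
    n_sim = 20000, seed = 77, sweeps = 1, tol = 0.02)
  # a zero dollar target maps back to a (near) zero planted log effect when
  # no clustering or stay effects are present (up to the calibration
  # cohort's own sampling noise, SE ~ 0.02 at n_sim = 20000)
  expect_lt(abs(cal$planted_log_effects[["hypertension"]]), 0.05)
  cal$n <- 20000
  cal$emit_codes <- FALSE
  co <- generate_cohort(cal, seed = 5)
  expect_rel(median(co$cost_total), 9000, 0.03, "median target")
})

test_that("an unattainable any-morbidity target errors with the range", {
  expect_error(
    calibrate_generator(cohort_config(), targets = list(p_any = 0.95),
                        n_sim = 1000),
    "attainable range")
})
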