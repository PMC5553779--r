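# Shared helpers for the test suite. All fixtures are built in code.

morb_ids <- function() names(ichcost:::MORBIDITY_IDS)

# A configuration with all dependence and planted structure stripped:
# independent flags, no length-of-stay risk effects, no cost effects.
null_config <- function(n = 2000, ...) {
  cfg <- cohort_config(n = n, ...)
  cfg$htn_assoc_rr[] <- 1
  cfg$planted_los_effects[] <- 0
  cfg$planted_log_effects[c(morb_ids(), "count_concavity")] <- 0
  cfg
}

# Tiny hand-checkable cohort for regression oracles.
toy_cost_cohort <- function() {
  data.frame(
    cost_total = c(1200, 3400, 980, 5600, 2100, 7400),
    exposure = c(0, 1, 0, 1, 0, 1),
    age = c(61, 74, 58, 80, 66, 71)
  )
}

# Independent OLS via explicit normal equations.
ols_oracle <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

expect_rel <- function(object, expected, tol, info = NULL) {
  expect_lt(abs(object - expected) / max(abs(expected), 1e-12), tol,
            label = paste0(info, " relative deviation"))
}

# Discharge-records fixture written programmatically at test time.
make_records_file <- function(path, n_ok = 987, n_missing_cost = 15,
                              n_minor = 0, n_malformed = 0) {
  co <- generate_cohort(cohort_config(n = n_ok), seed = 123)
  d <- as.data.frame(co)
  if (n_missing_cost > 0) {
    extra <- d[seq_len(n_missing_cost), ]
    extra$cost_total <- NA
    d <- rbind(d, extra)
  }
  if (n_minor > 0) {
    extra <- d[seq_len(n_minor), ]
    extra$age <- 16
    d <- rbind(d, extra)
  }
  write_cohort(d, path)
  if (n_malformed > 0) {
    lines <- readLines(path)
    bad <- paste(c("9999", "not_a_number", rep("", ncol(d) - 2)),
                 collapse = ",")
    writeLines(c(lines, rep(bad, n_malformed)), path)
  }
  path
}
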