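# Synthetic ICH discharge-cohort generator.
#
# The generator emulates the joint structure of an administrative discharge
# cohort: truncated-normal ages, Bernoulli morbidity flags at admission
# prevalences (with a hypertension-clustering mechanism and an optional
# shared frailty inducing realistic co-occurrence), a discretized log-normal
# length of stay whose exceedance of 7 days follows a log-binomial model
# with planted relative risks, and log-normal costs linked to length of stay
# through a monotone concave curve with planted morbidity effects on the
# log-cost scale.

# One "safe" ICD-9 / ICD-10 code per category: each matches its own category
# and no other, so generated code lists round-trip exactly through classify().
SAFE_ICD <- list(
  hypertension              = c("401.9",  "I10"),
  secondary_cerebrovascular = c("433.10", "I63.9"),
  diabetes                  = c("250.00", "E11.9"),
  cardiac                   = c("428.0",  "I50.0"),
  chronic_pulmonary         = c("493.90", "J44.9"),
  malignancy                = c("162.9",  "C34.9"),
  dementia                  = c("290.0",  "F03"),
  mood                      = c("296.20", "F32.9"),
  renal                     = c("585.9",  "N18.9"),
  peripheral_vascular       = c("440.9",  "I70.9"),
  liver                     = c("571.2",  "K74.6"),
  rheumatic                 = c("714.0",  "M06.9"),
  peptic_ulcer              = c("531.90", "K25.9")
)

# Eligible index (most responsible) ICH diagnosis codes.
ICH_MRDX_CODES <- c("431", paste0("I61.", c(0:6, 8, 9)))

#' Configuration of the synthetic ICH cohort generator
#'
#' Returns the generator configuration as a validated list. The defaults are
#' the study conditions the package is built around: a decade of 987 adult
#' ICH discharges from a single stroke centre, with admission-morbidity
#' prevalences, length-of-stay distribution, mortality and surgery fractions
#' matching the cohort summary, and planted effects (on the log-cost and
#' log-risk scales) calibrated so that the downstream estimation pipeline
#' recovers the published dollar-scale and relative-risk estimates (see the
#' methods vignette for the calibration procedure).
#'
#' @param n cohort size.
#' @param seed default random seed used by \code{\link{generate_cohort}}.
#' @param age_mean,age_sd,age_bounds truncated-normal age model (years).
#' @param male_frac proportion male.
#' @param years calendar admission years sampled uniformly.
#' @param morbidity_prev named admission prevalences of the 13 categories.
#' @param htn_assoc_rr named prevalence risk ratios of other morbidities
#'   given hypertension (marginal prevalences are preserved); the clustering
#'   this induces is what makes an hypertension-only cost model confounded
#'   relative to the fully adjusted model, as in real admission data.
#' @param frailty_rho latent Gaussian shared-frailty correlation applied to
#'   the non-hypertension morbidity draws (0 disables it).
#' @param planted_log_effects named coefficients of the true log-cost model:
#'   \code{intercept}, \code{age} (per year, centred at \code{age_mean}),
#'   one coefficient per morbidity category, and \code{count_concavity}, a
#'   diminishing-returns term added once per morbidity beyond the first
#'   (negative values make joint morbidity costs sub-additive, as the
#'   published per-added-morbidity estimate implies).
#' @param planted_los_effects named log relative risks for staying longer
#'   than 7 days, one per morbidity category.
#' @param los_meanlog,los_sdlog,los_bounds discretized log-normal length of
#'   stay model (days); the default median is 8 days, range 1--190.
#' @param cost_los_link list with \code{days} and \code{values}: the
#'   monotone concave log-cost vs length-of-stay curve, interpolated
#'   linearly between knots (non-decreasing values required).
#' @param cost_noise_sd residual SD of log cost.
#' @param category_split baseline (diagnostic, acute, rehabilitation) cost
#'   shares; \code{split_alpha} is the Dirichlet concentration of the
#'   per-record perturbation.
#' @param split_alpha Dirichlet concentration for category shares.
#' @param mortality_frac in-hospital death fraction; deaths are assigned
#'   preferentially to short stays with logistic strength
#'   \code{death_los_slope}.
#' @param death_los_slope slope of the death model on \code{-log(LOS)}.
#' @param surgery_frac surgery fraction.
#' @param severity_frac fraction of the cohort with recorded stroke-severity
#'   fields (admission NIHSS and discharge mRS), emulating a clinical
#'   subgroup; \code{NA} outside it.
#' @param nihss_p probability of NIHSS >= 15 in the subgroup (independent of
#'   hypertension).
#' @param emit_codes generate per-record ICD code lists consistent with the
#'   morbidity flags (disable for speed in large calibration runs).
#' @return object of class \code{cohort_config}.
#' @export
cohort_config <- function(
  n = 987,
  seed = 20170810,
  age_mean = 72, age_sd = 13, age_bounds = c(18, 99),
  male_frac = 0.55,
  years = 1999:2008,
  morbidity_prev = c(
    hypertension = 0.67, secondary_cerebrovascular = 0.23, diabetes = 0.15,
    cardiac = 0.10, chronic_pulmonary = 0.06, malignancy = 0.05,
    dementia = 0.05, mood = 0.03, renal = 0.03, peripheral_vascular = 0.02,
    liver = 0.01, rheumatic = 0.01, peptic_ulcer = 0.01),
  htn_assoc_rr = c(
    secondary_cerebrovascular = 2.738483, diabetes = 1.654836,
    cardiac = 1.654836, renal = 1.946159, peripheral_vascular = 1.654836),
  frailty_rho = 0,
  planted_log_effects = c(
    intercept = 7.204693, age = 0.004, count_concavity = -0.861894,
    hypertension = 0.504329, secondary_cerebrovascular = 1.089032,
    diabetes = 0.735097, cardiac = 0.762322, chronic_pulmonary = 0.05,
    malignancy = 0.15, dementia = 0.18, mood = 0.45, renal = 1.225161,
    peripheral_vascular = 0.217806, liver = 0.40, rheumatic = 0.30,
    peptic_ulcer = 0.55),
  planted_los_effects = log(c(
    hypertension = 1.31, secondary_cerebrovascular = 1.08, diabetes = 1.18,
    cardiac = 1.14, chronic_pulmonary = 1.09, malignancy = 1.08,
    dementia = 1.19, mood = 1.37, renal = 1.14, peripheral_vascular = 1.24,
    liver = 1.64, rheumatic = 1.24, peptic_ulcer = 1.62)),
  los_meanlog = log(8), los_sdlog = 0.9, los_bounds = c(1, 190),
  cost_los_link = list(
    days = c(1, 7, 14, 21, 28, 35, 42, 190),
    values = c(0, 1.542054, 2.507649, 3.072957, 3.474359, 3.785446,
               4.039667, 4.699751)),
  cost_noise_sd = 0.535698,
  category_split = c(diagnostic = 0.20, acute = 0.55, rehab = 0.25),
  split_alpha = 40,
  mortality_frac = 0.28, death_los_slope = 0.6,
  surgery_frac = 0.18,
  severity_frac = 148 / 987, nihss_p = 0.35,
  emit_codes = TRUE
) {
  cfg <- as.list(environment())
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

#' Validate a cohort generator configuration
#'
#' Checks ranges and structural invariants; called by
#' \code{\link{cohort_config}} and again by \code{\link{generate_cohort}}
#' before any sampling.
#'
#' @param cfg a \code{cohort_config}.
#' @return the config, invisibly; stops with a descriptive error otherwise.
#' @export
validate_cohort_config <- function(cfg) {
  ids <- names(MORBIDITY_IDS)
  chk <- function(ok, msg) if (!isTRUE(ok)) stop("invalid config: ", msg,
                                                 call. = FALSE)
  chk(is.numeric(cfg$n) && length(cfg$n) == 1L && cfg$n >= 1, "n must be >= 1")
  chk(all(sort(names(cfg$morbidity_prev)) == sort(ids)),
      "morbidity_prev must name all 13 categories")
  chk(all(cfg$morbidity_prev >= 0 & cfg$morbidity_prev <= 1),
      "morbidity prevalences must lie in [0, 1]")
  props <- c(cfg$male_frac, cfg$mortality_frac, cfg$surgery_frac,
             cfg$severity_frac, cfg$nihss_p)
  chk(all(props >= 0 & props <= 1), "proportions must lie in [0, 1]")
  chk(all(names(cfg$htn_assoc_rr) %in% setdiff(ids, "hypertension")) &&
        all(cfg$htn_assoc_rr > 0),
      "htn_assoc_rr must be positive and name non-hypertension categories")
  chk(cfg$frailty_rho >= 0 && cfg$frailty_rho < 1, "frailty_rho in [0, 1)")
  chk(all(c("intercept", "age", "count_concavity", ids) %in%
            names(cfg$planted_log_effects)),
      "planted_log_effects must include intercept, age, count_concavity and all 13 categories")
  chk(all(sort(names(cfg$planted_los_effects)) == sort(ids)),
      "planted_los_effects must name all 13 categories")
  chk(cfg$age_bounds[1] < cfg$age_bounds[2] && cfg$age_sd > 0, "age model")
  chk(cfg$los_bounds[1] >= 1 && cfg$los_bounds[1] < cfg$los_bounds[2] &&
        cfg$los_sdlog > 0, "length-of-stay model")
  lnk <- cfg$cost_los_link
  chk(is.list(lnk) && length(lnk$days) == length(lnk$values) &&
        !is.unsorted(lnk$days, strictly = TRUE) &&
        !is.unsorted(lnk$values),
      "cost_los_link must be non-decreasing over increasing days")
  chk(abs(sum(cfg$category_split) - 1) < 1e-8 && all(cfg$category_split > 0),
      "category_split must be positive and sum to 1")
  chk(cfg$cost_noise_sd >= 0, "cost_noise_sd must be >= 0")
  invisible(cfg)
}

# Inverse-CDF sampler for a truncated normal (no rejection, so the draw
# count per record is fixed and seeds are stable).
rtruncnorm_inv <- function(u, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + u * (phi - plo), mean, sd)
}

# Inverse-CDF sampler for a lognormal truncated to [lower, upper].
rlnorm_trunc_inv <- function(u, meanlog, sdlog, lower, upper) {
  plo <- stats::plnorm(lower, meanlog, sdlog)
  phi <- stats::plnorm(upper, meanlog, sdlog)
  stats::qlnorm(plo + u * (phi - plo), meanlog, sdlog)
}

# Evaluate the log-cost vs LOS link curve.
eval_los_link <- function(link, los) {
  stats::approx(link$days, link$values, xout = los, rule = 2)$y
}

# Conditional prevalences given hypertension that preserve the marginal:
# p = pH * p1 + (1 - pH) * p0 with p1 = rr * p0.
htn_conditional_prev <- function(p, rr, p_htn) {
  p0 <- p / (p_htn * rr + (1 - p_htn))
  list(p0 = p0, p1 = pmin(rr * p0, 1))
}

#' Generate a synthetic ICH discharge cohort
#'
#' Draws a cohort of discharge records under the generative model described
#' in \code{\link{cohort_config}}. Generation is vectorized with a fixed
#' draw order, so a given seed always yields the identical cohort.
#'
#' @param config a \code{cohort_config}.
#' @param seed integer seed; defaults to \code{config$seed}.
#' @return a data frame with one row per discharge: demographics
#'   (\code{age}, \code{sex}, \code{admission_year}), packed diagnosis codes
#'   (\code{codes}, see \code{\link{unpack_codes}}), morbidity flags
#'   (\code{morb_<category>}, \code{morb_count}, \code{morb_any}),
#'   \code{los_days}, \code{died}, \code{surgery}, costs in 2015 USD
#'   (\code{cost_total} = \code{cost_diagnostic} + \code{cost_acute} +
#'   \code{cost_rehab}, \code{cost_year}), and optional severity fields
#'   (\code{nihss_ge15}, \code{mrs_poor}). The config is attached as
#'   attribute \code{"config"}.
#' @examples
#' co <- generate_cohort(cohort_config(n = 200), seed = 1)
#' mean(co$morb_hypertension)
#' @export
generate_cohort <- function(config = cohort_config(), seed = config$seed) {
  validate_cohort_config(config)
  n <- as.integer(config$n)
  ids <- names(MORBIDITY_IDS)
  set.seed(seed)

  # demographics
  age <- rtruncnorm_inv(stats::runif(n), config$age_mean, config$age_sd,
                        config$age_bounds[1], config$age_bounds[2])
  sex <- ifelse(stats::runif(n) < config$male_frac, "M", "F")
  admission_year <- sample(config$years, n, replace = TRUE)

  # morbidity flags: hypertension first, then the remaining categories at
  # hypertension-conditional prevalences, sharing an optional latent frailty
  prev <- config$morbidity_prev[ids]
  f_htn <- stats::runif(n) < prev[["hypertension"]]
  flags <- matrix(FALSE, n, length(ids), dimnames = list(NULL, ids))
  flags[, "hypertension"] <- f_htn
  u_frail <- stats::rnorm(n)
  rho <- config$frailty_rho
  for (j in setdiff(ids, "hypertension")) {
    rr <- if (j %in% names(config$htn_assoc_rr)) config$htn_assoc_rr[[j]] else 1
    cp <- htn_conditional_prev(prev[[j]], rr, prev[["hypertension"]])
    pj <- ifelse(f_htn, cp$p1, cp$p0)
    z <- rho * u_frail + sqrt(1 - rho^2) * stats::rnorm(n)
    flags[, j] <- z < stats::qnorm(pj)
  }
  count <- rowSums(flags)

  # length of stay: exceedance of 7 days follows a log-binomial model with
  # the planted relative risks; within each side the stay is a discretized
  # truncated log-normal
  beta_los <- config$planted_los_effects[ids]
  mult <- exp(as.vector(flags %*% beta_los))
  # marginal exceedance anchored at the log-normal's own exceedance so the
  # overall stay distribution keeps its median
  target_marg <- 1 - stats::plnorm(7.5, config$los_meanlog, config$los_sdlog)
  p0 <- target_marg / mean(mult)
  p_gt7 <- pmin(p0 * mult, 0.99)
  exceed <- stats::runif(n) < p_gt7
  u_los <- stats::runif(n)
  lo <- config$los_bounds[1] - 0.5
  hi <- config$los_bounds[2] + 0.49
  x <- ifelse(exceed,
    rlnorm_trunc_inv(u_los, config$los_meanlog, config$los_sdlog, 7.5, hi),
    rlnorm_trunc_inv(u_los, config$los_meanlog, config$los_sdlog, lo, 7.5))
  los_days <- pmin(pmax(round(x), config$los_bounds[1]), config$los_bounds[2])

  # in-hospital death, assigned preferentially to short stays; the intercept
  # is solved so the realized-model mean matches the mortality fraction
  eta_los <- config$death_los_slope * (log(8) - log(los_days))
  alpha <- if (config$mortality_frac %in% c(0, 1)) {
    stats::qlogis(config$mortality_frac)
  } else {
    stats::uniroot(function(a) mean(stats::plogis(a + eta_los)) -
                     config$mortality_frac, c(-20, 20))$root
  }
  died <- stats::runif(n) < stats::plogis(alpha + eta_los)
  surgery <- stats::runif(n) < config$surgery_frac

  # costs: planted log-cost model + LOS link + noise
  b <- config$planted_log_effects
  lp <- b[["intercept"]] +
    b[["age"]] * (age - config$age_mean) +
    as.vector(flags %*% b[ids]) +
    b[["count_concavity"]] * pmax(count - 1, 0) +
    eval_los_link(config$cost_los_link, los_days)
  # residual noise truncated at +/- 3.5 SD: per-discharge administrative
  # costs are bounded in practice, and untruncated log-normal tails would
  # let a handful of extreme synthetic discharges dominate cohort means
  ptr <- stats::pnorm(c(-3.5, 3.5))
  znoise <- stats::qnorm(ptr[1] + stats::runif(n) * (ptr[2] - ptr[1]))
  lncost <- lp + config$cost_noise_sd * znoise
  cost_total <- round(exp(lncost), 2)

  # category split: Dirichlet perturbation around the baseline shares
  a <- config$split_alpha * config$category_split
  gd <- matrix(stats::rgamma(3L * n, shape = rep(a, each = n)), n, 3L)
  shares <- gd / rowSums(gd)
  cost_diagnostic <- round(cost_total * shares[, 1L], 2)
  cost_acute <- round(cost_total * shares[, 2L], 2)
  cost_rehab <- round(cost_total - cost_diagnostic - cost_acute, 2)

  # optional severity subgroup
  in_sub <- stats::runif(n) < config$severity_frac
  nihss_ge15 <- ifelse(in_sub, stats::runif(n) < config$nihss_p, NA)
  mrs_draw <- stats::runif(n) <
    stats::plogis(-0.3 + 0.8 * (log(los_days) - log(8)))
  mrs_poor <- ifelse(in_sub & !died, mrs_draw, NA)

  # diagnosis codes consistent with the flags (MRDx plus one safe code per
  # flagged category, ICD-9 or ICD-10 variant at random)
  codes <- rep(NA_character_, n)
  if (config$emit_codes) {
    mrdx <- sample(ICH_MRDX_CODES, n, replace = TRUE)
    variant <- matrix(stats::runif(n * length(ids)) < 0.5, n, length(ids))
    codes <- vapply(seq_len(n), function(i) {
      on <- which(flags[i, ])
      sec <- vapply(on, function(k) SAFE_ICD[[ids[k]]][1L + variant[i, k]],
                    character(1L))
      pack_codes(c(mrdx[i], sec), c(TRUE, rep(FALSE, length(sec))))
    }, character(1L))
  }

  out <- data.frame(
    id = seq_len(n), age = age, sex = sex, admission_year = admission_year,
    codes = codes, stringsAsFactors = FALSE
  )
  fl <- as.data.frame(flags)
  names(fl) <- paste0("morb_", ids)
  out <- cbind(out, fl)
  out$morb_count <- count
  out$morb_any <- count >= 1
  out$los_days <- los_days
  out$died <- died
  out$surgery <- surgery
  out$cost_total <- cost_total
  out$cost_diagnostic <- cost_diagnostic
  out$cost_acute <- cost_acute
  out$cost_rehab <- cost_rehab
  out$cost_year <- 2015L
  out$nihss_ge15 <- nihss_ge15
  out$mrs_poor <- mrs_poor
  attr(out, "config") <- config
  class(out) <- c("ich_cohort", "data.frame")
  out
}

#' Check that generated diagnosis codes reproduce the morbidity flags
#'
#' Re-classifies each record's packed ICD codes with
#' \code{\link{classify}} and compares the result to the stored flags.
#'
#' @param cohort a generated cohort (with \code{emit_codes = TRUE}).
#' @param catalog a \code{morbidity_catalog}.
#' @return logical vector, one entry per record; \code{TRUE} when the
#'   classification round-trips exactly.
#' @export
round_trip_codes <- function(cohort, catalog = morbidity_catalog()) {
  stopifnot(is.data.frame(cohort))
  if (anyNA(cohort$codes)) {
    stop("cohort was generated without codes (emit_codes = FALSE)",
         call. = FALSE)
  }
  ids <- names(MORBIDITY_IDS)
  reclass <- classify_cohort(cohort, catalog)
  stored <- as.matrix(cohort[, paste0("morb_", ids)])
  new <- as.matrix(reclass[, paste0("morb_", ids)])
  rowSums(stored != new) == 0L
}
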