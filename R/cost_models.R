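# Dollar-scale cost effect estimation: OLS on ln(cost) with
# heteroscedasticity-robust (HC1) standard errors, Duan smearing
# retransformation to the dollar scale, and percentile-bootstrap confidence
# intervals for the smeared average marginal effects.

#' Duan smearing factor
#'
#' The nonparametric retransformation factor: the mean of the exponentiated
#' residuals of a log-scale regression. Equals 1 when all residuals are 0;
#' multiplying log-scale predictions' exponentials by this factor makes the
#' mean smeared fitted cost match the mean observed cost without assuming
#' normal errors.
#'
#' @param residuals numeric residuals on the ln-cost scale.
#' @return the smearing factor (dimensionless, >= 0).
#' @examples
#' smear_factor(c(log(2), log(0.5)))  # 1.25
#' @export
smear_factor <- function(residuals) {
  mean(exp(residuals))
}

# Run expr with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# HC1 robust Wald p-values for an lm/glm fit.
robust_wald <- function(fit, type = "HC1") {
  V <- sandwich::vcovHC(fit, type = type)
  b <- stats::coef(fit)
  se <- sqrt(diag(V))
  z <- b / se
  list(se = se, p = 2 * stats::pnorm(-abs(z)), vcov = V)
}

# Smeared average marginal dollar effect of one covariate: the cohort-average
# difference between smeared predicted costs with the covariate set to
# (x + 1) for numeric covariates, or to 1 vs 0 for binary ones, all other
# covariates held at their observed values.
smeared_ame <- function(fit, data, covariate, smear, binary,
                        at_means = FALSE) {
  if (at_means) {
    data <- as.data.frame(lapply(data, function(x) mean(as.numeric(x))))
  }
  d1 <- data; d0 <- data
  if (binary) {
    d1[[covariate]] <- 1
    d0[[covariate]] <- 0
  } else {
    d1[[covariate]] <- d0[[covariate]] + 1
  }
  mean(smear * exp(stats::predict(fit, newdata = d1))) -
    mean(smear * exp(stats::predict(fit, newdata = d0)))
}

is_binary_col <- function(x) {
  is.logical(x) || (is.numeric(x) && all(x %in% c(0, 1)))
}

#' Fit a log-cost regression with smeared dollar-scale effects
#'
#' Ordinary least squares on \code{ln(cost)} with HC1 sandwich standard
#' errors. Each covariate's effect is retransformed to the dollar scale by
#' Duan smearing: the dollar change is the cohort-average difference in
#' smeared predicted cost with the covariate toggled (binary) or incremented
#' by one unit (numeric), all other covariates at their observed values
#' (an average marginal effect). Confidence intervals for the dollar changes
#' are percentile bootstrap over the whole procedure.
#'
#' @param cohort data frame; costs must be positive.
#' @param covariates character vector of covariate column names. Logical or
#'   0/1 columns are treated as binary exposures.
#' @param outcome cost column name (default \code{"cost_total"}).
#' @param n_boot bootstrap replicates for the dollar-scale CI (0 skips the
#'   CI; they are then \code{NA}).
#' @param boot_seed seed for the bootstrap stream (the caller's RNG state is
#'   left untouched).
#' @param conf confidence level.
#' @param dollar_scale how the smeared dollar change is aggregated:
#'   \code{"average-marginal"} (default; cohort-average difference in
#'   smeared predictions) or \code{"at-means"} (difference evaluated at the
#'   covariate means).
#' @return object of class \code{cost_fit}: list with \code{estimates} (a
#'   data frame with one row per covariate: \code{beta_log},
#'   \code{se_robust}, \code{p_value}, \code{dollar_change}, \code{ci_low},
#'   \code{ci_high}), \code{smear}, the underlying \code{model}, \code{n},
#'   and the bootstrap draws (\code{boot}) when computed.
#' @examples
#' co <- generate_cohort(cohort_config(n = 500), seed = 1)
#' fit <- fit_log_cost(co, c("morb_hypertension", "age"), n_boot = 0)
#' fit$estimates
#' @export
fit_log_cost <- function(cohort, covariates, outcome = "cost_total",
                         n_boot = 200, boot_seed = 1, conf = 0.95,
                         dollar_scale = c("average-marginal", "at-means")) {
  dollar_scale <- match.arg(dollar_scale)
  at_means <- dollar_scale == "at-means"
  stopifnot(is.data.frame(cohort), length(covariates) >= 1)
  missing_cols <- setdiff(c(outcome, covariates), names(cohort))
  if (length(missing_cols)) {
    stop("columns not found in cohort: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  y <- cohort[[outcome]]
  if (any(!is.finite(y)) || any(y <= 0)) {
    stop("all `", outcome, "` values must be positive and finite",
         call. = FALSE)
  }
  dat <- cohort[, covariates, drop = FALSE]
  dat <- as.data.frame(lapply(dat, function(x) {
    if (is.logical(x)) as.numeric(x) else x
  }))
  dat$.lny <- log(y)
  fml <- stats::as.formula(paste(".lny ~", paste(covariates, collapse = " + ")))

  fit_once <- function(d) {
    fit <- stats::lm(fml, data = d)
    X <- stats::model.matrix(fit)
    if (qr(X)$rank < ncol(X)) {
      bad <- names(which(is.na(stats::coef(fit))))
      stop("design matrix is rank deficient; collinear columns: ",
           paste(if (length(bad)) bad else "unknown", collapse = ", "),
           call. = FALSE)
    }
    fit
  }

  fit <- fit_once(dat)
  rw <- robust_wald(fit)
  smear <- smear_factor(stats::residuals(fit))
  binary <- vapply(covariates, function(cv) is_binary_col(cohort[[cv]]),
                   logical(1L))
  dollar <- vapply(covariates, function(cv) {
    smeared_ame(fit, dat, cv, smear, binary[[cv]], at_means)
  }, numeric(1L))

  boot <- NULL
  ci_low <- ci_high <- rep(NA_real_, length(covariates))
  if (n_boot > 0) {
    n <- nrow(dat)
    boot <- with_seed(boot_seed, {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        db <- dat[idx, , drop = FALSE]
        fb <- stats::lm(fml, data = db)
        sb <- smear_factor(stats::residuals(fb))
        vapply(covariates, function(cv) {
          smeared_ame(fb, db, cv, sb, binary[[cv]], at_means)
        }, numeric(1L))
      }, numeric(length(covariates)))
    })
    boot <- matrix(boot, nrow = length(covariates))
    rownames(boot) <- covariates
    alpha <- (1 - conf) / 2
    qs <- apply(boot, 1L, stats::quantile, probs = c(alpha, 1 - alpha),
                names = FALSE)
    ci_low <- qs[1L, ]
    ci_high <- qs[2L, ]
  }

  est <- data.frame(
    covariate = covariates,
    beta_log = stats::coef(fit)[covariates],
    se_robust = rw$se[covariates],
    p_value = rw$p[covariates],
    dollar_change = dollar,
    ci_low = ci_low,
    ci_high = ci_high,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(
    list(estimates = est, smear = smear, model = fit, n = nrow(dat),
         outcome = outcome, r_squared = summary(fit)$r.squared,
         mean_observed = mean(y),
         mean_smeared_fitted = mean(smear * exp(stats::fitted(fit))),
         boot = boot),
    class = "cost_fit"
  )
}

#' @export
print.cost_fit <- function(x, ...) {
  cat("Log-cost regression (", x$outcome, "), n = ", x$n,
      ", smear factor = ", round(x$smear, 4), "\n", sep = "")
  print(transform(x$estimates,
                  beta_log = round(beta_log, 4),
                  se_robust = round(se_robust, 4),
                  p_value = signif(p_value, 3),
                  dollar_change = round(dollar_change, 2),
                  ci_low = round(ci_low, 2),
                  ci_high = round(ci_high, 2)))
  invisible(x)
}

#' Age-adjusted cost increase per added morbidity
#'
#' Fits \code{ln(cost) ~ morbidity count + age} and reports the smeared
#' dollar change per one additional morbidity category.
#'
#' @inheritParams fit_log_cost
#' @param count_col morbidity count column.
#' @param age_col age column.
#' @return a \code{cost_fit}; the count estimate is the first row of
#'   \code{estimates}.
#' @export
fit_morbidity_count_cost <- function(cohort, outcome = "cost_total",
                                     count_col = "morb_count",
                                     age_col = "age", n_boot = 200,
                                     boot_seed = 1, conf = 0.95) {
  fit_log_cost(cohort, c(count_col, age_col), outcome = outcome,
               n_boot = n_boot, boot_seed = boot_seed, conf = conf)
}

#' Robust Wald association test between a binary exposure and log cost
#'
#' Fits an age-adjusted log-cost regression and returns the HC1 robust Wald
#' p-value for the exposure coefficient.
#'
#' @inheritParams fit_log_cost
#' @param exposure binary exposure column.
#' @param adjust additional adjustment columns (default age).
#' @return the two-sided p-value.
#' @export
association_test <- function(cohort, exposure, outcome = "cost_total",
                             adjust = "age") {
  x <- cohort[[exposure]]
  if (is.null(x)) stop("exposure column not found: ", exposure, call. = FALSE)
  if (length(unique(x[!is.na(x)])) < 2L) {
    stop("exposure '", exposure, "' has a single level", call. = FALSE)
  }
  fit <- fit_log_cost(cohort, c(exposure, adjust), outcome = outcome,
                      n_boot = 0)
  fit$estimates$p_value[fit$estimates$covariate == exposure]
}

#' Consumer Price Index series
#'
#' A CPI series is a named mapping of calendar year to index value, used to
#' express historical costs in reference-year dollars.
#'
#' @param years integer years.
#' @param index positive index values aligned with \code{years}.
#' @return object of class \code{cpi_series}.
#' @export
cpi_series <- function(years, index) {
  stopifnot(length(years) == length(index))
  if (any(!is.finite(index)) || any(index <= 0)) {
    stop("CPI index values must be positive", call. = FALSE)
  }
  if (anyDuplicated(years)) stop("duplicate years in CPI series", call. = FALSE)
  structure(stats::setNames(as.numeric(index), as.integer(years)),
            class = "cpi_series")
}

#' @rdname cpi_series
#' @param path two-column CSV (\code{year,index}) to read a series from.
#' @export
read_cpi_series <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(d) < 2L) stop("CPI file must have two columns: year, index",
                         call. = FALSE)
  cpi_series(d[[1L]], d[[2L]])
}

#' Inflate a cost between calendar years
#'
#' Rescales an amount by the ratio of CPI index values:
#' \code{amount * cpi[to_year] / cpi[from_year]}. Chaining through an
#' intermediate year is equivalent to inflating directly.
#'
#' @param amount numeric cost(s).
#' @param from_year,to_year calendar years present in the series.
#' @param cpi a \code{cpi_series}.
#' @return inflated amount(s).
#' @examples
#' cpi <- cpi_series(2008:2015, seq(100, 114, 2))
#' inflate(100, 2008, 2015, cpi)
#' @export
inflate <- function(amount, from_year, to_year, cpi) {
  stopifnot(inherits(cpi, "cpi_series"))
  key_from <- as.character(as.integer(from_year))
  key_to <- as.character(as.integer(to_year))
  missing_years <- setdiff(unique(c(key_from, key_to)), names(cpi))
  if (length(missing_years)) {
    stop("year(s) absent from CPI series: ",
         paste(missing_years, collapse = ", "), call. = FALSE)
  }
  unname(amount * unclass(cpi)[key_to] / unclass(cpi)[key_from])
}
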