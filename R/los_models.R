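# Relative-risk models for dichotomized outcomes (prolonged stay, death)
# and calendar-year prevalence trend tests.

#' Add the prolonged-stay indicator to a cohort
#'
#' Longer stay is defined as strictly more than \code{threshold} days
#' (a stay of exactly 7 days counts as short).
#'
#' @param cohort cohort data frame with \code{los_days}.
#' @param threshold days; default 7.
#' @return the cohort with a logical \code{los_gt7} column.
#' @export
add_long_stay <- function(cohort, threshold = 7) {
  stopifnot("los_days" %in% names(cohort))
  cohort$los_gt7 <- cohort$los_days > threshold
  cohort
}

as01 <- function(x) {
  if (is.logical(x)) return(as.numeric(x))
  if (is.numeric(x) && all(x %in% c(0, 1))) return(x)
  stop("column is not binary (logical or 0/1)", call. = FALSE)
}

#' Relative risk from a log-link binomial model
#'
#' Estimates the relative risk of a binary outcome for a binary exposure,
#' optionally adjusted for covariates, from a binomial GLM with log link
#' ("ordinary binomial regression" on the risk-ratio scale). When the
#' log-binomial fit does not converge -- common at high exposure prevalence
#' -- the model falls back to a modified Poisson regression with robust
#' (sandwich) variance, flagged in \code{model_used}. The Wald 95\% CI uses
#' the HC0 sandwich variance in either case.
#'
#' @param cohort data frame.
#' @param outcome binary outcome column; \code{"los_gt7"} is derived from
#'   \code{los_days} on the fly if absent.
#' @param exposure binary exposure column (must differ from the outcome).
#' @param adjust character vector of adjustment columns (may be empty).
#' @param conf confidence level.
#' @return object of class \code{rr_result}: list with \code{rr},
#'   \code{ci_low}, \code{ci_high}, \code{p_value}, \code{exposure},
#'   \code{adjusted_for}, \code{model_used} (\code{"log-binomial"} or
#'   \code{"poisson-robust"}), and the underlying \code{model}.
#' @examples
#' co <- add_long_stay(generate_cohort(cohort_config(n = 500), seed = 1))
#' fit_rr(co, "los_gt7", "morb_hypertension", adjust = "age")
#' @export
fit_rr <- function(cohort, outcome, exposure, adjust = character(),
                   conf = 0.95) {
  if (identical(outcome, exposure)) {
    stop("outcome and exposure must be distinct columns", call. = FALSE)
  }
  if (outcome == "los_gt7" && !"los_gt7" %in% names(cohort)) {
    cohort <- add_long_stay(cohort)
  }
  cols <- c(outcome, exposure, adjust)
  missing_cols <- setdiff(cols, names(cohort))
  if (length(missing_cols)) {
    stop("columns not found in cohort: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  y <- as01(cohort[[outcome]])
  x <- as01(cohort[[exposure]])
  if (length(unique(y)) < 2L) stop("outcome has a single level", call. = FALSE)
  if (length(unique(x)) < 2L) stop("exposure has a single level", call. = FALSE)

  dat <- data.frame(.y = y, .x = x)
  for (a in adjust) {
    dat[[a]] <- if (is.logical(cohort[[a]])) as.numeric(cohort[[a]])
                else cohort[[a]]
  }
  rhs <- paste(c(".x", adjust), collapse = " + ")
  fml <- stats::as.formula(paste(".y ~", rhs))

  start <- c(log(max(mean(y), 1e-6)), rep(0, length(adjust) + 1L))
  logbin <- tryCatch(
    suppressWarnings(stats::glm(fml, data = dat,
                                family = stats::binomial(link = "log"),
                                start = start)),
    error = function(e) NULL
  )
  if (!is.null(logbin) && logbin$converged &&
      all(is.finite(stats::coef(logbin)))) {
    fit <- logbin
    model_used <- "log-binomial"
  } else {
    fit <- tryCatch(
      suppressWarnings(stats::glm(fml, data = dat,
                                  family = stats::poisson(link = "log"))),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$converged) {
      stop("neither the log-binomial nor the modified Poisson model ",
           "converged for exposure '", exposure, "'", call. = FALSE)
    }
    model_used <- "poisson-robust"
  }

  V <- sandwich::vcovHC(fit, type = "HC0")
  b <- unname(stats::coef(fit)[".x"])
  se <- sqrt(V[".x", ".x"])
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  structure(
    list(exposure = exposure, rr = exp(b),
         ci_low = exp(b - zq * se), ci_high = exp(b + zq * se),
         p_value = 2 * stats::pnorm(-abs(b / se)),
         adjusted_for = adjust, model_used = model_used, model = fit),
    class = "rr_result"
  )
}

#' @export
print.rr_result <- function(x, ...) {
  cat(sprintf("RR (%s) = %.3f, 95%% CI %.3f-%.3f, p = %.4g [%s%s]\n",
              x$exposure, x$rr, x$ci_low, x$ci_high, x$p_value, x$model_used,
              if (length(x$adjusted_for))
                paste0("; adjusted for ",
                       paste(x$adjusted_for, collapse = ", "))
              else ", unadjusted"))
  invisible(x)
}

#' Calendar-year trend test for a binary characteristic
#'
#' Logistic regression of the characteristic on calendar year; reports the
#' direction of the slope and the Wald p-value, as used to flag
#' characteristics that increased or decreased over the study decade.
#'
#' @param cohort data frame.
#' @param characteristic binary column to test.
#' @param year_col calendar-year column.
#' @return list with \code{direction} (\code{"increase"}/\code{"decrease"}),
#'   \code{slope} (log-odds per year), and \code{p_value}.
#' @export
trend_test <- function(cohort, characteristic, year_col = "admission_year") {
  y <- as01(cohort[[characteristic]])
  yr <- cohort[[year_col]]
  if (length(unique(yr)) < 2L) {
    stop("trend test needs at least two distinct calendar years",
         call. = FALSE)
  }
  if (length(unique(y)) < 2L) {
    stop("characteristic '", characteristic, "' is constant; trend fit is ",
         "degenerate", call. = FALSE)
  }
  fit <- stats::glm(y ~ yr, family = stats::binomial())
  sm <- summary(fit)$coefficients
  list(direction = if (sm["yr", "Estimate"] >= 0) "increase" else "decrease",
       slope = unname(sm["yr", "Estimate"]),
       p_value = unname(sm["yr", "Pr(>|z|)"]))
}
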