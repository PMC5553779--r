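# The curvilinear relationship between ln(cost) and length of stay:
# restricted cubic spline fit, weekly-knot linear spline with slope and
# slope-change tests, and cost summaries by length-of-stay window.

#' Restricted cubic spline basis
#'
#' Truncated-power restricted cubic spline basis in Harrell's normalized
#' form: cubic between interior knots, constrained to be linear beyond the
#' boundary knots. For k knots the basis has k - 1 columns (the linear term
#' plus k - 2 nonlinear terms).
#'
#' @param x numeric vector.
#' @param knots increasing knot locations (length >= 3).
#' @return matrix with \code{length(knots) - 1} columns.
#' @export
rcs_basis <- function(x, knots) {
  k <- length(knots)
  if (k < 3L) stop("restricted cubic spline needs at least 3 knots",
                   call. = FALSE)
  if (is.unsorted(knots, strictly = TRUE)) {
    stop("knots must be strictly increasing", call. = FALSE)
  }
  tk <- knots[k]; tk1 <- knots[k - 1L]; t1 <- knots[1L]
  norm2 <- (tk - t1)^2
  pp <- function(u) pmax(u, 0)^3
  out <- matrix(0, length(x), k - 1L)
  out[, 1L] <- x
  for (j in seq_len(k - 2L)) {
    tj <- knots[j]
    out[, j + 1L] <- (pp(x - tj) -
                        pp(x - tk1) * (tk - tj) / (tk - tk1) +
                        pp(x - tk) * (tk1 - tj) / (tk - tk1)) / norm2
  }
  colnames(out) <- c("x", paste0("x", seq_len(k - 2L), "'"))
  out
}

# Harrell's default knot placement quantiles for a given knot count.
rcs_knot_quantiles <- function(n_knots) {
  switch(as.character(n_knots),
    "3" = c(0.10, 0.50, 0.90),
    "4" = c(0.05, 0.35, 0.65, 0.95),
    "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
    "6" = c(0.05, 0.23, 0.41, 0.59, 0.77, 0.95),
    "7" = c(0.025, 0.1833, 0.3417, 0.5, 0.6583, 0.8167, 0.975),
    stop("n_knots must be between 3 and 7", call. = FALSE))
}

#' Fit a restricted cubic spline of ln(cost) on length of stay
#'
#' Unadjusted (optionally age-adjusted) OLS of \code{ln(cost)} on a
#' restricted cubic spline in days of stay, with knots at Harrell's default
#' quantiles of the observed stays.
#'
#' @param cohort data frame with \code{los_days} and the outcome column.
#' @param n_knots number of knots (3--7; default 5).
#' @param outcome cost column (default \code{"cost_total"}).
#' @param adjust_age also include a linear age term.
#' @return object of class \code{spline_fit}: list with \code{knots},
#'   \code{coefficients}, \code{r2}, \code{fitted_curve} (a function mapping
#'   days of stay to predicted ln(cost), at mean age when adjusted), and the
#'   underlying \code{model}.
#' @examples
#' co <- generate_cohort(cohort_config(n = 500), seed = 1)
#' fit_rcs(co)$r2
#' @export
fit_rcs <- function(cohort, n_knots = 5, outcome = "cost_total",
                    adjust_age = FALSE) {
  los <- cohort$los_days
  y <- log(cohort[[outcome]])
  knots <- unique(stats::quantile(los, rcs_knot_quantiles(n_knots),
                                  type = 7, names = FALSE))
  if (length(unique(los)) < n_knots || length(knots) < 3L) {
    stop("too few distinct length-of-stay values for ", n_knots, " knots",
         call. = FALSE)
  }
  B <- rcs_basis(los, knots)
  dat <- data.frame(.y = y, B, check.names = FALSE)
  age0 <- if (adjust_age) mean(cohort$age) else NULL
  if (adjust_age) dat$.age <- cohort$age
  fml <- stats::as.formula(paste(".y ~",
    paste(sprintf("`%s`", colnames(B)), collapse = " + "),
    if (adjust_age) "+ .age" else ""))
  fit <- stats::lm(fml, data = dat)
  cf <- stats::coef(fit)
  names(cf) <- gsub("`", "", names(cf), fixed = TRUE)
  curve_fun <- function(los_new) {
    Bn <- rcs_basis(los_new, knots)
    eta <- cf[1L] + as.vector(Bn %*% cf[colnames(Bn)])
    if (adjust_age) eta <- eta + cf[".age"] * age0
    eta
  }
  structure(
    list(knots = knots, coefficients = cf, r2 = summary(fit)$r.squared,
         fitted_curve = curve_fun, model = fit, n = length(y),
         adjusted_for_age = adjust_age),
    class = "spline_fit"
  )
}

#' @export
print.spline_fit <- function(x, ...) {
  cat("Restricted cubic spline of ln(cost) on length of stay\n")
  cat("  knots (days):", paste(round(x$knots, 1), collapse = ", "), "\n")
  cat(sprintf("  n = %d, R^2 = %.3f%s\n", x$n, x$r2,
              if (x$adjusted_for_age) " (age-adjusted)" else ""))
  invisible(x)
}

#' Weekly linear spline of ln(cost) on length of stay
#'
#' Continuous piecewise-linear model with knots at weekly boundaries
#' (7, 14, 21, ... days). Reports, for each interval, the daily slope of
#' ln(cost), a robust (HC1) Wald test of the slope against zero, and a
#' robust test of the change in slope relative to the previous interval.
#' By default knots run weekly across the observed stays and trailing
#' sparse intervals (fewer than \code{min_per_interval} stays) are merged
#' into the final open interval, so every estimated slope is supported by
#' data. An interval containing no observations has its tests reported as
#' \code{NA} while the rest of the fit proceeds.
#'
#' @param cohort data frame with \code{los_days} and the outcome.
#' @param knots increasing knot days; intervals are \code{(0, k1], (k1, k2],
#'   ..., (k_last, max]}. Default: weekly knots with sparse-tail merging.
#' @param min_per_interval minimum stays per interval when choosing the
#'   default knots.
#' @param outcome cost column.
#' @return object of class \code{interval_slopes}: data frame with one row
#'   per interval (\code{interval}, \code{n}, \code{slope}, \code{p_within},
#'   \code{p_vs_previous}), plus the \code{model} and robust \code{vcov} as
#'   attributes.
#' @export
fit_weekly_linear_spline <- function(cohort, knots = NULL,
                                     min_per_interval = 10,
                                     outcome = "cost_total") {
  los <- cohort$los_days
  y <- log(cohort[[outcome]])
  if (is.null(knots)) {
    cand <- seq(7, max(los) - 1, by = 7)
    keep <- logical(length(cand))
    lo <- 0
    for (i in seq_along(cand)) {
      # keep a knot only if the interval it closes is populated and enough
      # stays remain beyond it to estimate the next slope
      if (sum(los > lo & los <= cand[i]) >= min_per_interval &&
          sum(los > cand[i]) >= min_per_interval) {
        keep[i] <- TRUE
        lo <- cand[i]
      }
    }
    knots <- cand[keep]
    if (length(knots) == 0L) {
      stop("data must span at least two weekly intervals", call. = FALSE)
    }
  }
  if (max(los) <= knots[1L]) {
    stop("data must span at least two weekly intervals", call. = FALSE)
  }
  knots <- knots[knots < max(los)]
  m <- length(knots)
  X <- cbind(los, vapply(knots, function(k) pmax(los - k, 0),
                         numeric(length(los))))
  colnames(X) <- c("slope1", paste0("dslope", seq_len(m)))
  dat <- data.frame(.y = y, X)
  fit <- stats::lm(.y ~ ., data = dat)
  V <- sandwich::vcovHC(fit, type = "HC1")
  cf <- stats::coef(fit)

  breaks <- c(0, knots, max(los))
  n_int <- m + 1L
  counts <- as.integer(table(cut(los, breaks, include.lowest = FALSE)))
  labs <- sprintf("(%g,%g]", breaks[-length(breaks)], breaks[-1L])

  # slope of interval i is the cumulative sum of the change coefficients
  slope <- p_within <- p_change <- rep(NA_real_, n_int)
  coef_names <- c("slope1", paste0("dslope", seq_len(m)))
  for (i in seq_len(n_int)) {
    if (counts[i] == 0L) next
    L <- as.numeric(names(cf) %in% coef_names[seq_len(i)])
    slope[i] <- sum(L * cf)
    se <- sqrt(drop(t(L) %*% V %*% L))
    p_within[i] <- 2 * stats::pnorm(-abs(slope[i] / se))
    if (i > 1L && counts[i - 1L] > 0L) {
      d <- coef_names[i]
      p_change[i] <- 2 * stats::pnorm(-abs(cf[d] / sqrt(V[d, d])))
    }
  }
  out <- data.frame(interval = labs, n = counts, slope = slope,
                    p_within = p_within, p_vs_previous = p_change,
                    stringsAsFactors = FALSE)
  attr(out, "model") <- fit
  attr(out, "vcov") <- V
  class(out) <- c("interval_slopes", "data.frame")
  out
}

#' @export
print.interval_slopes <- function(x, ...) {
  cat("Weekly linear spline of ln(cost) on length of stay\n")
  print.data.frame(transform(as.data.frame(x),
                             slope = round(slope, 4),
                             p_within = signif(p_within, 3),
                             p_vs_previous = signif(p_vs_previous, 3)))
  invisible(x)
}

#' Cost summaries by length-of-stay window
#'
#' Summarizes total cost over records whose length of stay falls within each
#' day window (windows may be nested, e.g. first day / first month / first
#' year). An empty window yields an \code{n = 0} row with \code{NA}
#' statistics.
#'
#' @param cohort data frame with \code{los_days} and the outcome.
#' @param windows list of two-element day ranges \code{c(lo, hi)};
#'   membership is \code{lo <= los_days <= hi}.
#' @param outcome cost column.
#' @return data frame with one row per window: \code{window}, \code{n},
#'   \code{median}, \code{q25}, \code{q75}, \code{mean}, \code{sd},
#'   \code{min}, \code{max}.
#' @examples
#' co <- generate_cohort(cohort_config(n = 500), seed = 1)
#' cost_by_los_window(co)
#' @export
cost_by_los_window <- function(cohort,
                               windows = list(c(0, 1), c(0, 30), c(0, 365)),
                               outcome = "cost_total") {
  rows <- lapply(windows, function(w) {
    stopifnot(length(w) == 2L, w[1L] <= w[2L])
    v <- cohort[[outcome]][cohort$los_days >= w[1L] & cohort$los_days <= w[2L]]
    if (length(v) == 0L) {
      data.frame(window = sprintf("%g-%g days", w[1L], w[2L]), n = 0L,
                 median = NA_real_, q25 = NA_real_, q75 = NA_real_,
                 mean = NA_real_, sd = NA_real_, min = NA_real_,
                 max = NA_real_)
    } else {
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      data.frame(window = sprintf("%g-%g days", w[1L], w[2L]),
                 n = length(v), median = q[2L], q25 = q[1L], q75 = q[3L],
                 mean = mean(v), sd = stats::sd(v), min = min(v),
                 max = max(v))
    }
  })
  do.call(rbind, rows)
}
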