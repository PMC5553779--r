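# Cohort ingest, validation and Table-2-style summarization.
#
# Cohorts are exchanged as comma-separated UTF-8 text with a header. Column
# dictionary (the generator writes the same layout): id, age (years), sex
# ("M"/"F"), admission_year, codes (semicolon-packed ICD codes, MRDx marked
# with "*"), los_days, died, surgery, cost_total/cost_diagnostic/cost_acute/
# cost_rehab (positive, in cost_year dollars), cost_year, and optional
# nihss_ge15 / mrs_poor.

REQUIRED_COLS <- c("age", "sex", "los_days", "died", "surgery",
                   "cost_total", "cost_year")

#' Write a cohort to CSV
#'
#' @param cohort cohort data frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Ingest a discharge-records file
#'
#' Reads a delimited discharge file, applies the study exclusions, and
#' returns typed records plus an ingest report. Exclusions, in order: rows
#' with missing or nonpositive total cost (cost not estimable), and patients
#' younger than 18 years. Rows with malformed required fields are skipped
#' and logged, or fatal under \code{strict}. When the file carries a
#' \code{codes} column but no morbidity flags, records are classified
#' against the catalog on the fly.
#'
#' @param path CSV file path.
#' @param strict fail on any malformed row instead of skipping it.
#' @param classify_codes derive morbidity flags from \code{codes} when flag
#'   columns are absent.
#' @param catalog a \code{morbidity_catalog}.
#' @param verbose log one line of counts to stderr.
#' @return list with \code{cohort} (data frame) and \code{report} (class
#'   \code{ingest_report}: \code{n_read}, \code{n_excluded_missing_cost},
#'   \code{n_excluded_age}, \code{n_malformed}, \code{n_retained},
#'   \code{notes}).
#' @export
ingest <- function(path, strict = FALSE, classify_codes = TRUE,
                   catalog = morbidity_catalog(), verbose = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("empty input file: ", path, call. = FALSE)
  missing_cols <- setdiff(REQUIRED_COLS, names(raw))
  if (length(missing_cols)) {
    stop("input header lacks required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n_read <- nrow(raw)
  notes <- character()

  # malformed rows: required numeric fields unparseable / missing (cost_total
  # missing is a counted exclusion, not a malformation)
  num_ok <- function(x) !is.na(suppressWarnings(as.numeric(x)))
  ok <- num_ok(raw$age) & num_ok(raw$los_days) & nzchar(as.character(raw$sex))
  if (any(!ok)) {
    lines <- which(!ok) + 1L  # header is line 1
    msg <- paste0("malformed row(s) at line(s): ",
                  paste(utils::head(lines, 10L), collapse = ", "),
                  if (length(lines) > 10L) ", ...")
    if (strict) stop(msg, call. = FALSE)
    notes <- c(notes, msg)
  }
  n_malformed <- sum(!ok)
  d <- raw[ok, , drop = FALSE]
  d$age <- as.numeric(d$age)
  d$los_days <- as.numeric(d$los_days)
  d$cost_total <- suppressWarnings(as.numeric(d$cost_total))

  # exclusion 1: cost not available / nonpositive
  bad_cost <- is.na(d$cost_total) | d$cost_total <= 0
  n_cost <- sum(bad_cost)
  d <- d[!bad_cost, , drop = FALSE]
  # exclusion 2: minors
  minor <- d$age < 18
  n_age <- sum(minor)
  d <- d[!minor, , drop = FALSE]

  for (cl in c("died", "surgery", "nihss_ge15", "mrs_poor")) {
    if (cl %in% names(d)) d[[cl]] <- as.logical(d[[cl]])
  }
  if (classify_codes && "codes" %in% names(d) &&
      !"morb_hypertension" %in% names(d) && nrow(d) > 0L) {
    d <- cbind(d, classify_cohort(d, catalog))
  }
  rownames(d) <- NULL

  report <- structure(
    list(n_read = n_read, n_excluded_missing_cost = n_cost,
         n_excluded_age = n_age, n_malformed = n_malformed,
         n_retained = nrow(d), notes = notes),
    class = "ingest_report"
  )
  if (verbose) {
    message(sprintf(
      "ingest: read=%d excluded_missing_cost=%d excluded_age=%d malformed=%d retained=%d",
      n_read, n_cost, n_age, n_malformed, nrow(d)))
  }
  list(cohort = d, report = report)
}

#' @export
print.ingest_report <- function(x, ...) {
  cat(sprintf(paste0("Ingest report: %d read, %d excluded (missing cost), ",
                     "%d excluded (age < 18), %d malformed, %d retained\n"),
              x$n_read, x$n_excluded_missing_cost, x$n_excluded_age,
              x$n_malformed, x$n_retained))
  for (nt in x$notes) cat(" ", nt, "\n")
  invisible(x)
}

#' Summarize a cohort (sample-characteristics table)
#'
#' Median (min--max) for continuous fields, percentages for binary ones, and
#' per-category morbidity prevalences. Percentages are kept unrounded
#' internally; the print method rounds to whole numbers for display.
#'
#' @param cohort cohort data frame.
#' @return object of class \code{cohort_summary} (a list).
#' @export
summarize_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort), nrow(cohort) >= 1L)
  mmm <- function(x) c(median = stats::median(x), min = min(x), max = max(x))
  ids <- names(MORBIDITY_IDS)
  morb_cols <- paste0("morb_", ids)
  have_morb <- all(morb_cols %in% names(cohort))
  s <- list(
    n = nrow(cohort),
    pct_male = 100 * mean(cohort$sex == "M"),
    age = mmm(cohort$age),
    los_days = mmm(cohort$los_days),
    pct_died = 100 * mean(cohort$died),
    pct_surgery = 100 * mean(cohort$surgery),
    cost_total = mmm(cohort$cost_total),
    morbidity_pct = if (have_morb) {
      stats::setNames(vapply(morb_cols, function(cl) 100 * mean(cohort[[cl]]),
                             numeric(1L)), ids)
    } else NULL,
    pct_any_morbidity = if (have_morb) 100 * mean(cohort$morb_count >= 1)
                        else NULL
  )
  class(s) <- "cohort_summary"
  s
}

#' @export
print.cohort_summary <- function(x, ...) {
  f <- function(v) sprintf("%g (%g-%g)", round(v[1], 1), round(v[2], 1),
                           round(v[3], 1))
  cat("Cohort summary (n =", x$n, ")\n")
  cat(sprintf("  Sex (%% male)            %d\n", round(x$pct_male)))
  cat("  Age (years)            ", f(x$age), "\n")
  cat("  Length of stay (days)  ", f(x$los_days), "\n")
  cat(sprintf("  Died in hospital (%%)    %d\n", round(x$pct_died)))
  cat(sprintf("  Had surgery (%%)         %d\n", round(x$pct_surgery)))
  cat("  Total cost (USD)       ", f(round(x$cost_total, 2)), "\n")
  if (!is.null(x$morbidity_pct)) {
    cat("  Morbidities at admission (%):\n")
    for (nm in names(x$morbidity_pct)) {
      cat(sprintf("    %-26s %d\n", MORBIDITY_IDS[[nm]],
                  round(x$morbidity_pct[[nm]])))
    }
    cat(sprintf("    %-26s %d\n", "Overall (any)",
                round(x$pct_any_morbidity)))
  }
  invisible(x)
}
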