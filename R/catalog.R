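# Canonical category identifiers, in catalog order. Display names are the
# stanza headers of the catalog file; ids are used as cohort column suffixes.
MORBIDITY_IDS <- c(
  "hypertension"              = "Hypertension",
  "secondary_cerebrovascular" = "Secondary Cerebrovascular Disease",
  "diabetes"                  = "Diabetes",
  "cardiac"                   = "Cardiac Disorders",
  "chronic_pulmonary"         = "Chronic Pulmonary Disease",
  "malignancy"                = "Malignancy or Tumour",
  "dementia"                  = "Dementia",
  "mood"                      = "Mood Disorders",
  "renal"                     = "Renal Disease",
  "peripheral_vascular"       = "Peripheral Vascular Disease",
  "liver"                     = "Liver Disease",
  "rheumatic"                 = "Rheumatic Disease",
  "peptic_ulcer"              = "Peptic Ulcer Disease"
)

#' Normalize an ICD code string
#'
#' Administrative extracts vary in case and whitespace; codes are compared in
#' a canonical form: whitespace stripped, letters upper-cased. The decimal
#' point is kept -- subcategory matching requires it.
#'
#' @param code character vector of raw ICD-9-CM or ICD-10-CA codes.
#' @return character vector of normalized codes.
#' @export
normalize_icd <- function(code) {
  toupper(gsub("[[:space:]]+", "", as.character(code)))
}

# Scheme of a normalized code or pattern stem. Digits (incl. leading zeros)
# and the ICD-9-CM supplementary V codes are ICD-9; E codes are ICD-9 only in
# the external-cause block (E800+), otherwise ICD-10 (E10-E14 diabetes);
# remaining letters are ICD-10.
icd_scheme <- function(code) {
  first <- substr(code, 1L, 1L)
  num <- suppressWarnings(as.numeric(sub("^[A-Z]+", "", sub("\\..*$", "", code))))
  ifelse(grepl("^[0-9]", code), "ICD9",
    ifelse(first == "V", "ICD9",
      ifelse(first == "E" & !is.na(num) & num >= 800, "ICD9", "ICD10")))
}

# Split a normalized code/bound into alpha prefix, integer stem value, and
# decimal suffix string ("" if none).
icd_parts <- function(code) {
  prefix <- sub("^([A-Z]*).*$", "\\1", code)
  rest <- substring(code, nchar(prefix) + 1L)
  intpart <- sub("\\..*$", "", rest)
  dec <- if (grepl("\\.", rest)) sub("^[^.]*\\.", "", rest) else ""
  if (intpart == "" || is.na(suppressWarnings(as.numeric(intpart)))) {
    stop("malformed ICD code or pattern stem: '", code, "'", call. = FALSE)
  }
  list(prefix = prefix, int = as.numeric(intpart), dec = dec)
}

# Numeric value of a code truncated to `k` decimal digits (string-based, so
# "250.31" truncated to 1 digit gives the same double as parsing "250.3").
icd_value_trunc <- function(parts, k) {
  dec <- substr(parts$dec, 1L, k)
  if (k == 0L || dec == "") return(parts$int)
  as.numeric(paste0(parts$int, ".", dec))
}

#' Parse a single code pattern
#'
#' A pattern is an exact code (\code{"416.8"}), a wildcard stem
#' (\code{"401.x"}), or an inclusive range (\code{"430.x-438.x"},
#' \code{"250.0-250.3"}); en-dash and ASCII hyphen are both accepted range
#' separators. The coding scheme (ICD-9-CM vs ICD-10-CA) is inferred from the
#' leading character class and both bounds of a range must agree.
#'
#' @param raw single pattern string as printed in the catalog.
#' @return an object of class \code{code_pattern}.
#' @export
code_pattern <- function(raw) {
  txt <- normalize_icd(raw)
  txt <- gsub("–|—", "-", txt)  # en/em dash -> hyphen
  if (txt == "") stop("empty code pattern", call. = FALSE)
  is_range <- grepl("-", txt, fixed = TRUE)
  p <- list(raw = raw)
  if (is_range) {
    bounds <- strsplit(txt, "-", fixed = TRUE)[[1L]]
    if (length(bounds) != 2L || any(bounds == "")) {
      stop("malformed range pattern: '", raw, "'", call. = FALSE)
    }
    lo <- sub("\\.X$", "", bounds[1L])
    hi <- sub("\\.X$", "", bounds[2L])
    plo <- icd_parts(lo); phi <- icd_parts(hi)
    if (icd_scheme(lo) != icd_scheme(hi) || plo$prefix != phi$prefix) {
      stop("range bounds mix coding schemes: '", raw, "'", call. = FALSE)
    }
    k <- max(nchar(plo$dec), nchar(phi$dec))
    p$kind <- "range"
    p$scheme <- icd_scheme(lo)
    p$prefix <- plo$prefix
    p$k <- k
    p$lo <- icd_value_trunc(plo, k)
    p$hi <- icd_value_trunc(phi, k)
    if (p$lo > p$hi) stop("descending range: '", raw, "'", call. = FALSE)
  } else if (grepl("\\.X$", txt)) {
    stem <- sub("\\.X$", "", txt)
    parts <- icd_parts(stem)
    p$kind <- "stem"
    p$scheme <- icd_scheme(stem)
    p$prefix <- parts$prefix
    p$stem <- stem
  } else {
    parts <- icd_parts(txt)  # validates
    p$kind <- "exact"
    p$scheme <- icd_scheme(txt)
    p$prefix <- parts$prefix
    p$code <- txt
  }
  structure(p, class = "code_pattern")
}

#' Test whether an ICD code matches a code pattern
#'
#' Matching rules: an exact pattern matches only the identical normalized
#' code; a wildcard stem \code{"401.x"} matches any code whose stem (the part
#' before the decimal point) equals \code{401}, including the bare stem
#' \code{"401"}; a range matches any code whose value, truncated to the
#' precision of the range bounds, lies inclusively between them. A pattern
#' never matches a code of the other coding scheme.
#'
#' @param pattern a \code{code_pattern} (or pattern string, parsed on the fly).
#' @param code one ICD code.
#' @return logical.
#' @examples
#' match_code("401.x", "401.9")        # TRUE
#' match_code("430.x-438.x", "434.11") # TRUE
#' match_code("I10.x", "K25.0")        # FALSE
#' @export
match_code <- function(pattern, code) {
  if (!inherits(pattern, "code_pattern")) pattern <- code_pattern(pattern)
  code <- normalize_icd(code)
  if (length(code) != 1L || code == "") {
    stop("`code` must be a single non-empty ICD code", call. = FALSE)
  }
  if (icd_scheme(code) != pattern$scheme) return(FALSE)
  parts <- icd_parts(code)
  if (parts$prefix != pattern$prefix) return(FALSE)
  switch(pattern$kind,
    exact = code == pattern$code,
    stem  = sub("\\..*$", "", code) == pattern$stem,
    range = {
      v <- icd_value_trunc(parts, pattern$k)
      v >= pattern$lo && v <= pattern$hi
    }
  )
}

#' Parse a morbidity catalog file
#'
#' Reads a plain-text catalog of morbidity categories. Each stanza starts
#' with the category name in square brackets, followed by comma-separated
#' code patterns (continuation lines allowed); \code{#} starts a comment.
#' The shipped default catalog defines the thirteen admission-morbidity
#' categories (Hypertension through Peptic Ulcer Disease) used throughout
#' the package.
#'
#' @param path path to the catalog file; defaults to the shipped catalog.
#' @return an object of class \code{morbidity_catalog}: a named list of
#'   lists of \code{code_pattern}s, in file order, with a \code{ids}
#'   attribute giving snake-case category identifiers.
#' @export
parse_morbidity_catalog <- function(path = system.file("extdata",
    "morbidity_catalog.txt", package = "ichcost")) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[lines != ""]
  cats <- list()
  current <- NULL
  buf <- character()
  flush <- function() {
    if (is.null(current)) return()
    pats <- unlist(strsplit(paste(buf, collapse = ","), ","))
    pats <- trimws(pats)
    pats <- pats[pats != ""]
    if (length(pats) == 0L) {
      stop("catalog category '", current, "' has no patterns", call. = FALSE)
    }
    cats[[current]] <<- lapply(pats, function(p) {
      tryCatch(code_pattern(p), error = function(e) {
        stop("catalog parse error in category '", current, "': ",
             conditionMessage(e), call. = FALSE)
      })
    })
  }
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      flush()
      current <- sub("^\\[(.*)\\]$", "\\1", ln)
      buf <- character()
    } else {
      if (is.null(current)) {
        stop("catalog line outside any category stanza: '", ln, "'",
             call. = FALSE)
      }
      buf <- c(buf, ln)
    }
  }
  flush()
  ids <- names(MORBIDITY_IDS)[match(names(cats), MORBIDITY_IDS)]
  structure(cats, ids = ids, class = "morbidity_catalog")
}

.catalog_cache <- new.env(parent = emptyenv())

#' Default morbidity catalog
#'
#' The shipped thirteen-category catalog, parsed once per session.
#' @return a \code{morbidity_catalog}.
#' @export
morbidity_catalog <- function() {
  if (is.null(.catalog_cache$default)) {
    .catalog_cache$default <- parse_morbidity_catalog()
  }
  .catalog_cache$default
}

#' @export
print.morbidity_catalog <- function(x, ...) {
  cat("Morbidity catalog:", length(x), "categories\n")
  for (nm in names(x)) {
    cat(sprintf("  %-34s %3d patterns\n", nm, length(x[[nm]])))
  }
  invisible(x)
}

#' Classify a discharge's diagnosis codes into morbidity categories
#'
#' Applies every catalog pattern to every secondary diagnosis code of one
#' discharge. The most responsible diagnosis (MRDx) -- the index ICH code --
#' is excluded from classification; any additional ICH or cerebrovascular
#' code among the secondary diagnoses sets the Secondary Cerebrovascular
#' Disease flag (patients with ICH in two or more locations count as primary
#' ICH with multimorbid secondary cerebrovascular disease). A code matching
#' several categories sets all of their flags; the multimorbidity count is
#' the number of distinct flagged categories, not of codes.
#'
#' @param codes character vector of ICD codes for one discharge.
#' @param mrdx logical vector flagging the most responsible diagnosis;
#'   exactly one element must be \code{TRUE}.
#' @param catalog a \code{morbidity_catalog}; the shipped default if omitted.
#' @return an object of class \code{morbidity_profile}: a list with
#'   \code{flags} (named logical over categories), \code{count} (number of
#'   flagged categories) and \code{any} (\code{count >= 1}).
#' @examples
#' classify(c("I61.0", "I10"), c(TRUE, FALSE))
#' @export
classify <- function(codes, mrdx, catalog = morbidity_catalog()) {
  codes <- normalize_icd(codes)
  mrdx <- as.logical(mrdx)
  if (length(codes) != length(mrdx) || anyNA(mrdx)) {
    stop("`codes` and `mrdx` must be aligned vectors without missing flags",
         call. = FALSE)
  }
  if (sum(mrdx) != 1L) {
    stop("exactly one code must carry the most-responsible-diagnosis flag ",
         "(got ", sum(mrdx), ")", call. = FALSE)
  }
  secondary <- codes[!mrdx]
  flags <- vapply(catalog, function(pats) {
    any(vapply(secondary, function(cd) {
      any(vapply(pats, match_code, logical(1L), code = cd))
    }, logical(1L)))
  }, logical(1L))
  names(flags) <- attr(catalog, "ids")
  structure(
    list(flags = flags, count = sum(flags), any = any(flags)),
    class = "morbidity_profile"
  )
}

#' @export
print.morbidity_profile <- function(x, ...) {
  pos <- names(x$flags)[x$flags]
  cat("Morbidity profile: count =", x$count,
      if (x$count > 0) paste0("(", paste(pos, collapse = ", "), ")") else "",
      "\n")
  invisible(x)
}

#' Classify every discharge of a cohort
#'
#' Convenience wrapper applying \code{\link{classify}} across a cohort data
#' frame carrying a \code{codes} column in the packed string encoding used
#' by \code{\link{write_cohort}} (semicolon-separated codes, the MRDx code
#' marked with a trailing \code{*}).
#'
#' @param cohort a cohort data frame with a \code{codes} column.
#' @param catalog a \code{morbidity_catalog}.
#' @return data frame of logical flag columns (\code{morb_<id>}) plus
#'   \code{morb_count} and \code{morb_any}, one row per discharge.
#' @export
classify_cohort <- function(cohort, catalog = morbidity_catalog()) {
  stopifnot(is.data.frame(cohort), "codes" %in% names(cohort))
  profs <- lapply(cohort$codes, function(s) {
    parsed <- unpack_codes(s)
    classify(parsed$code, parsed$mrdx, catalog)
  })
  flags <- do.call(rbind, lapply(profs, function(p) p$flags))
  out <- as.data.frame(flags)
  names(out) <- paste0("morb_", names(out))
  out$morb_count <- vapply(profs, function(p) p$count, numeric(1L))
  out$morb_any <- out$morb_count >= 1
  out
}

# Pack / unpack the per-discharge code list into a single CSV-safe string:
# "431*;401.9;250.00" -- the "*" marks the most responsible diagnosis.
pack_codes <- function(code, mrdx) {
  paste0(code, ifelse(mrdx, "*", ""), collapse = ";")
}

#' @rdname classify_cohort
#' @param s packed code string (\code{"431*;401.9"}).
#' @export
unpack_codes <- function(s) {
  toks <- strsplit(s, ";", fixed = TRUE)[[1L]]
  toks <- trimws(toks)
  toks <- toks[toks != ""]
  mrdx <- grepl("\\*$", toks)
  list(code = sub("\\*$", "", toks), mrdx = mrdx)
}
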