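# ICD pattern matching and morbidity classification.

test_that("wildcard, range and exact patterns match as printed", {
  expect_true(match_code("401.x", "401.9"))
  expect_true(match_code("401.x", "401"))
  expect_true(match_code("430.x–438.x", "434.11"))
  expect_true(match_code("416.8", "416.8"))
  expect_false(match_code("416.8", "416.9"))
  expect_false(match_code("I10.x", "K25.0"))
  expect_true(match_code("I60.x-I69.x", "I61.5"))
  expect_false(match_code("I60.x-I69.x", "I70.9"))
  # decimal-precision ranges truncate the code to the bounds' precision
  expect_true(match_code("250.0-250.3", "250.31"))
  expect_false(match_code("250.0-250.3", "250.4"))
  expect_true(match_code("E11.0-E11.9", "E11.9"))
  expect_false(match_code("E10.0-E10.9", "E11.9"))
  # scheme inference: V codes are ICD-9, low E codes ICD-10
  expect_true(match_code("V56.x", "V56.1"))
  expect_false(match_code("430.x-438.x", "I63.9"))
  expect_true(match_code("093.0", "093.0"))
  # normalization: case and whitespace
  expect_true(match_code("I10.x", " i10 "))
})

test_that("malformed patterns raise catalog-parse errors naming the text", {
  expect_error(code_pattern("401.x-"), "range")
  expect_error(code_pattern(""), "empty")
  expect_error(code_pattern("438.x-430.x"), "descending")
  expect_error(code_pattern("401.x-I10.x"), "scheme")
  tmp <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("[Bad Category]", "401.x, xx--yy"), tmp)
  expect_error(parse_morbidity_catalog(tmp), "Bad Category")
})

test_that("the shipped catalog has the 13 categories in printed order", {
  cat13 <- morbidity_catalog()
  expect_length(cat13, 13L)
  expect_identical(names(cat13)[1], "Hypertension")
  expect_identical(names(cat13)[13], "Peptic Ulcer Disease")
  expect_identical(attr(cat13, "ids"), morb_ids())
})

test_that("matcher agrees with a brute-force oracle over a small code universe", {
  # independent oracle: string/numeric logic written from the matching rules
  oracle <- function(raw, code) {
    txt <- gsub("–|—", "-", toupper(gsub("\\s", "", raw)))
    code <- toupper(gsub("\\s", "", code))
    scheme <- function(x) {
      if (grepl("^[0-9V]", x)) return("9")
      if (grepl("^E", x) && as.numeric(gsub("[^0-9.]", "", x)) >= 800)
        return("9")
      "10"
    }
    if (scheme(sub("-.*", "", txt)) != scheme(code)) return(FALSE)
    num <- function(x) as.numeric(sub("^[A-Z]+", "", x))
    pre <- function(x) sub("^([A-Z]*).*", "\\1", x)
    if (grepl("-", txt)) {
      b <- sub("\\.X$", "", strsplit(txt, "-")[[1]])
      if (pre(code) != pre(b[1])) return(FALSE)
      k <- max(nchar(sub("^[^.]*\\.?", "", b)))
      cut <- function(x) {
        v <- strsplit(sub("^[A-Z]+", "", x), ".", fixed = TRUE)[[1]]
        as.numeric(paste0(v[1], ".",
                          substr(ifelse(is.na(v[2]), "", v[2]), 1, k)))
      }
      return(cut(code) >= cut(b[1]) && cut(code) <= cut(b[2]))
    }
    if (grepl("\\.X$", txt)) {
      stem <- sub("\\.X$", "", txt)
      return(sub("\\..*", "", code) == stem)
    }
    code == txt
  }
  universe <- c(
    as.vector(outer(c(400:406, 429:439, 249:251, 530:535, 139:141),
                    c("", ".0", ".9", ".01", ".31"), paste0)),
    as.vector(outer(c("I09", "I10", "I15", "I59", "I60", "I61", "I69", "I70",
                      "E10", "E11", "E14", "E15", "K24", "K25", "K28", "K29"),
                    c("", ".0", ".5", ".9"), paste0)))
  pats <- c("401.x", "430.x-438.x", "250.0-250.3", "531.x-534.x",
            "140.x-172.x", "I10.x", "I60.x-I69.x", "E10.0-E10.9",
            "K25.x-K28.x", "416.8")
  for (p in pats) {
    cp <- code_pattern(p)
    got <- vapply(universe, function(cd) match_code(cp, cd), logical(1))
    want <- vapply(universe, function(cd) oracle(p, cd), logical(1))
    expect_identical(got, want, label = paste("pattern", p))
  }
})

test_that("classification excludes the MRDx and follows the ICH footnote", {
  p <- classify(c("I61.0", "I10"), c(TRUE, FALSE))
  expect_true(p$flags[["hypertension"]])
  expect_identical(p$count, 1L + 0L)
  p0 <- classify("431", TRUE)
  expect_identical(sum(p0$flags), 0L)
  expect_false(p0$any)
  # ICH in a second location counts as secondary cerebrovascular disease
  p2 <- classify(c("I61.0", "I61.5"), c(TRUE, FALSE))
  expect_true(p2$flags[["secondary_cerebrovascular"]])
  # a code listed under two categories sets both flags; count is categories
  p3 <- classify(c("431", "403.01"), c(TRUE, FALSE))
  expect_true(p3$flags[["hypertension"]])
  expect_true(p3$flags[["renal"]])
  expect_identical(p3$count, 2L)
})

test_that("zero or multiple MRDx flags are rejected", {
  expect_error(classify(c("431", "I10"), c(FALSE, FALSE)), "exactly one")
  expect_error(classify(c("431", "I61.0"), c(TRUE, TRUE)), "exactly one")
})

test_that("classification is order-independent and count is monotone", {
  set.seed(11)
  pool <- c("I10", "433.10", "250.00", "428.0", "F32.9", "N18.9", "K25.9")
  for (i in 1:20) {
    sec <- sample(pool, sample(1:5, 1))
    codes <- c("431", sec)
    mrdx <- c(TRUE, rep(FALSE, length(sec)))
    p1 <- classify(codes, mrdx)
    perm <- c(1L, 1L + sample(seq_along(sec)))
    p2 <- classify(codes[perm], mrdx[perm])
    expect_identical(p1$flags, p2$flags)
    # adding one more code never decreases the count
    extra <- sample(pool, 1)
    p3 <- classify(c(codes, extra), c(mrdx, FALSE))
    expect_gte(p3$count, p1$count)
  }
})
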