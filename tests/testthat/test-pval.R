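test_that("parsing normalizes decimal and scientific numerals canonically", {
  p <- parse_pvalue(c("0.05", "1", ".5", "0.0001234", "5E-3", "1.0"))
  expect_identical(vctrs::field(p, "mantissa"), c(5, 1, 5, 1.234, 5, 1))
  expect_identical(vctrs::field(p, "exponent"), c(-2L, 0L, -1L, -4L, -3L, 0L))
})

test_that("sub-double-precision exponents survive a parse/format round trip", {
  p <- parse_pvalue("3.2e-450")
  expect_identical(vctrs::field(p, "mantissa"), 3.2)
  expect_identical(vctrs::field(p, "exponent"), -450L)
  expect_identical(format_pvalue(p), "3.2e-450")
  # the double representation underflows to zero, the pval does not
  expect_identical(as.double(p), 0)
  expect_identical(pval_log10(p), -450 + log10(3.2))
})

test_that("values outside (0, 1] and non-numerals are rejected with distinct codes", {
  expect_error(parse_pvalue("2"), class = "sumstatr_range_error")
  expect_error(parse_pvalue("1.0000001"), class = "sumstatr_range_error")
  expect_error(parse_pvalue("0"), class = "sumstatr_range_error")
  expect_error(parse_pvalue("0.000"), class = "sumstatr_range_error")
  expect_error(parse_pvalue("-0.5"), class = "sumstatr_range_error")
  expect_error(parse_pvalue("abc"), class = "sumstatr_parse_error")
  expect_error(parse_pvalue("1e-5e-5"), class = "sumstatr_parse_error")
  expect_error(parse_pvalue(""), class = "sumstatr_parse_error")
})

test_that("formatting rounds half-even and re-canonicalizes on carry", {
  expect_identical(format_pvalue(pval("3.14159e-8"), sig_digits = 3), "3.14e-8")
  expect_identical(format_pvalue(pval("9.999e-5"), sig_digits = 2), "1.0e-4")
  expect_identical(format_pvalue(pval("1"), sig_digits = 1), "1e0")
  # half-even: 1.25 at 2 digits goes down to the even digit, 1.35 goes up
  expect_identical(format_pvalue(pval("1.25e-3"), sig_digits = 2), "1.2e-3")
  expect_identical(format_pvalue(pval("1.35e-3"), sig_digits = 2), "1.4e-3")
})

test_that("parse then lossless format is the identity on canonical numerals", {
  withr::local_seed(41)
  s <- random_pval_strings(400)
  p <- parse_pvalue(s$text)
  expect_identical(format_pvalue(p), s$text)
})

test_that("ordering of random p-values matches the independent oracle", {
  withr::local_seed(42)
  s <- random_pval_strings(1000)
  p <- parse_pvalue(s$text)
  key <- oracle_key(s$mantissa, s$exponent)

  ord <- vctrs::vec_order(p)
  expect_identical(ord, order(key))

  i <- sample(1000, 500, replace = TRUE)
  j <- sample(1000, 500, replace = TRUE)
  expect_identical(compare_pvalues(p[i], p[j]), as.integer(sign(key[i] - key[j])))
})

test_that("comparison is a total order: antisymmetric and transitive", {
  withr::local_seed(43)
  s <- random_pval_strings(60, lo = -20)
  p <- parse_pvalue(s$text)
  idx <- expand.grid(i = 1:60, j = 1:60)
  cmp <- compare_pvalues(p[idx$i], p[idx$j])
  rev <- compare_pvalues(p[idx$j], p[idx$i])
  expect_identical(cmp, -rev)
  for (k in 1:200) {
    t3 <- sample(60, 3)
    c12 <- compare_pvalues(p[t3[1]], p[t3[2]])
    c23 <- compare_pvalues(p[t3[2]], p[t3[3]])
    if (c12 <= 0 && c23 <= 0) {
      expect_lte(compare_pvalues(p[t3[1]], p[t3[3]]), 0)
    }
  }
  expect_identical(compare_pvalues(pval("5e-2"), pval("5e-2")), 0L)
  expect_identical(compare_pvalues(pval("1e-400"), pval("1e-300")), -1L)
})

test_that("no p-value operation produces 0 or a value above 1", {
  withr::local_seed(44)
  s <- random_pval_strings(300)
  p <- parse_pvalue(s$text)
  for (k in 1:3) {
    q <- pval_round(p, k)
    m <- vctrs::field(q, "mantissa")
    e <- vctrs::field(q, "exponent")
    expect_true(all(m >= 1 & m < 10))
    expect_true(all(e < 0L | (e == 0L & m == 1)))
  }
})

test_that("doubles in (0, 1] convert without losing their printed value", {
  p <- pval(c(0.05, 1e-300, 0.9999))
  expect_identical(format_pvalue(p), c("5e-2", "1e-300", "9.999e-1"))
  expect_error(pval(1.5), class = "sumstatr_range_error")
})
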