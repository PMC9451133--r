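# Shared fixtures and independent oracles. Everything is generated in code;
# no binary fixtures.

# Independent ordering oracle for p-values: a real value m * 10^e maps to the
# key e + log10(m), computed directly from the decimal representation with
# base R. Exact enough to totally order random values spanning e in
# [-500, 0]; never touches the pval comparison path it checks.
oracle_key <- function(mantissa, exponent) exponent + log10(mantissa)

# Random canonical p-value numerals: mantissa with no trailing zeros (so the
# string itself is the expected lossless re-emission), exponent in
# [lo, hi]; exponent 0 forces mantissa 1 (p <= 1).
random_pval_strings <- function(n, lo = -500, hi = 0) {
  expo <- sample(lo:hi, n, replace = TRUE)
  mant <- vapply(expo, function(e) {
    if (e == 0) return("1")
    nd <- sample(1:8, 1)
    d <- c(sample(1:9, 1), if (nd > 1) sample(0:9, nd - 2, replace = TRUE),
           if (nd > 1) sample(1:9, 1))
    paste0(d[1], if (nd > 1) ".", paste(d[-1], collapse = ""))
  }, character(1))
  list(text = paste0(mant, "e", expo),
       mantissa = as.numeric(mant),
       exponent = expo)
}

clean_sim <- function(n = 200, effect_type = "beta", seed = 1, ...) {
  simulate_sumstats(n, effect_type = effect_type, seed = seed, ...)$data
}

# field-level dataset equality (p-values compared on their exact
# mantissa/exponent representation)
expect_same_dataset <- function(a, b) {
  expect_equal(nrow(a), nrow(b))
  expect_setequal(names(a), names(b))
  for (col in names(a)) {
    if (is_pval(a[[col]])) {
      expect_identical(vctrs::field(a[[col]], "mantissa"),
                       vctrs::field(b[[col]], "mantissa"),
                       label = paste0(col, " mantissa"))
      expect_identical(vctrs::field(a[[col]], "exponent"),
                       vctrs::field(b[[col]], "exponent"),
                       label = paste0(col, " exponent"))
    } else {
      expect_identical(a[[col]], b[[col]], label = col)
    }
  }
}

write_tsv_lines <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

minimal_standard_lines <- function() {
  c(paste(c("variant_id", "chromosome", "base_pair_location", "p_value",
            "effect_allele", "other_allele", "effect_allele_frequency",
            "beta", "standard_error", "ci_upper", "ci_lower"),
          collapse = "\t"),
    paste(c("rs123", "7", "41000", "2.5e-9", "A", "G", "0.31", "0.07",
            "0.011", "0.0916", "0.0484"), collapse = "\t"))
}

# drop the on-dataset privacy declaration (to exercise the metadata route)
sumstats_keep_attrs_strip <- function(x) {
  attr(x, "privacy_profile_applied") <- NULL
  x
}

dialect_path <- function(name) {
  system.file("extdata", "dialects", paste0(name, ".tsv"), package = "sumstatr")
}
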