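#' Underflow-safe p-value vectors
#'
#' GWAS p-values routinely fall far below the smallest positive
#' double-precision number (about 5e-324); storing them as `numeric` silently
#' collapses them to zero. `pval` vectors store each p-value as a canonical
#' decimal mantissa in `[1, 10)` plus a signed integer exponent, so a value
#' such as 3.2e-450 survives parsing, comparison, rounding and re-emission
#' with the exponent intact.
#'
#' `pval()` builds a vector from character numerals (plain decimal or
#' scientific notation) or from doubles in `(0, 1]`. Values outside `(0, 1]`
#' are rejected: probabilities cannot exceed 1 and an exact 0 almost always
#' signals an upstream underflow bug (see [read_sumstats()]'s `p_floor`
#' option for the deliberate alternative).
#'
#' @param x character or numeric vector of p-values.
#' @return A `pval` vector.
#' @examples
#' p <- pval(c("0.05", "3.2e-450", "1"))
#' format(p)
#' pval_log10(p)
#' @seealso [parse_pvalue()], [format_pvalue()], [compare_pvalues()]
#' @export
pval <- function(x = character()) {
  if (is_pval(x)) return(x)
  if (is.numeric(x)) {
    txt <- rep(NA_character_, length(x))
    txt[!is.na(x)] <- fmt_double(x[!is.na(x)])
    return(parse_pvalue(txt))
  }
  parse_pvalue(as.character(x))
}

# Low-level constructor: does NOT enforce the (0, 1] range, so that corrupted
# records (error injection, foreign files) remain representable in memory for
# the validator to flag.
new_pval <- function(mantissa = double(), exponent = integer()) {
  vctrs::new_rcrd(
    list(mantissa = as.double(mantissa), exponent = as.integer(exponent)),
    class = "sumstatr_pval"
  )
}

#' @rdname pval
#' @export
is_pval <- function(x) inherits(x, "sumstatr_pval")

pval_na <- function(n = 1L) new_pval(rep(NA_real_, n), rep(NA_integer_, n))

#' Parse p-value numerals without underflow
#'
#' Parses decimal or scientific-notation numerals (`"0.05"`, `"3.2e-450"`)
#' into canonical mantissa/exponent form. The whole string is processed
#' digit-wise, so exponents far below the double-precision underflow limit
#' are preserved exactly.
#'
#' Two failure modes are distinguished: a string that is not a numeral at all
#' raises a condition of class `sumstatr_parse_error` (issue code
#' `P_PARSE_ERROR`), while a numeral outside `(0, 1]` raises
#' `sumstatr_range_error` (issue code `P_OUT_OF_RANGE`).
#'
#' @param text character vector of numerals. `NA` elements stay missing.
#' @return A `pval` vector with mantissas in `[1, 10)`.
#' @examples
#' parse_pvalue(c("0.05", "1", "3.2e-450"))
#' @export
parse_pvalue <- function(text) {
  parts <- pv_parse_quiet(text)
  bad_parse <- which(parts$code %in% "P_PARSE_ERROR")
  if (length(bad_parse)) {
    stopf("sumstatr_parse_error",
          "not a numeral: %s",
          paste(utils::head(unique(text[bad_parse]), 3L), collapse = ", "),
          code = "P_PARSE_ERROR")
  }
  bad_range <- which(parts$code %in% c("P_OUT_OF_RANGE", "P_ZERO"))
  if (length(bad_range)) {
    stopf("sumstatr_range_error",
          "p-value outside (0, 1]: %s",
          paste(utils::head(unique(text[bad_range]), 3L), collapse = ", "),
          code = "P_OUT_OF_RANGE")
  }
  new_pval(parts$mantissa, parts$exponent)
}

# Vectorized digit-wise parser. Returns mantissa/exponent (NA where invalid)
# plus a per-element issue code: NA, "P_PARSE_ERROR", "P_OUT_OF_RANGE",
# or "P_ZERO" (exactly zero; distinct so the reader can apply a floor).
pv_parse_quiet <- function(text) {
  n <- length(text)
  mantissa <- rep(NA_real_, n)
  exponent <- rep(NA_integer_, n)
  code <- rep(NA_character_, n)

  txt <- stringr::str_trim(as.character(text))
  m <- stringr::str_match(
    txt, "^([+-]?)([0-9]+(?:\\.[0-9]*)?|\\.[0-9]+)(?:[eE]([+-]?[0-9]+))?$"
  )
  missing <- is.na(txt)
  invalid <- !missing & is.na(m[, 1L])
  code[invalid] <- "P_PARSE_ERROR"

  ok <- which(!missing & !invalid)
  if (length(ok)) {
    sign <- m[ok, 2L]
    num <- m[ok, 3L]
    e_part <- m[ok, 4L]
    e_expl <- ifelse(is.na(e_part), 0, suppressWarnings(as.numeric(e_part)))

    has_dot <- grepl(".", num, fixed = TRUE)
    intpart <- ifelse(has_dot, sub("\\..*$", "", num), num)
    frac <- ifelse(has_dot, sub("^[^.]*\\.", "", num), "")
    digits <- paste0(intpart, frac)
    firstnz <- regexpr("[1-9]", digits)

    is_zero <- firstnz < 0L
    code[ok[is_zero]] <- "P_ZERO"
    neg <- sign == "-" & !is_zero
    code[ok[neg]] <- "P_OUT_OF_RANGE"

    use <- which(!is_zero & !neg)
    if (length(use)) {
      i <- firstnz[use]
      expo <- nchar(intpart[use]) - i + e_expl[use]
      sig <- sub("0+$", "", substring(digits[use], i))
      sig[sig == ""] <- "0" # cannot happen (first digit nonzero), defensive
      mant_str <- ifelse(
        nchar(sig) > 1L,
        paste0(substring(sig, 1L, 1L), ".", substring(sig, 2L)),
        sig
      )
      mant <- as.numeric(mant_str)
      # >17 significant digits can round up to 10; re-canonicalize
      carry <- mant >= 10
      mant[carry] <- mant[carry] / 10
      expo[carry] <- expo[carry] + 1

      too_big <- abs(expo) >= .Machine$integer.max
      out_rng <- expo > 0 | (expo == 0 & mant > 1)
      idx <- ok[use]
      code[idx[too_big]] <- "P_PARSE_ERROR"
      code[idx[!too_big & out_rng]] <- "P_OUT_OF_RANGE"
      keep <- !too_big & !out_rng
      mantissa[idx[keep]] <- mant[keep]
      exponent[idx[keep]] <- as.integer(expo[keep])
    }
  }
  list(mantissa = mantissa, exponent = exponent, code = code)
}

#' Format p-values in scientific notation
#'
#' Emits `"<mantissa>e<exponent>"` numerals. With `sig_digits = NULL`
#' (default) the mantissa is printed with the fewest digits that reproduce it
#' exactly when re-parsed, so formatting is lossless. With an integer
#' `sig_digits` the mantissa is rounded half-even to that many significant
#' digits — the reduction used by privacy profiles; a rounding carry
#' (e.g. 9.99 -> 10.0) re-canonicalizes the exponent.
#'
#' @param p a `pval` vector.
#' @param sig_digits `NULL` for lossless shortest output, or a positive
#'   integer number of significant digits.
#' @return character vector of numerals.
#' @examples
#' format_pvalue(pval("3.14159e-8"), sig_digits = 3) # "3.14e-8"
#' format_pvalue(pval("9.999e-5"), sig_digits = 2)   # carry: "1.0e-4"
#' @export
format_pvalue <- function(p, sig_digits = NULL) {
  stopifnot(is_pval(p))
  m <- vctrs::field(p, "mantissa")
  e <- vctrs::field(p, "exponent")
  out <- rep(NA_character_, length(p))
  ok <- !is.na(m) & !is.na(e)
  if (!any(ok)) return(out)
  m_ok <- m[ok]
  e_ok <- as.numeric(e[ok])
  if (is.null(sig_digits)) {
    mstr <- fmt_double(m_ok)
  } else {
    stopifnot(length(sig_digits) == 1L, sig_digits >= 1)
    k <- as.integer(sig_digits)
    scale <- 10^(k - 1L)
    m2 <- round(m_ok * scale) / scale
    carry <- !is.na(m2) & m2 >= 10
    m2[carry] <- m2[carry] / 10
    e_ok[carry] <- e_ok[carry] + 1
    mstr <- sprintf("%.*f", k - 1L, m2)
  }
  out[ok] <- paste0(mstr, "e", sprintf("%.0f", e_ok))
  out
}

#' Round p-values to a number of significant digits
#'
#' Half-even rounding of the mantissa, with exponent carry. Rounding is
#' idempotent and order-preserving (ties may appear, inversions never), which
#' is what makes it safe as a privacy-reduction transform.
#'
#' @inheritParams format_pvalue
#' @param sig_digits positive integer.
#' @return A `pval` vector.
#' @export
pval_round <- function(p, sig_digits) {
  stopifnot(is_pval(p), length(sig_digits) == 1L, sig_digits >= 1)
  k <- as.integer(sig_digits)
  m <- vctrs::field(p, "mantissa")
  e <- as.numeric(vctrs::field(p, "exponent"))
  scale <- 10^(k - 1L)
  m2 <- round(m * scale) / scale
  carry <- !is.na(m2) & m2 >= 10
  m2[carry] <- m2[carry] / 10
  e[carry] <- e[carry] + 1
  new_pval(m2, as.integer(e))
}

#' Compare p-values without underflow
#'
#' Total order over the represented real values, computed on the
#' mantissa/exponent representation so that 1e-400 < 1e-300 compares
#' correctly where doubles would see 0 == 0.
#'
#' @param a,b `pval` vectors (recycled to a common length).
#' @return integer vector: -1 (`a < b`), 0 (equal), 1 (`a > b`).
#' @examples
#' compare_pvalues(pval("1e-400"), pval("1e-300")) # -1
#' @export
compare_pvalues <- function(a, b) {
  stopifnot(is_pval(a), is_pval(b))
  vctrs::vec_compare(a, b)
}

#' Base-10 logarithm of p-values
#'
#' Computed as `exponent + log10(mantissa)`, exact to double precision even
#' for p-values whose direct double representation underflows. Useful for
#' Manhattan/QQ plots of extreme associations.
#'
#' @param p a `pval` vector.
#' @return numeric vector of `log10(p)` values.
#' @export
pval_log10 <- function(p) {
  stopifnot(is_pval(p))
  vctrs::field(p, "exponent") + log10(vctrs::field(p, "mantissa"))
}

pv_canonical_proxy <- function(x) {
  m <- vctrs::field(x, "mantissa")
  e <- as.numeric(vctrs::field(x, "exponent"))
  ok <- !is.na(m) & m > 0
  d <- rep(0, length(m))
  d[ok] <- floor(log10(m[ok]))
  data.frame(exponent = e + d, mantissa = m / 10^d)
}

#' @export
format.sumstatr_pval <- function(x, ...) format_pvalue(x)

#' @export
as.character.sumstatr_pval <- function(x, ...) format_pvalue(x)

#' @export
as.double.sumstatr_pval <- function(x, ...) {
  vctrs::field(x, "mantissa") * 10^as.numeric(vctrs::field(x, "exponent"))
}

#' @export
vec_ptype_abbr.sumstatr_pval <- function(x, ...) "pval"

#' @export
vec_ptype_full.sumstatr_pval <- function(x, ...) "pval"

#' @export
vec_ptype2.sumstatr_pval.sumstatr_pval <- function(x, y, ...) new_pval()

#' @export
vec_cast.sumstatr_pval.sumstatr_pval <- function(x, to, ...) x

#' @export
vec_proxy_compare.sumstatr_pval <- function(x, ...) pv_canonical_proxy(x)

#' @export
vec_proxy_equal.sumstatr_pval <- function(x, ...) pv_canonical_proxy(x)
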