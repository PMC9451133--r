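#' Deterministically inject validation errors
#'
#' Corrupts exactly the requested number of distinct cells with values
#' guaranteed to trigger the named validation code and no other, returning
#' the corrupted dataset plus an injection log. Together with
#' [validate_sumstats()] this forms a soundness/completeness oracle: the
#' validator must find exactly the logged `(row, column, code)` coordinates
#' and nothing on the uncorrupted twin.
#'
#' Every injectable code (see [issue_codes()]) targets one record-level
#' cell; `DUPLICATE_VARIANT` copies the identifying tuple of an untouched
#' earlier row onto the target row, so the target is the flagged (second)
#' occurrence. `NONPOS_OR` requires an odds-ratio dataset.
#'
#' @param x a clean [sumstats] dataset (validation findings on `x` itself
#'   will still be present afterwards and are not distinguished from
#'   injected ones).
#' @param spec named integer vector or list: code -> number of instances.
#' @param seed integer seed; target rows are sampled deterministically.
#' @return list with `data` (corrupted [sumstats]) and `log` (tibble:
#'   `row`, `column`, `code`, `original`, `corrupted`).
#' @export
inject_errors <- function(x, spec, seed) {
  stopifnot(is_sumstats(x))
  spec <- unlist(spec)
  spec <- spec[spec > 0]
  bad <- setdiff(names(spec), injectable_codes())
  if (length(bad)) {
    stopf("sumstatr_inject_error", "not injectable: %s", paste(bad, collapse = ", "))
  }
  et <- effect_type(x)
  if ("NONPOS_OR" %in% names(spec) && !identical(et, "odds_ratio")) {
    stopf("sumstatr_inject_error",
          "NONPOS_OR requires an odds_ratio dataset (this one reports %s)", et)
  }
  n <- nrow(x)
  total <- sum(spec)
  n_dup <- sum(spec[names(spec) == "DUPLICATE_VARIANT"])
  if (total + n_dup > n) {
    stopf("sumstatr_inject_error",
          "spec requests %d corruptions (plus %d duplicate sources) but only %d rows exist",
          total, n_dup, n)
  }
  if (total == 0L) {
    return(list(data = x, log = tibble(row = integer(), column = character(),
                                       code = character(), original = character(),
                                       corrupted = character())))
  }

  out <- as_tibble(x)
  withr::local_seed(as.integer(seed))
  targets <- sort(sample.int(n, total))
  # duplicates get the largest target rows so an untouched earlier source row
  # always exists
  codes <- rep(names(spec), spec)
  ord <- c(which(codes != "DUPLICATE_VARIANT"), which(codes == "DUPLICATE_VARIANT"))
  codes <- codes[ord]

  log <- vector("list", total)
  for (k in seq_len(total)) {
    row <- targets[[k]]
    code <- codes[[k]]
    rec <- switch(code,
      P_OUT_OF_RANGE = {
        orig <- format_pvalue(out$p_value[row])
        newp <- new_pval(stats::runif(1, 2, 9), 0L)
        out$p_value[row] <- newp
        c("p_value", orig, format_pvalue(newp))
      },
      EAF_OUT_OF_RANGE = {
        orig <- out$effect_allele_frequency[[row]]
        val <- 1 + stats::runif(1, 0.1, 2)
        out$effect_allele_frequency[[row]] <- val
        c("effect_allele_frequency", as.character(orig), as.character(val))
      },
      BAD_ALLELE = {
        orig <- out$effect_allele[[row]]
        out$effect_allele[[row]] <- "N"
        c("effect_allele", orig, "N")
      },
      ALLELES_IDENTICAL = {
        orig <- out$other_allele[[row]]
        out$other_allele[[row]] <- out$effect_allele[[row]]
        c("other_allele", orig, out$other_allele[[row]])
      },
      BAD_CHROMOSOME = {
        # invalid token, unique per row so no variant tuple is accidentally
        # duplicated between corrupted rows
        orig <- out$chromosome[[row]]
        val <- as.character(100L + row)
        out$chromosome[[row]] <- val
        c("chromosome", orig, val)
      },
      BAD_POSITION = {
        # non-positive and unique per row (see BAD_CHROMOSOME)
        orig <- out$base_pair_location[[row]]
        out$base_pair_location[[row]] <- -row
        c("base_pair_location", as.character(orig), as.character(-row))
      },
      BAD_RSID = {
        orig <- out$variant_id[[row]]
        val <- paste0("rsX", row)
        out$variant_id[[row]] <- val
        c("variant_id", orig, val)
      },
      NEG_SE = {
        orig <- out$standard_error[[row]]
        val <- -abs(orig) - 0.001
        out$standard_error[[row]] <- val
        c("standard_error", as.character(orig), as.character(val))
      },
      NONPOS_OR = {
        orig <- out$odds_ratio[[row]]
        out$odds_ratio[[row]] <- -0.3
        c("odds_ratio", as.character(orig), "-0.3")
      },
      CI_ORDER = {
        orig <- out$ci_lower[[row]]
        if (is.na(out$ci_upper[[row]])) out$ci_upper[[row]] <- 1
        val <- out$ci_upper[[row]] + 1
        out$ci_lower[[row]] <- val
        c("ci_lower", as.character(orig), as.character(val))
      },
      MISSING_MANDATORY_VALUE = {
        orig <- out$standard_error[[row]]
        out$standard_error[[row]] <- NA_real_
        c("standard_error", as.character(orig), NA_character_)
      },
      DUPLICATE_VARIANT = {
        src_pool <- setdiff(seq_len(row - 1L), targets)
        if (length(src_pool) == 0L) {
          stopf("sumstatr_inject_error",
                "cannot place DUPLICATE_VARIANT at row %d: no untouched earlier source row",
                row)
        }
        src <- if (length(src_pool) == 1L) src_pool else sample(src_pool, 1L)
        orig <- paste(out$chromosome[[row]], out$base_pair_location[[row]],
                      out$effect_allele[[row]], out$other_allele[[row]], sep = ":")
        out$chromosome[[row]] <- out$chromosome[[src]]
        out$base_pair_location[[row]] <- out$base_pair_location[[src]]
        out$effect_allele[[row]] <- out$effect_allele[[src]]
        out$other_allele[[row]] <- out$other_allele[[src]]
        c("variant", orig, paste(out$chromosome[[row]], out$base_pair_location[[row]],
                                 out$effect_allele[[row]], out$other_allele[[row]],
                                 sep = ":"))
      }
    )
    log[[k]] <- tibble(row = row, column = rec[[1L]], code = code,
                       original = rec[[2L]], corrupted = rec[[3L]])
  }
  log <- dplyr::arrange(dplyr::bind_rows(log), .data$row, .data$column, .data$code)
  list(data = sumstats_keep_attrs(out, x), log = log)
}
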