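MANDATORY_VALUE_COLUMNS <- c("p_value", "effect_allele", "other_allele",
                             "effect_allele_frequency", "standard_error")

#' Header-level conformance checks
#'
#' Checks a harmonized header (standard element names) against the standard's
#' mandatory set: `p_value`, `effect_allele`, `other_allele`,
#' `effect_allele_frequency`, `standard_error`, exactly one of
#' `odds_ratio`/`beta`, and one form of variant identification — `variant_id`
#' or `chromosome` plus `base_pair_location`. A lone confidence-interval
#' bound is a warning.
#'
#' @param headers character vector of standard elements present.
#' @return An issue tibble (`row == 0` marks header-level findings).
#' @export
check_header <- function(headers) {
  iss <- list()
  for (el in MANDATORY_VALUE_COLUMNS) {
    if (!el %in% headers) {
      iss[[length(iss) + 1L]] <- issue(
        "ERROR", "MISSING_MANDATORY", 0L, el,
        sprintf("mandatory element '%s' is absent", el))
    }
  }
  has_or <- "odds_ratio" %in% headers
  has_beta <- "beta" %in% headers
  if (has_or && has_beta) {
    iss[[length(iss) + 1L]] <- issue(
      "ERROR", "EFFECT_COLUMN_CONFLICT", 0L, "odds_ratio|beta",
      "both odds_ratio and beta present; a file carries a single effect scale")
  } else if (!has_or && !has_beta) {
    iss[[length(iss) + 1L]] <- issue(
      "ERROR", "MISSING_MANDATORY", 0L, "odds_ratio|beta",
      "mandatory effect element is absent (odds_ratio or beta)")
  }
  if (!("variant_id" %in% headers ||
        all(c("chromosome", "base_pair_location") %in% headers))) {
    iss[[length(iss) + 1L]] <- issue(
      "ERROR", "VARIANT_ID_RULE", 0L, "variant_id",
      "one form of variant ID is mandatory: variant_id, or chromosome plus base_pair_location")
  }
  if (xor("ci_upper" %in% headers, "ci_lower" %in% headers)) {
    present <- intersect(c("ci_upper", "ci_lower"), headers)
    iss[[length(iss) + 1L]] <- issue(
      "WARNING", "CI_UNPAIRED", 0L, present,
      "only one confidence-interval bound is present")
  }
  bind_issues(!!!iss)
}

# Record-level checks, vectorized over the whole table.
record_issues <- function(x, eaf_exempt = FALSE) {
  n <- nrow(x)
  present <- attr(x, "present_columns", exact = TRUE) %||%
    standard_columns(effect_type(x))
  iss <- list()
  add <- function(rows, code, column, message, observed) {
    if (length(rows) == 0L) return()
    iss[[length(iss) + 1L]] <<- new_issues(
      severity = rep(issue_severity(code), length(rows)),
      code = rep(code, length(rows)), row = rows,
      column = rep(column, length(rows)),
      message = rep(message, length(rows)),
      observed = as.character(observed))
  }

  pm <- vctrs::field(x$p_value, "mantissa")
  pe <- vctrs::field(x$p_value, "exponent")
  bad_p <- which(!is.na(pm) & (pm <= 0 | pe > 0L | (pe == 0L & pm > 1)))
  add(bad_p, "P_OUT_OF_RANGE", "p_value", "p-value outside (0, 1]",
      format_pvalue(x$p_value[bad_p]))

  eaf <- x$effect_allele_frequency
  bad_eaf <- which(!is.na(eaf) & (eaf < 0 | eaf > 1))
  add(bad_eaf, "EAF_OUT_OF_RANGE", "effect_allele_frequency",
      "effect allele frequency outside [0, 1]", eaf[bad_eaf])

  for (col in c("effect_allele", "other_allele")) {
    bad <- which(!is.na(x[[col]]) & !is_valid_allele(x[[col]]))
    add(bad, "BAD_ALLELE", col,
        "allele is not a non-empty uppercase A/C/G/T sequence", x[[col]][bad])
  }
  same <- which(!is.na(x$effect_allele) & !is.na(x$other_allele) &
                x$effect_allele == x$other_allele)
  add(same, "ALLELES_IDENTICAL", "other_allele",
      "effect and other allele are identical", x$other_allele[same])

  chr <- x$chromosome
  bad_chr <- which(!is.na(chr) & !chr %in% VALID_CHROMOSOMES)
  add(bad_chr, "BAD_CHROMOSOME", "chromosome",
      "chromosome token outside 1-22, X, Y, MT", chr[bad_chr])

  bp <- x$base_pair_location
  bad_bp <- which(!is.na(bp) & (bp <= 0 | bp != floor(bp)))
  add(bad_bp, "BAD_POSITION", "base_pair_location",
      "base-pair location must be a positive integer (1-based)", bp[bad_bp])

  vid <- x$variant_id
  bad_rs <- which(!is.na(vid) & !grepl(RSID_PATTERN, vid))
  add(bad_rs, "BAD_RSID", "variant_id", "variant_id does not match rs[0-9]+",
      vid[bad_rs])

  se <- x$standard_error
  bad_se <- which(!is.na(se) & se < 0)
  add(bad_se, "NEG_SE", "standard_error", "standard error is negative", se[bad_se])

  et <- effect_type(x)
  if (identical(et, "odds_ratio")) {
    or <- x$odds_ratio
    bad_or <- which(!is.na(or) & or <= 0)
    add(bad_or, "NONPOS_OR", "odds_ratio", "odds ratio must be strictly positive",
        or[bad_or])
    for (col in c("ci_lower", "ci_upper")) {
      bad <- which(!is.na(x[[col]]) & x[[col]] <= 0)
      add(bad, "CI_NONPOS", col,
          "odds-ratio confidence bound must be strictly positive", x[[col]][bad])
    }
  }

  ci_bad <- which(!is.na(x$ci_lower) & !is.na(x$ci_upper) & x$ci_lower > x$ci_upper)
  add(ci_bad, "CI_ORDER", "ci_lower", "ci_lower exceeds ci_upper",
      paste0(x$ci_lower[ci_bad], ">", x$ci_upper[ci_bad]))

  # mandatory cells present in the header must carry values; EAF is exempt
  # when a declared privacy profile masked it
  mand <- intersect(c(MANDATORY_VALUE_COLUMNS, et), c(present, et))
  if (eaf_exempt) mand <- setdiff(mand, "effect_allele_frequency")
  for (col in mand) {
    v <- if (col == "p_value") vctrs::field(x$p_value, "mantissa") else x[[col]]
    add(which(is.na(v)), "MISSING_MANDATORY_VALUE", col,
        sprintf("mandatory cell '%s' is missing", col), NA_character_)
  }

  # per-record variant identification
  if (any(c("variant_id", "chromosome", "base_pair_location") %in% present)) {
    no_id <- which(is.na(vid) & (is.na(chr) | is.na(bp)))
    add(no_id, "VARIANT_ID_RULE", "variant_id",
        "record has neither variant_id nor chromosome plus base_pair_location",
        NA_character_)
  }

  # duplicated variant tuples: every occurrence after the first is flagged
  full <- !is.na(chr) & !is.na(bp) & !is.na(x$effect_allele) & !is.na(x$other_allele)
  key <- paste(chr, bp, x$effect_allele, x$other_allele, sep = "\r")
  key[!full] <- paste0("\r#", seq_len(n)[!full])
  dup <- which(duplicated(key))
  add(dup, "DUPLICATE_VARIANT", "variant",
      "repeated (chromosome, base_pair_location, effect_allele, other_allele) tuple",
      gsub("\r", ":", key[dup]))

  bind_issues(!!!iss)
}

issue_severity <- function(code) {
  ISSUE_CODES$severity[match(code, ISSUE_CODES$code)]
}

#' Validate a single record
#'
#' Convenience wrapper running the record-level rules on one row of a
#' [sumstats] object (duplicate detection needs the full dataset and is not
#' applied here).
#'
#' @param x a [sumstats] object.
#' @param row record index to check.
#' @return An issue tibble with `row` set to `row`.
#' @export
validate_record <- function(x, row) {
  stopifnot(is_sumstats(x), row >= 1L, row <= nrow(x))
  one <- sumstats_keep_attrs(as_tibble(x)[row, , drop = FALSE], x)
  iss <- record_issues(one)
  iss <- iss[iss$code != "DUPLICATE_VARIANT", , drop = FALSE]
  iss$row <- as.integer(ifelse(iss$row == 1L, row, iss$row))
  iss
}

#' Validate a summary-statistics dataset
#'
#' Aggregates header-level checks ([check_header()]), vectorized record-level
#' rules, duplicate-variant detection and dataset-level conditions into a
#' machine-readable report. The report is `valid` exactly when no
#' ERROR-severity finding is present; issue ordering is deterministic (row,
#' then column, then code).
#'
#' `effect_allele_frequency` is schema-mandatory (the column must exist), but
#' its values may be missing when a privacy profile masking frequencies was
#' applied and declared — either in `metadata` or on the dataset itself by
#' [apply_privacy_profile()].
#'
#' @param x a [sumstats] object.
#' @param metadata optional [study_metadata] accompanying the dataset.
#' @return A `sumstats_report`: list with `issues`, `records_checked`,
#'   `counts_by_code`, `valid`.
#' @export
validate_sumstats <- function(x, metadata = NULL) {
  stopifnot(is_sumstats(x))
  present <- attr(x, "present_columns", exact = TRUE) %||%
    standard_columns(effect_type(x))
  iss <- list(check_header(present))

  if (nrow(x) == 0L) {
    iss[[length(iss) + 1L]] <- issue(
      "ERROR", "EMPTY_DATASET", 0L, NA_character_, "dataset contains no records")
    return(new_report(bind_issues(!!!iss), records_checked = 0L))
  }

  build <- genome_build(x) %||% metadata$genome_build
  relies_on_position <- any(is.na(x$variant_id))
  if (relies_on_position && is.null(build)) {
    iss[[length(iss) + 1L]] <- issue(
      "ERROR", "MISSING_GENOME_BUILD", 0L, "genome_build",
      "records identified by chromosome + position require a declared genome build")
  }

  eaf_exempt <- privacy_masks_frequencies(
    attr(x, "privacy_profile_applied", exact = TRUE) %||%
      metadata$privacy_profile_applied)
  iss[[length(iss) + 1L]] <- record_issues(x, eaf_exempt = eaf_exempt)
  new_report(bind_issues(!!!iss), records_checked = nrow(x))
}

privacy_masks_frequencies <- function(descr) {
  !is.null(descr) && isTRUE(descr$mask_frequencies)
}

new_report <- function(issues, records_checked) {
  counts <- table(issues$code)
  structure(
    list(
      issues = issues,
      records_checked = as.integer(records_checked),
      counts_by_code = stats::setNames(as.integer(counts), names(counts)),
      valid = !any(issues$severity == "ERROR")
    ),
    class = "sumstats_report"
  )
}

#' @export
print.sumstats_report <- function(x, ...) {
  cat(sprintf("# Validation report: %s (%d record(s) checked)\n",
              if (x$valid) "VALID" else "INVALID", x$records_checked))
  if (length(x$counts_by_code)) {
    for (code in names(x$counts_by_code)) {
      cat(sprintf("  %-24s %s x%d\n", code, issue_severity(code),
                  x$counts_by_code[[code]]))
    }
  } else {
    cat("  no findings\n")
  }
  invisible(x)
}

#' Serialize a report to JSON
#'
#' Stable machine-readable form with a `schema_version` field; the text form
#' is the print method.
#'
#' @param report a `sumstats_report`, `fair_report` or metadata issue tibble.
#' @param path destination file.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  payload <- if (inherits(report, "sumstats_report")) {
    list(schema_version = 1L, kind = "validation",
         valid = report$valid, records_checked = report$records_checked,
         counts_by_code = as.list(report$counts_by_code),
         issues = report$issues)
  } else if (inherits(report, "fair_report")) {
    list(schema_version = 1L, kind = "fair", results = as_tibble(report))
  } else {
    list(schema_version = 1L, kind = "issues", issues = as_tibble(report))
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
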