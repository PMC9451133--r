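ISSUE_CODES <- local({
  r <- function(code, severity, level, injectable, description) {
    tibble(code = code, severity = severity, level = level,
           injectable = injectable, description = description)
  }
  dplyr::bind_rows(
    # file / structural (reader)
    r("MISSING_HEADER", "ERROR", "file", FALSE, "first line is not a header row"),
    r("DUPLICATE_HEADER", "ERROR", "file", FALSE, "the same column header appears more than once"),
    r("RAGGED_ROW", "ERROR", "file", FALSE, "row field count differs from the header; row skipped"),
    r("EMPTY_CELL", "WARNING", "file", FALSE, "empty cell normalized to missing (canonical token is NA)"),
    r("UNKNOWN_COLUMN", "WARNING", "file", FALSE, "non-standard column preserved as auxiliary"),
    r("INVALID_NUMBER", "ERROR", "file", FALSE, "numeric cell is not a numeral"),
    r("P_PARSE_ERROR", "ERROR", "file", FALSE, "p-value cell is not a numeral"),
    r("P_ZERO_FLOORED", "WARNING", "file", FALSE, "p = 0 mapped to the configured floor"),
    r("EMPTY_DATASET", "ERROR", "file", FALSE, "dataset contains no records"),
    r("MISSING_GENOME_BUILD", "ERROR", "file", FALSE,
      "records are identified by chromosome + position but no genome build is declared"),
    # header level
    r("MISSING_MANDATORY", "ERROR", "header", FALSE, "mandatory standard element absent from the header"),
    r("VARIANT_ID_RULE", "ERROR", "header", FALSE,
      "one form of variant ID is mandatory: variant_id, or chromosome plus base_pair_location"),
    r("EFFECT_COLUMN_CONFLICT", "ERROR", "header", FALSE, "both odds_ratio and beta present; a file carries one effect scale"),
    r("CI_UNPAIRED", "WARNING", "header", FALSE, "only one confidence-interval bound present"),
    # record level (all representable in memory, hence injectable)
    r("P_OUT_OF_RANGE", "ERROR", "record", TRUE, "p-value outside (0, 1]"),
    r("EAF_OUT_OF_RANGE", "ERROR", "record", TRUE, "effect allele frequency outside [0, 1]"),
    r("BAD_ALLELE", "ERROR", "record", TRUE, "allele is not a non-empty uppercase A/C/G/T sequence"),
    r("ALLELES_IDENTICAL", "ERROR", "record", TRUE, "effect and other allele are identical"),
    r("BAD_CHROMOSOME", "ERROR", "record", TRUE, "chromosome token outside 1-22, X, Y, MT"),
    r("BAD_POSITION", "ERROR", "record", TRUE, "base-pair location is not a positive integer"),
    r("BAD_RSID", "ERROR", "record", TRUE, "variant_id does not match rs[0-9]+"),
    r("NEG_SE", "ERROR", "record", TRUE, "standard error is negative"),
    r("NONPOS_OR", "ERROR", "record", TRUE, "odds ratio is not strictly positive"),
    r("CI_ORDER", "ERROR", "record", TRUE, "ci_lower exceeds ci_upper"),
    r("CI_NONPOS", "ERROR", "record", FALSE, "odds-ratio confidence bound is not strictly positive"),
    r("MISSING_MANDATORY_VALUE", "ERROR", "record", TRUE, "mandatory cell is missing"),
    r("DUPLICATE_VARIANT", "WARNING", "record", TRUE,
      "repeated (chromosome, base_pair_location, effect_allele, other_allele) tuple"),
    # harmonizer
    r("NORMALIZED_VALUE", "WARNING", "harmonizer", FALSE,
      "value normalized during harmonization (chr prefix stripped, allele case folded)"),
    r("AMBIGUOUS_UNRESOLVED", "WARNING", "harmonizer", FALSE,
      "ambiguous source column left unmapped; preserved as auxiliary"),
    # metadata
    r("MISSING_METADATA", "ERROR", "metadata", FALSE, "mandatory metadata element absent"),
    r("BAD_ACCESSION", "ERROR", "metadata", FALSE, "accession does not match GCST[0-9]{6,}"),
    r("BAD_EFO_ID", "ERROR", "metadata", FALSE, "trait EFO id does not match PREFIX_digits"),
    r("BAD_GENOTYPING_TECHNOLOGY", "ERROR", "metadata", FALSE,
      "genotyping technology outside {array, WGS, WES, mixed}"),
    r("MAF_CUTOFF_OUT_OF_RANGE", "ERROR", "metadata", FALSE, "MAF cutoff outside [0, 1]"),
    r("SAMPLE_COUNT_INCONSISTENT", "ERROR", "metadata", FALSE, "n_cases + n_controls exceeds n_total"),
    r("PARTIAL_REASON_MISSING", "ERROR", "metadata", FALSE, "dataset flagged partial without a reason"),
    r("UNKNOWN_ANCESTRY", "WARNING", "metadata", FALSE, "ancestry category outside the configured vocabulary"),
    r("UNKNOWN_KEY", "WARNING", "metadata", FALSE, "unrecognized metadata key preserved verbatim"),
    # lifecycle
    r("LIFECYCLE_RETRACTED", "ERROR", "lifecycle", FALSE, "operation not permitted on a retracted accession")
  )
})

#' The validation code registry
#'
#' Every finding the toolkit can emit carries a code from this registry. The
#' `injectable` flag marks the record-level codes that [inject_errors()] can
#' plant in an in-memory dataset (file- and header-level problems only exist
#' at the byte/header level and are exercised through the reader instead).
#'
#' @param injectable if `TRUE`, return only injectable codes.
#' @return A tibble with columns `code`, `severity`, `level`, `injectable`,
#'   `description`.
#' @export
issue_codes <- function(injectable = FALSE) {
  if (injectable) ISSUE_CODES[ISSUE_CODES$injectable, ] else ISSUE_CODES
}

#' @rdname issue_codes
#' @export
injectable_codes <- function() issue_codes(injectable = TRUE)$code
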