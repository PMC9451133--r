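#' Standard column set
#'
#' The standard reporting elements, in canonical file order. Exactly one of
#' `odds_ratio`/`beta` appears in a given file, according to the dataset's
#' effect type.
#'
#' @param effect_type `"beta"`, `"odds_ratio"`, or `"both"` to list every
#'   recognized header token.
#' @return character vector of standard column headers.
#' @export
standard_columns <- function(effect_type = c("both", "beta", "odds_ratio")) {
  effect_type <- match.arg(effect_type)
  eff <- switch(effect_type,
    both = c("odds_ratio", "beta"),
    beta = "beta",
    odds_ratio = "odds_ratio"
  )
  c("variant_id", "chromosome", "base_pair_location", "p_value",
    "effect_allele", "other_allele", "effect_allele_frequency",
    eff, "standard_error", "ci_upper", "ci_lower")
}

VALID_CHROMOSOMES <- c(as.character(1:22), "X", "Y", "MT")
RSID_PATTERN <- "^rs[0-9]+$"
ALLELE_PATTERN <- "^[ACGT]+$"

#' Validate allele strings
#'
#' Alleles are non-empty uppercase A/C/G/T sequences. Indels are written as
#' full alternate sequences; legacy `"D"`/`"I"` tokens, `"-"` placeholders
#' and IUPAC ambiguity codes are not allowed because they are ambiguous
#' without a reference genome.
#'
#' @param x character vector.
#' @return logical vector, `NA` where `x` is `NA`.
#' @export
is_valid_allele <- function(x) {
  out <- grepl(ALLELE_PATTERN, x)
  out[is.na(x)] <- NA
  out
}

#' Construct a summary-statistics dataset
#'
#' A `sumstats` object is a tibble of per-variant association records carrying
#' the standard reporting elements, plus file-level descriptors stored as
#' attributes: the effect scale (`beta` or `odds_ratio`), the genome build
#' anchoring chromosome/base-pair coordinates (1-based, fully closed), and a
#' free-text source name. Columns beyond the standard set are preserved
#' untouched as auxiliary columns.
#'
#' The constructor normalizes column presence (absent standard columns are
#' added as missing) and coerces types; it does not judge values — that is
#' [validate_sumstats()]'s job, so invalid records remain representable.
#'
#' @param x a data frame with some or all standard columns; the effect column
#'   must match `effect_type`.
#' @param effect_type `"beta"` or `"odds_ratio"`.
#' @param genome_build assembly token such as `"GRCh38"`; required downstream
#'   whenever records are identified by chromosome + position.
#' @param source_name free-text provenance label.
#' @return A `sumstats` tibble.
#' @examples
#' sumstats(
#'   tibble::tibble(
#'     variant_id = "rs123", chromosome = "1", base_pair_location = 5000,
#'     p_value = pval("1e-12"), effect_allele = "A", other_allele = "G",
#'     effect_allele_frequency = 0.31, beta = 0.07, standard_error = 0.01
#'   ),
#'   effect_type = "beta", genome_build = "GRCh38"
#' )
#' @export
sumstats <- function(x, effect_type = c("beta", "odds_ratio"),
                     genome_build = NULL, source_name = NULL) {
  effect_type <- match.arg(effect_type)
  present <- attr(x, "present_columns", exact = TRUE)
  x <- as_tibble(x)
  std <- standard_columns(effect_type)
  present <- present %||% intersect(names(x), std)

  chr_cols <- c("variant_id", "chromosome", "effect_allele", "other_allele")
  dbl_cols <- c("base_pair_location", "effect_allele_frequency", effect_type,
                "standard_error", "ci_upper", "ci_lower")
  n <- nrow(x)
  for (col in std) {
    if (!col %in% names(x)) {
      x[[col]] <- if (col == "p_value") pval_na(n)
                  else if (col %in% chr_cols) rep(NA_character_, n)
                  else rep(NA_real_, n)
    }
  }
  for (col in chr_cols) x[[col]] <- as.character(x[[col]])
  for (col in dbl_cols) x[[col]] <- as.double(x[[col]])
  if (!is_pval(x$p_value)) x$p_value <- pval(x$p_value)

  aux <- setdiff(names(x), std)
  x <- x[, c(std, aux)]
  new_sumstats(x, effect_type = effect_type, genome_build = genome_build,
               source_name = source_name, present_columns = present)
}

new_sumstats <- function(x, effect_type, genome_build = NULL,
                         source_name = NULL, present_columns = NULL,
                         issues = NULL, privacy_profile_applied = NULL) {
  structure(
    x,
    class = c("sumstats", class(as_tibble(x))),
    effect_type = effect_type,
    genome_build = genome_build,
    source_name = source_name,
    present_columns = present_columns,
    issues = issues,
    privacy_profile_applied = privacy_profile_applied
  )
}

#' @rdname sumstats
#' @export
is_sumstats <- function(x) inherits(x, "sumstats")

#' @rdname sumstats
#' @export
effect_type <- function(x) attr(x, "effect_type", exact = TRUE)

#' @rdname sumstats
#' @export
genome_build <- function(x) attr(x, "genome_build", exact = TRUE)

#' Issues attached to an object
#'
#' The reader, harmonizer and metadata parser attach the findings they made
#' while constructing an object. Returns an empty issue table when nothing
#' was recorded.
#'
#' @param x an object returned by [read_sumstats()], [apply_mapping()] or
#'   [read_metadata()].
#' @return A tibble with columns `severity`, `code`, `row`, `column`,
#'   `message`, `observed`.
#' @export
sumstats_issues <- function(x) {
  attr(x, "issues", exact = TRUE) %||% new_issues()
}

#' @export
print.sumstats <- function(x, ...) {
  et <- effect_type(x)
  gb <- genome_build(x) %||% "unspecified"
  cat(sprintf("# GWAS summary statistics: %d record(s), effect = %s, build = %s\n",
              nrow(x), et, gb))
  NextMethod()
}

# Rebuild the sumstats wrapper around a row subset (dplyr verbs return bare
# tibbles; use this to retain file-level descriptors).
sumstats_keep_attrs <- function(new, template) {
  new_sumstats(
    as_tibble(new),
    effect_type = effect_type(template),
    genome_build = genome_build(template),
    source_name = attr(template, "source_name", exact = TRUE),
    present_columns = attr(template, "present_columns", exact = TRUE),
    privacy_profile_applied = attr(template, "privacy_profile_applied", exact = TRUE)
  )
}
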