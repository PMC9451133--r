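ACCESSION_PATTERN <- "^GCST[0-9]{6,}$"
EFO_PATTERN <- "^[A-Za-z]+_[0-9]+$"
GENOTYPING_TECHNOLOGIES <- c("array", "WGS", "WES", "mixed")

STUDY_METADATA_FIELDS <- c(
  "accession", "trait_label", "trait_efo_id", "measurement_method",
  "samples", "genotyping_technology", "imputation_method", "imputation_panel",
  "covariates", "analysis_software", "analysis_model", "maf_cutoff",
  "n_variants_analyzed", "genome_build", "qc_description",
  "inclusion_exclusion", "license", "doi", "pmid", "is_partial",
  "partial_reason", "privacy_profile_applied", "version"
)

#' Describe one sample group
#'
#' A study's samples are described per group: total size, case/control split
#' where applicable, an ancestry category from the configured controlled
#' vocabulary, and the contributing cohort names.
#'
#' @param n_total positive integer, total group size.
#' @param ancestry_category token from the ancestry vocabulary
#'   (see [ancestry_categories()]).
#' @param n_cases,n_controls optional non-negative integers.
#' @param cohort_names character vector of cohort labels.
#' @return A named list of class `sample_group`.
#' @export
sample_group <- function(n_total, ancestry_category, n_cases = NULL,
                         n_controls = NULL, cohort_names = character()) {
  structure(
    list(n_total = as.integer(n_total),
         ancestry_category = ancestry_category,
         n_cases = if (!is.null(n_cases)) as.integer(n_cases),
         n_controls = if (!is.null(n_controls)) as.integer(n_controls),
         cohort_names = as.character(cohort_names)),
    class = "sample_group"
  )
}

#' Study metadata
#'
#' The machine-readable description accompanying a summary-statistics
#' dataset. The mandatory elements mirror the community recommendation:
#' sample size (with cases/controls), sample ancestry, imputation method and
#' reference panel, covariates, trait measurement method, sample
#' inclusions/exclusions, cohort descriptors, analysis model and software,
#' genotyping technology, MAF cutoff, quality-control description, and the
#' number of variants analyzed. Absent fields stay absent (`NULL`) — parsing
#' never invents defaults; [validate_metadata()] is the separate step that
#' judges completeness.
#'
#' Lifecycle fields: `is_partial` flags a released subset of the full
#' results (a reason is then required), `version` counts dataset versions,
#' and `privacy_profile_applied` records any [apply_privacy_profile()]
#' transforms so validators can exempt masked frequencies.
#'
#' @param ... metadata fields by name; unknown names are an error. See
#'   `sumstatr:::STUDY_METADATA_FIELDS` for the full set.
#' @return A `study_metadata` object.
#' @export
study_metadata <- function(...) {
  fields <- list(...)
  unknown <- setdiff(names(fields), STUDY_METADATA_FIELDS)
  if (length(unknown)) {
    stopf("sumstatr_metadata_error", "unknown metadata field(s): %s",
          paste(unknown, collapse = ", "))
  }
  out <- stats::setNames(vector("list", length(STUDY_METADATA_FIELDS)),
                         STUDY_METADATA_FIELDS)
  for (nm in names(fields)) out[[nm]] <- fields[[nm]]
  if (!is.null(out$samples)) {
    out$samples <- lapply(out$samples, function(s) {
      if (inherits(s, "sample_group")) s else do.call(sample_group, s)
    })
  }
  structure(out, class = "study_metadata")
}

#' @export
print.study_metadata <- function(x, ...) {
  cat("# Study metadata\n")
  for (nm in STUDY_METADATA_FIELDS) {
    v <- x[[nm]]
    if (is.null(v)) next
    if (nm == "samples") {
      for (s in v) {
        cat(sprintf("  samples: n=%d ancestry=%s cohorts=%s\n", s$n_total,
                    s$ancestry_category, paste(s$cohort_names, collapse = "+")))
      }
    } else if (nm == "privacy_profile_applied") {
      cat(sprintf("  %s: %s\n", nm, paste(names(unlist(v)), unlist(v),
                                          sep = "=", collapse = " ")))
    } else {
      cat(sprintf("  %s: %s\n", nm, paste(v, collapse = ", ")))
    }
  }
  invisible(x)
}

#' The configured ancestry vocabulary
#'
#' @param path YAML file with an `ancestry_categories` list; default is the
#'   vocabulary shipped with the package, seeded from the GWAS Catalog
#'   standardized ancestry framework.
#' @return character vector of category tokens.
#' @export
ancestry_categories <- function(path = NULL) {
  path <- path %||% system.file("extdata", "ancestry_categories.yaml",
                                package = "sumstatr")
  as.character(yaml::read_yaml(path)$ancestry_categories)
}

#' Validate study metadata
#'
#' Emits one `MISSING_METADATA` error per absent mandatory element, pattern
#' errors for the accession (`GCST` + at least six digits) and the trait EFO
#' CURIE, a consistency error when cases + controls exceed the group total,
#' and warnings for ancestry tokens outside the configured vocabulary.
#' Pure: the same object always yields the same findings.
#'
#' @param meta a [study_metadata] object.
#' @param ancestry_vocabulary character vector of accepted ancestry tokens.
#' @return An issue tibble (`row` is 0 throughout; `column` names the field).
#' @export
validate_metadata <- function(meta, ancestry_vocabulary = ancestry_categories()) {
  stopifnot(inherits(meta, "study_metadata"))
  iss <- list()
  add <- function(severity, code, column, message, observed = NA_character_) {
    iss[[length(iss) + 1L]] <<- issue(severity, code, 0L, column, message,
                                      as.character(observed))
  }
  absent <- function(v) {
    is.null(v) || length(v) == 0L || (is.character(v) && all(!nzchar(v)))
  }
  mandatory <- c("trait_label", "measurement_method", "imputation_method",
                 "imputation_panel", "covariates", "analysis_model",
                 "analysis_software", "genotyping_technology", "maf_cutoff",
                 "qc_description", "n_variants_analyzed", "inclusion_exclusion")
  for (f in mandatory) {
    if (absent(meta[[f]])) {
      add("ERROR", "MISSING_METADATA", f, sprintf("mandatory element '%s' is absent", f))
    }
  }
  any_cohort <- FALSE
  if (absent(meta$samples)) {
    add("ERROR", "MISSING_METADATA", "samples", "at least one sample group is required")
  } else {
    for (i in seq_along(meta$samples)) {
      s <- meta$samples[[i]]
      tag <- sprintf("samples[%d]", i)
      if (absent(s$n_total)) {
        add("ERROR", "MISSING_METADATA", paste0(tag, ".n_total"), "sample size is required")
      }
      if (absent(s$ancestry_category)) {
        add("ERROR", "MISSING_METADATA", paste0(tag, ".ancestry_category"),
            "sample ancestry is required")
      } else if (!s$ancestry_category %in% ancestry_vocabulary) {
        add("WARNING", "UNKNOWN_ANCESTRY", paste0(tag, ".ancestry_category"),
            "ancestry category outside the configured vocabulary",
            s$ancestry_category)
      }
      if (!is.null(s$n_cases) && !is.null(s$n_controls) && !is.null(s$n_total) &&
          s$n_cases + s$n_controls > s$n_total) {
        add("ERROR", "SAMPLE_COUNT_INCONSISTENT", paste0(tag, ".n_total"),
            "n_cases + n_controls exceeds n_total",
            sprintf("%d+%d>%d", s$n_cases, s$n_controls, s$n_total))
      }
      if (length(s$cohort_names)) any_cohort <- TRUE
    }
  }
  if (!any_cohort) {
    add("ERROR", "MISSING_METADATA", "cohort_names",
        "cohort descriptors are required (no sample group names a cohort)")
  }
  if (!is.null(meta$accession) && !grepl(ACCESSION_PATTERN, meta$accession)) {
    add("ERROR", "BAD_ACCESSION", "accession",
        "accession does not match GCST[0-9]{6,}", meta$accession)
  }
  if (!is.null(meta$trait_efo_id) && !grepl(EFO_PATTERN, meta$trait_efo_id)) {
    add("ERROR", "BAD_EFO_ID", "trait_efo_id",
        "trait EFO id does not match PREFIX_digits", meta$trait_efo_id)
  }
  if (!is.null(meta$genotyping_technology) &&
      !meta$genotyping_technology %in% GENOTYPING_TECHNOLOGIES) {
    add("ERROR", "BAD_GENOTYPING_TECHNOLOGY", "genotyping_technology",
        sprintf("must be one of %s", paste(GENOTYPING_TECHNOLOGIES, collapse = ", ")),
        meta$genotyping_technology)
  }
  if (!is.null(meta$maf_cutoff) && (meta$maf_cutoff < 0 || meta$maf_cutoff > 1)) {
    add("ERROR", "MAF_CUTOFF_OUT_OF_RANGE", "maf_cutoff",
        "MAF cutoff must lie in [0, 1]", meta$maf_cutoff)
  }
  if (isTRUE(meta$is_partial) && absent(meta$partial_reason)) {
    add("ERROR", "PARTIAL_REASON_MISSING", "partial_reason",
        "datasets flagged partial must state why full sharing was not possible")
  }
  bind_issues(!!!iss)
}

meta_to_list <- function(meta) {
  out <- list()
  for (nm in STUDY_METADATA_FIELDS) {
    v <- meta[[nm]]
    if (is.null(v)) next
    if (nm == "samples") {
      v <- lapply(v, function(s) {
        s <- unclass(s)
        s[!vapply(s, is.null, logical(1))]
      })
    }
    out[[nm]] <- v
  }
  out
}

sort_keys <- function(x) {
  if (!is.list(x)) return(x)
  if (!is.null(names(x)) && all(nzchar(names(x)))) {
    x <- x[order(names(x))]
  }
  lapply(x, sort_keys)
}

#' Read and write study metadata documents
#'
#' The canonical on-disk form is a YAML sidecar (`<accession>-meta.yaml`)
#' next to the data file — the data file itself stays strictly tabular; JSON
#' documents are also accepted (by `.json` extension). Reading is lossless
#' and never invents defaults: absent fields stay absent, and unknown keys
#' are preserved under `$extra` with an `UNKNOWN_KEY` warning retrievable via
#' [sumstats_issues()]. Writing is deterministic (recursively sorted keys),
#' so identical objects serialize to identical bytes.
#'
#' @param path metadata document (`.yaml`/`.yml` or `.json`).
#' @return `read_metadata()`: a [study_metadata] object.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) {
    stopf("sumstatr_io_error", "cannot read '%s': no such file", path)
  }
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
             error = function(e) stopf("sumstatr_metadata_error",
                                       "malformed JSON in '%s': %s", path,
                                       conditionMessage(e)))
  } else {
    tryCatch(yaml::read_yaml(path),
             error = function(e) stopf("sumstatr_metadata_error",
                                       "malformed YAML in '%s': %s", path,
                                       conditionMessage(e)))
  }
  if (is.null(doc)) doc <- list()
  known <- intersect(names(doc), STUDY_METADATA_FIELDS)
  unknown <- setdiff(names(doc), STUDY_METADATA_FIELDS)
  fields <- doc[known]
  if (!is.null(fields$covariates)) fields$covariates <- as.character(unlist(fields$covariates))
  meta <- do.call(study_metadata, fields)
  iss <- list()
  for (k in unknown) {
    iss[[length(iss) + 1L]] <- issue(
      "WARNING", "UNKNOWN_KEY", 0L, k, "unrecognized metadata key preserved verbatim",
      k)
  }
  if (length(unknown)) attr(meta, "extra") <- doc[unknown]
  attr(meta, "issues") <- bind_issues(!!!iss)
  meta
}

#' @rdname read_metadata
#' @param meta a [study_metadata] object.
#' @param default_license if `TRUE` and no license is set, write the
#'   recommended default (`CC0`). Off by default so that serialization never
#'   silently adds content.
#' @return `write_metadata()`: invisibly, the number of bytes written.
#' @export
write_metadata <- function(meta, path, default_license = FALSE) {
  stopifnot(inherits(meta, "study_metadata"))
  lst <- meta_to_list(meta)
  if (default_license && is.null(lst$license)) lst$license <- "CC0"
  extra <- attr(meta, "extra", exact = TRUE)
  if (!is.null(extra)) lst <- c(lst, extra)
  lst <- sort_keys(lst)
  payload <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::toJSON(lst, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::as.yaml(lst)
  }
  payload <- paste0(sub("\n$", "", payload), "\n")
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  writeBin(charToRaw(enc2utf8(payload)), con)
  invisible(nchar(payload, type = "bytes"))
}

#' A fully populated conformant metadata example
#'
#' Used in documentation and as a starting point for constructing bundles; it
#' satisfies every mandatory-element and pattern rule in
#' [validate_metadata()].
#'
#' @param accession optional accession token to set.
#' @return A [study_metadata] object.
#' @export
example_study_metadata <- function(accession = NULL) {
  study_metadata(
    accession = accession,
    trait_label = "systolic blood pressure",
    trait_efo_id = "EFO_0006335",
    measurement_method = "clinically measured, mean of two readings",
    samples = list(
      sample_group(n_total = 45000L, ancestry_category = "European",
                   n_cases = 18000L, n_controls = 27000L,
                   cohort_names = c("COHORT-A", "COHORT-B"))
    ),
    genotyping_technology = "array",
    imputation_method = "minimac4",
    imputation_panel = "1000 Genomes Phase 3",
    covariates = c("age", "sex", "PC1-PC10"),
    analysis_software = "regenie 3.2",
    analysis_model = "additive linear mixed model",
    maf_cutoff = 0.01,
    n_variants_analyzed = 8000000L,
    genome_build = "GRCh38",
    qc_description = "info > 0.8, HWE p > 1e-6, call rate > 0.98",
    inclusion_exclusion = "unrelated adults; excluded pregnancy and secondary hypertension",
    license = "CC0",
    doi = "10.0000/example.1",
    pmid = "00000000",
    is_partial = FALSE,
    version = 1L
  )
}
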