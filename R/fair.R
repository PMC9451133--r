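FAIR_INDICATORS <- tibble(
  indicator = c("F1", "F2", "F3", "F4", "A1", "A1.1", "A1.2", "A2",
                "I1", "I2", "I3", "R1", "R1.1", "R1.2", "R1.3"),
  principle = c(rep("Findable", 4), rep("Accessible", 4),
                rep("Interoperable", 3), rep("Reusable", 4))
)

#' The FAIR indicator checklist
#'
#' @return A tibble of the fifteen indicators (F1..R1.3) with their core
#'   FAIR principle.
#' @export
fair_indicators <- function() FAIR_INDICATORS

#' FAIR self-assessment of a dataset bundle
#'
#' Evaluates a bundle — study metadata, optionally the summary-statistics
#' dataset and a ledger entry — against the FAIR indicator checklist and
#' returns one row per indicator with status `pass`, `fail` or
#' `not_auto_checkable` plus free-text evidence.
#'
#' Auto-checked indicators:
#' * **F1** — accession present, pattern-valid, and (when a ledger is
#'   supplied) registered there.
#' * **F2 / R1** — [validate_metadata()] yields no ERROR (rich, conformant
#'   metadata).
#' * **F3** — the metadata's accession equals the bundle's accession.
#' * **A1.2** — trivially satisfied: distribution is open, authentication is
#'   not applicable.
#' * **A2** — metadata resolvable even when the dataset is absent or the
#'   entry retracted.
#' * **I2** — controlled vocabularies: EFO trait CURIE present and
#'   pattern-valid, Genome Reference Consortium build token; the fraction of
#'   records carrying dbSNP rsIDs is reported as evidence, not gated.
#' * **R1.1** — a data-use license is declared.
#' * **R1.2** — provenance: a DOI or PMID is present.
#' * **R1.3** — [validate_sumstats()] finds the dataset valid.
#'
#' F4, A1, A1.1, I1 and I3 are properties of the hosting repository
#' (searchability, retrieval protocol, knowledge representation, cross
#' links); they are reported as `not_auto_checkable` rather than guessed.
#'
#' @param metadata a [study_metadata] object (required — it is what remains
#'   accessible even when data are gone).
#' @param data optional [sumstats] dataset.
#' @param ledger optional [ledger_open()] handle holding the bundle's entry.
#' @param accession the bundle's accession (e.g. from its file names);
#'   compared against the metadata's accession for F3.
#' @return A `fair_report` tibble: `indicator`, `principle`, `status`,
#'   `evidence`.
#' @export
evaluate_fair <- function(metadata, data = NULL, ledger = NULL, accession = NULL) {
  stopifnot(inherits(metadata, "study_metadata"))
  res <- list()
  say <- function(indicator, status, evidence) {
    res[[indicator]] <<- list(status = status, evidence = evidence)
  }

  acc <- metadata$accession
  if (is.null(acc) || !grepl(ACCESSION_PATTERN, acc)) {
    say("F1", "fail", sprintf("metadata accession %s is absent or not pattern-valid",
                              acc %||% "<none>"))
  } else if (!is.null(ledger) && !acc %in% ledger_accessions(ledger)) {
    say("F1", "fail", sprintf("%s is not registered in the ledger", acc))
  } else {
    say("F1", "pass", sprintf("unique identifier %s%s", acc,
                              if (is.null(ledger)) "" else " registered in the ledger"))
  }

  meta_issues <- validate_metadata(metadata)
  meta_ok <- !any(meta_issues$severity == "ERROR")
  rich_evidence <- if (meta_ok) {
    "metadata carry every mandatory reporting element"
  } else {
    sprintf("metadata validation errors: %s",
            paste(unique(meta_issues$code[meta_issues$severity == "ERROR"]),
                  collapse = ", "))
  }
  say("F2", if (meta_ok) "pass" else "fail", rich_evidence)
  say("R1", if (meta_ok) "pass" else "fail", rich_evidence)

  if (is.null(accession)) {
    say("F3", "fail", "bundle accession unknown: metadata cannot be linked to the data they describe")
  } else if (identical(acc, accession)) {
    say("F3", "pass", sprintf("metadata include the bundle accession %s", accession))
  } else {
    say("F3", "fail", sprintf("metadata accession %s != bundle accession %s",
                              acc %||% "<none>", accession))
  }

  say("F4", "not_auto_checkable",
      "searchability by accession, trait or publication is a repository property")
  say("A1", "not_auto_checkable",
      "retrieval over a standardized protocol (web/API) is a repository property")
  say("A1.1", "not_auto_checkable",
      "openness of the retrieval protocol is a repository property")
  say("A1.2", "pass",
      "distribution is open and unrestricted; an authentication and authorization protocol is not applicable")

  retracted <- FALSE
  if (!is.null(ledger) && !is.null(acc) && acc %in% ledger_accessions(ledger)) {
    retracted <- identical(accession_status(ledger, acc)$status, "retracted")
  }
  say("A2", "pass", sprintf(
    "metadata remain resolvable%s%s",
    if (is.null(data)) " although the dataset is absent" else " alongside the dataset",
    if (retracted) "; entry is retracted and carries its retraction indication" else ""))

  say("I1", "not_auto_checkable",
      "knowledge-representation language of the access interface is a repository property")

  efo_ok <- !is.null(metadata$trait_efo_id) && grepl(EFO_PATTERN, metadata$trait_efo_id)
  build <- metadata$genome_build %||% (if (!is.null(data)) genome_build(data))
  build_ok <- !is.null(build) && grepl("^GRCh[0-9]+(\\.p[0-9]+)?$", build)
  rs_evidence <- if (!is.null(data) && nrow(data) > 0) {
    sprintf("; %.1f%% of records carry dbSNP rsIDs",
            100 * mean(!is.na(data$variant_id) & grepl(RSID_PATTERN, data$variant_id)))
  } else ""
  say("I2", if (efo_ok && build_ok) "pass" else "fail",
      sprintf("trait EFO CURIE %s; genome build %s%s",
              if (efo_ok) metadata$trait_efo_id else "missing or malformed",
              if (build_ok) build else "is not a Genome Reference Consortium token",
              rs_evidence))

  say("I3", "not_auto_checkable",
      "qualified references to external records are a repository property")

  if (!is.null(metadata$license) && nzchar(metadata$license)) {
    say("R1.1", "pass", sprintf("data usage license declared: %s", metadata$license))
  } else {
    say("R1.1", "fail", "no data usage license declared")
  }

  if ((!is.null(metadata$doi) && nzchar(metadata$doi)) ||
      (!is.null(metadata$pmid) && nzchar(metadata$pmid))) {
    say("R1.2", "pass", sprintf("provenance link present (%s)",
                                paste(c(if (!is.null(metadata$doi)) paste0("doi:", metadata$doi),
                                        if (!is.null(metadata$pmid)) paste0("pmid:", metadata$pmid)),
                                      collapse = ", ")))
  } else {
    say("R1.2", "fail", "neither DOI nor PMID present")
  }

  if (is.null(data)) {
    say("R1.3", "fail", "no dataset available to check against the community standard")
  } else {
    rep13 <- validate_sumstats(data, metadata = metadata)
    say("R1.3", if (rep13$valid) "pass" else "fail",
        if (rep13$valid) "dataset conforms to the community standard (0 validation errors)"
        else sprintf("dataset validation errors: %s",
                     paste(names(rep13$counts_by_code), collapse = ", ")))
  }

  out <- FAIR_INDICATORS
  out$status <- vapply(out$indicator, function(i) res[[i]]$status, character(1))
  out$evidence <- vapply(out$indicator, function(i) res[[i]]$evidence, character(1))
  structure(out, class = c("fair_report", class(out)))
}

#' @export
print.fair_report <- function(x, ...) {
  cat("# FAIR indicator self-assessment\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-5s [%-18s] %s\n", x$indicator[[i]], x$status[[i]],
                x$evidence[[i]]))
  }
  n_auto <- sum(x$status != "not_auto_checkable")
  cat(sprintf("  %d/%d auto-checkable indicators pass\n",
              sum(x$status == "pass"), n_auto))
  invisible(x)
}
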