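#' The shipped column-alias table
#'
#' Loads the packaged alias configuration (or a user-supplied YAML file of
#' the same shape: an `aliases` map from standard element to accepted
#' headers, and an `ambiguous` map from header to candidate elements).
#'
#' @param path YAML file; default is the table shipped with the package.
#' @return list with elements `aliases` and `ambiguous`.
#' @export
default_aliases <- function(path = NULL) {
  path <- path %||% system.file("extdata", "column_aliases.yaml", package = "sumstatr")
  cfg <- yaml::read_yaml(path)
  stopifnot(is.list(cfg$aliases), is.list(cfg$ambiguous))
  cfg
}

#' Detect a summary-statistics dialect
#'
#' Maps an ordered set of source headers onto the standard reporting
#' elements using the shipped alias table, case-insensitively. Headers whose
#' community usage conflicts across tools (`A1`, `A2`, `REF`, `ALT`,
#' `Allele1`, ... and `MAF`/`FRQ`-style frequency columns, which may be
#' minor- rather than effect-allele frequencies) are returned as *ambiguous*
#' with their candidate elements and are never auto-assigned — a wrong
#' effect-allele or frequency assignment corrupts every downstream use
#' silently. Exact standard headers map to themselves.
#'
#' @param headers character vector of source column headers (unique after
#'   case-folding).
#' @param aliases alias configuration, see [default_aliases()].
#' @return A `column_mapping`: list with `assignments` (named character
#'   vector, source header -> standard element), `ambiguous` (tibble with
#'   `header` and list-column `candidates`) and `unmapped` (character).
#' @export
detect_dialect <- function(headers, aliases = default_aliases()) {
  stopifnot(length(headers) > 0)
  folded <- tolower(headers)
  if (anyDuplicated(folded)) {
    stopf("sumstatr_harmonize_error",
          "duplicate headers after case-folding: %s",
          paste(unique(headers[duplicated(folded)]), collapse = ", "))
  }
  lut <- unlist(lapply(names(aliases$aliases), function(el) {
    stats::setNames(rep(el, length(aliases$aliases[[el]])),
                    tolower(aliases$aliases[[el]]))
  }))
  amb_lut <- stats::setNames(aliases$ambiguous, tolower(names(aliases$ambiguous)))

  assignments <- character()
  amb_headers <- character()
  amb_cands <- list()
  unmapped <- character()
  for (i in seq_along(headers)) {
    h <- headers[[i]]
    f <- folded[[i]]
    if (f %in% names(amb_lut)) {
      amb_headers <- c(amb_headers, h)
      amb_cands <- c(amb_cands, list(as.character(amb_lut[[f]])))
    } else if (f %in% names(lut)) {
      el <- unname(lut[[f]])
      if (el %in% assignments) {
        unmapped <- c(unmapped, h) # element already taken by an earlier header
      } else {
        assignments[h] <- el
      }
    } else {
      unmapped <- c(unmapped, h)
    }
  }
  structure(
    list(
      assignments = assignments,
      ambiguous = tibble(header = amb_headers, candidates = amb_cands),
      unmapped = unmapped
    ),
    class = "column_mapping"
  )
}

#' @export
print.column_mapping <- function(x, ...) {
  cat("# Column mapping\n")
  if (length(x$assignments)) {
    for (h in names(x$assignments)) cat(sprintf("  %-24s -> %s\n", h, x$assignments[[h]]))
  }
  if (nrow(x$ambiguous)) {
    for (i in seq_len(nrow(x$ambiguous))) {
      cat(sprintf("  %-24s ?? ambiguous: %s (needs override)\n",
                  x$ambiguous$header[[i]],
                  paste(x$ambiguous$candidates[[i]], collapse = " | ")))
    }
  }
  if (length(x$unmapped)) cat("  unmapped:", paste(x$unmapped, collapse = ", "), "\n")
  invisible(x)
}

#' Apply a column mapping to a raw table
#'
#' Converts a raw (all-character) table into a standard [sumstats] dataset
#' under a detected mapping plus user overrides. Overrides must resolve every
#' ambiguous header that is needed to cover the mandatory elements; the
#' merged assignment must satisfy [check_header()]. Value conventions are
#' normalized with WARNING findings rather than rejected (`chr`-prefixed
#' chromosomes stripped, lowercase alleles uppercased): the harmonizer fixes,
#' the validator judges. Unmapped columns are preserved as auxiliary.
#'
#' @param rows a data frame of character columns (e.g. from a foreign TSV).
#' @param mapping a `column_mapping` from [detect_dialect()].
#' @param overrides named character vector, source header -> standard
#'   element, resolving ambiguous (or unmapped) headers.
#' @param genome_build,source_name attached to the resulting dataset.
#' @param p_floor optional floor for `p = 0` cells, as in [read_sumstats()].
#' @return A [sumstats] object; per-cell parse failures are ERROR findings in
#'   its `issues` attribute.
#' @export
apply_mapping <- function(rows, mapping, overrides = character(),
                          genome_build = NULL, source_name = NULL,
                          p_floor = NULL) {
  stopifnot(inherits(mapping, "column_mapping"))
  rows <- as_tibble(rows)
  std_all <- standard_columns("both")

  merged <- mapping$assignments
  if (length(overrides)) {
    bad_el <- setdiff(unname(overrides), std_all)
    if (length(bad_el)) {
      stopf("sumstatr_harmonize_error",
            "override targets unknown element(s): %s", paste(bad_el, collapse = ", "))
    }
    for (h in names(overrides)) {
      if (!h %in% names(rows)) {
        stopf("sumstatr_harmonize_error", "override source '%s' is not a column", h)
      }
      merged[h] <- overrides[[h]]
    }
  }
  if (anyDuplicated(unname(merged))) {
    dup <- unique(unname(merged)[duplicated(unname(merged))])
    stopf("sumstatr_harmonize_error",
          "standard element assigned twice: %s", paste(dup, collapse = ", "))
  }

  elements <- unname(merged)
  header_issues <- check_header(elements)
  errs <- header_issues[header_issues$severity == "ERROR", , drop = FALSE]
  if (nrow(errs)) {
    unresolved <- mapping$ambiguous[!mapping$ambiguous$header %in% names(overrides), , drop = FALSE]
    needed <- unlist(lapply(seq_len(nrow(errs)), function(i) {
      switch(errs$code[[i]],
        MISSING_MANDATORY = if (errs$column[[i]] == "odds_ratio|beta")
          c("odds_ratio", "beta") else errs$column[[i]],
        VARIANT_ID_RULE = c("variant_id", "chromosome", "base_pair_location"),
        character())
    }))
    could_fix <- any(vapply(
      unresolved$candidates,
      function(cand) length(intersect(cand, needed)) > 0,
      logical(1)))
    if (nrow(unresolved) && could_fix) {
      stopf("sumstatr_harmonize_error",
            "ambiguous header(s) touch mandatory elements and need --map overrides: %s",
            paste(unresolved$header, collapse = ", "),
            code = "HARMONIZE_AMBIGUOUS")
    }
    stopf("sumstatr_harmonize_error",
          "mandatory element(s) absent after mapping: %s",
          paste(errs$column, collapse = ", "),
          code = "MISSING_MANDATORY")
  }

  et <- if ("odds_ratio" %in% elements) "odds_ratio" else "beta"
  issues <- list()
  out <- tibble(.rows = nrow(rows))
  for (h in names(merged)) {
    el <- merged[[h]]
    raw <- as.character(rows[[h]])
    raw[raw %in% c("", "NA")] <- NA_character_
    n <- length(raw)
    if (el == "chromosome") {
      pref <- which(!is.na(raw) & grepl("^(?i)chr", raw))
      if (length(pref)) {
        issues[[length(issues) + 1L]] <- new_issues(
          severity = "WARNING", code = rep("NORMALIZED_VALUE", length(pref)),
          row = pref, column = rep("chromosome", length(pref)),
          message = rep("'chr' prefix stripped", length(pref)), observed = raw[pref])
        raw[pref] <- sub("^(?i)chr", "", raw[pref], perl = TRUE)
      }
      out[[el]] <- raw
    } else if (el %in% c("effect_allele", "other_allele")) {
      up <- toupper(raw)
      low <- which(!is.na(raw) & raw != up)
      if (length(low)) {
        issues[[length(issues) + 1L]] <- new_issues(
          severity = "WARNING", code = rep("NORMALIZED_VALUE", length(low)),
          row = low, column = rep(el, length(low)),
          message = rep("allele case folded to uppercase", length(low)),
          observed = raw[low])
      }
      out[[el]] <- up
    } else if (el == "p_value") {
      parts <- pv_parse_quiet(raw)
      if (!is.null(p_floor)) {
        fl <- pval(p_floor)
        zi <- which(parts$code %in% "P_ZERO")
        if (length(zi)) {
          parts$mantissa[zi] <- vctrs::field(fl, "mantissa")
          parts$exponent[zi] <- vctrs::field(fl, "exponent")
          parts$code[zi] <- NA_character_
          issues[[length(issues) + 1L]] <- new_issues(
            severity = "WARNING", code = rep("P_ZERO_FLOORED", length(zi)),
            row = zi, column = rep("p_value", length(zi)),
            message = rep(sprintf("p = 0 floored to %s", format_pvalue(fl)), length(zi)),
            observed = raw[zi])
        }
      }
      parts$code[parts$code %in% "P_ZERO"] <- "P_OUT_OF_RANGE"
      bad <- which(!is.na(parts$code))
      if (length(bad)) {
        issues[[length(issues) + 1L]] <- new_issues(
          severity = "ERROR", code = parts$code[bad], row = bad,
          column = rep("p_value", length(bad)),
          message = ifelse(parts$code[bad] == "P_PARSE_ERROR",
                           "p-value cell is not a numeral", "p-value outside (0, 1]"),
          observed = raw[bad])
      }
      out[[el]] <- new_pval(parts$mantissa, parts$exponent)
    } else if (el == "variant_id") {
      out[[el]] <- raw
    } else {
      val <- suppressWarnings(as.numeric(raw))
      bad <- which(!is.na(raw) & is.na(val))
      if (length(bad)) {
        issues[[length(issues) + 1L]] <- new_issues(
          severity = "ERROR", code = rep("INVALID_NUMBER", length(bad)),
          row = bad, column = rep(el, length(bad)),
          message = rep("cell is not a numeral; value set to missing", length(bad)),
          observed = raw[bad])
      }
      out[[el]] <- val
    }
  }

  unresolved_amb <- setdiff(mapping$ambiguous$header, names(overrides))
  for (h in unresolved_amb) {
    issues[[length(issues) + 1L]] <- issue(
      "WARNING", "AMBIGUOUS_UNRESOLVED", 0L, h,
      "ambiguous source column preserved as auxiliary (no override supplied)")
  }
  aux_cols <- setdiff(names(rows), names(merged))
  for (h in aux_cols) out[[h]] <- as.character(rows[[h]])

  attr(out, "present_columns") <- intersect(std_all, elements)
  res <- sumstats(out, effect_type = et, genome_build = genome_build,
                  source_name = source_name)
  attr(res, "issues") <- bind_issues(!!!issues)
  res
}

#' Harmonize a foreign summary-statistics file
#'
#' One-step convenience: read a foreign tab-separated file as raw text,
#' detect its dialect, apply overrides, and return a standard [sumstats]
#' dataset. Harmonizing an already-standard file is the identity: rewriting
#' it with [write_sumstats()] reproduces the input bytes.
#'
#' @param path tab-separated source file (optionally gzipped).
#' @param overrides named character vector, source header -> standard element.
#' @param aliases alias configuration, see [default_aliases()].
#' @inheritParams apply_mapping
#' @return A [sumstats] object.
#' @export
harmonize_sumstats <- function(path, overrides = character(),
                               aliases = default_aliases(),
                               genome_build = NULL, p_floor = NULL) {
  raw <- read_raw_tsv(path)
  mapping <- detect_dialect(names(raw), aliases = aliases)
  apply_mapping(raw, mapping, overrides = overrides,
                genome_build = genome_build, source_name = basename(path),
                p_floor = p_floor)
}

# Raw all-character TSV read (no value interpretation), used by the
# harmonizer front end.
read_raw_tsv <- function(path) {
  if (!file.exists(path)) {
    stopf("sumstatr_io_error", "cannot read '%s': no such file", path)
  }
  con <- gzfile(path, open = "rt", encoding = "UTF-8")
  on.exit(close(con), add = TRUE)
  lines <- readLines(con, warn = FALSE)
  if (length(lines) == 0L) stopf("sumstatr_io_error", "'%s' is empty", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  cells <- strsplit(lines[-1L], "\t", fixed = TRUE)
  lens <- lengths(cells)
  short1 <- which(lens == length(header) - 1L & endsWith(lines[-1L], "\t"))
  for (i in short1) cells[[i]] <- c(cells[[i]], "")
  keep <- which(lengths(cells) == length(header))
  mat <- matrix(unlist(cells[keep], use.names = FALSE),
                nrow = length(keep), ncol = length(header), byrow = TRUE)
  colnames(mat) <- header
  as_tibble(as.data.frame(mat, stringsAsFactors = FALSE))
}
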