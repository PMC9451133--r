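#' Read a standard-format summary-statistics file
#'
#' Reads the community standard tab-separated format: a header row of
#' standard column tokens, UTF-8, LF line endings, `"NA"` for missing cells,
#' optionally gzip-compressed (detected transparently). Unknown columns are
#' preserved as auxiliary columns with a `UNKNOWN_COLUMN` warning; structural
#' problems (ragged rows, duplicate headers) are reported as `ERROR` issues;
#' every parseable record is returned even when some rows fail. Findings are
#' attached to the result and retrievable with [sumstats_issues()].
#'
#' @param path path to a `.tsv` or `.tsv.gz` file.
#' @param genome_build assembly token to attach (normally from the metadata
#'   sidecar; the data file itself is strictly tabular).
#' @param p_floor optional floor for `p = 0` cells, e.g. `"1e-999"`. By
#'   default an exact zero is an error finding (`P_OUT_OF_RANGE`): silently
#'   coercing it would hide upstream underflow bugs. When a floor is given,
#'   zero cells are mapped to it with a `P_ZERO_FLOORED` warning instead.
#' @return A [sumstats] tibble with an `issues` attribute.
#' @export
read_sumstats <- function(path, genome_build = NULL, p_floor = NULL) {
  if (!file.exists(path)) {
    stopf("sumstatr_io_error", "cannot read '%s': no such file", path)
  }
  con <- gzfile(path, open = "rt", encoding = "UTF-8")
  on.exit(close(con), add = TRUE)
  lines <- readLines(con, warn = FALSE)
  if (length(lines) == 0L) {
    stopf("sumstatr_io_error", "'%s' is empty", path)
  }

  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (all(grepl("^[-+0-9.eE]*$", header))) {
    stopf("sumstatr_structural_error",
          "'%s' has no header row (first line looks numeric)", path,
          code = "MISSING_HEADER")
  }
  issues <- list()
  dup <- duplicated(header)
  if (any(dup)) {
    issues[[length(issues) + 1L]] <- issue(
      "ERROR", "DUPLICATE_HEADER", 0L, header[dup][1L],
      "duplicate column header", paste(unique(header[dup]), collapse = ","))
    header[dup] <- paste0(header[dup], ".dup", cumsum(dup)[dup])
  }
  std_all <- standard_columns("both")
  unknown <- setdiff(header, std_all)
  for (col in unknown) {
    issues[[length(issues) + 1L]] <- issue(
      "WARNING", "UNKNOWN_COLUMN", 0L, col,
      "column is not a standard reporting element; preserved as auxiliary", col)
  }

  ncol <- length(header)
  body <- lines[-1L]
  cells <- strsplit(body, "\t", fixed = TRUE)
  # a trailing empty field is dropped by strsplit; pad rows one short whose
  # line ends in a tab
  lens <- lengths(cells)
  short1 <- which(lens == ncol - 1L & endsWith(body, "\t"))
  for (i in short1) cells[[i]] <- c(cells[[i]], "")
  lens[short1] <- ncol
  ragged <- which(lens != ncol)
  for (i in ragged) {
    issues[[length(issues) + 1L]] <- issue(
      "ERROR", "RAGGED_ROW", i, NA_character_,
      sprintf("expected %d fields, found %d; row skipped", ncol, lens[i]),
      body[[i]])
  }
  keep <- setdiff(seq_along(cells), ragged)
  mat <- matrix(unlist(cells[keep], use.names = FALSE),
                nrow = length(keep), ncol = ncol, byrow = TRUE)
  colnames(mat) <- header
  rowid <- keep # record index (1-based, header excluded)

  empty <- which(mat == "", arr.ind = TRUE)
  if (nrow(empty)) {
    issues[[length(issues) + 1L]] <- new_issues(
      severity = "WARNING", code = rep("EMPTY_CELL", nrow(empty)),
      row = rowid[empty[, 1L]], column = header[empty[, 2L]],
      message = "empty cell normalized to missing", observed = "")
    mat[empty] <- NA_character_
  }
  mat[mat == "NA"] <- NA_character_

  get_col <- function(nm) {
    if (nm %in% colnames(mat)) unname(mat[, nm]) else rep(NA_character_, nrow(mat))
  }

  num_col <- function(nm) {
    raw <- get_col(nm)
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(val))
    if (length(bad)) {
      issues[[length(issues) + 1L]] <<- new_issues(
        severity = "ERROR", code = rep("INVALID_NUMBER", length(bad)),
        row = rowid[bad], column = rep(nm, length(bad)),
        message = rep("cell is not a numeral; value set to missing", length(bad)),
        observed = raw[bad])
    }
    val
  }

  # p-values: digit-wise parse, never through doubles
  p_raw <- get_col("p_value")
  parts <- pv_parse_quiet(p_raw)
  if (!is.null(p_floor)) {
    floor_p <- pval(p_floor)
    zi <- which(parts$code %in% "P_ZERO")
    if (length(zi)) {
      parts$mantissa[zi] <- vctrs::field(floor_p, "mantissa")
      parts$exponent[zi] <- vctrs::field(floor_p, "exponent")
      parts$code[zi] <- NA_character_
      issues[[length(issues) + 1L]] <- new_issues(
        severity = "WARNING", code = rep("P_ZERO_FLOORED", length(zi)),
        row = rowid[zi], column = rep("p_value", length(zi)),
        message = rep(sprintf("p = 0 floored to %s", format_pvalue(floor_p)), length(zi)),
        observed = p_raw[zi])
    }
  }
  parts$code[parts$code %in% "P_ZERO"] <- "P_OUT_OF_RANGE"
  bad_p <- which(!is.na(parts$code))
  if (length(bad_p)) {
    issues[[length(issues) + 1L]] <- new_issues(
      severity = "ERROR", code = parts$code[bad_p],
      row = rowid[bad_p], column = rep("p_value", length(bad_p)),
      message = ifelse(parts$code[bad_p] == "P_PARSE_ERROR",
                       "p-value cell is not a numeral",
                       "p-value outside (0, 1]"),
      observed = p_raw[bad_p])
  }

  has_or <- "odds_ratio" %in% header
  has_beta <- "beta" %in% header
  et <- if (has_or && !has_beta) "odds_ratio" else "beta"

  tbl <- tibble(
    variant_id = get_col("variant_id"),
    chromosome = get_col("chromosome"),
    base_pair_location = num_col("base_pair_location"),
    p_value = new_pval(parts$mantissa, parts$exponent),
    effect_allele = get_col("effect_allele"),
    other_allele = get_col("other_allele"),
    effect_allele_frequency = num_col("effect_allele_frequency"),
    standard_error = num_col("standard_error"),
    ci_upper = num_col("ci_upper"),
    ci_lower = num_col("ci_lower")
  )
  tbl[[et]] <- num_col(et)
  if (has_or && has_beta) {
    # one effect scale per file; keep the first, demote the other to auxiliary
    unknown <- c(unknown, "odds_ratio")
  }
  for (col in unknown) tbl[[col]] <- get_col(col)

  attr(tbl, "present_columns") <- intersect(header, std_all)
  out <- sumstats(tbl, effect_type = et, genome_build = genome_build,
                  source_name = basename(path))
  attr(out, "issues") <- bind_issues(!!!issues)
  out
}

#' Write a standard-format summary-statistics file
#'
#' Emits UTF-8, LF line endings, tab delimiters, the canonical column order
#' (`variant_id`, `chromosome`, `base_pair_location`, `p_value`,
#' `effect_allele`, `other_allele`, `effect_allele_frequency`,
#' `odds_ratio`|`beta`, `standard_error`, `ci_upper`, `ci_lower`, then any
#' auxiliary columns), and `"NA"` for missing values. Numeric columns use the
#' shortest decimal representation that round-trips exactly, so
#' `write_sumstats()` then [read_sumstats()] reproduces the dataset
#' field-for-field; p-values go through [format_pvalue()]. Output is
#' deterministic: identical datasets yield identical bytes.
#'
#' @param x a [sumstats] object with at least one record.
#' @param path destination; a `.gz` suffix (or `compress = "gzip"`) enables
#'   gzip compression.
#' @param sig_digits significant digits for p-value emission; `NULL` keeps
#'   full (lossless) precision.
#' @param compress `"auto"` (by extension), `"none"` or `"gzip"`.
#' @return Invisibly, the number of uncompressed bytes written.
#' @export
write_sumstats <- function(x, path, sig_digits = NULL,
                           compress = c("auto", "none", "gzip")) {
  stopifnot(is_sumstats(x))
  compress <- match.arg(compress)
  if (nrow(x) == 0L) {
    stopf("sumstatr_empty_dataset", "refusing to write a dataset with no records",
          code = "EMPTY_DATASET")
  }
  et <- effect_type(x)
  std <- standard_columns(et)
  aux <- setdiff(names(x), std)
  cols <- c(std, aux)

  fmt_col <- function(nm) {
    v <- x[[nm]]
    s <- if (nm == "p_value") format_pvalue(v, sig_digits)
         else if (nm == "base_pair_location") fmt_position(v)
         else if (is.double(v)) fmt_double(v)
         else as.character(v)
    ifelse(is.na(s), "NA", s)
  }
  fields <- vapply(cols, fmt_col, character(nrow(x)))
  if (nrow(x) == 1L) fields <- matrix(fields, nrow = 1L, dimnames = list(NULL, cols))
  lines <- c(paste(cols, collapse = "\t"),
             apply(fields, 1L, paste, collapse = "\t"))

  gz <- compress == "gzip" || (compress == "auto" && grepl("\\.gz$", path))
  con <- if (gz) gzfile(path, open = "wb") else file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  payload <- paste0(paste(lines, collapse = "\n"), "\n")
  writeBin(charToRaw(enc2utf8(payload)), con)
  invisible(nchar(payload, type = "bytes"))
}

#' Extract top associations
#'
#' Returns the records whose p-value is strictly below `threshold`, in their
#' original order. The default threshold, 1e-5, is the conventional cutoff
#' for a study's "top associations". Comparison happens on the
#' mantissa/exponent representation, so thresholds below the double underflow
#' limit behave correctly.
#'
#' @param x a [sumstats] object.
#' @param threshold a `pval`, numeral string, or number.
#' @return A [sumstats] object with the qualifying subset.
#' @export
top_associations <- function(x, threshold = "1e-5") {
  stopifnot(is_sumstats(x))
  thr <- pval(threshold)
  stopifnot(length(thr) == 1L)
  cmp <- vctrs::vec_compare(x$p_value, vctrs::vec_rep(thr, nrow(x)))
  keep <- !is.na(cmp) & cmp < 0
  sumstats_keep_attrs(as_tibble(x)[keep, , drop = FALSE], x)
}

#' Content digest of a dataset
#'
#' MD5 digest of the canonical serialized bytes (the exact file
#' [write_sumstats()] produces), so ledger versions are content-addressed:
#' equal datasets always hash equal, any field change hashes different.
#'
#' @param x a [sumstats] object.
#' @param sig_digits passed to [write_sumstats()].
#' @return hex digest string.
#' @export
sumstats_digest <- function(x, sig_digits = NULL) {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp), add = TRUE)
  write_sumstats(x, tmp, sig_digits = sig_digits, compress = "none")
  unname(tools::md5sum(tmp))
}
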