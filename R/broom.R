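#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy validation and FAIR reports
#'
#' `tidy()` returns the per-finding (or per-indicator) table; `glance()`
#' returns a one-row summary.
#'
#' @param x a `sumstats_report`, `fair_report`, [sumstats] or
#'   [study_metadata] object.
#' @param ... unused.
#' @return A tibble.
#' @name sumstatr-tidiers
NULL

#' @rdname sumstatr-tidiers
#' @export
tidy.sumstats_report <- function(x, ...) as_tibble(x$issues)

#' @rdname sumstatr-tidiers
#' @export
glance.sumstats_report <- function(x, ...) {
  tibble(
    valid = x$valid,
    records_checked = x$records_checked,
    n_issues = nrow(x$issues),
    n_errors = sum(x$issues$severity == "ERROR"),
    n_warnings = sum(x$issues$severity == "WARNING")
  )
}

#' @rdname sumstatr-tidiers
#' @export
tidy.fair_report <- function(x, ...) {
  tibble(indicator = x$indicator, principle = x$principle,
         status = x$status, evidence = x$evidence)
}

#' @rdname sumstatr-tidiers
#' @export
glance.fair_report <- function(x, ...) {
  auto <- x$status != "not_auto_checkable"
  tibble(
    n_indicators = nrow(x),
    n_auto_checkable = sum(auto),
    n_pass = sum(x$status == "pass"),
    n_fail = sum(x$status == "fail"),
    all_auto_pass = all(x$status[auto] == "pass")
  )
}

#' @rdname sumstatr-tidiers
#' @export
glance.sumstats <- function(x, ...) {
  p_med <- if (nrow(x)) stats::median(pval_log10(x$p_value), na.rm = TRUE) else NA_real_
  tibble(
    n_records = nrow(x),
    effect_type = effect_type(x),
    genome_build = genome_build(x) %||% NA_character_,
    n_top_1e5 = nrow(top_associations(x, "1e-5")),
    median_log10_p = p_med
  )
}

#' @rdname sumstatr-tidiers
#' @export
tidy.study_metadata <- function(x, ...) {
  flat <- unlist(meta_to_list(x))
  tibble(field = names(flat), value = as.character(flat))
}
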