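#' Privacy-reduction profiles
#'
#' For datasets judged sensitive (isolated populations, rare traits),
#' identification risk can be reduced without withholding the whole dataset:
#' by not sharing study-specific allele frequencies, and/or by reducing the
#' precision of the reported p-values. A profile enables at least one of the
#' two transforms.
#'
#' @param mask_frequencies set every `effect_allele_frequency` to missing
#'   (the column is retained for schema conformance, and the applied profile
#'   is declared so validators exempt the missing values).
#' @param p_sig_digits round every p-value to this many significant digits
#'   (half-even, see [pval_round()]).
#' @return A `privacy_profile` object.
#' @export
privacy_profile <- function(mask_frequencies = FALSE, p_sig_digits = NULL) {
  if (!isTRUE(mask_frequencies) && is.null(p_sig_digits)) {
    stopf("sumstatr_privacy_error",
          "a privacy profile must enable at least one transform")
  }
  if (!is.null(p_sig_digits)) {
    stopifnot(length(p_sig_digits) == 1L, p_sig_digits >= 1)
    p_sig_digits <- as.integer(p_sig_digits)
  }
  structure(list(mask_frequencies = isTRUE(mask_frequencies),
                 p_sig_digits = p_sig_digits),
            class = "privacy_profile")
}

#' Apply a privacy profile to a dataset
#'
#' Applies the enabled transforms and records them: the returned dataset
#' carries the applied profile as an attribute, and the returned metadata
#' (when supplied) records it in `privacy_profile_applied`. All fields not
#' targeted by a transform are byte-identical on re-serialization. The
#' transform is idempotent, and p-value rounding preserves non-strict
#' p-value ordering (ties may appear, inversions never) with relative error
#' at most `0.5 * 10^(1 - k)` for `k = p_sig_digits`.
#'
#' @param x a [sumstats] dataset.
#' @param metadata optional [study_metadata] to annotate.
#' @param profile a [privacy_profile].
#' @return list with elements `data` and `metadata` (the latter `NULL` when
#'   none was supplied).
#' @export
apply_privacy_profile <- function(x, metadata = NULL, profile) {
  stopifnot(is_sumstats(x), inherits(profile, "privacy_profile"))
  out <- as_tibble(x)
  if (profile$mask_frequencies) {
    out$effect_allele_frequency <- rep(NA_real_, nrow(out))
  }
  if (!is.null(profile$p_sig_digits)) {
    out$p_value <- pval_round(out$p_value, profile$p_sig_digits)
  }
  descr <- list(mask_frequencies = profile$mask_frequencies,
                p_sig_digits = profile$p_sig_digits)
  descr <- descr[!vapply(descr, is.null, logical(1))]
  res <- sumstats_keep_attrs(out, x)
  attr(res, "privacy_profile_applied") <- descr
  if (!is.null(metadata)) {
    stopifnot(inherits(metadata, "study_metadata"))
    metadata$privacy_profile_applied <- descr
  }
  list(data = res, metadata = metadata)
}
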