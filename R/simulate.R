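#' Simulate GWAS summary statistics
#'
#' Generates a standard-conformant dataset of single-variant association
#' results together with the generating truth, for fully offline testing of
#' readers, validators and downstream tooling.
#'
#' Per variant *i*: the effect allele frequency is drawn uniformly from
#' `eaf_range`; the variant is causal with probability `prop_causal`, in
#' which case its true per-allele effect is Normal(0, `effect_sd`^2) and 0
#' otherwise; the standard error follows the standard GWAS approximation
#' `se = 1 / sqrt(2 * n_samples * f * (1 - f))`; the estimated effect is
#' Normal(true effect, se^2); and the two-sided p-value `2 * pnorm(-|z|)` is
#' computed in log space and stored as a [pval], so extreme associations
#' (|z| of 40+, p below 1e-300) survive without underflow. Under
#' `prop_causal = 0` the p-values are exactly Uniform(0, 1).
#'
#' Variants are laid out with sequential 1-based positions (1 kb apart)
#' within chromosomes 1..22, distinct single-base alleles, and rsIDs
#' `rs1..rsN`. For `effect_type = "odds_ratio"` the effect is reported as
#' `exp(beta)` with the standard error on the log-odds scale, plus 95%
#' confidence bounds; for `"beta"` the bounds are on the effect scale.
#' Output is deterministic given `seed`: identical parameters produce
#' byte-identical files.
#'
#' @param n_variants number of variants.
#' @param n_samples analyzed sample size (>= 2); drives the standard errors.
#' @param prop_causal fraction of variants with a true effect, in `[0, 1]`.
#' @param effect_sd standard deviation of true causal effects (per-allele,
#'   trait-SD or log-odds units).
#' @param eaf_range range the effect allele frequencies are drawn from,
#'   strictly inside (0, 1).
#' @param effect_type `"beta"` or `"odds_ratio"`.
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @return list with `data` (a [sumstats] with genome build GRCh38) and
#'   `truth` (tibble: `variant_id`, `causal`, `beta_true`).
#' @export
simulate_sumstats <- function(n_variants, n_samples = 10000, prop_causal = 0.01,
                              effect_sd = 0.1, eaf_range = c(0.05, 0.95),
                              effect_type = c("beta", "odds_ratio"), seed) {
  effect_type <- match.arg(effect_type)
  stopifnot(n_variants >= 1, n_samples >= 2,
            prop_causal >= 0, prop_causal <= 1, effect_sd > 0,
            length(eaf_range) == 2L, eaf_range[1] < eaf_range[2],
            eaf_range[1] > 0, eaf_range[2] < 1)
  n <- as.integer(n_variants)

  withr::local_seed(as.integer(seed))
  f <- stats::runif(n, eaf_range[1], eaf_range[2])
  causal <- stats::runif(n) < prop_causal
  beta_true <- ifelse(causal, stats::rnorm(n, 0, effect_sd), 0)
  se <- 1 / sqrt(2 * n_samples * f * (1 - f))
  beta_hat <- stats::rnorm(n, beta_true, se)
  z <- beta_hat / se
  # two-sided normal p in log10 space; exact mantissa/exponent split
  log10p <- (log(2) + stats::pnorm(-abs(z), log.p = TRUE)) / log(10)
  expo <- floor(log10p)
  mant <- 10^(log10p - expo)
  carry <- mant >= 10
  mant[carry] <- mant[carry] / 10
  expo[carry] <- expo[carry] + 1
  # z == 0 gives p = 1 exactly
  mant[z == 0] <- 1
  expo[z == 0] <- 0
  p <- new_pval(mant, as.integer(expo))

  bases <- c("A", "C", "G", "T")
  ea_idx <- sample.int(4L, n, replace = TRUE)
  oa_idx <- (ea_idx - 1L + sample.int(3L, n, replace = TRUE)) %% 4L + 1L
  chrom <- sort(rep_len(1:22, n))
  pos <- (stats::ave(rep(1, n), chrom, FUN = cumsum)) * 1000

  zq <- stats::qnorm(0.975)
  tbl <- tibble(
    variant_id = paste0("rs", seq_len(n)),
    chromosome = as.character(chrom),
    base_pair_location = pos,
    p_value = p,
    effect_allele = bases[ea_idx],
    other_allele = bases[oa_idx],
    effect_allele_frequency = f,
    standard_error = se
  )
  if (effect_type == "beta") {
    tbl$beta <- beta_hat
    tbl$ci_upper <- beta_hat + zq * se
    tbl$ci_lower <- beta_hat - zq * se
  } else {
    tbl$odds_ratio <- exp(beta_hat)
    tbl$ci_upper <- exp(beta_hat + zq * se)
    tbl$ci_lower <- exp(beta_hat - zq * se)
  }
  data <- sumstats(tbl, effect_type = effect_type, genome_build = "GRCh38",
                   source_name = sprintf("simulated (seed %d)", as.integer(seed)))
  truth <- tibble(variant_id = tbl$variant_id, causal = causal,
                  beta_true = beta_true)
  list(data = data, truth = truth)
}
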