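# Column-header alias table for harmonizing legacy summary-statistics
# dialects onto the standard reporting elements. Matching is
# case-insensitive. Curated from common tool outputs (PLINK, BOLT-LMM,
# SAIGE, METAL, SNPTEST, GCTA); edit or replace via detect_dialect(aliases=)
# to teach the harmonizer a new dialect without a code change.
#
# "ambiguous" lists headers whose community usage conflicts between tools
# (A1/A2 swap meaning across PLINK versions; Allele1 is the effect allele in
# METAL but the other allele in SAIGE; MAF/FRQ-style frequency columns may be
# minor-allele rather than effect-allele frequencies). These are never
# auto-assigned: they are reported with their candidate elements and require
# an explicit override.
aliases:
  variant_id: [variant_id, snp, snpid, rsid, rs_id, markername, markerid, marker, id, varid]
  chromosome: [chromosome, chr, chrom, "#chrom", chr_id]
  base_pair_location: [base_pair_location, bp, pos, position, genpos, base_pair, bpos]
  p_value: [p_value, p, pval, pvalue, p-value, p.value, p_bolt_lmm, p_wald, p_lrt, p-val]
  effect_allele: [effect_allele, ea, risk_allele, tested_allele]
  other_allele: [other_allele, oa, nea, non_effect_allele, reference_allele, noneffect_allele]
  effect_allele_frequency: [effect_allele_frequency, eaf, effect_allele_freq]
  odds_ratio: [odds_ratio, or]
  beta: [beta, effect, b, est, stdbeta, beta_hat]
  standard_error: [standard_error, se, stderr, std_err, sebeta, stderrlogor]
  ci_upper: [ci_upper, or_95u, u95, upper_ci]
  ci_lower: [ci_lower, or_95l, l95, lower_ci]
ambiguous:
  a1: [effect_allele, other_allele]
  a2: [effect_allele, other_allele]
  allele1: [effect_allele, other_allele]
  allele2: [effect_allele, other_allele]
  allele0: [effect_allele, other_allele]
  ref: [effect_allele, other_allele]
  alt: [effect_allele, other_allele]
  maf: [effect_allele_frequency]
  frq: [effect_allele_frequency]
  freq: [effect_allele_frequency]
  freq1: [effect_allele_frequency]
  a1freq: [effect_allele_frequency]
  af: [effect_allele_frequency]
  af_allele2: [effect_allele_frequency]
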