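# sumstatr

Standards-based tools for sharing GWAS summary statistics.

A genome-wide association study (GWAS) reports, for each of millions of
variants, an aggregate association result: a p-value, an effect size (linear
`beta` or `odds_ratio`), its standard error, the effect and other alleles,
and the effect allele frequency. These "SumStats" files power meta-analysis,
polygenic prediction, Mendelian randomization and drug-target work — but in
practice they arrive in dozens of ad hoc column dialects, with thin
metadata, and with p-values that dip far below what double-precision floats
can hold. `sumstatr` is for the people on both sides of that exchange:
analysts preparing a submission-ready dataset, and repository or pipeline
maintainers who need to validate, harmonize and track what they receive.

The toolkit implements, as one coherent package:

* **An exact p-value type.** A `pval` vector stores p = m × 10^E with a
  decimal mantissa m ∈ [1, 10) and an integer exponent E, so p = 3.2e-450
  parses, compares, rounds and re-serializes without underflow.
  Parsing rejects p ∉ (0, 1]; comparison is a total order on (E, m).
* **A bit-exact reader/writer** for the standard tab-separated format
  (`variant_id`, `chromosome`, `base_pair_location`, `p_value`,
  `effect_allele`, `other_allele`, `effect_allele_frequency`,
  `odds_ratio`|`beta`, `standard_error`, `ci_upper`, `ci_lower`), with
  structural findings as machine-readable issues and unknown columns
  preserved as auxiliary.
* **A dialect harmonizer** driven by a shipped alias table that maps legacy
  headers (`SNP`, `CHR`, `BP`, `P`, ...) onto the standard and *refuses to
  guess* where community usage conflicts (`A1`/`A2`, `Allele1`/`Allele2`,
  `MAF`/`FRQ`) — those need explicit `--map` overrides.
* **A rule-based validator** with a documented code registry
  (`issue_codes()`): header rules (mandatory elements, one variant-ID form,
  exactly one effect scale), record rules (ranges, token patterns, CI
  order), and dataset rules (duplicates, emptiness), plus a deterministic
  error injector (`inject_errors()`) that serves as the validator's
  soundness/completeness oracle.
* **Study metadata** as a YAML sidecar with the community-mandatory elements
  (sample sizes and ancestry, imputation method/panel, covariates, analysis
  model/software, MAF cutoff, QC, ...), pattern checks for `GCST` accessions
  and EFO trait CURIEs, and lossless round trips.
* **Privacy reduction** for sensitive cohorts: mask study-specific allele
  frequencies and/or round p-values to k significant digits (half-even;
  relative error ≤ 0.5·10^(1−k), order never inverted).
* **A local accession ledger** (append-only JSON-lines): `GCST`-style
  assignment, content-addressed versions, retraction tombstones that keep
  history resolvable, partial-data flags.
* **A FAIR self-assessment** scoring a bundle against the 15-indicator
  checklist (10 auto-checked, 5 reported as repository properties).
* **A statistically grounded simulator**: EAF ~ Uniform, causal effects ~
  Normal(0, effect_sd²), se = 1/√(2·n·f·(1−f)), β̂ ~ Normal(β, se²),
  p = 2Φ(−|z|) computed in log space — null p-values are exactly uniform and
  extreme tails exercise the exact p-value type.

## Worked example

```r
library(sumstatr)

sim <- simulate_sumstats(n_variants = 5000, n_samples = 20000,
                         prop_causal = 0.02, seed = 42)
glance(sim$data)
#> # A tibble: 1 × 5
#>   n_records effect_type genome_build n_top_1e5 median_log10_p
#>       <int> <chr>       <chr>            <int>          <dbl>
#> 1      5000 beta        GRCh38              69         -0.307
```

5,000 simulated variants, 2% of them causal: 69 records clear the
conventional top-association threshold (p < 1e-5), and the median log10 p of
−0.307 sits at the null expectation (log10 0.5 ≈ −0.301), as it should when
98% of variants are null. The strongest hit is far below double-precision
underflow and survives intact:

```r
hits <- top_associations(sim$data)   # default threshold 1e-5
format_pvalue(hits$p_value[which.min(pval_log10(hits$p_value))], sig_digits = 3)
#> [1] "3.06e-119"
```

The dataset validates cleanly, and injected corruption is found exactly
where it was planted:

```r
validate_sumstats(sim$data)
#> # Validation report: VALID (5000 record(s) checked)
#>   no findings

bad <- inject_errors(sim$data, c(EAF_OUT_OF_RANGE = 2, NEG_SE = 1), seed = 7)
validate_sumstats(bad$data)
#> # Validation report: INVALID (5000 record(s) checked)
#>   EAF_OUT_OF_RANGE         ERROR x2
#>   NEG_SE                   ERROR x1
```

A legacy PLINK-style header maps where safe and stops where unsafe:

```r
detect_dialect(c("SNP", "CHR", "BP", "A1", "A2", "FRQ", "OR", "SE", "P"))
#> # Column mapping
#>   SNP                      -> variant_id
#>   CHR                      -> chromosome
#>   BP                       -> base_pair_location
#>   OR                       -> odds_ratio
#>   SE                       -> standard_error
#>   P                        -> p_value
#>   A1                       ?? ambiguous: effect_allele | other_allele (needs override)
#>   A2                       ?? ambiguous: effect_allele | other_allele (needs override)
#>   FRQ                      ?? ambiguous: effect_allele_frequency (needs override)
```

`A1`/`A2` have swapped meaning across tool generations and `FRQ` may be a
minor- rather than effect-allele frequency; a wrong guess would silently
flip effect directions downstream, so the harmonizer demands
`overrides = c(A1 = "effect_allele", A2 = "other_allele", FRQ = "effect_allele_frequency")`.

See the vignette (`vignettes/sumstats-toolkit.Rmd`) for the full data model,
the validation code registry, the privacy error bounds, and what the
simulator does and does not emulate.

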