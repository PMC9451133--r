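---
title: "Sharing GWAS summary statistics: the sumstatr data model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sharing GWAS summary statistics: the sumstatr data model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sumstatr)
```

Genome-wide association studies report, per analyzed variant, an aggregate
association result: a p-value, an effect size on one of two scales (a linear
`beta` or an `odds_ratio`), its standard error, the two alleles the effect is
oriented against, and the effect allele frequency (EAF) in the analyzed
sample. Meta-analysis, fine-mapping, polygenic prediction and Mendelian
randomization all consume these files wholesale, and all suffer from the same
pair of problems: files arrive in dozens of ad hoc dialects, and the
accompanying study metadata are thin or absent. `sumstatr` implements a
community-standard tabular format plus the surrounding sharing workflow —
validation, harmonization, metadata, privacy reduction, accessioning and a
FAIR self-assessment — entirely offline.

## The record model

A dataset is a tibble of per-variant records with a fixed column vocabulary:

| element | mandatory | notes |
|---|---|---|
| `variant_id` | one form of variant ID is mandatory | dbSNP rsID (`rs` + digits) |
| `chromosome`, `base_pair_location` | (the other form) | tokens 1–22/X/Y/MT; 1-based, fully closed coordinates, anchored by a declared genome build |
| `p_value` | yes | stored exactly, see below |
| `effect_allele`, `other_allele` | yes | uppercase A/C/G/T sequences; indels as full sequences, never `D`/`I`/`-`, which are ambiguous without a reference |
| `effect_allele_frequency` | yes (column) | values may be masked by a declared privacy profile |
| `odds_ratio` **or** `beta` | yes, exactly one | one effect scale per file |
| `standard_error` | yes | on the log-odds scale for odds ratios |
| `ci_upper`, `ci_lower` | optional | either both or neither |

Columns outside the vocabulary are never dropped: they ride along as
auxiliary columns and come back out on re-serialization.

## Exact p-values

The smallest positive double is ~5e-324, and well-powered GWAS and
meta-analyses exceed that routinely (|z| = 40 corresponds to p ≈ 1e-350).
`pval` vectors therefore store a decimal mantissa m ∈ [1, 10) and a signed
integer exponent E, representing p = m × 10^E. Parsing is digit-wise (the
value never passes through a double), comparison and sorting operate on the
(E, m) pair, and `pval_log10()` gives exact −log10 p for plotting. Parsing
rejects values outside (0, 1]: p = 0 in an input file almost always means an
upstream pipeline underflowed, and silently accepting it would launder that
bug, so the reader reports it as an error unless the caller opts into an
explicit floor (`p_floor =`), which is then recorded as a warning finding.

Two numerical choices matter here:

* **Rounding is half-even** (banker's rounding), applied to the mantissa at a
  requested number of significant digits, with a carry re-canonicalizing the
  exponent (9.99 at two digits becomes 1.0 × 10 of the next exponent). The
  choice is bias-free and reproducible across platforms. A consequence used
  by the privacy profile: rounding to k significant digits changes a p-value
  by a relative error of at most 0.5 × 10^(1−k), and, being a monotone map,
  can introduce ties but never order inversions.
* **Emission is lossless by default.** The writer prints each mantissa (and
  every other numeric column) with the fewest decimal digits that reproduce
  the stored double exactly on re-parse. Write → read is therefore the
  identity, field for field, and a rewritten standard file is byte-identical
  — which is also what makes ledger digests content-addressed. An integer
  `sig_digits` engages the half-even reduction instead.

## Reader, writer and structural findings

The on-disk format is deliberately plain: UTF-8, LF, tab-separated, a single
header row, `NA` for missing cells, optional gzip. The reader is strict
about structure but generous about recovery: ragged rows and duplicate
headers are ERROR findings, empty cells are normalized to missing with a
warning, and every parseable record is returned even when some rows fail.
Every departure from the standard yields a coded finding; nothing is fixed
silently. One study per file; a multi-study `study_id` column was considered
and deferred — the community standard leaves multi-study packaging open, and
a bundle directory of one file per study keeps validation semantics simple.

## Harmonization: fix what is safe, refuse what is not

Legacy files use dozens of header conventions. The harmonizer applies a
shipped, editable alias table (YAML; `default_aliases()`) case-insensitively,
and divides headers into three classes:

* **Unambiguous aliases** (`SNP`, `CHR`, `BP`, `P`, `EA`, `NEA`, `EAF`, ...)
  map automatically.
* **Ambiguous headers** are never auto-assigned. `A1`/`A2` swap meaning
  between tool generations; `Allele1` is the effect allele in METAL output
  but the non-effect allele in SAIGE output; and `MAF`/`FRQ`-style columns
  may hold minor-allele rather than effect-allele frequencies. A wrong guess
  at any of these corrupts every downstream effect direction or frequency
  silently, so these headers are reported with their candidate elements and
  require an explicit override (`--map A1=effect_allele`).
* **Unknown headers** are preserved as auxiliary.

Value conventions that are safe to fix are normalized with WARNING findings
rather than rejected — `chr1` becomes `1`, lowercase alleles are upcased.
The division of labor is deliberate: the harmonizer fixes, the validator
judges. Harmonizing an already-standard file is a byte-exact no-op. The
alias table is a curated artifact: the standard itself does not enumerate
legacy headers, so the table ships as configuration that can grow without a
code change. Orientation of effect alleles against a reference panel, strand
flips and build liftover are out of scope.

## Validation and the code registry

`validate_sumstats()` aggregates header-level rules (mandatory elements; the
variant-ID-or-location rule; exactly one effect scale), vectorized
record-level rules (ranges, token patterns, CI ordering, negative standard
errors, non-positive odds ratios, missing mandatory cells), and dataset-level
rules (duplicate variant tuples, empty datasets) into a deterministic report
whose `valid` flag is true exactly when no ERROR-severity finding exists.
Every finding carries a code from the documented registry (`issue_codes()`),
a row (0 = file/header level), a column and the observed value, so reports
are machine-consumable (`write_report()` emits versioned JSON).

Three judgment calls are worth recording. `effect_allele_frequency` is
schema-mandatory but value-optional *when a privacy profile is declared* —
this reconciles the mandatory reporting elements with the sanctioned privacy
mitigation. Both effect columns present is an ERROR, not a warning: a single
effect scale per file keeps downstream parsing unambiguous. Duplicate
variant tuples are a WARNING: multi-allelic sites and legitimate re-tests
exist. Statistical sanity checks (p versus beta/se concordance) are
deliberately not a gate.

The validator's contract is tested against its adversary: `inject_errors()`
plants an exact number of corruptions for every record-level code, each
designed to trigger that code and no other (corrupted chromosome and
position values are unique per row, so injections cannot collide into
accidental duplicate tuples), and the validator must recover the injection
log exactly — same counts, same coordinates — with zero findings on the
uncorrupted twin.

## Study metadata

Metadata live in a YAML sidecar (`<accession>-meta.yaml`), not inside the
data file: opinions on embedded-versus-sidecar metadata genuinely differ,
and a sidecar keeps the data file strictly tabular and stream-processable.
The mandatory element set follows the community recommendation: sample size
with case/control split, sample ancestry, imputation method and reference
panel, covariates, trait measurement method, inclusions/exclusions, cohort
descriptors, analysis model and software, genotyping technology, MAF
cutoff, QC description, and number of variants analyzed. Parsing never
invents defaults (absent stays absent; only the recommended CC0 license can
be defaulted, only at write time, only on request), unknown keys are
preserved with a warning, and serialization sorts keys so writes are
deterministic. The ancestry vocabulary ships as a configurable list seeded
from the GWAS Catalog standardized ancestry framework; unknown tokens warn
rather than error because the framework evolves. Live EFO/PubMed/DOI
resolution is out of scope — patterns are checked, services are not called.

## Lifecycle: accessions, versions, retraction, partial data

`ledger_open()` maintains a local, append-only JSON-lines operation log;
opening replays the log, so the file is the single source of truth.
Accessions are `GCST` + zero-padded serial starting at 1 (the real
repository's serial policy is not public; this local scheme is documented as
an artifact convention, and tokens are namespaced as locally assigned).
Versions are contiguous integers carrying an MD5 digest of the canonical
serialized bytes, so a version is content-addressed: resolvers can serve
"the most recent dataset" and detect silent edits. Retraction is a
tombstone, not a deletion — the accession, metadata and full version history
stay resolvable, with the retraction reason attached; new versions are
refused. Datasets released as subsets are flagged `is_partial` with a
mandatory reason, so users know a fuller version may follow. Controlled
access and embargo scheduling are explicitly out of scope.

## Privacy profiles

For studies where sharing carries identification risk (isolated
populations, rare traits), two reductions are supported, separately or
together: masking study-specific allele frequencies (column retained, values
missing, profile declared in metadata so validation stays green) and
reducing p-value precision to k significant digits. The transforms touch
nothing else — non-frequency bytes are identical after masking — and both
are idempotent. The rounding error bound and order preservation follow from
the half-even mantissa rounding described above.

## FAIR self-assessment

`evaluate_fair()` scores a bundle against the fifteen-indicator checklist.
Ten indicators are decidable from the bundle alone and are auto-checked
(identifier present/registered, metadata richness, metadata–data linkage,
open-access applicability, metadata persistence, controlled vocabularies,
license, provenance, standards conformance). Five — searchability,
retrieval protocol and its openness, knowledge-representation language,
cross-references — are properties of whichever repository hosts the bundle;
they are reported as `not_auto_checkable` rather than guessed. Two design
notes: metadata richness is a single check reported under the two indicators
that share its definition (F2 and R1), and rsID coverage is reported as
evidence under I2 rather than gated, since full dbSNP compliance is not
achievable for all variant classes. Whether partial datasets should cap an
indicator is left open; partial status appears as evidence only.

## The simulator: what it emulates and what it does not

`simulate_sumstats()` generates the data the standard describes, with
enough statistical structure to exercise every consumer honestly. Per
variant: EAF ~ Uniform(`eaf_range`), causal status ~
Bernoulli(`prop_causal`), true effect ~ Normal(0, `effect_sd`²) for causal
variants and 0 otherwise, standard error from the standard approximation
se = 1/sqrt(2·n·f·(1−f)) for a quantitative trait in per-SD units,
estimated effect ~ Normal(true, se²), and two-sided p = 2Φ(−|z|) computed
in log space so that extreme tails (p ≈ 1e-440) land in the exact `pval`
representation rather than underflowing — deliberately exercising the
p-value type's reason for existing. Under `prop_causal = 0` the p-values
are exactly Uniform(0, 1), which grounds the calibration checks: the
Kolmogorov–Smirnov statistic against uniformity, and the expected count of
about n·10⁻⁵ records below the conventional top-association threshold of
1e-5. Power at genome-wide significance (5e-8) is non-decreasing in sample
size, which the tests verify on a three-point grid.

Defaults (n_samples = 10,000; prop_causal = 0.01; effect_sd = 0.1; EAF in
[0.05, 0.95]) describe a mid-sized array-based quantitative-trait GWAS of a
polygenic trait — common variants, mostly null, modest effects — and are
not tuned per test. The generator emits a truth table alongside the data to
support power/FDR demonstrations, and each simulated bundle carries a fully
populated metadata sidecar.

What it does **not** emulate, and what passing tests therefore do not show:
linkage disequilibrium (each variant is independent, so clumping and
LD-score behavior are untested), population stratification or other
confounding (no inflation; genomic-control lambda is ~1 by construction),
case-control ascertainment, allele-frequency spectra (uniform, not
site-frequency-spectrum shaped), imputation uncertainty, or multi-variant
aggregate tests, whose reporting the community is still standardizing.

## Problem sizes and determinism in the checks

The shipped checks run on sizes chosen to make their statistics meaningful
while staying comfortably reproducible on a laptop: round trips on
1,000-record datasets per effect scale; validator/injector agreement over 50
seeds on 500-record fixtures with five instances of every injectable code;
null calibration at 100,000 variants over 100 seeds (KS) and 200 seeds
(top-hit counts); 1,000 random p-values spanning exponents −500..0 against
an independent digit-level oracle; 10,000 ledger assignments. All
randomness flows through explicit seeds; `simulate_sumstats()` restores the
caller's RNG state. One statistical caveat is worth naming: a check of the
form "the KS statistic beats its 5% critical value in ≥95% of seeds" is
centered exactly on its own expectation, so over any fixed seed panel the
observed pass count fluctuates around 95 with standard deviation ≈ 2; the
seed panel used here is fixed a priori and the observed pass rate is
reported as-is.

## Known limitations

No variant normalization against a reference genome, no liftover, no strand
or effect-allele orientation, no VCF serialization (the community has not
settled the flat-file-versus-VCF question), no tabix indexing, no live
ontology or literature services, no controlled-access machinery, and no
aggregate (burden/SKAT-O) association records. Haplotype and non-rsID
variant identification await a community decision and are representable only
through the auxiliary-column mechanism.
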