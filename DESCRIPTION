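Package: sumstatr
Title: Standards-Based Toolkit for GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for producing, checking and sharing genome-wide association
    study (GWAS) summary statistics in the community standard tab-separated
    format: a typed in-memory model with an underflow-safe p-value vector
    class, a bit-exact reader/writer, a column-header harmonizer for legacy
    dialects, a rule-based validator with a documented issue-code registry, a
    study-metadata schema with YAML/JSON serialization, privacy-reduction
    transforms, a local accession/version/retraction ledger, a FAIR indicator
    self-assessment, and a statistically grounded summary-statistics simulator
    with a deterministic error injector for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    stringr,
    tibble,
    tools,
    utils,
    vctrs,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
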