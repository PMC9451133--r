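test_that("exact standard headers map to themselves with nothing ambiguous", {
  hdr <- standard_columns("beta")
  m <- detect_dialect(hdr)
  expect_identical(m$assignments, stats::setNames(hdr, hdr))
  expect_identical(nrow(m$ambiguous), 0L)
  expect_identical(m$unmapped, character())
})

test_that("the common unambiguous shorthand dialect maps fully", {
  m <- detect_dialect(c("SNP", "CHR", "BP", "P", "EA", "NEA", "EAF", "BETA", "SE"))
  expect_identical(
    unname(m$assignments),
    c("variant_id", "chromosome", "base_pair_location", "p_value",
      "effect_allele", "other_allele", "effect_allele_frequency", "beta",
      "standard_error"))
  expect_identical(nrow(m$ambiguous), 0L)
  expect_identical(m$unmapped, character())
})

test_that("A1/A2 and MAF-style frequency headers are ambiguous, never guessed", {
  m <- detect_dialect(c("A1", "A2", "FRQ", "OR", "SE", "P", "SNP"))
  expect_setequal(m$ambiguous$header, c("A1", "A2", "FRQ"))
  expect_identical(m$ambiguous$candidates[[which(m$ambiguous$header == "A1")]],
                   c("effect_allele", "other_allele"))
  expect_identical(m$ambiguous$candidates[[which(m$ambiguous$header == "FRQ")]],
                   "effect_allele_frequency")
  expect_false(any(c("A1", "A2", "FRQ") %in% names(m$assignments)))
})

test_that("case-folded duplicate headers are refused", {
  expect_error(detect_dialect(c("SNP", "snp", "P")),
               class = "sumstatr_harmonize_error")
})

test_that("harmonizing a standard-dialect table equals the standard reader", {
  f <- write_tsv_lines(minimal_standard_lines())
  via_reader <- read_sumstats(f)
  via_harmonizer <- harmonize_sumstats(f)
  expect_same_dataset(as_tibble(via_harmonizer), as_tibble(via_reader))
})

test_that("overrides resolve ambiguity; removing them reinstates the error", {
  f <- dialect_path("plink")
  ov <- c(A1 = "effect_allele", A2 = "other_allele", FRQ = "effect_allele_frequency")
  x <- harmonize_sumstats(f, overrides = ov, genome_build = "GRCh37")
  expect_identical(effect_type(x), "odds_ratio")
  expect_identical(x$effect_allele, c("A", "G", "T"))
  expect_true(validate_sumstats(x)$valid)

  err <- tryCatch(harmonize_sumstats(f), error = identity)
  expect_s3_class(err, "sumstatr_harmonize_error")
  expect_identical(err$code, "HARMONIZE_AMBIGUOUS")
})

test_that("a table lacking any p-value column names p_value in the error", {
  f <- write_tsv_lines(c("SNP\tCHR\tBP\tEA\tNEA\tEAF\tBETA\tSE",
                         "rs1\t1\t100\tA\tG\t0.2\t0.1\t0.05"))
  err <- tryCatch(harmonize_sumstats(f), error = identity)
  expect_s3_class(err, "sumstatr_harmonize_error")
  expect_identical(err$code, "MISSING_MANDATORY")
  expect_match(conditionMessage(err), "p_value")
})

test_that("chr prefixes and lowercase alleles are normalized with warnings", {
  f <- write_tsv_lines(c("SNP\tCHR\tBP\tEA\tNEA\tEAF\tBETA\tSE\tP",
                         "rs1\tchr1\t100\ta\tG\t0.2\t0.1\t0.05\t0.5"))
  x <- harmonize_sumstats(f)
  expect_identical(x$chromosome, "1")
  expect_identical(x$effect_allele, "A")
  iss <- sumstats_issues(x)
  expect_identical(sum(iss$code == "NORMALIZED_VALUE"), 2L)
  expect_true(all(iss$severity[iss$code == "NORMALIZED_VALUE"] == "WARNING"))
})

test_that("every shipped dialect fixture maps its unambiguous columns fully", {
  expected <- list(
    plink = list(
      assigned = c(SNP = "variant_id", CHR = "chromosome", BP = "base_pair_location",
                   OR = "odds_ratio", SE = "standard_error", P = "p_value"),
      ambiguous = c("A1", "A2", "FRQ")),
    bolt = list(
      assigned = c(SNP = "variant_id", CHR = "chromosome", BP = "base_pair_location",
                   BETA = "beta", SE = "standard_error", P_BOLT_LMM = "p_value"),
      ambiguous = c("ALLELE1", "ALLELE0", "A1FREQ")),
    saige = list(
      assigned = c(CHR = "chromosome", POS = "base_pair_location",
                   MarkerID = "variant_id", BETA = "beta", SE = "standard_error",
                   "p.value" = "p_value"),
      ambiguous = c("Allele1", "Allele2", "AF_Allele2")),
    metal = list(
      assigned = c(MarkerName = "variant_id", Effect = "beta",
                   StdErr = "standard_error", "P-value" = "p_value"),
      ambiguous = c("Allele1", "Allele2", "Freq1")),
    legacy = list(
      assigned = c(rsid = "variant_id", chrom = "chromosome",
                   position = "base_pair_location", effect_allele = "effect_allele",
                   non_effect_allele = "other_allele", eaf = "effect_allele_frequency",
                   beta = "beta", stderr = "standard_error", pval = "p_value"),
      ambiguous = character())
  )
  for (name in names(expected)) {
    hdr <- strsplit(readLines(dialect_path(name), n = 1), "\t")[[1]]
    m <- detect_dialect(hdr)
    expect_identical(m$assignments[names(expected[[name]]$assigned)],
                     expected[[name]]$assigned, label = name)
    expect_setequal(m$ambiguous$header, expected[[name]]$ambiguous)
    expect_identical(m$unmapped, character())
  }
})

test_that("harmonizing an already-standard file is byte-exact idempotent", {
  x <- clean_sim(40, seed = 9)
  f <- tempfile(fileext = ".tsv")
  write_sumstats(x, f)
  h <- harmonize_sumstats(f, genome_build = "GRCh38")
  f2 <- tempfile(fileext = ".tsv")
  write_sumstats(h, f2)
  expect_identical(readLines(f), readLines(f2))
})
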