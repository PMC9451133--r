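full_header <- function(effect = "beta") standard_columns(effect)

test_that("a full standard header passes and single gaps raise targeted errors", {
  expect_identical(nrow(check_header(full_header())), 0L)

  iss <- check_header(setdiff(full_header(), "standard_error"))
  expect_identical(iss$code, "MISSING_MANDATORY")
  expect_identical(iss$column, "standard_error")

  iss <- check_header(c("chromosome", "p_value", "effect_allele", "other_allele",
                        "effect_allele_frequency", "beta", "standard_error"))
  expect_identical(iss$code[iss$severity == "ERROR"], "VARIANT_ID_RULE")

  iss <- check_header(setdiff(full_header(), c("beta")))
  expect_identical(iss$column[iss$severity == "ERROR"], "odds_ratio|beta")

  iss <- check_header(c(full_header(), "odds_ratio"))
  expect_identical(iss$code[iss$severity == "ERROR"], "EFFECT_COLUMN_CONFLICT")

  iss <- check_header(setdiff(full_header(), "ci_lower"))
  expect_identical(iss$code, "CI_UNPAIRED")
  expect_identical(iss$severity, "WARNING")
})

test_that("record-level rules emit the documented codes", {
  x <- clean_sim(10, effect_type = "odds_ratio", seed = 2)
  expect_identical(nrow(validate_record(x, 1)), 0L)

  x$effect_allele_frequency[1] <- 1.2
  expect_identical(validate_record(x, 1)$code, "EAF_OUT_OF_RANGE")

  x$odds_ratio[2] <- -0.3
  expect_identical(validate_record(x, 2)$code, "NONPOS_OR")

  x$effect_allele[3] <- "N"
  expect_identical(validate_record(x, 3)$code, "BAD_ALLELE")

  x$other_allele[4] <- x$effect_allele[4]
  expect_identical(validate_record(x, 4)$code, "ALLELES_IDENTICAL")

  x$chromosome[5] <- "chr1"
  expect_identical(validate_record(x, 5)$code, "BAD_CHROMOSOME")

  x$base_pair_location[6] <- -10
  expect_identical(validate_record(x, 6)$code, "BAD_POSITION")

  x$variant_id[7] <- "rs_77"
  expect_identical(validate_record(x, 7)$code, "BAD_RSID")

  x$standard_error[8] <- -0.01
  expect_identical(validate_record(x, 8)$code, "NEG_SE")

  x$ci_lower[9] <- x$ci_upper[9] + 1
  expect_identical(validate_record(x, 9)$code, "CI_ORDER")

  x$p_value[10] <- sumstatr:::new_pval(3, 0L)
  expect_identical(validate_record(x, 10)$code, "P_OUT_OF_RANGE")
})

test_that("clean simulated datasets yield zero findings for both effect scales", {
  for (et in c("beta", "odds_ratio")) {
    report <- validate_sumstats(clean_sim(500, effect_type = et, seed = 4))
    expect_true(report$valid)
    expect_identical(nrow(report$issues), 0L)
    expect_identical(report$records_checked, 500L)
  }
})

test_that("an empty dataset is invalid with EMPTY_DATASET", {
  x <- sumstats(clean_sim(3)[0, ])
  report <- validate_sumstats(x)
  expect_false(report$valid)
  expect_true("EMPTY_DATASET" %in% report$issues$code)
})

test_that("injected corruption is recovered exactly, by count and coordinate", {
  x <- clean_sim(200, effect_type = "beta", seed = 6)
  spec <- c(EAF_OUT_OF_RANGE = 3L, NEG_SE = 2L, BAD_CHROMOSOME = 1L)
  inj <- inject_errors(x, spec, seed = 99)
  report <- validate_sumstats(inj$data)
  expect_identical(report$counts_by_code[sort(names(spec))], spec[sort(names(spec))])
  found <- report$issues[, c("row", "column", "code")]
  logged <- inj$log[, c("row", "column", "code")]
  expect_identical(dplyr::arrange(found, row, column, code),
                   dplyr::arrange(logged, row, column, code))
})

test_that("validator agrees with the injection log for every injectable code", {
  # compact soundness/completeness sweep; the acceptance suite runs 50 seeds
  for (seed in 1:5) {
    x <- clean_sim(150, effect_type = "odds_ratio", seed = seed)
    spec <- stats::setNames(rep(2L, length(injectable_codes())), injectable_codes())
    inj <- inject_errors(x, spec, seed = seed + 1000)
    report <- validate_sumstats(inj$data)
    expect_identical(report$counts_by_code[sort(names(spec))],
                     spec[sort(names(spec))])
    expect_identical(
      report$issues[, c("row", "column", "code")],
      inj$log[, c("row", "column", "code")])
    expect_identical(nrow(validate_sumstats(x)$issues), 0L)
  }
})

test_that("reports are deterministic and the valid flag is monotone", {
  x <- clean_sim(100, seed = 8)
  r1 <- validate_sumstats(x)
  r2 <- validate_sumstats(x)
  expect_identical(r1, r2)

  inj <- inject_errors(x, c(NEG_SE = 1), seed = 1)
  bad_row <- inj$log$row[1]
  expect_false(validate_sumstats(inj$data)$valid)
  without <- sumstats(as_tibble(inj$data)[-bad_row, ], genome_build = "GRCh38")
  expect_true(validate_sumstats(without)$valid)
})

test_that("missing genome build is an error only when identification needs it", {
  x <- clean_sim(5, seed = 10)
  attr(x, "genome_build") <- NULL
  expect_true(validate_sumstats(x)$valid) # rsIDs identify every record
  x$variant_id[2] <- NA_character_
  report <- validate_sumstats(x)
  expect_true("MISSING_GENOME_BUILD" %in% report$issues$code)
})

test_that("report serialization and tidiers expose the same findings", {
  x <- clean_sim(50, seed = 12)
  inj <- inject_errors(x, c(BAD_ALLELE = 2), seed = 2)
  report <- validate_sumstats(inj$data)
  expect_identical(tidy(report), report$issues)
  g <- glance(report)
  expect_false(g$valid)
  expect_identical(g$n_errors, 2L)
  out <- tempfile(fileext = ".json")
  write_report(report, out)
  parsed <- jsonlite::read_json(out, simplifyVector = TRUE)
  expect_identical(parsed$schema_version, 1L)
  expect_false(parsed$valid)
  expect_identical(parsed$counts_by_code$BAD_ALLELE, 2L)
})
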