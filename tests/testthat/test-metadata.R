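test_that("a fully populated document validates cleanly", {
  expect_identical(nrow(validate_metadata(example_study_metadata("GCST000123"))), 0L)
})

test_that("each missing mandatory element is reported by name", {
  meta <- example_study_metadata("GCST000123")
  meta$covariates <- NULL
  iss <- validate_metadata(meta)
  expect_identical(iss$code, "MISSING_METADATA")
  expect_identical(iss$column, "covariates")

  meta2 <- example_study_metadata()
  meta2$samples <- NULL
  iss2 <- validate_metadata(meta2)
  expect_identical(sort(iss2$column), c("cohort_names", "samples"))
})

test_that("sample arithmetic and token patterns are checked", {
  meta <- example_study_metadata("GCST000123")
  meta$samples <- list(sample_group(100L, "European", n_cases = 70L,
                                    n_controls = 40L, cohort_names = "C"))
  iss <- validate_metadata(meta)
  expect_identical(iss$code, "SAMPLE_COUNT_INCONSISTENT")

  meta <- example_study_metadata("GCST12")
  expect_true("BAD_ACCESSION" %in% validate_metadata(meta)$code)

  meta <- example_study_metadata("GCST000123")
  meta$trait_efo_id <- "not a curie"
  expect_true("BAD_EFO_ID" %in% validate_metadata(meta)$code)

  meta$trait_efo_id <- "EFO_0006335"
  meta$genotyping_technology <- "microarray"
  expect_true("BAD_GENOTYPING_TECHNOLOGY" %in% validate_metadata(meta)$code)

  meta <- example_study_metadata("GCST000123")
  meta$is_partial <- TRUE
  expect_true("PARTIAL_REASON_MISSING" %in% validate_metadata(meta)$code)
  meta$partial_reason <- "cohort restrictions on one contributing study"
  expect_identical(nrow(validate_metadata(meta)), 0L)
})

test_that("unknown ancestry tokens warn rather than error", {
  meta <- example_study_metadata("GCST000123")
  meta$samples[[1]]$ancestry_category <- "Martian"
  iss <- validate_metadata(meta)
  expect_identical(iss$code, "UNKNOWN_ANCESTRY")
  expect_identical(iss$severity, "WARNING")
  expect_identical(nrow(validate_metadata(meta, ancestry_vocabulary = "Martian")), 0L)
})

test_that("YAML and JSON documents round trip losslessly and deterministically", {
  meta <- example_study_metadata("GCST000123")
  for (ext in c(".yaml", ".json")) {
    f <- tempfile(fileext = ext)
    n1 <- write_metadata(meta, f)
    expect_gt(n1, 0L)
    back <- read_metadata(f)
    expect_identical(sumstatr:::meta_to_list(back), sumstatr:::meta_to_list(meta))
    f2 <- tempfile(fileext = ext)
    write_metadata(back, f2)
    expect_identical(readLines(f), readLines(f2))
  }
})

test_that("accessions are preserved verbatim and parsing invents no defaults", {
  meta <- example_study_metadata("GCST000123")
  f <- tempfile(fileext = ".yaml")
  write_metadata(meta, f)
  expect_identical(read_metadata(f)$accession, "GCST000123")

  empty <- tempfile(fileext = ".yaml")
  writeLines("{}", empty)
  back <- read_metadata(empty)
  expect_true(all(vapply(unclass(back), is.null, logical(1))))
  expect_identical(nrow(sumstats_issues(back)), 0L)
  # validation is a separate step, and it has plenty to say
  expect_gt(nrow(validate_metadata(back)), 5L)
})

test_that("unknown keys are preserved with a warning, license defaults only on demand", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("trait_label: height", "favourite_colour: green"), f)
  meta <- read_metadata(f)
  iss <- sumstats_issues(meta)
  expect_identical(iss$code, "UNKNOWN_KEY")
  expect_identical(iss$column, "favourite_colour")
  out <- tempfile(fileext = ".yaml")
  write_metadata(meta, out)
  expect_true(any(grepl("favourite_colour: green", readLines(out))))
  expect_false(any(grepl("license", readLines(out))))
  write_metadata(meta, out, default_license = TRUE)
  expect_true(any(grepl("license: CC0", readLines(out))))
})

test_that("malformed documents fail with a located parse error", {
  f <- tempfile(fileext = ".json")
  writeLines("{not json", f)
  expect_error(read_metadata(f), class = "sumstatr_metadata_error")
})
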