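conformant_bundle <- function() {
  list(metadata = example_study_metadata("GCST000123"),
       data = clean_sim(100, seed = 31),
       accession = "GCST000123")
}

fair_status <- function(report) stats::setNames(report$status, report$indicator)

test_that("a conformant bundle passes all ten auto-checkable indicators", {
  b <- conformant_bundle()
  report <- evaluate_fair(b$metadata, data = b$data, accession = b$accession)
  expect_identical(nrow(report), 15L)
  expect_identical(anyDuplicated(report$indicator), 0L)
  st <- fair_status(report)
  expect_identical(unname(st[c("F4", "A1", "A1.1", "I1", "I3")]),
                   rep("not_auto_checkable", 5))
  auto <- setdiff(report$indicator, c("F4", "A1", "A1.1", "I1", "I3"))
  expect_identical(length(auto), 10L)
  expect_identical(unname(st[auto]), rep("pass", 10))
  expect_true(glance(report)$all_auto_pass)
})

test_that("each single-field ablation flips exactly its own indicator", {
  b <- conformant_bundle()
  base <- fair_status(evaluate_fair(b$metadata, data = b$data, accession = b$accession))

  flips <- function(metadata = b$metadata, data = b$data, accession = b$accession) {
    st <- fair_status(evaluate_fair(metadata, data = data, accession = accession))
    names(st)[st != base]
  }

  meta <- b$metadata; meta$license <- NULL
  expect_identical(flips(metadata = meta), "R1.1")

  meta <- b$metadata; meta$doi <- NULL; meta$pmid <- NULL
  expect_identical(flips(metadata = meta), "R1.2")

  meta <- b$metadata; meta$trait_efo_id <- NULL
  expect_identical(flips(metadata = meta), "I2")

  meta <- b$metadata; meta$accession <- "GCST000999"
  expect_identical(flips(metadata = meta), "F3")

  meta <- b$metadata; meta$accession <- NULL
  expect_setequal(flips(metadata = meta), c("F1", "F3"))

  # metadata richness is one check reported under two linked indicators
  meta <- b$metadata; meta$covariates <- NULL
  expect_setequal(flips(metadata = meta), c("F2", "R1"))

  bad <- inject_errors(b$data, c(NEG_SE = 1), seed = 3)$data
  expect_identical(flips(data = bad), "R1.3")
})

test_that("F3 failure evidence names both accession tokens", {
  b <- conformant_bundle()
  meta <- b$metadata; meta$accession <- "GCST000999"
  report <- evaluate_fair(meta, data = b$data, accession = b$accession)
  ev <- report$evidence[report$indicator == "F3"]
  expect_match(ev, "GCST000999")
  expect_match(ev, "GCST000123")
})

test_that("metadata stay assessable when the dataset is gone (A2), ledger-aware (F1)", {
  led <- ledger_open(tempfile(fileext = ".jsonl"))
  acc <- assign_accession(led) # GCST000001
  meta <- example_study_metadata(acc)
  retract_accession(led, acc, "withdrawn")
  report <- evaluate_fair(meta, data = NULL, ledger = led, accession = acc)
  st <- fair_status(report)
  expect_identical(unname(st["A2"]), "pass")
  expect_match(report$evidence[report$indicator == "A2"], "retract")
  expect_identical(unname(st["F1"]), "pass")
  expect_identical(unname(st["R1.3"]), "fail") # nothing left to check

  # an accession the ledger does not know fails F1
  meta2 <- example_study_metadata("GCST000777")
  st2 <- fair_status(evaluate_fair(meta2, ledger = led, accession = "GCST000777"))
  expect_identical(unname(st2["F1"]), "fail")
})

test_that("rsID coverage is reported as evidence, not gated", {
  b <- conformant_bundle()
  b$data$variant_id[1:50] <- NA_character_
  b$data <- sumstats(as_tibble(b$data), genome_build = "GRCh38")
  report <- evaluate_fair(b$metadata, data = b$data, accession = b$accession)
  expect_identical(fair_status(report)[["I2"]], "pass")
  expect_match(report$evidence[report$indicator == "I2"], "50.0% of records")
})
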