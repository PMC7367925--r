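test_that("write/read round-trip preserves every field including flags", {
  ds <- tiny_dataset()
  ds$measurements$flags[4] <- "outlier"
  ds$measurements$flags[5] <- "lab_error|below_detection"
  f <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, f)
  txt <- readLines(f)
  expect_true(any(grepl("outlier", txt)))      # flag token written verbatim
  ds2 <- read_dataset(f)
  expect_equal(ds2$measurements$flags, ds$measurements$flags)
  expect_equal(ds2$measurements$raw_value, ds$measurements$raw_value,
               tolerance = 1e-12)
  expect_equal(ds2$measurements$conc_neglog_molar,
               ds$measurements$conc_neglog_molar, tolerance = 1e-12)
  expect_equal(ds2$measurements$well, ds$measurements$well)
  expect_equal(ds2$metadata$test_method_id, ds$metadata$test_method_id)
  expect_equal(ds2$metadata$exposure_h, 24)
})

test_that("two writes of the same dataset are byte-identical", {
  ds <- generate_plate(synthetic_spec(3, viability_truth(), noise_cv = 0.1))
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_dataset(ds, f1)
  write_dataset(ds, f2)
  expect_identical(readLines(f1), readLines(f2))
  # write(read(f)) is also byte-stable
  f3 <- withr::local_tempfile()
  write_dataset(read_dataset(f1), f3)
  expect_identical(readLines(f1), readLines(f3))
})

test_that("round-trip identity holds on randomized synthetic datasets", {
  for (seed in 1:100) {
    spec <- synthetic_spec(seed, viability_truth(), n_replicates = 2,
                           series = c(4, 8, 1), noise_cv = 0.1,
                           outlier_rate = 0.2, n_controls = 3)
    ds <- generate_plate(spec)
    f <- tempfile()
    write_dataset(ds, f)
    ds2 <- read_dataset(f)
    expect_equal(ds2$measurements$raw_value, ds$measurements$raw_value,
                 tolerance = 1e-12)
    expect_identical(ds2$measurements$flags, ds$measurements$flags)
    expect_identical(ds2$measurements$role, ds$measurements$role)
    unlink(f)
  }
})

test_that("empty dataset writes a header-only file", {
  ds <- tiny_dataset()
  ds$measurements <- ds$measurements[0, ]
  f <- withr::local_tempfile()
  write_dataset(ds, f)
  ds2 <- read_dataset(f)
  expect_equal(nrow(ds2$measurements), 0)
})

test_that("a file missing a mandatory metadata key errors naming the key", {
  ds <- tiny_dataset()
  f <- withr::local_tempfile()
  write_dataset(ds, f)
  txt <- readLines(f)
  writeLines(txt[!grepl("^# exposure_h", txt)], f)
  expect_error(read_dataset(f), "exposure_h")
})

test_that("a file without the dialect declaration is rejected", {
  f <- withr::local_tempfile()
  writeLines(c("# some-other-format: 2", "a,b", "1,2"), f)
  expect_error(read_dataset(f), "navitro-plate-format")
})

test_that("spreadsheet date artifacts and locale commas become structured errors", {
  ds <- tiny_dataset()
  f <- withr::local_tempfile()
  write_dataset(ds, f)
  txt <- readLines(f)
  # corrupt one concentration cell into a spreadsheet date and one raw value
  # into a locale-comma decimal, the classic Excel failure modes
  i <- grep("^P01,A4", txt)
  txt[i] <- sub(",4,", ",Jun-05,", txt[i])
  j <- grep("^P01,A5", txt)
  txt[j] <- sub(",40,", ",\"40,5\",", txt[j])
  writeLines(txt, f)
  ds2 <- read_dataset(f)
  rep <- validate_dataset(ds2)
  expect_true("SPREADSHEET_DATE_ARTIFACT" %in% rep$code)
  expect_true("LOCALE_COMMA" %in% rep$code)
  expect_false(is_conformant(rep))
})

test_that("validator flags missing control linkage and duplicates", {
  m <- data.frame(
    plate_id = "P01", well = c("A1", "A2", "A3", "A3"),
    role = "treatment", compound_id = "cmpA",
    conc_neglog_molar = c(4, 5, 6, 6), endpoint_id = "viability",
    raw_value = c(10, 20, 30, 30), replicate = 1L, flags = "",
    timestamp = "", stringsAsFactors = FALSE)
  ds <- plate_dataset(m, list(test_method_id = "t", lab_id = "l",
                              solvent = "DMSO", exposure_h = 24))
  rep <- validate_dataset(ds)
  expect_true("MISSING_CONTROL_LINK" %in% rep$code)
  expect_true("DUPLICATE_WELL" %in% rep$code)
})

test_that("validator resolves compounds and concentrations against declarations", {
  ds <- tiny_dataset(metadata = list(series_start = 4, series_end = 10,
                                     series_step = 0.5))
  ds$measurements$conc_neglog_molar[5] <- 4.3   # off-series
  ds$measurements$compound_id[6] <- "ghost"
  rep <- validate_dataset(ds, registry = test_registry())
  expect_true("CONC_OUT_OF_SERIES" %in% rep$code)
  expect_true("UNRESOLVED_COMPOUND" %in% rep$code)
})

test_that("treatment rows need compound and concentration; flags are a closed set", {
  ds <- tiny_dataset()
  ds$measurements$conc_neglog_molar[4] <- NA
  ds$measurements$flags[5] <- "made_up_flag"
  rep <- validate_dataset(ds)
  expect_true("TREATMENT_INCOMPLETE" %in% rep$code)
  expect_true("UNKNOWN_FLAG" %in% rep$code)
})

test_that("non-standard DMSO percentage is a note, not an error", {
  ds <- tiny_dataset(metadata = list(solvent_final_percent = 0.5))
  rep <- validate_dataset(ds)
  expect_true("NONSTANDARD_DMSO_PERCENT" %in% rep$code)
  expect_equal(rep$severity[rep$code == "NONSTANDARD_DMSO_PERCENT"], "note")
  expect_true(is_conformant(rep))
})

test_that("a clean synthetic dataset validates with zero errors", {
  ds <- generate_plate(synthetic_spec(5, viability_truth(), noise_cv = 0.1))
  rep <- validate_dataset(ds)
  expect_true(is_conformant(rep))
  expect_equal(sum(rep$severity == "error"), 0)
})

test_that("the validator is pure: repeated calls give identical reports", {
  ds <- tiny_dataset()
  ds$measurements$compound_id[6] <- "ghost"
  r1 <- validate_dataset(ds, registry = test_registry())
  r2 <- validate_dataset(ds, registry = test_registry())
  expect_identical(r1, r2)
})

test_that("copy-pasted metadata across distinct run ids draws a warning", {
  ds1 <- tiny_dataset(metadata = list(seed_or_run_id = "run-1"))
  ds2 <- tiny_dataset(metadata = list(seed_or_run_id = "run-2"))
  rep <- validate_datasets(list(ds1, ds2))
  expect_true("COPY_PASTED_METADATA" %in% rep$code)
  expect_equal(rep$severity[rep$code == "COPY_PASTED_METADATA"], "warning")
  # genuinely different metadata is not flagged
  ds3 <- tiny_dataset(metadata = list(seed_or_run_id = "run-3",
                                      exposure_h = 48))
  rep2 <- validate_datasets(list(ds1, ds3))
  expect_false("COPY_PASTED_METADATA" %in% rep2$code)
})

test_that("validation reports serialize to JSON", {
  ds <- tiny_dataset()
  ds$measurements$compound_id[6] <- "ghost"
  rep <- validate_dataset(ds, registry = test_registry())
  js <- report_to_json(rep)
  parsed <- jsonlite::fromJSON(js)
  expect_true("UNRESOLVED_COMPOUND" %in% parsed$code)
})
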