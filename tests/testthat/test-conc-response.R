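test_that("normalization expresses responses as percent of solvent control", {
  ds <- tiny_dataset(ctrl_raw = c(90, 110), trt_conc = c(4, 5, 6, 7),
                     trt_raw = c(50, 100, 150, 0))
  normed <- normalize_to_controls(ds, "viability")
  resp <- normed$measurements$response_percent
  expect_equal(resp[3], 50)    # first treatment: 50 / mean(90,110) * 100
  expect_equal(resp[4], 100)
  expect_equal(resp[6], 0)
  # control wells normalize to an average of exactly 100%
  expect_equal(mean(resp[1:2]), 100)
})

test_that("blank wells are subtracted before normalization", {
  extra <- data.frame(
    plate_id = "P01", well = c("B1", "B2"), role = "blank",
    compound_id = "", conc_neglog_molar = NA_real_,
    endpoint_id = "viability", raw_value = c(10, 10), replicate = 1L,
    flags = "", timestamp = "", stringsAsFactors = FALSE)
  ds <- tiny_dataset(ctrl_raw = c(100, 120), trt_raw = c(10, 65, 100, 110),
                     extra_rows = extra)
  normed <- normalize_to_controls(ds, "viability")
  # (raw - 10) / (110 - 10) * 100
  expect_equal(normed$measurements$response_percent[3], 0)
  expect_equal(normed$measurements$response_percent[4], 55)
})

test_that("flagged controls are excluded from the control mean but kept in data", {
  ds <- tiny_dataset(ctrl_raw = c(100, 100, 500))
  ds$measurements$flags[3] <- "outlier"
  normed <- normalize_to_controls(ds, "viability")
  # control mean is 100, not 233
  expect_equal(normed$measurements$response_percent[1], 100)
  expect_equal(nrow(normed$measurements), 7)   # flagged row not dropped
  ds2 <- tiny_dataset()
  ds2$measurements$flags[1:3] <- "lab_error"
  expect_error(normalize_to_controls(ds2, "viability"), "solvent control")
})

test_that("noiseless 4PL data recover the generating parameters", {
  concs <- rep(dilution_series(4, 10, 0.5), each = 3)
  true <- list(top = 100, bottom = 0, log_ec50 = 6, hill = 1)
  y <- true$bottom + (true$top - true$bottom) /
    (1 + 10^(true$hill * (true$log_ec50 - concs)))
  fit <- fit_4pl(concs, y, "decline")
  expect_true(fit$fit_ok)
  expect_equal(fit$top, true$top, tolerance = 1e-6)
  expect_equal(fit$bottom, true$bottom, tolerance = 1e-6)
  expect_equal(fit$log_ec50, true$log_ec50, tolerance = 1e-6)
  expect_equal(fit$hill, true$hill, tolerance = 1e-6)
})

test_that("noiseless induction data recover their parameters too", {
  concs <- rep(dilution_series(4, 10, 0.5), each = 3)
  y <- 100 + (400 - 100) / (1 + 10^(1.5 * (concs - 6.5)))
  fit <- fit_4pl(concs, y, "induce")
  expect_true(fit$fit_ok)
  expect_equal(fit$top, 400, tolerance = 1e-5)
  expect_equal(fit$bottom, 100, tolerance = 1e-5)
  expect_equal(fit$log_ec50, 6.5, tolerance = 1e-6)
})

test_that("flat responses yield fit_ok = FALSE with a no-effect note", {
  concs <- dilution_series(4, 10, 0.5)
  fit <- fit_4pl(concs, rep(100, 13), "decline")
  expect_false(fit$fit_ok)
  expect_match(fit$diagnostics$note, "no effect")
  expect_error(fit_4pl(c(4, 5, 6), c(100, 50, 0), "decline"), "4 distinct")
})

test_that("fit accuracy under realistic noise stays within 0.2 log units", {
  errs <- vapply(1:50, simulate_ec50_error, numeric(1), cv = 0.05)
  expect_true(all(is.finite(errs)))
  expect_lt(median(abs(errs)), 0.2)
})

test_that("BMC inversion matches known closed-form anchor points", {
  # top=100, bottom=0, hill=1, EC50 = 1 uM
  cur <- curve_4pl(100, 0, 6, 1, "decline")
  expect_equal(derive_bmc(cur, 50)$bmc_neglog_molar, 6)  # BMC50 = EC50
  bmc25 <- derive_bmc(cur, 25)
  # EC50/3, cross-checked below by numeric root finding
  expect_equal(neglog_to_conc(bmc25$bmc_neglog_molar, "uM"), 1 / 3,
               tolerance = 1e-9)
  expect_error(derive_bmc(cur, 0), "bmr")
  expect_error(derive_bmc(cur, 120), "bmr")
})

test_that("shallow curves censor at the highest tested concentration", {
  cur <- curve_4pl(100, 85, 6, 1, "decline", conc_range = c(4, 10))
  bmc <- derive_bmc(cur, 25)   # max decline 15% < BMR 25%
  expect_true(bmc$censored)
  expect_equal(bmc$censor_bound, 4)   # -log10(M) of the highest tested conc
  pod <- derive_pod(cur, 25)
  expect_true(pod$censored)
})

test_that("closed-form BMC agrees with numeric root finding on random curves", {
  set.seed(19)
  for (i in 1:200) {
    dirn <- sample(c("decline", "induce"), 1)
    if (dirn == "decline") {
      top <- runif(1, 85, 120); bottom <- runif(1, -10, 40)
    } else {
      bottom <- runif(1, 85, 110); top <- runif(1, 160, 1000)
    }
    cur <- curve_4pl(top, bottom, runif(1, 4.5, 9.5), runif(1, 0.5, 5), dirn)
    bmc <- derive_bmc(cur, 25)
    y0 <- if (dirn == "decline") 75 else 125
    root <- uniroot(function(c) predict(cur, c) - y0,
                    interval = c(-10, 25), tol = 1e-13)$root
    expect_equal(bmc$bmc_neglog_molar, root, tolerance = 1e-9)
  }
})

test_that("BMC is monotone in the benchmark response", {
  set.seed(23)
  for (i in 1:50) {
    cur <- curve_4pl(runif(1, 90, 110), runif(1, -10, 20),
                     runif(1, 5, 9), runif(1, 0.5, 4), "decline")
    bmrs <- c(10, 25, 50, 75)
    bmcs <- vapply(bmrs, function(b) derive_bmc(cur, b)$bmc_neglog_molar,
                   numeric(1))
    # larger BMR means a higher concentration, i.e. a lower -log10(M)
    expect_true(all(diff(bmcs) < 0))
  }
})

test_that("PoD is the BMC in -log10(M) with censoring propagated", {
  cur <- curve_4pl(100, 0, 6, 1, "decline",
                   compound_id = "cmpA", endpoint_id = "viability")
  pod <- derive_pod(cur, 50)
  expect_equal(pod$pod_neglog_molar, 6)   # BMC of 1 uM -> PoD 6.0
  expect_equal(pod$bmr_percent, 50)       # BMR recorded (provenance)
  flat <- fit_4pl(dilution_series(4, 10, 0.5), rep(100, 13), "decline")
  pod2 <- derive_pod(flat, 25)
  expect_true(pod2$censored)
  expect_equal(pod2$censor_bound, 4)
})

test_that("cytotoxicity anchoring classifies specificity ratios", {
  f <- derive_pod(curve_4pl(100, 0, 7.4, 1, "decline",
                            compound_id = "taxol",
                            endpoint_id = "AR-anta"),
                  50, mode = "functional_antagonist")
  v <- derive_pod(curve_4pl(100, 0, 5.6, 1, "decline",
                            compound_id = "taxol",
                            endpoint_id = "cytotox"), 50)
  anc <- cytotox_anchor(f, v)
  expect_equal(anc$specificity_ratio, 10^1.8, tolerance = 1e-9)  # ~63-fold
  expect_equal(anc$class, "specific")

  equal <- cytotox_anchor(
    derive_pod(curve_4pl(100, 0, 6, 1, "decline"), 50),
    derive_pod(curve_4pl(100, 0, 6, 1, "decline"), 50))
  expect_equal(equal$specificity_ratio, 1)
  expect_equal(equal$class, "cytotoxicity_confounded")

  mid <- cytotox_anchor(
    derive_pod(curve_4pl(100, 0, 6.7, 1, "decline"), 50),
    derive_pod(curve_4pl(100, 0, 6, 1, "decline"), 50))
  expect_equal(mid$class, "borderline")   # 5-fold

  flat <- fit_4pl(dilution_series(4, 10, 0.5), rep(100, 13), "decline")
  expect_equal(cytotox_anchor(derive_pod(flat, 25), v)$class, "undetermined")
  only_v <- cytotox_anchor(f, derive_pod(flat, 25))
  expect_equal(only_v$class, "specific")
  expect_true(only_v$ratio_is_lower_bound)
})

test_that("reference EC50 is exposed for antagonist-mode co-treatment", {
  cur <- curve_4pl(100, 0, 7, 1, "decline")
  expect_equal(reference_ec50(cur), 7)
  expect_equal(neglog_to_conc(reference_ec50(cur), "nM"), 100)
  flat <- fit_4pl(dilution_series(4, 10, 0.5), rep(100, 13), "decline")
  expect_error(reference_ec50(flat), "no EC50")
})

test_that("PoD matrix is rectangular, sorted, and marks censored cells", {
  flat <- fit_4pl(dilution_series(4, 10, 0.5), rep(100, 13), "decline")
  flat$compound_id <- "cmpB"; flat$endpoint_id <- "ep2"
  pods <- list(
    derive_pod(curve_4pl(100, 0, 6, 1, "decline", compound_id = "cmpB",
                         endpoint_id = "ep1"), 50),
    derive_pod(curve_4pl(100, 0, 7, 1, "decline", compound_id = "cmpA",
                         endpoint_id = "ep1"), 50),
    derive_pod(curve_4pl(100, 0, 5, 1, "decline", compound_id = "cmpA",
                         endpoint_id = "ep2"), 50),
    derive_pod(flat, 25))
  mat <- assemble_pod_matrix(pods)
  expect_equal(rownames(mat), c("cmpA", "cmpB"))
  expect_equal(colnames(mat), c("ep1", "ep2"))
  expect_equal(mat["cmpB", "ep2"], "no effect")
  expect_equal(mat["cmpA", "ep1"], "7")
  # duplicates conflict
  expect_error(assemble_pod_matrix(c(pods, pods[1])), "duplicate")
  # empty input gives an empty matrix
  expect_equal(dim(assemble_pod_matrix(list())), c(0, 0))
  # pending visual checks can be refused
  expect_error(assemble_pod_matrix(pods, require_visual_check = TRUE),
               "visual check")
  pods_ok <- lapply(pods, function(p) {
    p$source_curve <- set_visual_check(p$source_curve, "passed"); p
  })
  expect_silent(assemble_pod_matrix(pods_ok, require_visual_check = TRUE))
})
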