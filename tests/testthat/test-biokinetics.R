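test_that("medium composition scales linearly from the 100% FCS reference", {
  m100 <- medium_from_fcs(100)
  expect_equal(m100$albumin_um, 346)
  expect_equal(m100$lipid_mg_l, 6000)
  m10 <- medium_from_fcs(10)
  expect_equal(m10$albumin_um, 34.6)
  expect_equal(m10$lipid_mg_l, 600)
  m0 <- medium_from_fcs(0)
  expect_true(m0$serum_free)
  expect_equal(medium_from_fcs(5, extra_albumin_um = 100)$albumin_um,
               5 * 3.46 + 100)
  expect_error(medium_from_fcs(120), "0, 100")
  expect_error(medium_composition("m", albumin_um = -1), "albumin")
})

test_that("media files read back with FCS-derived defaults", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("medium_id,fcs_percent,albumin_um,lipid_mg_l,notes",
               "rpmi_10fcs,10,,,",
               "dmem_dcc,5,17.3,0,charcoal-stripped serum"), f)
  media <- read_media(f)
  expect_equal(media$rpmi_10fcs$albumin_um, 34.6)
  expect_equal(media$rpmi_10fcs$lipid_mg_l, 600)
  expect_equal(media$dmem_dcc$lipid_mg_l, 0)   # explicit zero not overridden
  expect_match(media$dmem_dcc$notes, "charcoal")
})

test_that("binding constants behave at their anchor points", {
  reg <- test_registry()
  cmp0 <- compound("x", "x", "64-17-5", 100, log_kow = 0)
  k <- binding_constants(cmp0, "kow_regression")
  expect_equal(k$k_lipid, 1)              # Kow = 10^0
  expect_equal(k$k_protein, 10^0.42)
  unbound <- compound("y", "y", "64-17-5", 100, ppb_fraction_bound = 0,
                      log_kow = 1)
  expect_equal(binding_constants(unbound, "ppb_scaled")$k_protein, 0)
  no_kow <- compound("z", "z", "64-17-5", 100)
  expect_error(binding_constants(no_kow, "kow_regression"), "log_kow")
  expect_error(binding_constants(no_kow, "ppb_scaled"), "ppb")
  # auto mode picks PPB when available and records the method
  tolb <- registry_compound(reg, "tolbutamide")
  expect_equal(binding_constants(tolb, "auto")$method, "ppb_scaled")
  cmpA <- registry_compound(reg, "cmpA")
  expect_equal(binding_constants(cmpA, "auto")$method, "kow_regression")
})

test_that("binding constants increase strictly with logKow", {
  kows <- seq(-2, 6, by = 0.5)
  ks <- vapply(kows, function(lk) {
    cmp <- compound("x", "x", "64-17-5", 100, log_kow = lk)
    unlist(binding_constants(cmp, "kow_regression")[c("k_protein", "k_lipid")])
  }, numeric(2))
  expect_true(all(diff(ks[1, ]) > 0))
  expect_true(all(diff(ks[2, ]) > 0))
})

test_that("serum-free media leave the free fraction at exactly 1", {
  reg <- test_registry()
  m0 <- medium_from_fcs(0)
  for (id in reg$compound_id) {
    ff <- free_fraction(registry_compound(reg, id), m0)
    expect_identical(ff$f_unbound, 1)
    expect_identical(ff$bound_to_protein, 0)
    fc <- free_concentration(6, ff)
    expect_equal(fc$micromolar, 1)   # free equals nominal
  }
})

test_that("the three fractions sum to one on random compound/medium pairs", {
  set.seed(55)
  for (i in 1:1000) {
    cmp <- compound("x", "x", "64-17-5", 100,
                    log_kow = runif(1, -2, 6),
                    ppb_fraction_bound = runif(1, 0, 0.99))
    med <- medium_composition("m", albumin_um = runif(1, 0, 400),
                              lipid_mg_l = runif(1, 0, 7000))
    mode <- sample(c("ppb_scaled", "kow_regression"), 1)
    ff <- free_fraction(cmp, med, mode)
    expect_equal(ff$f_unbound + ff$bound_to_protein + ff$bound_to_lipid, 1,
                 tolerance = 1e-9)
    expect_gt(ff$f_unbound, 0)
    expect_lte(ff$f_unbound, 1)
  }
})

test_that("free fraction is monotone in albumin, lipid and logKow", {
  cmp <- compound("x", "x", "64-17-5", 100, log_kow = 2,
                  ppb_fraction_bound = 0.9)
  alb <- seq(0, 400, by = 50)
  fa <- vapply(alb, function(a) free_fraction(
    cmp, medium_composition("m", albumin_um = a, lipid_mg_l = 100))$f_unbound,
    numeric(1))
  expect_true(all(diff(fa) < 0))
  lip <- seq(0, 6000, by = 500)
  fl <- vapply(lip, function(l) free_fraction(
    cmp, medium_composition("m", albumin_um = 50, lipid_mg_l = l))$f_unbound,
    numeric(1))
  expect_true(all(diff(fl) < 0))
  med <- medium_from_fcs(10)
  fk <- vapply(seq(-2, 8, by = 0.5), function(lk) free_fraction(
    compound("x", "x", "64-17-5", 100, log_kow = lk), med,
    "kow_regression")$f_unbound, numeric(1))
  expect_true(all(diff(fk) < 0))
  # limit behaviour: binding phases to zero -> 1; extreme hydrophobicity -> 0
  expect_equal(fa[1], free_fraction(
    cmp, medium_composition("m", 0, 0, 100))$f_unbound, tolerance = 1e-9)
  expect_lt(fk[length(fk)], 0.01)
})

test_that("weak binders keep free equal to nominal in serum media", {
  # paracetamol-like: low logKow, 15% plasma protein binding
  reg <- test_registry()
  par <- registry_compound(reg, "paracetamol")
  for (mode in c("ppb_scaled", "kow_regression")) {
    ff <- free_fraction(par, medium_from_fcs(10), mode)
    expect_gte(ff$f_unbound, 0.98)
  }
})

test_that("a strong binder stays within the expected band across a media panel", {
  # tolbutamide-like, 95% plasma-bound: across serum-free to 10% FCS media
  # the free fraction stays within 70-100% under the Kow-driven constants
  reg <- test_registry()
  tolb <- registry_compound(reg, "tolbutamide")
  panel <- list(medium_from_fcs(0), medium_from_fcs(5), medium_from_fcs(10),
                medium_composition("dcc5", 5, albumin_um = 17.3,
                                   lipid_mg_l = 0))
  fu <- vapply(panel, function(m)
    free_fraction(tolb, m, "kow_regression")$f_unbound, numeric(1))
  expect_gte(min(fu), 0.70)
  expect_lte(max(fu), 1.00)
})

test_that("free concentration applies the unbound fraction to the nominal", {
  ff <- structure(list(f_unbound = 0.5), class = "free_fraction")
  expect_equal(free_concentration(4, ff)$micromolar, 50)     # 100 uM nominal
  ff86 <- structure(list(f_unbound = 0.86), class = "free_fraction")
  expect_equal(free_concentration(5, ff86)$micromolar, 8.6)  # 10 uM nominal
  ff1 <- structure(list(f_unbound = 1), class = "free_fraction")
  expect_equal(free_concentration(6.3, ff1)$neglog, 6.3)
})

test_that("volatility and hydrophobicity warnings are attached", {
  hg <- compound("hgcl2", "Mercuric chloride", "7487-94-7", 271.5,
                 log_kow = 0.5, k_aw = 0.02, ppb_fraction_bound = 0.5)
  ff <- free_fraction(hg, medium_from_fcs(10))
  expect_true(any(grepl("borderline", ff$warnings)))
  pcb <- compound("pcb180", "PCB 180", "35065-29-3", 395.3, log_kow = 7.36)
  ff2 <- free_fraction(pcb, medium_from_fcs(10), "kow_regression")
  expect_true(any(grepl("plastic", ff2$warnings)))
})
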