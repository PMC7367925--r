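# Fixture builders shared across test files. All fixtures are built in code;
# nothing is read from disk except files the tests themselves write.

test_registry <- function() {
  df <- data.frame(
    compound_id = c("tolbutamide", "paracetamol", "colchicine", "cmpA"),
    name = c("Tolbutamide", "Paracetamol", "Colchicine", "Test compound A"),
    cas = c("64-77-7", "103-90-2", "64-86-8", "50-00-0"),
    smiles = c("", "", "", ""),
    mw_da = c(270.35, 151.16, 399.44, 30.03),
    log_kow = c(2.34, 0.46, 1.3, 0.35),
    k_aw = c(NA, NA, NA, NA),
    solubility_mol_l = c(1e-3, 0.1, 0.1, 1),
    ppb_fraction_bound = c(0.95, 0.15, 0.40, NA),
    stock_solvent = c("DMSO", "DMSO", "DMSO", "water"),
    stock_conc_m = c(0.1, 0.1, 0.1, 0.1),
    handling_notes = c("", "", "", ""),
    stringsAsFactors = FALSE)
  class(df) <- c("navitro_registry", "data.frame")
  df
}

# minimal hand-built plate: n solvent controls + treatment wells for one
# compound at the given concentrations (one replicate per conc)
tiny_dataset <- function(ctrl_raw = c(95, 100, 105),
                         trt_conc = c(4, 5, 6, 7),
                         trt_raw = c(10, 40, 80, 100),
                         endpoint = "viability",
                         compound = "cmpA",
                         extra_rows = NULL,
                         metadata = list()) {
  n_c <- length(ctrl_raw)
  m <- data.frame(
    plate_id = "P01",
    well = paste0("A", seq_len(n_c + length(trt_conc))),
    role = c(rep("solvent_control", n_c), rep("treatment", length(trt_conc))),
    compound_id = c(rep("", n_c), rep(compound, length(trt_conc))),
    conc_neglog_molar = c(rep(NA_real_, n_c), trt_conc),
    endpoint_id = endpoint,
    raw_value = c(ctrl_raw, trt_raw),
    replicate = 1L,
    flags = "",
    timestamp = "",
    stringsAsFactors = FALSE)
  if (!is.null(extra_rows)) m <- rbind(m, extra_rows)
  md <- utils::modifyList(list(
    test_method_id = "toy_method", test_method_version = "1.0",
    lab_id = "lab1", solvent = "DMSO", solvent_final_percent = 0.1,
    exposure_h = 24, seed_or_run_id = "run-1"), metadata)
  plate_dataset(m, md)
}

viability_truth <- function(compound = "cmpA", endpoint = "viability",
                            top = 100, bottom = 0, log_ec50 = 6, hill = 1) {
  data.frame(compound_id = compound, endpoint_id = endpoint, top = top,
             bottom = bottom, log_ec50 = log_ec50, hill = hill,
             direction = "decline", stringsAsFactors = FALSE)
}

# simulate a 13-point, n-replicate series from a known decline curve with
# multiplicative lognormal noise and return the fitted log EC50 error
simulate_ec50_error <- function(seed, cv = 0.05, n_rep = 3,
                                top = 100, bottom = 0, log_ec50 = 6,
                                hill = 1) {
  set.seed(seed)
  concs <- rep(dilution_series(4, 10, 0.5), each = n_rep)
  y_true <- bottom + (top - bottom) / (1 + 10^(hill * (log_ec50 - concs)))
  sdlog <- sqrt(log(1 + cv^2))
  y <- y_true * stats::rlnorm(length(concs), -sdlog^2 / 2, sdlog)
  fit <- fit_4pl(concs, y, "decline")
  if (!fit$fit_ok) return(NA_real_)
  fit$log_ec50 - log_ec50
}
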