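# Free (unbound) compound concentration in culture medium, from a
# three-compartment mass balance: a test compound distributes between the
# aqueous phase, serum protein (albumin as proxy for all serum proteins)
# and lipid (triacylglycerol). With linear binding,
#
#   f_unbound = 1 / (1 + K_protein * C_protein + K_lipid * C_lipid)
#
# where the K are sorption coefficients (L/kg) and the phase concentrations
# are in kg/L. Albumin mass is derived from its molar concentration with
# MW 66.5 kDa; the fetal-calf-serum reference is 23 mg/mL protein (346 uM
# albumin) and ~6000 mg/L lipid at 100% FCS. Binding to plastic and to the
# cells themselves is deliberately outside the model.

.ALBUMIN_MW_KDA <- 66.5
# kg of albumin per litre per uM: 66.5e3 g/mol * 1e-6 mol/L / 1e3 g/kg
.ALB_KG_L_PER_UM <- .ALBUMIN_MW_KDA * 1e3 * 1e-6 / 1e3
.ALBUMIN_UM_PER_PCT_FCS <- 3.46    # 346 uM at 100% FCS
.LIPID_MG_L_PER_PCT_FCS <- 60      # 6000 mg/L at 100% FCS
.PLASMA_ALBUMIN_UM <- 600          # reference for scaling plasma PPB

#' Construct a medium composition record
#'
#' @param medium_id Short label.
#' @param fcs_percent Fetal calf serum, percent v/v.
#' @param albumin_um Total albumin in uM (including the FCS contribution).
#' @param lipid_mg_l Total lipid (triacylglycerol) in mg/L.
#' @param notes Free text (e.g. "charcoal-stripped serum").
#' @return An object of class `medium_composition`; `serum_free` is derived
#'   (zero albumin and zero lipid).
#' @export
medium_composition <- function(medium_id, fcs_percent = 0, albumin_um = 0,
                               lipid_mg_l = 0, notes = "") {
  if (!is.finite(albumin_um) || albumin_um < 0)
    stop("albumin_um must be >= 0", call. = FALSE)
  if (!is.finite(lipid_mg_l) || lipid_mg_l < 0)
    stop("lipid_mg_l must be >= 0", call. = FALSE)
  structure(list(medium_id = medium_id, fcs_percent = fcs_percent,
                 albumin_um = albumin_um, lipid_mg_l = lipid_mg_l,
                 serum_free = (albumin_um == 0 && lipid_mg_l == 0),
                 notes = notes),
            class = "medium_composition")
}

#' Derive a medium composition from its FCS percentage
#'
#' Linear scaling from the 100% FCS reference (346 uM albumin, ~6000 mg/L
#' lipid), plus explicit protein/lipid supplements.
#'
#' @param fcs_percent FCS content, percent v/v in `[0, 100]`.
#' @param extra_albumin_um Additional albumin beyond the FCS contribution,
#'   uM.
#' @param extra_lipid_mg_l Additional lipid, mg/L.
#' @param medium_id Label (default derived from the FCS percentage).
#' @param notes Free text.
#' @return A `medium_composition`.
#' @examples
#' medium_from_fcs(10)   # 34.6 uM albumin, 600 mg/L lipid
#' medium_from_fcs(0)    # serum-free
#' @export
medium_from_fcs <- function(fcs_percent, extra_albumin_um = 0,
                            extra_lipid_mg_l = 0,
                            medium_id = sprintf("fcs_%g", fcs_percent),
                            notes = "") {
  if (!is.finite(fcs_percent) || fcs_percent < 0 || fcs_percent > 100)
    stop("fcs_percent must lie in [0, 100]", call. = FALSE)
  medium_composition(
    medium_id = medium_id, fcs_percent = fcs_percent,
    albumin_um = fcs_percent * .ALBUMIN_UM_PER_PCT_FCS + extra_albumin_um,
    lipid_mg_l = fcs_percent * .LIPID_MG_L_PER_PCT_FCS + extra_lipid_mg_l,
    notes = notes)
}

#' @export
print.medium_composition <- function(x, ...) {
  cat(sprintf("<medium %s> %g%% FCS, %.4g uM albumin, %.4g mg/L lipid%s\n",
              x$medium_id, x$fcs_percent, x$albumin_um, x$lipid_mg_l,
              if (x$serum_free) " (serum-free)" else ""))
  invisible(x)
}

#' Read a media configuration file
#'
#' CSV with columns `medium_id,fcs_percent,albumin_um,lipid_mg_l,notes`.
#' When `albumin_um` or `lipid_mg_l` is empty the value is derived from the
#' FCS percentage.
#'
#' @param path Path to the CSV.
#' @return Named list of `medium_composition` objects.
#' @export
read_media <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- list()
  for (i in seq_len(nrow(df))) {
    fcs <- df$fcs_percent[i]
    alb <- df$albumin_um[i]
    lip <- df$lipid_mg_l[i]
    if (is.na(alb)) alb <- fcs * .ALBUMIN_UM_PER_PCT_FCS
    if (is.na(lip)) lip <- fcs * .LIPID_MG_L_PER_PCT_FCS
    out[[df$medium_id[i]]] <- medium_composition(
      df$medium_id[i], fcs, alb, lip,
      notes = if (is.null(df$notes) || is.na(df$notes[i])) "" else df$notes[i])
  }
  out
}

#' Sorption coefficients of a compound for protein and lipid
#'
#' Two routes to the binding constants:
#'
#' * `ppb_scaled` -- the albumin affinity is inferred from the measured
#'   plasma protein binding: in plasma, `bound/free = K_protein * C_alb,plasma`,
#'   so `K_protein = (PPB / (1 - PPB)) / C_alb,plasma` with the plasma
#'   albumin reference (default 600 uM) converted to kg/L. The lipid
#'   coefficient falls back to `K_lipid = Kow` when logKow is available,
#'   else 0.
#' * `kow_regression` -- fully property-driven:
#'   `log10 K_protein = 0.71 * logKow + 0.42` (serum-albumin sorption
#'   regression) and `K_lipid = Kow` for storage lipid.
#'
#' `mode = "auto"` picks `ppb_scaled` when a PPB value is present, else
#' `kow_regression`; the mode actually used is recorded in the result.
#'
#' @param compound A `navitro_compound`.
#' @param mode `"auto"`, `"ppb_scaled"` or `"kow_regression"`.
#' @param plasma_albumin_um Plasma albumin reference for PPB scaling, uM.
#' @return List: `k_protein` (L/kg), `k_lipid` (L/kg), `method`.
#' @export
binding_constants <- function(compound,
                              mode = c("auto", "ppb_scaled", "kow_regression"),
                              plasma_albumin_um = .PLASMA_ALBUMIN_UM) {
  mode <- match.arg(mode)
  has_ppb <- !is.null(compound$ppb_fraction_bound) &&
    !is.na(compound$ppb_fraction_bound)
  has_kow <- !is.null(compound$log_kow) && !is.na(compound$log_kow)
  if (mode == "auto") mode <- if (has_ppb) "ppb_scaled" else "kow_regression"
  if (mode == "ppb_scaled") {
    if (!has_ppb)
      stop(paste("ppb_fraction_bound missing; use mode = 'kow_regression'",
                 "or supply a PPB value"), call. = FALSE)
    ppb <- compound$ppb_fraction_bound
    c_alb_plasma <- plasma_albumin_um * .ALB_KG_L_PER_UM
    k_protein <- if (ppb >= 1) Inf else (ppb / (1 - ppb)) / c_alb_plasma
    k_lipid <- if (has_kow) 10^compound$log_kow else 0
    list(k_protein = k_protein, k_lipid = k_lipid, method = "ppb_scaled")
  } else {
    if (!has_kow)
      stop(paste("log_kow missing; use mode = 'ppb_scaled'",
                 "or supply a logKow value"), call. = FALSE)
    list(k_protein = 10^(0.71 * compound$log_kow + 0.42),
         k_lipid = 10^compound$log_kow,
         method = "kow_regression")
  }
}

#' Predict the free (unbound) fraction of a compound in a medium
#'
#' Mass-balance partitioning over the aqueous, protein and lipid phases:
#' `f_unbound = 1 / (1 + K_protein * C_protein + K_lipid * C_lipid)` with
#' phase concentrations in kg/L (albumin mass from uM via 66.5 kDa, lipid
#' from mg/L). The three fractions sum to one by construction, and a
#' serum-free medium gives `f_unbound = 1` exactly.
#'
#' Assumption checks add warnings rather than failing: a compound that is
#' not clearly non-volatile (air-water partition coefficient at or above
#' half the 0.03 threshold) is flagged, extreme hydrophobics
#' (logKow > 5) carry a note that plastic adsorption -- never modelled
#' here -- can remove of the order of a third of such compounds.
#'
#' @param compound A `navitro_compound`.
#' @param medium A `medium_composition`.
#' @param mode Binding-constant mode, see [binding_constants()].
#' @param plasma_albumin_um Passed to [binding_constants()].
#' @return An object of class `free_fraction`: `f_unbound`, `bound_to_protein`,
#'   `bound_to_lipid` (fractions summing to 1), `method`, `warnings`.
#' @export
free_fraction <- function(compound, medium, mode = "auto",
                          plasma_albumin_um = .PLASMA_ALBUMIN_UM) {
  stopifnot(inherits(medium, "medium_composition"))
  warnings <- character(0)
  vf <- volatility_flag(compound)
  if (vf %in% c("borderline", "volatile"))
    warnings <- c(warnings, sprintf(
      "compound is %s (K_AW = %g); evaporation losses not modelled",
      vf, compound$k_aw))
  if (vf == "unknown")
    warnings <- c(warnings, "volatility unknown (no K_AW value)")
  if (!is.na(compound$log_kow) && compound$log_kow > 5)
    warnings <- c(warnings, paste(
      "extremely hydrophobic compound: plastic adsorption (not modelled)",
      "can bind of the order of one third of the compound"))
  warnings <- c(warnings, "binding to plastics and cells is not modelled")

  if (medium$serum_free) {
    k <- list(k_protein = NA_real_, k_lipid = NA_real_, method = "none")
    return(structure(list(
      f_unbound = 1, bound_to_protein = 0, bound_to_lipid = 0,
      method = "serum_free", medium_id = medium$medium_id,
      compound_id = compound$compound_id, warnings = warnings),
      class = "free_fraction"))
  }
  k <- binding_constants(compound, mode, plasma_albumin_um)
  c_protein <- medium$albumin_um * .ALB_KG_L_PER_UM   # kg/L
  c_lipid <- medium$lipid_mg_l * 1e-6                 # kg/L
  tp <- k$k_protein * c_protein
  tl <- k$k_lipid * c_lipid
  denom <- 1 + tp + tl
  structure(list(
    f_unbound = 1 / denom, bound_to_protein = tp / denom,
    bound_to_lipid = tl / denom, method = k$method,
    medium_id = medium$medium_id, compound_id = compound$compound_id,
    warnings = warnings),
    class = "free_fraction")
}

#' @export
print.free_fraction <- function(x, ...) {
  cat(sprintf(
    "<free_fraction %s in %s> f_u = %.3f (protein %.3f, lipid %.3f) [%s]\n",
    x$compound_id, x$medium_id, x$f_unbound, x$bound_to_protein,
    x$bound_to_lipid, x$method))
  for (w in x$warnings) cat("  note:", w, "\n")
  invisible(x)
}

#' Free concentration from a nominal concentration
#'
#' @param nominal_neglog Nominal test concentration in -log10(M).
#' @param result A `free_fraction`.
#' @return List: `neglog` (-log10 M), `molar`, `micromolar` of the free
#'   concentration, plus `f_unbound`.
#' @examples
#' # f_u = 0.86 at 10 uM nominal gives 8.6 uM free
#' @export
free_concentration <- function(nominal_neglog, result) {
  stopifnot(inherits(result, "free_fraction"))
  molar <- 10^(-nominal_neglog) * result$f_unbound
  list(neglog = -log10(molar), molar = molar, micromolar = molar * 1e6,
       f_unbound = result$f_unbound)
}
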