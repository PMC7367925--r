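# Compound records, concentration-unit conversions and physicochemical
# screening rules. The canonical internal concentration representation is
# -log10 of the molar concentration ("neglog"); all I/O converts at the
# boundary so that micromolar/nanomolar mix-ups cannot propagate.

.STOCK_SOLVENTS <- c("DMSO", "PBS", "water", "medium")

#' Validate a CAS registry number
#'
#' Checks the `NNNNNNN-NN-N` pattern (2-7 digits, 2 digits, 1 check digit) and
#' the standard CAS check-digit: the digits excluding the check digit, read
#' right to left and weighted 1, 2, 3, ..., must sum to the check digit
#' modulo 10.
#'
#' @param cas Character vector of CAS strings.
#' @return Logical vector, `TRUE` where the string is a well-formed CAS number
#'   with a correct check digit.
#' @examples
#' cas_valid("64-17-5")    # ethanol, TRUE
#' cas_valid("64-17-6")    # wrong check digit, FALSE
#' @export
cas_valid <- function(cas) {
  vapply(cas, function(x) {
    if (is.na(x) || !grepl("^[0-9]{2,7}-[0-9]{2}-[0-9]$", x)) return(FALSE)
    digits <- as.integer(strsplit(gsub("-", "", x), "")[[1]])
    n <- length(digits)
    body <- rev(digits[-n])
    sum(body * seq_along(body)) %% 10 == digits[n]
  }, logical(1), USE.NAMES = FALSE)
}

#' Create a compound record
#'
#' A compound record carries chemical identity (CAS, optional SMILES),
#' the physicochemical constants used downstream (molecular weight, logKow,
#' air-water partition coefficient, aqueous solubility, plasma protein
#' binding) and stock-handling metadata (solvent, stock concentration,
#' free-text handling notes such as "dissolve freshly before each use").
#'
#' @param compound_id Short label used as registry key.
#' @param name Free-text compound name.
#' @param cas CAS registry number; must pass [cas_valid()].
#' @param mw Molecular weight in Dalton; must be positive.
#' @param smiles Optional SMILES string, stored verbatim (not canonicalized).
#' @param log_kow Optional octanol-water partition coefficient, log10 units.
#' @param k_aw Optional dimensionless air-water partition coefficient.
#' @param aqueous_solubility Optional aqueous solubility in mol/L at pH 7.4.
#' @param ppb_fraction_bound Optional plasma-protein-bound fraction in `[0, 1]`.
#' @param stock_solvent One of `"DMSO"`, `"PBS"`, `"water"`, `"medium"`.
#' @param stock_conc Optional stock concentration in mol/L.
#' @param handling_notes Free text.
#' @return An object of class `navitro_compound` (a named list).
#' @export
compound <- function(compound_id, name, cas, mw,
                     smiles = NA_character_,
                     log_kow = NA_real_,
                     k_aw = NA_real_,
                     aqueous_solubility = NA_real_,
                     ppb_fraction_bound = NA_real_,
                     stock_solvent = "DMSO",
                     stock_conc = NA_real_,
                     handling_notes = "") {
  if (!is.character(compound_id) || nchar(compound_id) == 0)
    stop("compound_id must be a non-empty string", call. = FALSE)
  if (!cas_valid(cas))
    stop(sprintf("invalid CAS number '%s' (pattern or check digit)", cas),
         call. = FALSE)
  if (!is.numeric(mw) || !is.finite(mw) || mw <= 0)
    stop("mw must be a positive number (Dalton)", call. = FALSE)
  if (!is.na(ppb_fraction_bound) &&
      (ppb_fraction_bound < 0 || ppb_fraction_bound > 1))
    stop("ppb_fraction_bound must lie in [0, 1]", call. = FALSE)
  if (!stock_solvent %in% .STOCK_SOLVENTS)
    stop(sprintf("stock_solvent must be one of: %s",
                 paste(.STOCK_SOLVENTS, collapse = ", ")), call. = FALSE)
  structure(list(
    compound_id = compound_id, name = name, cas = cas, smiles = smiles,
    mw = mw, log_kow = log_kow, k_aw = k_aw,
    aqueous_solubility = aqueous_solubility,
    ppb_fraction_bound = ppb_fraction_bound,
    stock_solvent = stock_solvent, stock_conc = stock_conc,
    handling_notes = handling_notes
  ), class = "navitro_compound")
}

#' @export
print.navitro_compound <- function(x, ...) {
  cat(sprintf("<compound %s> %s (CAS %s), MW %.5g Da\n",
              x$compound_id, x$name, x$cas, x$mw))
  if (!is.na(x$log_kow)) cat(sprintf("  logKow %.3g", x$log_kow))
  if (!is.na(x$ppb_fraction_bound))
    cat(sprintf("  PPB %.0f%%", 100 * x$ppb_fraction_bound))
  cat(sprintf("  stock: %s\n", x$stock_solvent))
  invisible(x)
}

.check_unit <- function(unit) {
  unit <- match.arg(unit, c("M", "uM", "nM"))
  switch(unit, M = 1, uM = 1e6, nM = 1e9)
}

#' Convert between -log10(M) and concentration units
#'
#' `neglog_to_conc()` converts the unified `-log10(M)` representation into a
#' molar, micromolar or nanomolar concentration; `conc_to_neglog()` is its
#' inverse. The pair round-trips to better than 1e-12 relative error.
#'
#' @param neglog Numeric, `-log10` of the molar concentration (e.g. 6.0 is
#'   1 uM, 5.6 is about 2.5 uM).
#' @param conc Numeric concentration expressed in `unit`.
#' @param unit One of `"M"`, `"uM"`, `"nM"`.
#' @return Numeric vector: the concentration in `unit`, or the neglog value.
#' @examples
#' neglog_to_conc(6.0, "uM")   # 1 uM
#' neglog_to_conc(5.6, "uM")   # ~2.5 uM
#' conc_to_neglog(100, "nM")   # 7
#' @export
neglog_to_conc <- function(neglog, unit = "M") {
  scale <- .check_unit(unit)
  if (any(!is.finite(neglog)))
    stop("neglog must be finite", call. = FALSE)
  10^(-neglog) * scale
}

#' @rdname neglog_to_conc
#' @export
conc_to_neglog <- function(conc, unit = "M") {
  scale <- .check_unit(unit)
  if (any(!is.finite(conc)) || any(conc <= 0))
    stop("conc must be finite and positive", call. = FALSE)
  -log10(conc / scale)
}

#' Convert a mass concentration to a molar concentration
#'
#' Used for the serum-protein conversion: a protein mass concentration in
#' mg/mL divided by the molecular weight in kDa gives mmol/L, i.e. times 1000
#' gives micromolar. With bovine serum albumin at 66.5 kDa, the 23 mg/mL
#' reference value for fetal calf serum corresponds to ~346 uM.
#'
#' @param mass_conc Mass concentration in mg/mL; non-negative.
#' @param mw Molecular weight in kDa; positive.
#' @return Molar concentration in uM.
#' @examples
#' mass_conc_to_molar(23, 66.5)   # ~346 uM albumin in 100% FCS
#' @export
mass_conc_to_molar <- function(mass_conc, mw) {
  if (any(!is.finite(mass_conc)) || any(mass_conc < 0))
    stop("mass_conc must be finite and >= 0 (mg/mL)", call. = FALSE)
  if (any(!is.finite(mw)) || any(mw <= 0))
    stop("mw must be finite and > 0 (kDa)", call. = FALSE)
  mass_conc / mw * 1000
}

#' Build a dilution series in -log10(M) steps
#'
#' Inclusive arithmetic series from `start_neglog` to `end_neglog` in steps of
#' `step_log`. The standard reporter-battery design, 4 to 10 in 0.5-log
#' increments, yields 13 concentrations from 100 uM down to 0.1 nM.
#'
#' @param start_neglog Series start (highest concentration), -log10(M).
#' @param end_neglog Series end (lowest concentration), >= `start_neglog`.
#' @param step_log Positive step in log10 units.
#' @return Numeric vector of -log10(M) values, ordered from highest to lowest
#'   concentration. Length is `floor((end - start)/step) + 1`.
#' @examples
#' dilution_series(4, 10, 0.5)   # 13 points
#' @export
dilution_series <- function(start_neglog, end_neglog, step_log) {
  if (!is.finite(step_log) || step_log <= 0)
    stop("step_log must be a positive number", call. = FALSE)
  if (!is.finite(start_neglog) || !is.finite(end_neglog) ||
      end_neglog < start_neglog)
    stop("end_neglog must be >= start_neglog", call. = FALSE)
  # small tolerance so that e.g. (10 - 4)/0.5 is robust to representation error
  n <- floor((end_neglog - start_neglog) / step_log + 1e-9) + 1
  start_neglog + step_log * (seq_len(n) - 1)
}

#' Check a test concentration against a compound's aqueous solubility
#'
#' The maximal tested concentration should not exceed the solubility of the
#' compound; exceeding it risks precipitation artifacts in the dilution
#' series.
#'
#' @param compound A `navitro_compound`.
#' @param test_conc_neglog Test concentration in -log10(M).
#' @return `"ok"`, `"warn_exceeds_solubility"`, or `"unknown"` when the
#'   compound has no solubility value.
#' @export
check_solubility <- function(compound, test_conc_neglog) {
  sol <- compound$aqueous_solubility
  if (is.null(sol) || is.na(sol)) return("unknown")
  molar <- 10^(-test_conc_neglog)
  if (molar > sol) "warn_exceeds_solubility" else "ok"
}

#' Classify compound volatility from the air-water partition coefficient
#'
#' Compounds with K_AW below 0.03 are treated as non-volatile; a band just
#' below the threshold (default half-threshold, i.e. `[0.015, 0.03)`) is
#' reported as borderline -- mercuric chloride at K_AW = 0.02 is the classic
#' borderline case.
#'
#' @param compound A `navitro_compound`.
#' @param threshold Volatility threshold on K_AW (default 0.03).
#' @param borderline_from Lower edge of the borderline band
#'   (default `threshold / 2`).
#' @return `"non_volatile"`, `"borderline"`, `"volatile"`, or `"unknown"`.
#' @export
volatility_flag <- function(compound, threshold = 0.03,
                            borderline_from = threshold / 2) {
  k <- compound$k_aw
  if (is.null(k) || is.na(k)) return("unknown")
  if (k >= threshold) return("volatile")
  if (k >= borderline_from) return("borderline")
  "non_volatile"
}

#' Format a concentration for display
#'
#' Two significant figures, matching the reporting convention for assay
#' concentrations; full precision is kept internally.
#'
#' @param conc Numeric concentration.
#' @param unit Unit label appended to the value.
#' @return Character vector.
#' @export
format_conc <- function(conc, unit = "uM") {
  paste(signif(conc, 2), unit)
}

# ---- registry I/O ----------------------------------------------------------

.REGISTRY_COLS <- c("compound_id", "name", "cas", "smiles", "mw_da", "log_kow",
                    "k_aw", "solubility_mol_l", "ppb_fraction_bound",
                    "stock_solvent", "stock_conc_m", "handling_notes")

#' Read a compound registry file
#'
#' CSV with header `compound_id,name,cas,smiles,mw_da,log_kow,k_aw,
#' solubility_mol_l,ppb_fraction_bound,stock_solvent,stock_conc_m,
#' handling_notes`; UTF-8, "." decimal separator. Each row is validated as a
#' compound record; validation failures are collected and raised together.
#'
#' @param path Path to the registry CSV.
#' @return A data frame of class `navitro_registry`.
#' @seealso [registry_compound()] to extract one row as a compound object.
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", strip.white = TRUE)
  missing_cols <- setdiff(.REGISTRY_COLS, names(df))
  if (length(missing_cols) > 0)
    stop(sprintf("registry is missing columns: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  df <- df[, .REGISTRY_COLS]
  num_cols <- c("mw_da", "log_kow", "k_aw", "solubility_mol_l",
                "ppb_fraction_bound", "stock_conc_m")
  errs <- character(0)
  for (col in num_cols) {
    bad <- !is.na(df[[col]]) & df[[col]] != "" &
      !grepl("^-?[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?$", df[[col]])
    if (any(bad))
      errs <- c(errs, sprintf("non-numeric value in %s, row %s", col,
                              paste(which(bad), collapse = ",")))
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  bad_cas <- !cas_valid(df$cas)
  if (any(bad_cas))
    errs <- c(errs, sprintf("invalid CAS in row %s: %s",
                            paste(which(bad_cas), collapse = ","),
                            paste(df$cas[bad_cas], collapse = ", ")))
  bad_solvent <- !df$stock_solvent %in% .STOCK_SOLVENTS
  if (any(bad_solvent))
    errs <- c(errs, sprintf("unknown stock_solvent in row %s",
                            paste(which(bad_solvent), collapse = ",")))
  if (any(duplicated(df$compound_id)))
    errs <- c(errs, "duplicate compound_id values")
  bad_mw <- is.na(df$mw_da) | df$mw_da <= 0
  if (any(bad_mw))
    errs <- c(errs, sprintf("mw_da missing or non-positive in row %s",
                            paste(which(bad_mw), collapse = ",")))
  bad_ppb <- !is.na(df$ppb_fraction_bound) &
    (df$ppb_fraction_bound < 0 | df$ppb_fraction_bound > 1)
  if (any(bad_ppb))
    errs <- c(errs, sprintf("ppb_fraction_bound outside [0,1] in row %s",
                            paste(which(bad_ppb), collapse = ",")))
  if (length(errs) > 0)
    stop(paste(c("registry validation failed:", errs), collapse = "\n  "),
         call. = FALSE)
  class(df) <- c("navitro_registry", "data.frame")
  df
}

#' Extract one registry row as a compound object
#'
#' @param registry A `navitro_registry` data frame.
#' @param compound_id Registry key.
#' @return A `navitro_compound`.
#' @export
registry_compound <- function(registry, compound_id) {
  i <- match(compound_id, registry$compound_id)
  if (is.na(i))
    stop(sprintf("compound_id '%s' not in registry", compound_id), call. = FALSE)
  r <- registry[i, ]
  compound(
    compound_id = r$compound_id, name = r$name, cas = r$cas,
    smiles = if (is.na(r$smiles) || r$smiles == "") NA_character_ else r$smiles,
    mw = r$mw_da, log_kow = r$log_kow, k_aw = r$k_aw,
    aqueous_solubility = r$solubility_mol_l,
    ppb_fraction_bound = r$ppb_fraction_bound,
    stock_solvent = r$stock_solvent, stock_conc = r$stock_conc_m,
    handling_notes = if (is.na(r$handling_notes)) "" else r$handling_notes
  )
}

#' Write a compound registry file
#'
#' @param registry A `navitro_registry` data frame (or compatible data frame
#'   with the registry columns).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_registry <- function(registry, path) {
  utils::write.csv(as.data.frame(registry)[, .REGISTRY_COLS], path,
                   row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}
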