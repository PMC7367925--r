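# Deterministic generator of synthetic plate datasets with known ground
# truth. The defaults emulate the reporter-battery design: 13-point
# dilution series from 4 to 10 -log10(M) in 0.5-log increments, triplicate
# wells, multiplicative lognormal noise with 10% CV on solvent controls.
# Random streams are per-plate substreams derived from the master seed, so
# adding plates never reshuffles existing ones.

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.plate_seed <- function(master, plate_index) {
  (as.numeric(master) + 104729 * plate_index) %% 2147483647
}

.well_name <- function(i) {
  # 384-well layout, row-major: A1..A24, B1..B24, ... P24
  if (any(i > 384)) stop("plate layout exceeds 384 wells", call. = FALSE)
  paste0(LETTERS[(i - 1) %/% 24 + 1], (i - 1) %% 24 + 1)
}

#' Specify a synthetic plate experiment
#'
#' Ground truth is a table of 4PL parameters per compound x endpoint; wells
#' receive the true curve response times multiplicative lognormal noise
#' (plus optional additive noise). Compounds listed in `negative_controls`
#' respond flat at 100% of control and are laid out with role
#' `negative_control_compound`.
#'
#' @param seed Master seed (integer); same spec + seed gives an identical
#'   dataset.
#' @param true_curves Data frame with columns `compound_id`, `endpoint_id`,
#'   `top`, `bottom`, `log_ec50`, `hill`, `direction`.
#' @param n_plates Number of plates.
#' @param n_replicates Technical replicates per concentration.
#' @param series Dilution-series parameters `c(start, end, step)` in
#'   -log10(M); default `c(4, 10, 0.5)` (13 concentrations, 100 uM to
#'   0.1 nM).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   noise (fraction, default 0.10).
#' @param additive_sd Additive Gaussian noise SD in raw units (default 0).
#' @param outlier_rate Fraction of treatment wells flagged `outlier` with an
#'   injected 3x deviation (default 0).
#' @param negative_controls Compound ids with flat 100% response.
#' @param n_controls Solvent-control wells per plate (default 6).
#' @param base_signal Raw instrument units corresponding to 100% of control
#'   (default 1000).
#' @param method_id Test-method id written into the metadata.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed, true_curves, n_plates = 1, n_replicates = 3,
                           series = c(4, 10, 0.5), noise_cv = 0.10,
                           additive_sd = 0, outlier_rate = 0,
                           negative_controls = character(0), n_controls = 6,
                           base_signal = 1000,
                           method_id = "synthetic_method") {
  stopifnot(is.data.frame(true_curves),
            all(c("compound_id", "endpoint_id", "top", "bottom", "log_ec50",
                  "hill", "direction") %in% names(true_curves)))
  if (!is.finite(noise_cv) || noise_cv < 0)
    stop("noise_cv must be >= 0", call. = FALSE)
  if (outlier_rate < 0 || outlier_rate > 1)
    stop("outlier_rate must lie in [0, 1]", call. = FALSE)
  if (anyDuplicated(true_curves[, c("compound_id", "endpoint_id")]))
    stop("duplicate (compound_id, endpoint_id) in true_curves", call. = FALSE)
  structure(list(seed = seed, true_curves = true_curves, n_plates = n_plates,
                 n_replicates = n_replicates, series = series,
                 noise_cv = noise_cv, additive_sd = additive_sd,
                 outlier_rate = outlier_rate,
                 negative_controls = negative_controls,
                 n_controls = n_controls, base_signal = base_signal,
                 method_id = method_id),
            class = "synthetic_spec")
}

.noise_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic plate dataset
#'
#' Lays out solvent controls and treatment wells on each plate, evaluates
#' the true 4PL response of each compound x endpoint at every series
#' concentration, applies the noise model, injects flagged outliers at the
#' declared rate, and attaches a fully populated metadata block. The result
#' passes [validate_dataset()] with zero errors by construction.
#'
#' @param spec A `synthetic_spec`.
#' @return A `plate_dataset`.
#' @export
generate_plate <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  concs <- dilution_series(spec$series[1], spec$series[2], spec$series[3])
  tc <- spec$true_curves
  compounds <- unique(tc$compound_id)
  endpoints <- unique(tc$endpoint_id)
  rows <- list()
  for (p in seq_len(spec$n_plates)) {
    plate_id <- sprintf("P%02d", p)
    rows[[p]] <- .with_seed(.plate_seed(spec$seed, p), {
      # well layout: controls first, then compound x conc x replicate
      layout <- data.frame(
        role = rep("solvent_control", spec$n_controls),
        compound_id = "", conc = NA_real_, replicate = seq_len(spec$n_controls),
        stringsAsFactors = FALSE)
      for (cp in compounds) {
        role <- if (cp %in% spec$negative_controls)
          "negative_control_compound" else "treatment"
        grid <- expand.grid(replicate = seq_len(spec$n_replicates),
                            conc = concs)
        layout <- rbind(layout, data.frame(
          role = role, compound_id = cp, conc = grid$conc,
          replicate = grid$replicate, stringsAsFactors = FALSE))
      }
      layout$well <- .well_name(seq_len(nrow(layout)))
      plate_rows <- list()
      for (ep in endpoints) {
        true_pct <- vapply(seq_len(nrow(layout)), function(i) {
          if (layout$role[i] == "solvent_control") return(100)
          if (layout$compound_id[i] %in% spec$negative_controls) return(100)
          r <- tc[tc$compound_id == layout$compound_id[i] &
                    tc$endpoint_id == ep, ]
          if (nrow(r) == 0) return(NA_real_)
          .curve_predict(layout$conc[i], r$bottom, r$top, r$log_ec50,
                         r$hill, r$direction)
        }, numeric(1))
        keep <- !is.na(true_pct)
        raw <- spec$base_signal * true_pct[keep] / 100 *
          .noise_factor(sum(keep), spec$noise_cv)
        if (spec$additive_sd > 0)
          raw <- raw + stats::rnorm(sum(keep), 0, spec$additive_sd)
        flags <- rep("", sum(keep))
        trt <- layout$role[keep] == "treatment"
        if (spec$outlier_rate > 0 && any(trt)) {
          out <- trt & stats::runif(sum(keep)) < spec$outlier_rate
          raw[out] <- raw[out] * 3
          flags[out] <- "outlier"
        }
        plate_rows[[ep]] <- data.frame(
          plate_id = plate_id, well = layout$well[keep],
          role = layout$role[keep], compound_id = layout$compound_id[keep],
          conc_neglog_molar = layout$conc[keep], endpoint_id = ep,
          raw_value = raw, replicate = layout$replicate[keep],
          flags = flags, timestamp = "", stringsAsFactors = FALSE)
      }
      do.call(rbind, plate_rows)
    })
  }
  measurements <- do.call(rbind, rows)
  metadata <- list(
    test_method_id = spec$method_id, test_method_version = "1.0",
    lab_id = "synthlab", solvent = "DMSO", solvent_final_percent = 0.1,
    exposure_h = 24, method_description_ref = "synthetic://generator",
    compound_batch = "synthetic-batch-1",
    seed_or_run_id = sprintf("seed-%s", spec$seed),
    series_start = spec$series[1], series_end = spec$series[2],
    series_step = spec$series[3])
  plate_dataset(measurements, metadata)
}

#' Generate a multi-method battery with a ground-truth table
#'
#' Runs [generate_plate()] for each spec and assembles a truth table of the
#' design parameters and the true PoD (BMC at the given benchmark response,
#' computed from the true curve in closed form) for every
#' compound x endpoint, for use in recovery experiments. Compounds designed
#' flat (negative controls, or curves whose maximal effect is below the
#' BMR) carry a censored truth entry.
#'
#' @param spec_list List of `synthetic_spec` objects; `method_id`s must be
#'   unique.
#' @param bmr_percent Benchmark response for the truth PoDs (default 25).
#' @return List of class `synthetic_battery`: `datasets` (named by
#'   method_id) and `truth` (data frame with `method_id`, `compound_id`,
#'   `endpoint_id`, `true_log_ec50`, `true_pod_neglog`, `censored`).
#' @export
generate_battery <- function(spec_list, bmr_percent = 25) {
  ids <- vapply(spec_list, function(s) s$method_id, character(1))
  if (anyDuplicated(ids))
    stop(sprintf("method_id collision: %s", ids[duplicated(ids)][1]),
         call. = FALSE)
  datasets <- lapply(spec_list, generate_plate)
  names(datasets) <- ids
  truth <- list()
  for (s in spec_list) {
    tc <- s$true_curves
    rng <- c(s$series[1], s$series[2])
    for (i in seq_len(nrow(tc))) {
      flat <- tc$compound_id[i] %in% s$negative_controls
      if (flat) {
        truth[[length(truth) + 1]] <- data.frame(
          method_id = s$method_id, compound_id = tc$compound_id[i],
          endpoint_id = tc$endpoint_id[i], true_log_ec50 = NA_real_,
          true_pod_neglog = NA_real_, censored = TRUE,
          stringsAsFactors = FALSE)
        next
      }
      cur <- curve_4pl(tc$top[i], tc$bottom[i], tc$log_ec50[i], tc$hill[i],
                       tc$direction[i], conc_range = rng)
      bmc <- derive_bmc(cur, bmr_percent)
      truth[[length(truth) + 1]] <- data.frame(
        method_id = s$method_id, compound_id = tc$compound_id[i],
        endpoint_id = tc$endpoint_id[i], true_log_ec50 = tc$log_ec50[i],
        true_pod_neglog = bmc$bmc_neglog_molar, censored = bmc$censored,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(datasets = datasets, truth = do.call(rbind, truth)),
            class = "synthetic_battery")
}

#' Fit and derive PoDs for one compound/endpoint from a dataset
#'
#' Convenience pipeline used in recovery experiments and by the command-line
#' interface: normalize to solvent controls, drop flagged wells, fit the
#' 4PL and derive the PoD.
#'
#' @param dataset A `plate_dataset`.
#' @param compound_id,endpoint Compound and endpoint to analyze.
#' @param direction Curve direction, see [fit_4pl()].
#' @param bmr_percent Benchmark response (default 25).
#' @param mode PoD mode label, see [derive_pod()].
#' @return A `pod_result`.
#' @export
fit_and_pod <- function(dataset, compound_id, endpoint,
                        direction = "decline", bmr_percent = 25,
                        mode = "viability") {
  normed <- normalize_to_controls(dataset, endpoint)
  m <- normed$measurements
  sel <- m$compound_id == compound_id &
    m$role %in% c("treatment", "negative_control_compound") &
    !has_flag(m$flags, "lab_error") & !has_flag(m$flags, "outlier")
  if (!any(sel))
    stop(sprintf("no usable wells for compound '%s', endpoint '%s'",
                 compound_id, endpoint), call. = FALSE)
  curve <- fit_4pl(m$conc_neglog_molar[sel], m$response_percent[sel],
                   direction = direction, compound_id = compound_id,
                   endpoint_id = endpoint)
  derive_pod(curve, bmr_percent = bmr_percent, mode = mode)
}
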