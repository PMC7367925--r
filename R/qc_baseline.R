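# Baseline-variance statistics of solvent controls. Technical replicates x
# on one plate are normalized to their plate average mu (x_norm = x/mu), and
# the plate-level noise metric is the relative standard deviation
# RSD [%] = SD * 100 / mu, which makes test methods with different raw
# signal scales comparable.

#' Normalize technical replicates to their average
#'
#' @param values Numeric vector of raw replicate values (length >= 2).
#' @return `values / mean(values)`; the normalized values average to 1.
#' @export
normalize_replicates <- function(values) {
  if (length(values) < 2)
    stop("need at least 2 replicates", call. = FALSE)
  if (any(!is.finite(values)))
    stop("values must be finite", call. = FALSE)
  mu <- mean(values)
  if (mu == 0)
    stop("replicate mean is zero; cannot normalize", call. = FALSE)
  values / mu
}

#' Relative standard deviation of technical replicates
#'
#' `SD * 100 / mean`, in percent. The standard deviation uses the sample
#' (n - 1) denominator by default: technical replicates are a sample and n
#' is typically small (3-6), where the choice matters. The RSD is invariant
#' under uniform scaling of the inputs.
#'
#' @param values Numeric vector (length >= 2, positive mean).
#' @param sample_sd Use the n-1 denominator (default `TRUE`); set `FALSE`
#'   for the population (n) denominator.
#' @return RSD in percent.
#' @examples
#' rsd(c(90, 100, 110))   # 10
#' @export
rsd <- function(values, sample_sd = TRUE) {
  if (length(values) < 2)
    stop("need at least 2 replicates", call. = FALSE)
  if (any(!is.finite(values)))
    stop("values must be finite", call. = FALSE)
  mu <- mean(values)
  if (mu <= 0)
    stop("replicate mean must be positive for RSD", call. = FALSE)
  s <- stats::sd(values)
  if (!sample_sd) s <- s * sqrt((length(values) - 1) / length(values))
  s * 100 / mu
}

#' Per-plate baseline variance of solvent controls
#'
#' For each plate carrying the endpoint, takes the solvent-control wells
#' (rows flagged `lab_error` excluded), computes the replicate mean, SD,
#' RSD and the normalized values, and summarizes across plates with the
#' unweighted mean of per-plate RSDs.
#'
#' @param dataset A `plate_dataset`.
#' @param endpoint Endpoint id.
#' @param sample_sd Passed to [rsd()].
#' @return A list of class `baseline_profile`: `per_plate` (data frame with
#'   `plate_id`, `endpoint_id`, `n_replicates`, `mean_raw`, `sd_raw`,
#'   `rsd_percent`), `normalized` (named list of per-plate x_norm vectors)
#'   and `average_rsd` (unweighted mean across plates).
#' @export
plate_baseline_profile <- function(dataset, endpoint, sample_sd = TRUE) {
  stopifnot(inherits(dataset, "plate_dataset"))
  m <- dataset$measurements
  m <- m[m$endpoint_id == endpoint, , drop = FALSE]
  if (nrow(m) == 0)
    stop(sprintf("endpoint '%s' not present in dataset", endpoint),
         call. = FALSE)
  ctrl <- m[m$role == "solvent_control" & !has_flag(m$flags, "lab_error"), ,
            drop = FALSE]
  plates <- sort(unique(ctrl$plate_id))
  rows <- list()
  normalized <- list()
  for (p in plates) {
    v <- ctrl$raw_value[ctrl$plate_id == p]
    v <- v[!is.na(v)]
    if (length(v) < 2) next
    rows[[p]] <- data.frame(
      plate_id = p, endpoint_id = endpoint, n_replicates = length(v),
      mean_raw = mean(v), sd_raw = stats::sd(v),
      rsd_percent = rsd(v, sample_sd = sample_sd),
      stringsAsFactors = FALSE)
    normalized[[p]] <- normalize_replicates(v)
  }
  if (length(rows) == 0)
    stop(sprintf(
      "no plate has >= 2 unflagged solvent-control replicates for '%s'",
      endpoint), call. = FALSE)
  per_plate <- do.call(rbind, unname(rows))
  structure(list(per_plate = per_plate, normalized = normalized,
                 average_rsd = mean(per_plate$rsd_percent)),
            class = "baseline_profile")
}

#' @export
print.baseline_profile <- function(x, ...) {
  cat(sprintf("baseline profile: %d plate(s), average RSD %.2f%%\n",
              nrow(x$per_plate), x$average_rsd))
  print(x$per_plate, row.names = FALSE)
  invisible(x)
}

#' Pooled spread of negative-control compounds
#'
#' For each endpoint, pools the solvent-control-normalized responses of the
#' two lowest tested concentrations of each listed negative-control
#' compound, keeping only concentrations below the per-compound cap (both
#' conditions applied conjunctively). A well-behaved test method keeps these
#' pooled values close to 100% of solvent control, mostly within 80-120%.
#'
#' @param dataset A `plate_dataset` (raw values; normalization to solvent
#'   controls is performed internally via [normalize_to_controls()]).
#' @param neg_compounds Character vector of negative-control compound ids.
#' @param max_conc_map Named numeric vector: per-compound concentration cap
#'   in uM (e.g. `c(clofibrate = 31.6, tolbutamide = 100)`).
#' @param endpoints Endpoints to analyze; default all endpoints in the
#'   dataset.
#' @return A list of class `nc_spread`: per endpoint a list with `values`
#'   (pooled normalized responses, % of solvent control), `mean`, `sd`,
#'   `fraction_within_80_120`; plus `warnings` for compounds that were
#'   absent or tested only above their cap.
#' @export
negative_control_spread <- function(dataset, neg_compounds, max_conc_map,
                                    endpoints = NULL) {
  stopifnot(inherits(dataset, "plate_dataset"))
  m <- dataset$measurements
  if (is.null(endpoints)) endpoints <- sort(unique(m$endpoint_id))
  warnings <- character(0)
  out <- list()
  for (ep in endpoints) {
    normed <- normalize_to_controls(dataset, ep)
    nm <- normed$measurements
    pooled <- numeric(0)
    for (cp in neg_compounds) {
      rows <- nm[nm$compound_id == cp & nm$role %in%
                   c("treatment", "negative_control_compound") &
                   !is.na(nm$conc_neglog_molar) &
                   !has_flag(nm$flags, "lab_error"), , drop = FALSE]
      if (nrow(rows) == 0) {
        warnings <- c(warnings,
                      sprintf("%s: compound '%s' absent, skipped", ep, cp))
        next
      }
      # two lowest concentrations = two largest -log10(M) values
      concs <- sort(unique(rows$conc_neglog_molar), decreasing = TRUE)
      lowest2 <- concs[seq_len(min(2, length(concs)))]
      cap_um <- max_conc_map[[cp]]
      keep <- lowest2
      if (!is.null(cap_um) && !is.na(cap_um))
        keep <- lowest2[neglog_to_conc(lowest2, "uM") < cap_um]
      if (length(keep) == 0) {
        warnings <- c(warnings, sprintf(
          "%s: compound '%s' tested only at/above its %g uM cap, excluded",
          ep, cp, cap_um))
        next
      }
      sel <- rows$conc_neglog_molar %in% keep
      pooled <- c(pooled, rows$response_percent[sel])
    }
    out[[ep]] <- list(
      values = pooled,
      mean = if (length(pooled) > 0) mean(pooled) else NA_real_,
      sd = if (length(pooled) > 1) stats::sd(pooled) else NA_real_,
      fraction_within_80_120 = if (length(pooled) > 0)
        mean(pooled >= 80 & pooled <= 120) else NA_real_)
  }
  structure(list(endpoints = out, warnings = warnings), class = "nc_spread")
}

#' @export
print.nc_spread <- function(x, ...) {
  for (ep in names(x$endpoints)) {
    e <- x$endpoints[[ep]]
    cat(sprintf(
      "%s: n=%d pooled, mean %.1f%%, SD %.1f, %.0f%% within 80-120%%\n",
      ep, length(e$values), e$mean, e$sd, 100 * e$fraction_within_80_120))
  }
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
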