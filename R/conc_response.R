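# Concentration-response analysis: normalization of treatment wells to
# solvent controls, four-parameter log-logistic (4PL) fitting, closed-form
# benchmark-concentration (BMC) inversion, point-of-departure (PoD)
# derivation in -log10(M), and cytotoxicity anchoring of functional hits.
#
# Model, with c the test concentration in -log10(M) and e = log_ec50 the
# half-maximal concentration on the same scale:
#   decline:  y(c) = bottom + (top - bottom) / (1 + 10^( hill * (e - c) ))
#   induce:   y(c) = bottom + (top - bottom) / (1 + 10^( hill * (c - e) ))
# so that a declining endpoint runs from top (low concentration) down to
# bottom, and an inducing endpoint from bottom (baseline) up to top.

#' Normalize plate measurements to solvent controls
#'
#' Per plate: when blank wells are present their mean is subtracted first,
#' then every well's response is expressed as percent of the mean of the
#' plate's unflagged solvent controls. Rows flagged `lab_error` or `outlier`
#' are excluded from the control and blank means but still receive a
#' normalized response (flags are annotations, not deletions).
#'
#' @param dataset A `plate_dataset`.
#' @param endpoint Endpoint id to normalize.
#' @return A `plate_dataset` restricted to `endpoint`, with an added
#'   `response_percent` column.
#' @export
normalize_to_controls <- function(dataset, endpoint) {
  stopifnot(inherits(dataset, "plate_dataset"))
  m <- dataset$measurements
  m <- m[m$endpoint_id == endpoint, , drop = FALSE]
  if (nrow(m) == 0)
    stop(sprintf("endpoint '%s' not present in dataset", endpoint),
         call. = FALSE)
  usable <- !has_flag(m$flags, "lab_error") & !has_flag(m$flags, "outlier") &
    !is.na(m$raw_value)
  m$response_percent <- NA_real_
  for (p in unique(m$plate_id)) {
    on_plate <- m$plate_id == p
    blanks <- m$raw_value[on_plate & usable & m$role == "blank"]
    b <- if (length(blanks) > 0) mean(blanks) else 0
    ctrl <- m$raw_value[on_plate & usable & m$role == "solvent_control"]
    if (any(on_plate & m$role == "treatment") && length(ctrl) == 0)
      stop(sprintf("plate %s has no usable solvent control for '%s'",
                   p, endpoint), call. = FALSE)
    if (length(ctrl) == 0) next
    denom <- mean(ctrl) - b
    if (denom == 0)
      stop(sprintf("plate %s: control mean equals blank mean for '%s'",
                   p, endpoint), call. = FALSE)
    m$response_percent[on_plate] <- 100 * (m$raw_value[on_plate] - b) / denom
  }
  out <- dataset
  out$measurements <- m
  out
}

.default_bounds <- function(direction) {
  if (direction == "decline")
    list(lower = c(bottom = -10, top = 50, hill = 1e-3),
         upper = c(bottom = 50, top = 120, hill = 10))
  else
    list(lower = c(bottom = 50, top = 100, hill = 1e-3),
         upper = c(bottom = 120, top = 1e4, hill = 10))
}

.curve_predict <- function(conc_neglog, bottom, top, log_ec50, hill,
                           direction) {
  s <- if (direction == "decline") 1 else -1
  bottom + (top - bottom) / (1 + 10^(hill * s * (log_ec50 - conc_neglog)))
}

#' Fit a four-parameter log-logistic concentration-response curve
#'
#' Bounded least-squares fit (Levenberg-Marquardt, [minpack.lm::nlsLM()])
#' of response percent against concentration in -log10(M), with multi-start
#' initialization over a grid of EC50 and Hill-slope candidates. Parameter
#' bounds default to bottom in \[-10, 50\]%, top in \[50, 120\]% and hill in
#' (0, 10\] for declining endpoints (baseline in \[50, 120\]% and plateau up
#' to 10000% for inducing endpoints), with log_ec50 constrained to the
#' tested concentration range +/- 1 log unit so that a fitted EC50 can never
#' be an extrapolation artifact far outside the tested series.
#'
#' Points whose flags mark them `lab_error` or `outlier` should be excluded
#' by the caller (e.g. via [normalize_to_controls()] + subsetting); no
#' automatic statistical outlier rejection is applied unless
#' `residual_screen = TRUE`, which drops points with studentized residuals
#' beyond 3 and refits once.
#'
#' `fit_ok` is `FALSE` when the optimizer fails or when the observed
#' response range is smaller than `min_effect` percent (a flat, "no effect"
#' profile): fitting four parameters to noise would be meaningless.
#'
#' @param conc_neglog Concentrations in -log10(M).
#' @param response Responses in percent of solvent control (same length).
#' @param direction `"decline"` (viability-type) or `"induce"`
#'   (reporter-induction-type).
#' @param bounds Optional list with named vectors `lower`/`upper` for
#'   `bottom`, `top`, `hill`.
#' @param min_effect Minimum observed response range (percentage points)
#'   required to attempt a fit; default 10.
#' @param residual_screen Enable the optional |studentized residual| > 3
#'   screen (default `FALSE`).
#' @param compound_id,endpoint_id Optional identifiers carried into the
#'   curve object (used by [assemble_pod_matrix()]).
#' @return An object of class `curve4pl` with elements `top`, `bottom`,
#'   `log_ec50`, `hill`, `direction`, `fit_ok`, `visual_check`
#'   (initially `"pending"`) and `diagnostics` (residual SD, n_points,
#'   tested range, convergence note).
#' @export
fit_4pl <- function(conc_neglog, response, direction = c("decline", "induce"),
                    bounds = NULL, min_effect = 10, residual_screen = FALSE,
                    compound_id = NA_character_, endpoint_id = NA_character_) {
  direction <- match.arg(direction)
  ok <- is.finite(conc_neglog) & is.finite(response)
  conc_neglog <- conc_neglog[ok]
  response <- response[ok]
  n_conc <- length(unique(conc_neglog))
  if (n_conc < 4)
    stop(sprintf("need >= 4 distinct concentrations, got %d", n_conc),
         call. = FALSE)
  rng <- range(conc_neglog)
  blank_curve <- function(note) {
    structure(list(
      top = mean(response), bottom = mean(response), log_ec50 = NA_real_,
      hill = NA_real_, direction = direction, fit_ok = FALSE,
      compound_id = compound_id, endpoint_id = endpoint_id,
      visual_check = "pending",
      diagnostics = list(residual_sd = stats::sd(response),
                         n_points = length(response),
                         conc_range = rng, note = note,
                         provenance = list())),
      class = "curve4pl")
  }
  # per-concentration means define the observed effect range
  mu_by_conc <- tapply(response, conc_neglog, mean)
  if (diff(range(mu_by_conc)) < min_effect)
    return(blank_curve("no effect"))

  b <- bounds %||% .default_bounds(direction)
  lower <- c(b$lower[["bottom"]], b$lower[["top"]], rng[1] - 1,
             b$lower[["hill"]])
  upper <- c(b$upper[["bottom"]], b$upper[["top"]], rng[2] + 1,
             b$upper[["hill"]])
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

  df <- data.frame(c = conc_neglog, y = response)
  fits <- list()
  e_starts <- unique(clamp(
    stats::quantile(conc_neglog, c(0.25, 0.5, 0.75), names = FALSE),
    lower[3], upper[3]))
  h_starts <- c(0.5, 1, 2)
  bot0 <- clamp(min(mu_by_conc), lower[1], upper[1])
  top0 <- clamp(max(mu_by_conc), lower[2], upper[2])
  for (e0 in e_starts) for (h0 in h_starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ .curve_predict(c, bottom, top, log_ec50, hill, direction),
        data = df,
        start = list(bottom = bot0, top = top0, log_ec50 = e0, hill = h0),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                             ptol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit)) fits[[length(fits) + 1]] <- fit
  }
  if (length(fits) == 0)
    return(blank_curve("no convergence"))
  rss <- vapply(fits, function(f) sum(stats::residuals(f)^2), numeric(1))
  best <- fits[[which.min(rss)]]

  if (residual_screen) {
    r <- stats::residuals(best)
    sr <- r / stats::sd(r)
    keep <- abs(sr) <= 3
    if (any(!keep) && sum(keep) >= 4 &&
        length(unique(conc_neglog[keep])) >= 4) {
      return(fit_4pl(conc_neglog[keep], response[keep], direction, bounds,
                     min_effect, residual_screen = FALSE,
                     compound_id = compound_id, endpoint_id = endpoint_id))
    }
  }

  p <- stats::coef(best)
  structure(list(
    top = unname(p["top"]), bottom = unname(p["bottom"]),
    log_ec50 = unname(p["log_ec50"]), hill = unname(p["hill"]),
    direction = direction, fit_ok = TRUE,
    compound_id = compound_id, endpoint_id = endpoint_id,
    visual_check = "pending",
    diagnostics = list(
      residual_sd = stats::sd(stats::residuals(best)),
      n_points = nrow(df), conc_range = rng, note = "converged",
      provenance = list())),
    class = "curve4pl")
}

#' Construct a 4PL curve from known parameters
#'
#' Builds a `curve4pl` object directly from parameter values, without
#' fitting -- used for ground-truth curves in simulations and for deriving
#' BMC/PoD from externally fitted parameters.
#'
#' @param top,bottom Upper/lower asymptote, percent of control.
#' @param log_ec50 Half-maximal concentration, -log10(M).
#' @param hill Hill slope (> 0).
#' @param direction `"decline"` or `"induce"`.
#' @param conc_range Tested concentration range in -log10(M),
#'   `c(min, max)`; used for censoring bounds.
#' @param compound_id,endpoint_id Optional identifiers.
#' @return A `curve4pl` with `fit_ok = TRUE`.
#' @export
curve_4pl <- function(top, bottom, log_ec50, hill,
                      direction = c("decline", "induce"),
                      conc_range = c(4, 10),
                      compound_id = NA_character_,
                      endpoint_id = NA_character_) {
  direction <- match.arg(direction)
  if (!is.finite(hill) || hill <= 0)
    stop("hill must be > 0", call. = FALSE)
  if (top < bottom)
    stop("top must be >= bottom", call. = FALSE)
  structure(list(
    top = top, bottom = bottom, log_ec50 = log_ec50, hill = hill,
    direction = direction, fit_ok = TRUE,
    compound_id = compound_id, endpoint_id = endpoint_id,
    visual_check = "pending",
    diagnostics = list(residual_sd = NA_real_, n_points = 0L,
                       conc_range = sort(conc_range), note = "constructed",
                       provenance = list())),
    class = "curve4pl")
}

#' @export
print.curve4pl <- function(x, ...) {
  if (!x$fit_ok) {
    cat(sprintf("<curve4pl> fit_ok=FALSE (%s)\n", x$diagnostics$note))
    return(invisible(x))
  }
  cat(sprintf(
    "<curve4pl %s> top %.1f%%  bottom %.1f%%  log EC50 %.3f (-log10 M)  hill %.2f\n",
    x$direction, x$top, x$bottom, x$log_ec50, x$hill))
  cat(sprintf("  visual check: %s; residual SD %.2f on %d points\n",
              x$visual_check, x$diagnostics$residual_sd,
              x$diagnostics$n_points))
  invisible(x)
}

#' Predict responses from a fitted curve
#'
#' @param object A `curve4pl`.
#' @param conc_neglog Concentrations in -log10(M).
#' @param ... Unused.
#' @return Predicted responses in percent of control.
#' @export
predict.curve4pl <- function(object, conc_neglog, ...) {
  stopifnot(object$fit_ok)
  .curve_predict(conc_neglog, object$bottom, object$top, object$log_ec50,
                 object$hill, object$direction)
}

#' Record the outcome of the visual curve check
#'
#' Every fitted curve carries a visual-check flag (`pending`, `passed`,
#' `failed`); summary exports such as [assemble_pod_matrix()] can be set to
#' refuse curves still pending, enforcing the expert-inspection step of the
#' data-processing workflow.
#'
#' @param curve A `curve4pl`.
#' @param status `"passed"` or `"failed"`.
#' @return The curve with its flag updated.
#' @export
set_visual_check <- function(curve, status = c("passed", "failed")) {
  status <- match.arg(status)
  curve$visual_check <- status
  curve
}

#' Derive a benchmark concentration from a fitted curve
#'
#' Closed-form inversion of the 4PL at the benchmark response: target
#' response is `100 - bmr` percent of control for declining endpoints and
#' `100 + bmr` for inducing ones. When the fitted asymptote never reaches
#' the target (maximal effect smaller than the BMR), the BMC is censored at
#' the highest tested concentration: "no effect observed" up to that bound.
#'
#' @param curve A `curve4pl` with `fit_ok = TRUE`, or a flat/no-effect curve
#'   (which yields a censored result directly).
#' @param bmr_percent Benchmark response in percent change from control
#'   (0 < bmr < 100 for declining endpoints).
#' @return A list of class `bmc_result`: `bmr_percent`, `bmc_neglog_molar`
#'   (NA when censored), `censored`, `censor_bound` (the -log10(M) of the
#'   highest tested concentration when censored) and `note`.
#' @examples
#' # top=100, bottom=0, hill=1, EC50 = 1 uM: BMC at bmr=50 is the EC50
#' @export
derive_bmc <- function(curve, bmr_percent) {
  stopifnot(inherits(curve, "curve4pl"))
  if (!is.finite(bmr_percent) || bmr_percent <= 0 || bmr_percent >= 100)
    stop("bmr_percent must lie in (0, 100)", call. = FALSE)
  censor_bound <- curve$diagnostics$conc_range[1]  # highest tested conc
  censored <- function(note) {
    structure(list(bmr_percent = bmr_percent, bmc_neglog_molar = NA_real_,
                   censored = TRUE, censor_bound = censor_bound, note = note),
              class = "bmc_result")
  }
  if (!curve$fit_ok) {
    if (identical(curve$diagnostics$note, "no effect"))
      return(censored("no effect observed"))
    stop("curve did not fit (fit_ok = FALSE); cannot derive a BMC",
         call. = FALSE)
  }
  if (curve$direction == "decline") {
    y0 <- 100 - bmr_percent
    if (curve$bottom >= y0)
      return(censored(sprintf(
        "maximal fitted decline %.1f%% below BMR %.1f%%",
        100 - curve$bottom, bmr_percent)))
    if (curve$top <= y0)
      return(structure(list(
        bmr_percent = bmr_percent, bmc_neglog_molar = NA_real_,
        censored = FALSE, censor_bound = NA_real_,
        note = "response exceeds BMR at all concentrations (top below target)"),
        class = "bmc_result"))
    bmc <- curve$log_ec50 -
      log10((curve$top - y0) / (y0 - curve$bottom)) / curve$hill
  } else {
    y0 <- 100 + bmr_percent
    if (curve$top <= y0)
      return(censored(sprintf(
        "maximal fitted induction %.1f%% below BMR %.1f%%",
        curve$top - 100, bmr_percent)))
    if (curve$bottom >= y0)
      return(structure(list(
        bmr_percent = bmr_percent, bmc_neglog_molar = NA_real_,
        censored = FALSE, censor_bound = NA_real_,
        note = "response exceeds BMR at all concentrations (baseline above target)"),
        class = "bmc_result"))
    bmc <- curve$log_ec50 +
      log10((curve$top - y0) / (y0 - curve$bottom)) / curve$hill
  }
  structure(list(bmr_percent = bmr_percent, bmc_neglog_molar = bmc,
                 censored = FALSE, censor_bound = NA_real_, note = "ok"),
            class = "bmc_result")
}

#' Derive a point of departure in -log10(M)
#'
#' The PoD is the BMC at the policy's benchmark response, expressed in the
#' unified -log10(M) convention; a BMC of 1 uM is a PoD of 6.0. Censoring
#' propagates: a no-effect curve yields a censored PoD ("no effect
#' observed" up to the highest tested concentration). The BMR in force is
#' recorded in the result (provenance).
#'
#' @param curve A `curve4pl` (fit_ok may be `FALSE` for no-effect curves).
#' @param bmr_percent Benchmark response; default 25 (percent change from
#'   control).
#' @param mode Endpoint mode label: `"viability"`, `"functional_agonist"`
#'   or `"functional_antagonist"`.
#' @return A list of class `pod_result`: `compound_id`, `endpoint_id`,
#'   `mode`, `pod_neglog_molar` (NA when censored), `censored`,
#'   `censor_bound`, `bmr_percent`, `source_curve`.
#' @export
derive_pod <- function(curve, bmr_percent = 25,
                       mode = c("viability", "functional_agonist",
                                "functional_antagonist")) {
  mode <- match.arg(mode)
  bmc <- derive_bmc(curve, bmr_percent)
  structure(list(
    compound_id = curve$compound_id, endpoint_id = curve$endpoint_id,
    mode = mode, pod_neglog_molar = bmc$bmc_neglog_molar,
    censored = bmc$censored, censor_bound = bmc$censor_bound,
    bmr_percent = bmr_percent, source_curve = curve),
    class = "pod_result")
}

#' @export
print.pod_result <- function(x, ...) {
  lab <- if (x$censored)
    sprintf("no effect observed (up to %.1f -log10 M)", x$censor_bound)
  else sprintf("%.2f -log10(M) (%s)", x$pod_neglog_molar,
               format_conc(neglog_to_conc(x$pod_neglog_molar, "uM")))
  cat(sprintf("<pod %s/%s %s> %s at BMR %g%%\n", x$compound_id,
              x$endpoint_id, x$mode, lab, x$bmr_percent))
  invisible(x)
}

#' Anchor a functional PoD to the cytotoxicity PoD
#'
#' Compares a functional endpoint's PoD with the viability PoD of the same
#' system. The specificity ratio is the fold-difference in concentration,
#' `10^(functional_pod - viability_pod)` (both in -log10(M)): functional
#' activity 10-100x below the cytotoxic concentration indicates a specific
#' pathway effect rather than an indirect consequence of dying cells.
#'
#' Classes (configurable cut-offs): `specific` when the ratio is at least
#' `specific_fold` (default 10), `borderline` in \[`borderline_fold`,
#' `specific_fold`) (default \[3, 10)), `cytotoxicity_confounded` below
#' that. A censored functional PoD gives `undetermined`; when only the
#' viability PoD is censored the ratio is a lower bound and the class is
#' `specific`.
#'
#' @param functional_pod,viability_pod `pod_result` objects for the same
#'   compound/test family.
#' @param specific_fold,borderline_fold Class cut-offs on the fold ratio.
#' @return A list: `specificity_ratio`, `ratio_is_lower_bound`, `class`.
#' @export
cytotox_anchor <- function(functional_pod, viability_pod,
                           specific_fold = 10, borderline_fold = 3) {
  stopifnot(inherits(functional_pod, "pod_result"),
            inherits(viability_pod, "pod_result"))
  if (functional_pod$censored)
    return(list(specificity_ratio = NA_real_, ratio_is_lower_bound = FALSE,
                class = "undetermined"))
  if (viability_pod$censored) {
    # no cytotoxicity up to the highest tested concentration: the true
    # ratio is at least the ratio against that bound
    ratio <- 10^(functional_pod$pod_neglog_molar - viability_pod$censor_bound)
    return(list(specificity_ratio = ratio, ratio_is_lower_bound = TRUE,
                class = "specific"))
  }
  ratio <- 10^(functional_pod$pod_neglog_molar -
                 viability_pod$pod_neglog_molar)
  cls <- if (ratio >= specific_fold) "specific"
  else if (ratio >= borderline_fold) "borderline"
  else "cytotoxicity_confounded"
  list(specificity_ratio = ratio, ratio_is_lower_bound = FALSE, class = cls)
}

#' EC50 of a reference-agonist curve for antagonist-mode co-treatment
#'
#' In antagonist mode the reference agonist is co-applied at its EC50; this
#' accessor returns the fitted EC50 of the agonist curve as that
#' co-treatment concentration, in -log10(M).
#'
#' @param curve A fitted `curve4pl`.
#' @return The `log_ec50` in -log10(M).
#' @export
reference_ec50 <- function(curve) {
  stopifnot(inherits(curve, "curve4pl"))
  if (!curve$fit_ok || !is.finite(curve$log_ec50))
    stop("curve has no EC50 (flat or failed fit)", call. = FALSE)
  curve$log_ec50
}

#' Assemble a compound x endpoint PoD matrix
#'
#' Rectangular character matrix of PoDs in -log10(M), with censored cells
#' rendered as `"no effect"`; rows (compounds) and columns (endpoints)
#' sorted alphabetically so output is deterministic.
#'
#' @param pod_results List of `pod_result` objects.
#' @param digits Significant digits for the PoD values (default 3).
#' @param require_visual_check Refuse curves whose visual check is still
#'   `"pending"` (default `FALSE`).
#' @return Character matrix (compounds x endpoints); combinations never
#'   measured are `NA`.
#' @export
assemble_pod_matrix <- function(pod_results, digits = 3,
                                require_visual_check = FALSE) {
  if (length(pod_results) == 0)
    return(matrix(character(0), nrow = 0, ncol = 0))
  cps <- vapply(pod_results, function(p) p$compound_id, character(1))
  eps <- vapply(pod_results, function(p) p$endpoint_id, character(1))
  if (any(is.na(cps)) || any(is.na(eps)))
    stop("every PoD needs compound_id and endpoint_id", call. = FALSE)
  key <- paste(cps, eps, sep = "\r")
  if (anyDuplicated(key))
    stop(sprintf("duplicate (compound, endpoint) entries: %s",
                 gsub("\r", "/", key[duplicated(key)][1], fixed = TRUE)),
         call. = FALSE)
  if (require_visual_check) {
    pending <- vapply(pod_results, function(p)
      identical(p$source_curve$visual_check, "pending"), logical(1))
    if (any(pending))
      stop(sprintf("%d curve(s) still pending visual check", sum(pending)),
           call. = FALSE)
  }
  rows <- sort(unique(cps))
  cols <- sort(unique(eps))
  mat <- matrix(NA_character_, nrow = length(rows), ncol = length(cols),
                dimnames = list(rows, cols))
  for (p in pod_results) {
    mat[p$compound_id, p$endpoint_id] <- if (p$censored) "no effect"
    else as.character(signif(p$pod_neglog_molar, digits))
  }
  mat
}

#' Write a PoD matrix to CSV
#'
#' @param mat Matrix from [assemble_pod_matrix()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_pod_matrix <- function(mat, path) {
  df <- data.frame(compound_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
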