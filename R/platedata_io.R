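# Unified plate-level data format: long-format CSV (one row per
# well x endpoint) preceded by a "#"-prefixed metadata header block parsed as
# "key: value". Flags are additive annotations kept in the file verbatim;
# flagged values are excluded only at computation time, never dropped on
# write. The dialect uses "." as the only decimal separator -- a comma inside
# a numeric field is a validation error, not something to auto-coerce, and
# spreadsheet date artifacts ("Jun-05") are detected rather than silently
# parsed to NA.

.FORMAT_TAG <- "navitro-plate-format"
.FORMAT_VERSION <- "1.0"
.WELL_ROLES <- c("treatment", "solvent_control", "positive_control",
                 "negative_control_compound", "blank")
.FLAG_TOKENS <- c("lab_error", "outlier", "below_detection")
.MEASUREMENT_COLS <- c("plate_id", "well", "role", "compound_id",
                       "conc_neglog_molar", "endpoint_id", "raw_value",
                       "replicate", "flags", "timestamp")
.MANDATORY_META <- c("test_method_id", "lab_id", "solvent", "exposure_h")
.META_ORDER <- c("test_method_id", "test_method_version", "lab_id", "solvent",
                 "solvent_final_percent", "exposure_h",
                 "method_description_ref", "compound_batch", "seed_or_run_id",
                 "series_start", "series_end", "series_step")

.NUMERIC_RE <- "^-?[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?$"

#' Construct a plate dataset
#'
#' Couples well-level measurements to the metadata block that makes them
#' interpretable (test method, laboratory, solvent, exposure time, ...).
#' Measurements are a long-format data frame, one row per well x endpoint.
#'
#' @param measurements Data frame with columns `plate_id`, `well`, `role`,
#'   `compound_id`, `conc_neglog_molar`, `endpoint_id`, `raw_value`,
#'   `replicate`, `flags` (tokens separated by `|`, may be empty) and
#'   optionally `timestamp`.
#' @param metadata Named list; `test_method_id`, `lab_id`, `solvent` and
#'   `exposure_h` are mandatory.
#' @return An object of class `plate_dataset`.
#' @export
plate_dataset <- function(measurements, metadata) {
  measurements <- as.data.frame(measurements, stringsAsFactors = FALSE)
  if (!"timestamp" %in% names(measurements))
    measurements$timestamp <- ""
  if (!"flags" %in% names(measurements))
    measurements$flags <- ""
  missing_cols <- setdiff(.MEASUREMENT_COLS, names(measurements))
  if (length(missing_cols) > 0)
    stop(sprintf("measurements missing columns: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  measurements <- measurements[, .MEASUREMENT_COLS]
  missing_meta <- setdiff(.MANDATORY_META, names(metadata))
  if (length(missing_meta) > 0)
    stop(sprintf("metadata missing mandatory key(s): %s",
                 paste(missing_meta, collapse = ", ")), call. = FALSE)
  bad_role <- !measurements$role %in% .WELL_ROLES
  if (any(bad_role))
    stop(sprintf("unknown role(s): %s",
                 paste(unique(measurements$role[bad_role]), collapse = ", ")),
         call. = FALSE)
  structure(list(measurements = measurements, metadata = metadata),
            class = "plate_dataset")
}

#' @export
print.plate_dataset <- function(x, ...) {
  m <- x$measurements
  cat(sprintf("<plate_dataset> %d wells, %d plate(s), %d endpoint(s)\n",
              nrow(m), length(unique(m$plate_id)),
              length(unique(m$endpoint_id))))
  cat(sprintf("  method %s, lab %s, %s h exposure\n",
              x$metadata$test_method_id, x$metadata$lab_id,
              x$metadata$exposure_h))
  invisible(x)
}

#' Split and join flag tokens
#'
#' Flags are stored as `|`-separated tokens from the closed set
#' `lab_error`, `outlier`, `below_detection`.
#'
#' @param flags Character vector of flag strings (as stored in the file).
#' @return `parse_flags()`: list of character vectors. `has_flag()`: logical.
#' @param token Single flag token to test for.
#' @export
parse_flags <- function(flags) {
  lapply(flags, function(f) {
    if (is.na(f) || f == "") character(0) else strsplit(f, "|", fixed = TRUE)[[1]]
  })
}

#' @rdname parse_flags
#' @export
has_flag <- function(flags, token) {
  vapply(parse_flags(flags), function(f) token %in% f, logical(1))
}

#' Read a plate dataset file
#'
#' Parses the `#`-prefixed metadata header and the long-format CSV body.
#' The first line must declare the dialect
#' (`# navitro-plate-format: 1.0`). Numeric fields are parsed strictly:
#' malformed cells (locale commas, spreadsheet date artifacts) are recorded
#' as structured parse issues carried on the returned object (attribute
#' `parse_issues`) and reported by [validate_dataset()] -- never silently
#' coerced. A missing mandatory metadata key is an immediate error naming
#' the key.
#'
#' @param path Path to a plate-data file written by [write_dataset()].
#' @return A `plate_dataset`.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- grepl("^#", lines)
  # header block must be a prefix of the file
  n_hdr <- if (any(!hdr)) which(!hdr)[1] - 1 else length(lines)
  header <- lines[seq_len(n_hdr)]
  if (n_hdr == 0 ||
      !grepl(sprintf("^#\\s*%s:\\s*%s\\s*$", .FORMAT_TAG, .FORMAT_VERSION),
             header[1]))
    stop(sprintf("not a %s %s file: %s", .FORMAT_TAG, .FORMAT_VERSION, path),
         call. = FALSE)
  metadata <- list()
  for (ln in header[-1]) {
    kv <- sub("^#\\s*", "", ln)
    pos <- regexpr(":", kv, fixed = TRUE)
    if (pos < 0) next
    key <- trimws(substr(kv, 1, pos - 1))
    val <- trimws(substr(kv, pos + 1, nchar(kv)))
    metadata[[key]] <- val
  }
  missing_meta <- setdiff(.MANDATORY_META, names(metadata))
  if (length(missing_meta) > 0)
    stop(sprintf("metadata missing mandatory key(s): %s",
                 paste(missing_meta, collapse = ", ")), call. = FALSE)
  for (key in c("solvent_final_percent", "exposure_h",
                "series_start", "series_end", "series_step")) {
    if (!is.null(metadata[[key]]) && grepl(.NUMERIC_RE, metadata[[key]]))
      metadata[[key]] <- as.numeric(metadata[[key]])
  }
  body <- lines[!hdr]
  con <- textConnection(body)
  on.exit(close(con))
  raw <- utils::read.csv(con, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing_cols <- setdiff(.MEASUREMENT_COLS, names(raw))
  if (length(missing_cols) > 0)
    stop(sprintf("plate file missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  raw <- raw[, .MEASUREMENT_COLS]

  issues <- list()
  note_issue <- function(row, col, value, code) {
    issues[[length(issues) + 1]] <<- data.frame(
      row = row, column = col, value = value, code = code,
      stringsAsFactors = FALSE)
  }
  parse_num <- function(col, allow_empty) {
    x <- raw[[col]]
    out <- rep(NA_real_, length(x))
    for (i in seq_along(x)) {
      v <- trimws(x[i])
      if (v == "" || is.na(v)) {
        if (!allow_empty) note_issue(i, col, v, "MISSING_VALUE")
      } else if (grepl(.NUMERIC_RE, v)) {
        out[i] <- as.numeric(v)
      } else if (grepl("^[0-9]{1,2}-[A-Za-z]{3}$|^[A-Za-z]{3}-[0-9]{1,2}$", v)) {
        note_issue(i, col, v, "SPREADSHEET_DATE_ARTIFACT")
      } else if (grepl(",", v, fixed = TRUE)) {
        note_issue(i, col, v, "LOCALE_COMMA")
      } else {
        note_issue(i, col, v, "MALFORMED_NUMERIC")
      }
    }
    out
  }
  conc <- parse_num("conc_neglog_molar", allow_empty = TRUE)
  rawv <- parse_num("raw_value", allow_empty = FALSE)
  repl <- parse_num("replicate", allow_empty = FALSE)

  meas <- data.frame(
    plate_id = raw$plate_id, well = raw$well, role = raw$role,
    compound_id = raw$compound_id, conc_neglog_molar = conc,
    endpoint_id = raw$endpoint_id, raw_value = rawv,
    replicate = as.integer(round(repl)), flags = raw$flags,
    timestamp = raw$timestamp, stringsAsFactors = FALSE)
  ds <- plate_dataset(meas, metadata)
  attr(ds, "parse_issues") <- if (length(issues) > 0)
    do.call(rbind, issues)
  else
    data.frame(row = integer(0), column = character(0),
               value = character(0), code = character(0),
               stringsAsFactors = FALSE)
  ds
}

.format_num <- function(x) {
  ifelse(is.na(x), "", vapply(x, function(v) sprintf("%.15g", v), character(1)))
}

#' Write a plate dataset file
#'
#' Deterministic output: fixed metadata-key order, fixed column order, fixed
#' numeric formatting (15 significant digits), so two writes of the same
#' dataset are byte-identical and flags round-trip verbatim.
#'
#' @param dataset A `plate_dataset`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "plate_dataset"))
  md <- dataset$metadata
  keys <- c(intersect(.META_ORDER, names(md)),
            sort(setdiff(names(md), .META_ORDER)))
  hdr <- c(sprintf("# %s: %s", .FORMAT_TAG, .FORMAT_VERSION),
           vapply(keys, function(k) sprintf("# %s: %s", k, md[[k]]),
                  character(1)))
  m <- dataset$measurements
  body_df <- data.frame(
    plate_id = m$plate_id, well = m$well, role = m$role,
    compound_id = m$compound_id,
    conc_neglog_molar = .format_num(m$conc_neglog_molar),
    endpoint_id = m$endpoint_id, raw_value = .format_num(m$raw_value),
    replicate = ifelse(is.na(m$replicate), "", as.character(m$replicate)),
    flags = ifelse(is.na(m$flags), "", m$flags),
    timestamp = ifelse(is.na(m$timestamp), "", m$timestamp),
    stringsAsFactors = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  rows <- c(paste(.MEASUREMENT_COLS, collapse = ","),
            do.call(paste, c(unname(as.list(body_df)), sep = ",")))
  writeLines(rows, con)
  invisible(path)
}

# ---- validation ------------------------------------------------------------

.report_row <- function(severity, code, location, message) {
  data.frame(severity = severity, code = code, location = location,
             message = message, stringsAsFactors = FALSE)
}

#' Validate a plate dataset
#'
#' Automated format validation covering the error modes that plague
#' spreadsheet-era data handling. Checks, at minimum: numeric cells corrupted
#' into spreadsheet dates (`SPREADSHEET_DATE_ARTIFACT`) or containing locale
#' commas (`LOCALE_COMMA`); unresolvable compound ids against the registry
#' (`UNRESOLVED_COMPOUND`); treatment wells present on a plate without any
#' solvent-control well for the same endpoint (`MISSING_CONTROL_LINK`);
#' duplicate (plate, well, endpoint) coordinates (`DUPLICATE_WELL`);
#' concentrations outside the declared dilution series
#' (`CONC_OUT_OF_SERIES`); treatment rows lacking compound or concentration
#' (`TREATMENT_INCOMPLETE`); malformed well coordinates (`BAD_WELL`); and
#' unknown flag tokens (`UNKNOWN_FLAG`). A non-standard DMSO working
#' concentration (anything other than 0.1%) is reported as a note
#' (`NONSTANDARD_DMSO_PERCENT`). The validator is pure: repeated calls give
#' the same report.
#'
#' @param dataset A `plate_dataset`.
#' @param registry Optional `navitro_registry` used to resolve compound ids.
#' @param declared_series Optional numeric vector of -log10(M) values the
#'   concentrations must belong to; defaults to the series described by the
#'   metadata keys `series_start`/`series_end`/`series_step` when present.
#' @return A data frame of class `validation_report` with columns `severity`
#'   (`error`/`warning`/`note`), `code`, `location`, `message`.
#' @export
validate_dataset <- function(dataset, registry = NULL, declared_series = NULL) {
  stopifnot(inherits(dataset, "plate_dataset"))
  m <- dataset$measurements
  md <- dataset$metadata
  rep_rows <- list()
  add <- function(...) rep_rows[[length(rep_rows) + 1]] <<- .report_row(...)

  pi <- attr(dataset, "parse_issues")
  if (!is.null(pi) && nrow(pi) > 0) {
    for (i in seq_len(nrow(pi)))
      add("error", pi$code[i], sprintf("row %d, %s", pi$row[i], pi$column[i]),
          sprintf("cell value '%s' is not a valid number", pi$value[i]))
  }

  bad_well <- !grepl("^[A-P][0-9]{1,2}$", m$well) |
    suppressWarnings(as.integer(sub("^[A-P]", "", m$well))) < 1 |
    suppressWarnings(as.integer(sub("^[A-P]", "", m$well))) > 24
  for (i in which(bad_well))
    add("error", "BAD_WELL", sprintf("row %d", i),
        sprintf("well coordinate '%s' is not letter-row + 1-based column (A1..P24)",
                m$well[i]))

  key <- paste(m$plate_id, m$well, m$endpoint_id, sep = "\r")
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  for (k in unique(key[dup])) {
    rows <- which(key == k)
    add("error", "DUPLICATE_WELL", sprintf("rows %s", paste(rows, collapse = ",")),
        sprintf("duplicate (plate, well, endpoint): %s",
                gsub("\r", "/", k, fixed = TRUE)))
  }

  trt <- m$role == "treatment"
  incomplete <- trt & (is.na(m$conc_neglog_molar) | m$compound_id == "" |
                         is.na(m$compound_id))
  for (i in which(incomplete))
    add("error", "TREATMENT_INCOMPLETE", sprintf("row %d", i),
        "treatment well lacks compound_id or concentration")

  # every plate x endpoint with treatments needs >= 1 solvent control
  pe <- unique(m[trt, c("plate_id", "endpoint_id")])
  if (nrow(pe) > 0) {
    for (i in seq_len(nrow(pe))) {
      has_ctrl <- any(m$role == "solvent_control" &
                        m$plate_id == pe$plate_id[i] &
                        m$endpoint_id == pe$endpoint_id[i])
      if (!has_ctrl)
        add("error", "MISSING_CONTROL_LINK",
            sprintf("plate %s, endpoint %s", pe$plate_id[i], pe$endpoint_id[i]),
            "treatment wells without any solvent_control well on the plate")
    }
  }

  if (!is.null(registry)) {
    ids <- unique(m$compound_id[m$compound_id != "" & !is.na(m$compound_id)])
    unresolved <- setdiff(ids, registry$compound_id)
    for (id in unresolved)
      add("error", "UNRESOLVED_COMPOUND", sprintf("compound_id %s", id),
          "compound_id does not resolve against the registry")
  }

  if (is.null(declared_series) &&
      all(c("series_start", "series_end", "series_step") %in% names(md)) &&
      is.numeric(md$series_start) && is.numeric(md$series_end) &&
      is.numeric(md$series_step))
    declared_series <- dilution_series(md$series_start, md$series_end,
                                       md$series_step)
  if (!is.null(declared_series)) {
    conc <- m$conc_neglog_molar
    off <- !is.na(conc) &
      vapply(conc, function(c) min(abs(c - declared_series)) > 1e-6, logical(1))
    for (i in which(off))
      add("error", "CONC_OUT_OF_SERIES", sprintf("row %d", i),
          sprintf("concentration %.4g -log10(M) is not in the declared series",
                  conc[i]))
  }

  all_flags <- unique(unlist(parse_flags(m$flags)))
  for (f in setdiff(all_flags, .FLAG_TOKENS))
    add("error", "UNKNOWN_FLAG", "flags column",
        sprintf("unknown flag token '%s'", f))

  if (identical(md$solvent, "DMSO") &&
      !is.null(md$solvent_final_percent) &&
      is.numeric(md$solvent_final_percent) &&
      md$solvent_final_percent <= 1 &&
      md$solvent_final_percent != 0.1)
    add("note", "NONSTANDARD_DMSO_PERCENT", "metadata",
        sprintf("final DMSO %.3g%% differs from the 0.1%% convention",
                md$solvent_final_percent))

  report <- if (length(rep_rows) > 0) do.call(rbind, rep_rows) else
    .report_row(character(0), character(0), character(0), character(0))
  class(report) <- c("validation_report", "data.frame")
  report
}

#' Cross-dataset metadata checks
#'
#' Detects copy-pasted metadata blocks: datasets whose metadata are identical
#' in every field except the run identifier, while the run identifiers
#' differ, are reported with a warning (`COPY_PASTED_METADATA`) -- the
#' typical signature of a metadata block pasted between experiments without
#' adaptation.
#'
#' @param datasets List of `plate_dataset` objects.
#' @param registry,declared_series Passed to [validate_dataset()] for each
#'   dataset.
#' @return A `validation_report` covering all datasets.
#' @export
validate_datasets <- function(datasets, registry = NULL,
                              declared_series = NULL) {
  reports <- lapply(seq_along(datasets), function(i) {
    r <- validate_dataset(datasets[[i]], registry, declared_series)
    if (nrow(r) > 0) r$location <- sprintf("dataset %d: %s", i, r$location)
    r
  })
  rep_rows <- do.call(rbind, reports)
  strip_run <- function(md) {
    md$seed_or_run_id <- NULL
    md[order(names(md))]
  }
  sigs <- vapply(datasets, function(d)
    paste(deparse(strip_run(d$metadata)), collapse = ""), character(1))
  runs <- vapply(datasets, function(d)
    as.character(d$metadata$seed_or_run_id %||% ""), character(1))
  for (s in unique(sigs[duplicated(sigs)])) {
    idx <- which(sigs == s)
    if (length(unique(runs[idx])) > 1)
      rep_rows <- rbind(rep_rows, .report_row(
        "warning", "COPY_PASTED_METADATA",
        sprintf("datasets %s", paste(idx, collapse = ",")),
        "identical metadata blocks across distinct run ids"))
  }
  class(rep_rows) <- c("validation_report", "data.frame")
  rep_rows
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Does a validation report mark the dataset conformant?
#'
#' @param report A `validation_report`.
#' @return `TRUE` when the report contains no `error`-severity entries.
#' @export
is_conformant <- function(report) {
  !any(report$severity == "error")
}

#' @export
print.validation_report <- function(x, ...) {
  if (nrow(x) == 0) {
    cat("validation report: clean (no findings)\n")
    return(invisible(x))
  }
  n <- table(factor(x$severity, levels = c("error", "warning", "note")))
  cat(sprintf("validation report: %d error(s), %d warning(s), %d note(s)\n",
              n[["error"]], n[["warning"]], n[["note"]]))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  [%s] %s @ %s: %s\n", x$severity[i], x$code[i],
                x$location[i], x$message[i]))
  invisible(x)
}

#' Serialize a validation report to JSON
#'
#' @param report A `validation_report`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
report_to_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(as.data.frame(report), auto_unbox = FALSE,
                         pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
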