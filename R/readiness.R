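# Fit-for-purpose readiness scoring of test methods: a rubric of 13
# categories with 62 sub-items in total, scored independently by (at least)
# two experts, averaged per sub-item, summed and expressed as percent of the
# maximum reachable points. Discrepant scorings (>= 20 percentage points
# between raters' overall percentages) trigger a third rater. Traffic-light
# bands: high (>= 85%, green), intermediate (>= 50%, orange), low (< 50%,
# red). Boundaries are assigned to the better band.

# Sub-items per category in the default skeleton (sums to 62). The authentic
# sub-item wordings live in the readiness-criteria literature; this skeleton
# carries ids and max scores only and makes no claim about their text.
.DEFAULT_RUBRIC_LAYOUT <- c(5, 5, 5, 5, 5, 5, 5, 5, 5, 4, 4, 4, 5)
.DEFAULT_CATEGORY_NAMES <- c(
  "Test definition", "Exposure scheme", "Endpoint and analytics",
  "Test system", "Controls and acceptance criteria", "Data management",
  "Documentation level", "Prediction model", "Robustness",
  "Transferability", "Applicability domain", "Regulatory context",
  "High-throughput readiness")

#' Build the default readiness rubric skeleton
#'
#' 13 categories, 62 sub-items in total, every sub-item with the same
#' maximum score (default 2 points). Placeholder descriptions; supply your
#' own rubric config via [load_rubric()] for real evaluations.
#'
#' @param max_score Maximum points per sub-item.
#' @return A `readiness_rubric`.
#' @export
default_rubric <- function(max_score = 2) {
  categories <- lapply(seq_along(.DEFAULT_RUBRIC_LAYOUT), function(i) {
    n <- .DEFAULT_RUBRIC_LAYOUT[i]
    list(category_id = i, name = .DEFAULT_CATEGORY_NAMES[i],
         sub_items = data.frame(
           item_id = sprintf("c%02d_i%02d", i, seq_len(n)),
           description = sprintf("%s: sub-item %d (placeholder)",
                                 .DEFAULT_CATEGORY_NAMES[i], seq_len(n)),
           max_score = rep(max_score, n),
           stringsAsFactors = FALSE))
  })
  .rubric(categories, version = "skeleton-1.0")
}

.rubric <- function(categories, version) {
  cat_ids <- vapply(categories, function(c) c$category_id, numeric(1))
  if (anyDuplicated(cat_ids))
    stop("duplicate category_id in rubric", call. = FALSE)
  items <- do.call(rbind, lapply(categories, function(c) c$sub_items))
  if (anyDuplicated(items$item_id))
    stop(sprintf("duplicate item_id in rubric: %s",
                 items$item_id[duplicated(items$item_id)][1]), call. = FALSE)
  if (any(!is.finite(items$max_score) | items$max_score <= 0))
    stop("every max_score must be > 0", call. = FALSE)
  structure(list(categories = categories, version = version),
            class = "readiness_rubric")
}

#' Load a readiness rubric from a YAML config
#'
#' Expected structure: a top-level `version` string and a `categories` list,
#' each with `category_id`, `name` and `sub_items` (each with `item_id`,
#' `description`, `max_score`). Duplicate ids or non-positive max scores are
#' schema errors.
#'
#' @param config Path to a YAML file, or an already-parsed list of the same
#'   shape.
#' @return A `readiness_rubric`.
#' @export
load_rubric <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$categories))
    stop("rubric config needs a 'categories' list", call. = FALSE)
  categories <- lapply(config$categories, function(c) {
    if (is.null(c$category_id) || is.null(c$sub_items))
      stop("each category needs category_id and sub_items", call. = FALSE)
    si <- do.call(rbind, lapply(c$sub_items, function(s) {
      if (is.null(s$item_id) || is.null(s$max_score))
        stop("each sub-item needs item_id and max_score", call. = FALSE)
      data.frame(item_id = s$item_id,
                 description = s$description %||% "",
                 max_score = as.numeric(s$max_score),
                 stringsAsFactors = FALSE)
    }))
    list(category_id = c$category_id, name = c$name %||% "",
         sub_items = si)
  })
  .rubric(categories, version = config$version %||% "unversioned")
}

#' @export
print.readiness_rubric <- function(x, ...) {
  n_items <- sum(vapply(x$categories, function(c) nrow(c$sub_items),
                        numeric(1)))
  cat(sprintf("<readiness_rubric %s> %d categories, %d sub-items, %g points max\n",
              x$version, length(x$categories), n_items,
              sum(rubric_items(x)$max_score)))
  invisible(x)
}

#' Flatten a rubric into one row per sub-item
#'
#' @param rubric A `readiness_rubric`.
#' @return Data frame with `category_id`, `category_name`, `item_id`,
#'   `max_score`.
#' @export
rubric_items <- function(rubric) {
  do.call(rbind, lapply(rubric$categories, function(c)
    data.frame(category_id = c$category_id, category_name = c$name,
               item_id = c$sub_items$item_id,
               max_score = c$sub_items$max_score,
               stringsAsFactors = FALSE)))
}

#' Create a rater's score sheet
#'
#' @param method_id Test-method id being evaluated.
#' @param rater_id Rater identifier.
#' @param scores Named numeric vector, `item_id -> points`.
#' @param rubric Optional rubric; when given, coverage and score ranges are
#'   validated immediately.
#' @return An object of class `score_sheet`.
#' @export
score_sheet <- function(method_id, rater_id, scores, rubric = NULL) {
  sheet <- structure(list(method_id = method_id, rater_id = rater_id,
                          scores = scores),
                     class = "score_sheet")
  if (!is.null(rubric)) .check_sheet(sheet, rubric)
  sheet
}

.check_sheet <- function(sheet, rubric) {
  items <- rubric_items(rubric)
  missing <- setdiff(items$item_id, names(sheet$scores))
  if (length(missing) > 0)
    stop(sprintf("score sheet of rater '%s' is missing item(s): %s",
                 sheet$rater_id, paste(missing, collapse = ", ")),
         call. = FALSE)
  s <- sheet$scores[items$item_id]
  bad <- !is.finite(s) | s < 0 | s > items$max_score
  if (any(bad))
    stop(sprintf("rater '%s': score out of [0, max] for item(s): %s",
                 sheet$rater_id,
                 paste(items$item_id[bad], collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

.overall_percent <- function(scores, items) {
  100 * sum(scores[items$item_id]) / sum(items$max_score)
}

#' Aggregate multiple raters' score sheets
#'
#' Per-item mean across raters. The discrepancy metric is the spread of the
#' raters' overall percentages (max minus min, in percentage points); with
#' exactly two raters a discrepancy of 20 points or more requires a third
#' rater before a report can be issued. With three or more sheets the mean
#' over all of them is used and the requirement is considered resolved.
#'
#' @param sheets List of at least two `score_sheet` objects for the same
#'   method and rubric.
#' @param rubric A `readiness_rubric`.
#' @param discrepancy_limit Percentage-point threshold for the third-rater
#'   rule (default 20).
#' @return List of class `rater_aggregate`: `method_id`, `mean_scores`
#'   (named vector), `per_rater_percent`, `discrepancy_percent`,
#'   `third_rater_required`, `raters_used`, `per_item_range` (per-item
#'   max-min across raters, for transparency).
#' @export
aggregate_raters <- function(sheets, rubric, discrepancy_limit = 20) {
  if (length(sheets) < 2)
    stop("need at least two score sheets", call. = FALSE)
  methods <- unique(vapply(sheets, function(s) s$method_id, character(1)))
  if (length(methods) != 1)
    stop("all sheets must score the same method", call. = FALSE)
  for (s in sheets) .check_sheet(s, rubric)
  items <- rubric_items(rubric)
  mat <- vapply(sheets, function(s) s$scores[items$item_id],
                numeric(nrow(items)))
  mean_scores <- rowMeans(mat)
  names(mean_scores) <- items$item_id
  per_rater <- apply(mat, 2, function(col) {
    names(col) <- items$item_id
    .overall_percent(col, items)
  })
  discrepancy <- max(per_rater) - min(per_rater)
  structure(list(
    method_id = methods, mean_scores = mean_scores,
    per_rater_percent = per_rater,
    discrepancy_percent = discrepancy,
    third_rater_required = (length(sheets) == 2 &&
                              discrepancy >= discrepancy_limit),
    raters_used = vapply(sheets, function(s) s$rater_id, character(1)),
    per_item_range = apply(mat, 1, function(r) max(r) - min(r))),
    class = "rater_aggregate")
}

#' Classify an overall readiness percentage into a traffic-light band
#'
#' `high` (green) at 85% and above, `intermediate` (orange) from 50% up to
#' 85%, `low` (red) below 50%. The boundary values 85 and 50 belong to the
#' better band.
#'
#' @param percent Overall readiness in `[0, 100]`.
#' @param high_from,intermediate_from Band boundaries (config-overridable).
#' @return `"high"`, `"intermediate"` or `"low"` (vectorized).
#' @export
classify_readiness <- function(percent, high_from = 85,
                               intermediate_from = 50) {
  if (any(!is.finite(percent) | percent < 0 | percent > 100))
    stop("percent must lie in [0, 100]", call. = FALSE)
  ifelse(percent >= high_from, "high",
         ifelse(percent >= intermediate_from, "intermediate", "low"))
}

#' Score a test method from aggregated rater scores
#'
#' Per-category percent is the points-weighted sum of item means over the
#' category maximum; the overall percent is computed the same way over all
#' items (so categories with more points weigh more, rather than each
#' category counting equally). Refuses to produce a report while a third
#' rater is still required.
#'
#' @param rubric A `readiness_rubric`.
#' @param aggregated A `rater_aggregate` from [aggregate_raters()].
#' @return An object of class `readiness_report`: `method_id`,
#'   `per_category_percent` (named by category id), `overall_percent`,
#'   `band`, `raters_used`, `third_rater_required` (always `FALSE` here).
#' @export
score_method <- function(rubric, aggregated) {
  stopifnot(inherits(aggregated, "rater_aggregate"))
  if (aggregated$third_rater_required)
    stop(sprintf(
      "rater discrepancy %.1f percentage points: a third rater is required",
      aggregated$discrepancy_percent), call. = FALSE)
  items <- rubric_items(rubric)
  s <- aggregated$mean_scores[items$item_id]
  per_cat <- vapply(split(seq_len(nrow(items)), items$category_id),
                    function(idx)
                      100 * sum(s[idx]) / sum(items$max_score[idx]),
                    numeric(1))
  overall <- .overall_percent(aggregated$mean_scores, items)
  structure(list(
    method_id = aggregated$method_id,
    per_category_percent = per_cat,
    overall_percent = overall,
    band = classify_readiness(overall),
    raters_used = aggregated$raters_used,
    third_rater_required = FALSE),
    class = "readiness_report")
}

#' @export
print.readiness_report <- function(x, ...) {
  marker <- c(high = "green", intermediate = "orange", low = "red")
  cat(sprintf("<readiness %s> overall %.1f%% -> %s (%s)\n", x$method_id,
              x$overall_percent, x$band, marker[[x$band]]))
  bands <- classify_readiness(x$per_category_percent)
  for (i in seq_along(x$per_category_percent))
    cat(sprintf("  category %2s: %5.1f%%  [%s]\n",
                names(x$per_category_percent)[i],
                x$per_category_percent[i], marker[[bands[i]]]))
  cat(sprintf("  raters: %s\n", paste(x$raters_used, collapse = ", ")))
  invisible(x)
}

#' Serialize a readiness report to JSON
#'
#' @param report A `readiness_report`.
#' @param path Optional output path.
#' @return JSON string (invisibly when written to a file).
#' @export
readiness_to_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
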