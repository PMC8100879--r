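## Instrument model: questionnaire definitions, scoring, severity bands.
##
## All six screeners share one structure: ordered items with a contiguous
## integer option scale, optional reverse keying (min + max - value), an
## optional subscale tag per item, a total-score transformation (identity,
## or doubling for the DASS-21 stress subscale so its 7-item total aligns
## with the 42-item parent scale), and a list of inclusive severity bands.

#' Define a questionnaire item
#'
#' @param id unique item identifier (unique across the whole script).
#' @param text prompt wording shown to the respondent.
#' @param values integer vector of legal option values; must be contiguous
#'   and ascending (e.g. `0:3`).
#' @param labels optional character vector of option labels, same length as
#'   `values`.
#' @param reverse logical; if `TRUE` the item is reverse-keyed at scoring
#'   time: it contributes `min + max - value` to the total.
#' @param subscale optional subscale tag (e.g. `"exhaustion"`).
#' @return an object of class `checkup_item`.
#' @export
checkup_item <- function(id, text, values, labels = NULL, reverse = FALSE,
                         subscale = NULL) {
  values <- as.integer(values)
  if (length(values) < 2L)
    stop_checkup("checkup_validation_error",
                 sprintf("item '%s': needs at least 2 options", id))
  if (anyDuplicated(values) || !all(diff(values) == 1L))
    stop_checkup("checkup_validation_error",
                 sprintf("item '%s': option values must be distinct and contiguous", id))
  if (!is.null(labels) && length(labels) != length(values))
    stop_checkup("checkup_validation_error",
                 sprintf("item '%s': labels/values length mismatch", id))
  structure(
    list(id = as.character(id), text = as.character(text), values = values,
         labels = labels, reverse = isTRUE(reverse),
         subscale = if (is.null(subscale)) NULL else as.character(subscale)),
    class = "checkup_item"
  )
}

#' Define a severity band
#'
#' An inclusive integer interval `[lower, upper]` mapped to a category label;
#' `upper = Inf` expresses an open-ended top band such as "severe (15+)".
#'
#' @param label category name.
#' @param lower,upper inclusive integer bounds (`upper` may be `Inf`).
#' @return an object of class `checkup_band`.
#' @export
category_band <- function(label, lower, upper = Inf) {
  if (lower > upper)
    stop_checkup("checkup_validation_error",
                 sprintf("band '%s': lower > upper", label))
  structure(list(label = as.character(label), lower = lower, upper = upper),
            class = "checkup_band")
}

#' Define an instrument
#'
#' @param id instrument identifier; the six canonical ids are `gad7`, `phq9`,
#'   `dass21_stress`, `isi`, `olbi`, `jss`.
#' @param items list of [checkup_item()] objects, in delivery order.
#' @param transform total-score transformation: `"identity"` or `"double"`.
#' @param bands list of [category_band()] objects covering every achievable
#'   transformed total, sorted and non-overlapping.
#' @param subscales optional character vector of subscale tags; when given,
#'   every item must carry one of these tags.
#' @param subscale_bands optional named list (tag -> list of bands) used to
#'   categorize subscale totals.
#' @return an object of class `checkup_instrument`.
#' @export
checkup_instrument <- function(id, items, transform = c("identity", "double"),
                               bands, subscales = NULL, subscale_bands = NULL) {
  transform <- match.arg(transform)
  ids <- vapply(items, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop_checkup("checkup_validation_error",
                 sprintf("instrument '%s': duplicate item ids", id))
  if (!is.null(subscales)) {
    tags <- vapply(items, function(it) it$subscale %||% NA_character_, "")
    if (anyNA(tags) || !all(tags %in% subscales))
      stop_checkup("checkup_validation_error",
                   sprintf("instrument '%s': every item must carry one of the declared subscale tags", id))
  }
  structure(
    list(id = as.character(id), items = items, transform = transform,
         bands = bands, subscales = subscales, subscale_bands = subscale_bands),
    class = "checkup_instrument"
  )
}

item_ids <- function(instrument) vapply(instrument$items, `[[`, "", "id")

n_items <- function(instrument) length(instrument$items)

keyed_value <- function(item, value) {
  if (item$reverse) min(item$values) + max(item$values) - value else value
}

apply_transform <- function(total, transform) {
  switch(transform, identity = total, double = 2L * total,
         stop_checkup("checkup_validation_error",
                      sprintf("unknown transform '%s'", transform)))
}

## Range of achievable transformed totals (keying preserves per-item ranges).
achievable_range <- function(instrument) {
  lo <- sum(vapply(instrument$items, function(it) min(it$values), 0L))
  hi <- sum(vapply(instrument$items, function(it) max(it$values), 0L))
  c(apply_transform(lo, instrument$transform),
    apply_transform(hi, instrument$transform))
}

#' Map a total score to its severity band
#'
#' @param total integer total (already transformed where the instrument
#'   defines a transformation).
#' @param bands list of [category_band()] objects.
#' @return the label of the unique band whose inclusive interval contains
#'   `total`; an error of class `checkup_coverage_error` if no band matches
#'   (which signals a misconfigured script, not user input).
#' @export
categorize <- function(total, bands) {
  hit <- vapply(bands, function(b) total >= b$lower && total <= b$upper, NA)
  if (sum(hit) == 0L)
    stop_checkup("checkup_coverage_error",
                 sprintf("total %s falls in no band", total))
  if (sum(hit) > 1L)
    stop_checkup("checkup_coverage_error",
                 sprintf("total %s falls in %d overlapping bands", total, sum(hit)))
  bands[[which(hit)]]$label
}

check_answers <- function(instrument, answers) {
  if (length(answers) != n_items(instrument))
    stop_checkup("checkup_validation_error",
                 sprintf("instrument '%s': expected %d answers, got %d",
                         instrument$id, n_items(instrument), length(answers)))
  answers <- as.integer(answers)
  for (i in seq_along(answers)) {
    it <- instrument$items[[i]]
    if (!answers[i] %in% it$values)
      stop_checkup("checkup_validation_error",
                   sprintf("item '%s': value %d outside options [%d, %d]",
                           it$id, answers[i], min(it$values), max(it$values)))
  }
  answers
}

#' Score an answer vector
#'
#' Applies reverse keying, sums, applies the instrument's total-score
#' transformation, computes subscale totals where defined, and assigns the
#' severity category of the transformed total (and of each subscale total
#' when subscale bands are configured).
#'
#' @param instrument a [checkup_instrument()].
#' @param answers integer vector of raw option values, one per item, in item
#'   order.
#' @return an object of class `checkup_score` with fields `instrument_id`,
#'   `raw_total` (sum after reverse keying), `transformed_total`,
#'   `subscale_totals`, `category`, `subscale_categories`, `item_answers`.
#' @examples
#' gad7 <- default_instruments()$gad7
#' score_instrument(gad7, c(1, 2, 1, 0, 1, 0, 1))
#' @export
score_instrument <- function(instrument, answers) {
  answers <- check_answers(instrument, answers)
  keyed <- mapply(keyed_value, instrument$items, answers)
  raw <- as.integer(sum(keyed))
  transformed <- as.integer(apply_transform(raw, instrument$transform))
  sub <- NULL
  sub_cat <- NULL
  if (!is.null(instrument$subscales)) {
    sub <- subscale_totals(instrument, answers)
    if (!is.null(instrument$subscale_bands)) {
      sub_cat <- vapply(names(sub), function(tag) {
        bands <- instrument$subscale_bands[[tag]]
        if (is.null(bands)) NA_character_ else categorize(sub[[tag]], bands)
      }, "")
    }
  }
  structure(
    list(instrument_id = instrument$id,
         raw_total = raw,
         transformed_total = transformed,
         subscale_totals = sub,
         category = categorize(transformed, instrument$bands),
         subscale_categories = sub_cat,
         item_answers = stats::setNames(answers, item_ids(instrument))),
    class = "checkup_score"
  )
}

#' Per-subscale keyed totals
#'
#' @inheritParams score_instrument
#' @return named integer vector of keyed sums, one per declared subscale tag;
#'   these always sum to the instrument's raw total.
#' @export
subscale_totals <- function(instrument, answers) {
  if (is.null(instrument$subscales))
    stop_checkup("checkup_validation_error",
                 sprintf("instrument '%s' declares no subscales", instrument$id))
  tags <- vapply(instrument$items, function(it) it$subscale %||% NA_character_, "")
  if (anyNA(tags)) {
    bad <- item_ids(instrument)[is.na(tags)]
    stop_checkup("checkup_validation_error",
                 sprintf("untagged item(s) in subscale instrument '%s': %s",
                         instrument$id, paste(bad, collapse = ", ")))
  }
  answers <- check_answers(instrument, answers)
  keyed <- mapply(keyed_value, instrument$items, answers)
  sums <- vapply(instrument$subscales,
                 function(tag) as.integer(sum(keyed[tags == tag])), 0L)
  stats::setNames(sums, instrument$subscales)
}

## Canonical structural expectations per instrument id.
instrument_specs <- list(
  gad7          = list(n = 7L,  values = 0:3, transform = "identity"),
  phq9          = list(n = 9L,  values = 0:3, transform = "identity"),
  dass21_stress = list(n = 7L,  values = 0:3, transform = "double"),
  isi           = list(n = 7L,  values = 0:4, transform = "identity"),
  olbi          = list(n = 16L, values = 1:4, transform = "identity"),
  jss           = list(n = 15L, values = 1:4, transform = "identity")
)

#' Validate an instrument definition
#'
#' Checks item counts, option ranges and the transformation against the
#' canonical expectations for the instrument's id, and checks that the bands
#' form a sorted, non-overlapping partition covering every achievable
#' transformed total. Bands lying entirely outside the achievable range
#' (possible when a published band table assumes a 0-based scale but items
#' score from 1, as for the OLBI) yield warnings, not errors.
#'
#' @param instrument a [checkup_instrument()].
#' @return a list of violation records, each `list(level, message)` with
#'   `level` either `"error"` or `"warning"`; empty when the definition is
#'   canonical.
#' @export
validate_instrument <- function(instrument) {
  out <- list()
  note <- function(level, msg) out[[length(out) + 1L]] <<- list(level = level, message = msg)

  spec <- instrument_specs[[instrument$id]]
  if (!is.null(spec)) {
    if (n_items(instrument) != spec$n)
      note("error", sprintf("instrument '%s': %d items, expected %d",
                            instrument$id, n_items(instrument), spec$n))
    for (it in instrument$items)
      if (!identical(it$values, as.integer(spec$values)))
        note("error", sprintf("item '%s': option values %d-%d, expected %d-%d",
                              it$id, min(it$values), max(it$values),
                              min(spec$values), max(spec$values)))
    if (instrument$transform != spec$transform)
      note("error", sprintf("instrument '%s': transform '%s', expected '%s'",
                            instrument$id, instrument$transform, spec$transform))
  }

  bands <- instrument$bands
  lowers <- vapply(bands, `[[`, 0, "lower")
  uppers <- vapply(bands, `[[`, 0, "upper")
  labels <- vapply(bands, `[[`, "", "label")
  if (is.unsorted(lowers, strictly = TRUE))
    note("error", "bands are not sorted by lower bound")
  if (any(lowers > uppers))
    note("error", "band with lower > upper")
  if (length(bands) > 1L) {
    for (i in seq_len(length(bands) - 1L)) {
      if (uppers[i] >= lowers[i + 1L])
        note("error", sprintf("bands '%s' and '%s' overlap",
                              labels[i], labels[i + 1L]))
      else if (uppers[i] + 1 < lowers[i + 1L])
        note("error", sprintf("coverage gap between bands '%s' and '%s' (%s..%s)",
                              labels[i], labels[i + 1L],
                              uppers[i] + 1, lowers[i + 1L] - 1))
    }
  }
  rng <- achievable_range(instrument)
  if (length(bands)) {
    if (min(lowers) > rng[1])
      note("error", sprintf("achievable total %s below the lowest band", rng[1]))
    if (max(uppers) < rng[2])
      note("error", sprintf("achievable total %s above the highest band", rng[2]))
    for (i in seq_along(bands))
      if (uppers[i] < rng[1] || lowers[i] > rng[2])
        note("warning",
             sprintf("band '%s' (%s-%s) is unreachable: achievable totals span %s-%s",
                     labels[i], lowers[i], uppers[i], rng[1], rng[2]))
  }

  if (!is.null(instrument$subscale_bands)) {
    extra <- setdiff(names(instrument$subscale_bands), instrument$subscales %||% character())
    if (length(extra))
      note("error", sprintf("subscale bands for undeclared tag(s): %s",
                            paste(extra, collapse = ", ")))
  }
  out
}

#' Batch-score a table of answer vectors
#'
#' Scores one respondent per row of a delimited file (or data frame) whose
#' header carries the instrument's item ids, in any order.
#'
#' @param instrument a [checkup_instrument()].
#' @param answers a data frame, or path to a CSV file, with one column per
#'   item (header = item ids) and one row per respondent.
#' @param out optional path; when given, the result is also written as CSV.
#' @return a data frame with `raw_total`, `transformed_total`, `category`
#'   and one column per subscale total, one row per respondent.
#' @export
score_batch <- function(instrument, answers, out = NULL) {
  if (is.character(answers))
    answers <- utils::read.csv(answers, check.names = FALSE)
  ids <- item_ids(instrument)
  missing <- setdiff(ids, names(answers))
  if (length(missing))
    stop_checkup("checkup_validation_error",
                 sprintf("missing item column(s): %s",
                         paste(missing, collapse = ", ")))
  res <- lapply(seq_len(nrow(answers)), function(i)
    score_instrument(instrument, as.integer(answers[i, ids])))
  df <- data.frame(
    raw_total = vapply(res, `[[`, 0L, "raw_total"),
    transformed_total = vapply(res, `[[`, 0L, "transformed_total"),
    category = vapply(res, `[[`, "", "category"),
    stringsAsFactors = FALSE)
  for (tag in instrument$subscales %||% character())
    df[[tag]] <- vapply(res, function(r) r$subscale_totals[[tag]], 0L)
  if (!is.null(out)) utils::write.csv(df, out, row.names = FALSE)
  df
}

#' @export
print.checkup_score <- function(x, ...) {
  cat(sprintf("<checkup_score> %s: total %d", x$instrument_id, x$transformed_total))
  if (x$transformed_total != x$raw_total)
    cat(sprintf(" (raw %d)", x$raw_total))
  cat(sprintf(" -> '%s'\n", x$category))
  if (!is.null(x$subscale_totals)) {
    cat("  subscales:",
        paste(sprintf("%s=%d", names(x$subscale_totals), x$subscale_totals),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.checkup_instrument <- function(x, ...) {
  rng <- achievable_range(x)
  cat(sprintf("<checkup_instrument> %s: %d items, totals %s-%s (%s), %d bands\n",
              x$id, n_items(x), rng[1], rng[2], x$transform, length(x$bands)))
  invisible(x)
}
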