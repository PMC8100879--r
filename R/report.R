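## Feedback and organization-level reporting: personalized end-of-checkup
## messages, campaign rates, pooled category distributions (k-anonymity),
## symptomatic breakdowns, and the per-instrument summary table.
##
## Percent rendering convention: rates are computed at full precision and
## rendered half-up to one decimal; whole-percent figures (the breakdown
## percentages) are obtained by rounding the one-decimal value, the
## convention used in the organization reports this engine reproduces
## (so 45.45% renders as 45.5 -> 46%).

pct1 <- function(x) round_half_up(x, 1)
pct_whole <- function(x) round_half_up(round_half_up(x, 1), 0)

completed_only <- function(sessions)
  Filter(function(s) identical(s$status, "completed"), sessions)

#' Personalized end-of-checkup feedback
#'
#' One feedback block per scored instrument, keyed by the assigned category,
#' followed by a care recommendation for high-severity categories and always
#' closed by the non-diagnosis disclaimer.
#'
#' @param scores named list of `checkup_score` objects (in delivery order).
#' @param feedback feedback configuration (see [checkup_script()]).
#' @return ordered character vector of messages.
#' @export
personal_feedback <- function(scores, feedback) {
  msgs <- character()
  for (sc in scores) {
    tpl <- feedback$templates[[sc$instrument_id]][[sc$category]]
    if (is.null(tpl))
      stop_checkup("checkup_validation_error",
                   sprintf("no feedback template for %s category '%s'",
                           sc$instrument_id, sc$category))
    msgs <- c(msgs, tpl)
    care <- feedback$care_categories[[sc$instrument_id]]
    if (!is.null(care) && sc$category %in% care)
      msgs <- c(msgs, feedback$care_recommendation)
  }
  c(msgs, feedback$disclaimer)
}

#' Campaign engagement rates
#'
#' Initiation = started/eligible, completion = completed/started, response =
#' completed/eligible, all as percentages at full precision (the print method
#' renders one decimal, half-up). Every stored session counts as started;
#' expired and in-progress sessions are non-completers.
#'
#' @param eligible_n number of eligible employees.
#' @param sessions list of `checkup_session` objects (the campaign store).
#' @return an object of class `checkup_campaign_stats` with counts and the
#'   three rates.
#' @examples
#' # 98 of 120 started, 77 completed -> 81.7 / 78.6 / 64.2
#' @export
campaign_stats <- function(eligible_n, sessions) {
  if (eligible_n <= 0)
    stop_checkup("checkup_validation_error",
                 "eligible_n must be positive: rates are undefined")
  started <- length(sessions)
  completed <- length(completed_only(sessions))
  if (eligible_n < started)
    stop_checkup("checkup_validation_error",
                 sprintf("eligible_n (%d) smaller than sessions started (%d)",
                         eligible_n, started))
  structure(
    list(eligible_n = as.integer(eligible_n), started_n = started,
         completed_n = completed,
         initiation_rate = 100 * started / eligible_n,
         completion_rate = if (started == 0) 0 else 100 * completed / started,
         response_rate = 100 * completed / eligible_n),
    class = "checkup_campaign_stats")
}

#' @export
print.checkup_campaign_stats <- function(x, ...) {
  cat(sprintf("<campaign_stats> eligible %d, started %d, completed %d\n",
              x$eligible_n, x$started_n, x$completed_n))
  cat(sprintf("  initiation %.1f%%  completion %.1f%%  response %.1f%%\n",
              pct1(x$initiation_rate), pct1(x$completion_rate),
              pct1(x$response_rate)))
  invisible(x)
}

## Greedy small-cell pooling: repeatedly merge the smallest group under k
## into the smallest other group (ties broken by label order) until every
## reported group has >= k members or only one group remains; a final single
## group still under k is reported as "all".
pool_groups <- function(sizes, k) {
  if (!length(sizes)) return(stats::setNames(character(), character()))
  members <- lapply(names(sizes), identity)
  counts <- as.numeric(sizes)
  glabel <- function(m) paste(sort(m), collapse = "+")
  while (length(counts) > 1L && any(counts < k)) {
    labs <- vapply(members, glabel, "")
    i <- order(counts, labs)[1L]
    rest <- setdiff(seq_along(counts), i)
    j <- rest[order(counts[rest], labs[rest])[1L]]
    members[[j]] <- c(members[[j]], members[[i]])
    counts[j] <- counts[j] + counts[i]
    members[[i]] <- NULL
    counts <- counts[-i]
  }
  if (length(counts) == 1L && counts[1L] < k) {
    pooled <- stats::setNames(rep("all", length(members[[1L]])), members[[1L]])
    return(pooled[names(sizes)])
  }
  out <- stats::setNames(character(length(sizes)), names(sizes))
  for (m in members) out[m] <- glabel(m)
  out
}

group_labels_for <- function(sessions, group_of) {
  tokens <- vapply(sessions, `[[`, "", "token")
  if (is.null(group_of))
    return(stats::setNames(vapply(sessions, function(s) s$group_label %||% "all", ""), tokens))
  if (is.function(group_of))
    return(stats::setNames(vapply(sessions, function(s) as.character(group_of(s)), ""), tokens))
  stats::setNames(as.character(group_of[tokens]), tokens)
}

#' Pooled per-instrument category distributions
#'
#' Counts completed sessions per (group, category) for every scored
#' instrument, after merging any reporting group with fewer than `k` members
#' into larger ones so that no reported group can re-identify a respondent.
#' Pooling is per instrument (the insomnia block is answered by a subset).
#' The output carries no session tokens.
#'
#' @param sessions list of `checkup_session` objects; only completed sessions
#'   are counted.
#' @param group_of `NULL` (use each session's `group_label`), a function of a
#'   session, or a named vector keyed by token.
#' @param k minimum reported group size (default 8).
#' @param script optional `checkup_script`; when given, categories are
#'   ordered as the instrument's bands.
#' @return list of `checkup_distribution` objects, one per instrument, each
#'   with `instrument_id`, a `counts` matrix (pooled group x category) and
#'   the `pooled_from` mapping of original to pooled labels.
#' @export
aggregate_distributions <- function(sessions, group_of = NULL, k = 8,
                                    script = NULL) {
  if (k < 1) stop_checkup("checkup_validation_error", "k must be >= 1")
  done <- completed_only(sessions)
  groups <- group_labels_for(done, group_of)
  ins_ids <- unique(unlist(lapply(done, function(s) names(s$scores))))
  out <- list()
  for (id in ins_ids) {
    has <- vapply(done, function(s) !is.null(s$scores[[id]]), NA)
    subset <- done[has]
    cats <- vapply(subset, function(s) s$scores[[id]]$category, "")
    g <- unname(groups[vapply(subset, `[[`, "", "token")])
    sizes <- table(g)
    pooled_from <- pool_groups(stats::setNames(as.integer(sizes), names(sizes)), k)
    pg <- pooled_from[g]
    levels <- if (!is.null(script) && !is.null(script$instruments[[id]]))
      vapply(script$instruments[[id]]$bands, `[[`, "", "label")
    else unique(cats)
    counts <- table(factor(pg, levels = sort(unique(pg))),
                    factor(cats, levels = levels))
    out[[id]] <- structure(
      list(instrument_id = id,
           counts = unclass(as.matrix(counts)),
           pooled_from = pooled_from, n = length(subset), k = k),
      class = "checkup_distribution")
  }
  out
}

#' @export
print.checkup_distribution <- function(x, ...) {
  cat(sprintf("<checkup_distribution> %s (n=%d, k=%d)\n", x$instrument_id,
              x$n, x$k))
  print(x$counts)
  invisible(x)
}

default_baselines <- c(gad7 = "none", phq9 = "none", dass21_stress = "normal",
                       isi = "absence")

#' Category breakdown among symptomatic respondents
#'
#' Excludes the instrument's no-symptom band (GAD-7/PHQ-9 "none", DASS-21
#' "normal", ISI "absence") and tabulates the remaining respondents per
#' severity band with percentages of the symptomatic count. For instruments
#' without a no-symptom baseline (OLBI, JSS), pass `baseline = NULL` to get
#' category shares among all scored respondents. `pct` is the one-decimal
#' percentage; `pct_display` is the whole-percent rendering (rounded from the
#' one-decimal value).
#'
#' @param sessions list of `checkup_session` objects (completed ones count).
#' @param instrument_id which instrument to tabulate.
#' @param baseline `"auto"` (default per instrument), a band label, or `NULL`.
#' @param script optional `checkup_script` for band ordering.
#' @return an object of class `checkup_breakdown` with `instrument_id`,
#'   `baseline_label`, `n_scored`, `symptomatic_n` and a `table` data frame
#'   (category, count, pct, pct_display); the table is empty when no
#'   respondent is symptomatic.
#' @export
symptomatic_breakdown <- function(sessions, instrument_id, baseline = "auto",
                                  script = NULL) {
  done <- completed_only(sessions)
  scored <- Filter(function(s) !is.null(s$scores[[instrument_id]]), done)
  cats <- vapply(scored, function(s) s$scores[[instrument_id]]$category, "")
  if (identical(baseline, "auto"))
    baseline <- if (instrument_id %in% names(default_baselines))
      default_baselines[[instrument_id]] else NULL
  symptomatic <- if (is.null(baseline)) cats else cats[cats != baseline]
  levels <- if (!is.null(script) && !is.null(script$instruments[[instrument_id]]))
    vapply(script$instruments[[instrument_id]]$bands, `[[`, "", "label")
  else unique(cats)
  if (!is.null(baseline)) levels <- setdiff(levels, baseline)
  n_sym <- length(symptomatic)
  tab <- if (n_sym == 0L) {
    data.frame(category = character(), count = integer(), pct = numeric(),
               pct_display = numeric())
  } else {
    counts <- table(factor(symptomatic, levels = levels))
    data.frame(category = names(counts), count = as.integer(counts),
               pct = pct1(100 * as.integer(counts) / n_sym),
               pct_display = pct_whole(100 * as.integer(counts) / n_sym),
               row.names = NULL)
  }
  structure(list(instrument_id = instrument_id, baseline_label = baseline,
                 n_scored = length(scored), symptomatic_n = n_sym,
                 table = tab),
            class = "checkup_breakdown")
}

#' @export
print.checkup_breakdown <- function(x, ...) {
  cat(sprintf("<checkup_breakdown> %s: %d symptomatic of %d scored%s\n",
              x$instrument_id, x$symptomatic_n, x$n_scored,
              if (is.null(x$baseline_label)) " (all respondents)"
              else sprintf(" (baseline '%s' excluded)", x$baseline_label)))
  if (nrow(x$table)) print(x$table, row.names = FALSE)
  invisible(x)
}

#' Per-instrument summary of a campaign
#'
#' Mean and SD of transformed totals over completed sessions, with the
#' severity category of the (half-up rounded) mean. The insomnia row counts
#' only sessions where the ISI was administered. With a single respondent the
#' SD is undefined and reported as 0 with `sd_degenerate = TRUE`.
#'
#' @param sessions list of `checkup_session` objects.
#' @param script a `checkup_script` (for instrument order and bands).
#' @return a data frame with columns `instrument_id`, `n`, `mean`, `sd`,
#'   `sd_degenerate`, `category`.
#' @export
summary_table <- function(sessions, script) {
  done <- completed_only(sessions)
  if (!length(done))
    stop_checkup("checkup_state_error", "no completed sessions to summarize")
  rows <- lapply(script$sections, function(sec) {
    id <- sec$instrument_id
    totals <- unlist(lapply(done, function(s)
      if (!is.null(s$scores[[id]])) s$scores[[id]]$transformed_total))
    if (!length(totals)) return(NULL)
    m <- mean(totals)
    s <- if (length(totals) > 1L) stats::sd(totals) else 0
    data.frame(instrument_id = id, n = length(totals), mean = m, sd = s,
               sd_degenerate = length(totals) == 1L,
               category = categorize(round_half_up(m, 0),
                                     script$instruments[[id]]$bands),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Export / re-import a pooled distribution report
#'
#' The delimited export has one row per instrument x group x category and
#' contains no session tokens and no group under the pooling threshold.
#'
#' @param distributions output of [aggregate_distributions()].
#' @param path CSV path.
#' @return `path` invisibly for `write_report()`; a named list of count
#'   matrices (per instrument) for `read_report()`.
#' @export
write_report <- function(distributions, path) {
  rows <- lapply(distributions, function(d) {
    grid <- expand.grid(group = rownames(d$counts),
                        category = colnames(d$counts),
                        stringsAsFactors = FALSE)
    grid$instrument <- d$instrument_id
    grid$count <- as.integer(d$counts[cbind(grid$group, grid$category)])
    grid[, c("instrument", "group", "category", "count")]
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- list()
  for (id in unique(df$instrument)) {
    sub <- df[df$instrument == id, ]
    groups <- unique(sub$group)
    cats <- unique(sub$category)
    m <- matrix(0L, length(groups), length(cats),
                dimnames = list(groups, cats))
    m[cbind(sub$group, sub$category)] <- sub$count
    out[[id]] <- m
  }
  out
}

#' Assemble the dashboard payload
#'
#' A single structured document combining campaign rates, pooled
#' distributions and symptomatic breakdowns, suitable for JSON export; it
#' contains no tokens and no item-level answers.
#'
#' @param stats a `checkup_campaign_stats`.
#' @param distributions output of [aggregate_distributions()].
#' @param breakdowns optional list of `checkup_breakdown` objects.
#' @return a plain list.
#' @export
dashboard_payload <- function(stats, distributions, breakdowns = list()) {
  list(
    campaign = list(
      eligible_n = stats$eligible_n, started_n = stats$started_n,
      completed_n = stats$completed_n,
      initiation_rate = pct1(stats$initiation_rate),
      completion_rate = pct1(stats$completion_rate),
      response_rate = pct1(stats$response_rate)),
    distributions = lapply(distributions, function(d)
      list(instrument = d$instrument_id, n = d$n, k = d$k,
           counts = as.data.frame.table(as.table(d$counts),
                                        responseName = "count"))),
    breakdowns = lapply(breakdowns, function(b)
      list(instrument = b$instrument_id, baseline = b$baseline_label,
           symptomatic_n = b$symptomatic_n, table = b$table))
  )
}
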