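## Session store: one flat JSON record per session, token-named, in a store
## directory that represents one campaign. Records contain the anonymous
## token, timestamps, status, answers, scores, risk flags and transcript —
## never a name or any personal identifier.

score_to_list <- function(sc) {
  list(instrument_id = sc$instrument_id, raw_total = sc$raw_total,
       transformed_total = sc$transformed_total,
       subscale_totals = if (is.null(sc$subscale_totals)) NULL
                         else as.list(sc$subscale_totals),
       category = sc$category,
       subscale_categories = if (is.null(sc$subscale_categories)) NULL
                             else as.list(sc$subscale_categories),
       item_answers = as.list(sc$item_answers))
}

score_from_list <- function(x) {
  structure(
    list(instrument_id = x$instrument_id,
         raw_total = as.integer(x$raw_total),
         transformed_total = as.integer(x$transformed_total),
         subscale_totals = if (is.null(x$subscale_totals)) NULL
                           else unlist(x$subscale_totals),
         category = x$category,
         subscale_categories = if (is.null(x$subscale_categories)) NULL
                               else unlist(x$subscale_categories),
         item_answers = unlist(x$item_answers)),
    class = "checkup_score")
}

parse_iso <- function(x) {
  if (is.null(x)) return(NULL)
  as.POSIXct(sub("Z$", "", x), format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
}

session_to_list <- function(session) {
  list(
    token = session$token, company_code = session$company_code,
    consented = session$consented, group_label = session$group_label,
    started_at = format_utc(session$started_at),
    updated_at = format_utc(session$updated_at),
    completed_at = if (is.null(session$completed_at)) NULL
                   else format_utc(session$completed_at),
    status = session$status,
    answers = as.list(session$answers),
    scores = lapply(session$scores, score_to_list),
    risk_events = lapply(session$risk_events, function(e)
      list(trigger = e$trigger, source = e$source,
           severity_tier = e$severity_tier,
           timestamp = format_utc(e$timestamp))),
    transcript = lapply(session$transcript, function(ev)
      list(timestamp = format_utc(ev$timestamp), actor = ev$actor,
           kind = ev$kind, payload = ev$payload)),
    feedback = session$feedback,
    can_go_back = isTRUE(session$can_go_back),
    halted = isTRUE(session$halted)
  )
}

session_from_list <- function(x) {
  answers <- vapply(x$answers, as.integer, 0L)
  if (!length(answers)) answers <- stats::setNames(integer(), character())
  structure(
    list(token = x$token, company_code = x$company_code,
         consented = isTRUE(x$consented), group_label = x$group_label %||% "all",
         started_at = parse_iso(x$started_at),
         updated_at = parse_iso(x$updated_at),
         completed_at = parse_iso(x$completed_at),
         status = x$status, answers = answers,
         scores = lapply(x$scores, score_from_list),
         risk_events = lapply(x$risk_events, function(e)
           risk_event(e$trigger, e$source, e$severity_tier,
                      parse_iso(e$timestamp))),
         transcript = lapply(x$transcript, function(ev)
           list(timestamp = parse_iso(ev$timestamp), actor = ev$actor,
                kind = ev$kind, payload = ev$payload)),
         feedback = if (is.null(x$feedback)) NULL else unlist(x$feedback),
         can_go_back = isTRUE(x$can_go_back),
         halted = isTRUE(x$halted)),
    class = "checkup_session")
}

#' Persist a session record
#'
#' Writes one JSON file named after the session token into the store
#' directory (created if needed).
#'
#' @param session a `checkup_session`.
#' @param store path to the store directory.
#' @return the record path, invisibly.
#' @export
write_session <- function(session, store) {
  if (!dir.exists(store)) dir.create(store, recursive = TRUE)
  path <- file.path(store, paste0(session$token, ".json"))
  jsonlite::write_json(session_to_list(session), path, auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' Read a session record
#'
#' @param path path to a session JSON file.
#' @return a `checkup_session`.
#' @export
read_session <- function(path) {
  session_from_list(jsonlite::read_json(path, simplifyVector = FALSE))
}

#' Load every session in a store
#'
#' @param store path to the store directory.
#' @return list of `checkup_session` objects.
#' @export
load_sessions <- function(store) {
  if (!dir.exists(store))
    stop_checkup("checkup_usage_error", sprintf("store not found: %s", store))
  files <- list.files(store, pattern = "\\.json$", full.names = TRUE)
  lapply(files, read_session)
}

#' Tokens already present in a store
#'
#' @param store path to the store directory.
#' @return character vector of tokens (empty for a missing store).
#' @export
store_tokens <- function(store) {
  if (!dir.exists(store)) return(character())
  sub("\\.json$", "", list.files(store, pattern = "\\.json$"))
}
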