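## Risk detection and the safety protocol: very high anxiety or depression
## scores, any endorsement of the PHQ-9 self-harm item, or a key phrase in
## free text route the conversation into a referral flow (care network for
## elevated risk, emergency services first for urgent risk).

risk_event <- function(trigger, source, severity_tier, timestamp) {
  structure(list(trigger = trigger, source = source,
                 severity_tier = severity_tier, timestamp = as_now(timestamp)),
            class = "checkup_risk_event")
}

#' Build a risk lexicon
#'
#' @param phrases character vector of key phrases; normalized (case-folded,
#'   diacritics stripped, whitespace squashed) before matching.
#' @return an object of class `checkup_lexicon`.
#' @export
risk_lexicon <- function(phrases) {
  phrases <- unique(normalize_text(phrases[nzchar(trimws(phrases))]))
  structure(list(phrases = phrases, normalization = "casefold+deaccent"),
            class = "checkup_lexicon")
}

#' Read a lexicon file
#'
#' One phrase per line, UTF-8; blank lines and lines starting with `#` are
#' ignored.
#'
#' @param path path to the lexicon file.
#' @return a `checkup_lexicon`.
#' @export
load_lexicon <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  risk_lexicon(lines[nzchar(lines) & !startsWith(lines, "#")])
}

#' Assess instrument-driven risk
#'
#' Emits a `severe_anxiety` event when the GAD-7 category is "severe", a
#' `severe_depression` event when the PHQ-9 category is "severe", and a
#' `suicide_item` event when the PHQ-9 self-harm item was answered above 0 —
#' the item-level rule fires regardless of the total (a respondent can score
#' "none" overall and still endorse the item). Severity events are elevated
#' tier unless they co-occur with a suicide-item event, in which case the
#' whole batch is urgent. Risk events never alter scores or categories.
#'
#' @param scores named list of `checkup_score` objects keyed by instrument id.
#' @param answers named integer answer vector (for the item-level rule).
#' @param config risk configuration (see [checkup_script()]); defaults to the
#'   bundled settings.
#' @param now event timestamp.
#' @return list of risk events (possibly empty).
#' @export
assess_risk <- function(scores, answers, config = default_risk(),
                        now = Sys.time()) {
  events <- list()
  severe <- config$severe %||% list()
  trigger_name <- c(gad7 = "severe_anxiety", phq9 = "severe_depression")
  for (id in names(severe)) {
    sc <- scores[[id]]
    if (!is.null(sc) && identical(sc$category, severe[[id]])) {
      trg <- trigger_name[id]
      if (is.na(trg)) trg <- paste0("severe_", id)
      events[[length(events) + 1L]] <-
        risk_event(unname(trg), sprintf("%s:%s", id, sc$category), "elevated", now)
    }
  }
  si <- config$suicide_item
  if (!is.null(si) && !is.null(scores[[si$instrument]])) {
    v <- answers[si$item]
    if (!is.na(v) && v > 0L)
      events[[length(events) + 1L]] <-
        risk_event("suicide_item", sprintf("%s:%s", si$instrument, si$item),
                   "urgent", now)
  }
  urgent <- any(vapply(events, function(e) e$trigger == "suicide_item", NA))
  if (isTRUE(urgent))
    events <- lapply(events, function(e) { e$severity_tier <- "urgent"; e })
  events
}

#' Scan free text for risk key phrases
#'
#' Normalized substring matching: both the text and the lexicon phrases are
#' case-folded and stripped of diacritics, so a phrase matches regardless of
#' capitalization or accents. A match yields an urgent keyword event whose
#' source is a hash of the snippet (the text itself is never stored).
#'
#' @param text free text typed by the user.
#' @param lexicon a `checkup_lexicon`.
#' @param now event timestamp.
#' @return a risk event, or `NULL` when nothing matches (including for empty
#'   text or an empty lexicon).
#' @export
scan_free_text <- function(text, lexicon, now = Sys.time()) {
  if (is.null(text) || !nzchar(trimws(text)) || !length(lexicon$phrases))
    return(NULL)
  norm <- normalize_text(text)
  for (p in lexicon$phrases)
    if (grepl(p, norm, fixed = TRUE))
      return(risk_event("keyword", sprintf("text:%s", text_hash(text)),
                        "urgent", now))
  NULL
}

#' The referral message flow for a risk event
#'
#' Urgent events (suicide item, keyword match, or severity co-occurring with
#' either) get the emergency-services message first, then the care-network
#' referral; elevated events get the care-network referral alone.
#' Simultaneous events produce a single merged flow at the highest tier.
#'
#' @param events a risk event or list of risk events.
#' @param script the `checkup_script` (source of the referral messages).
#' @return ordered character vector of referral messages.
#' @export
safety_flow <- function(events, script) {
  if (inherits(events, "checkup_risk_event")) events <- list(events)
  if (!length(events)) return(character())
  tiers <- vapply(events, `[[`, "", "severity_tier")
  msgs <- script$risk$messages %||% default_risk()$messages
  if (any(tiers == "urgent")) c(msgs$emergency, msgs$care_network)
  else msgs$care_network
}

## Append new risk events to a session (deduplicated by trigger + source)
## and, if any are new, append the referral flow to the transcript. The
## assessment resumes afterwards unless the script says to halt.
record_risk_events <- function(session, script, events, now) {
  if (!length(events)) return(session)
  seen <- vapply(session$risk_events,
                 function(e) paste(e$trigger, e$source), "")
  new <- Filter(function(e) !(paste(e$trigger, e$source) %in% seen), events)
  if (!length(new)) return(session)
  session$risk_events <- c(session$risk_events, new)
  flow <- safety_flow(new, script)
  session <- add_event(session, "bot", "risk_referral",
                       list(messages = flow,
                            triggers = vapply(new, `[[`, "", "trigger")),
                       now)
  if (isTRUE(script$risk$halt_on_urgent) &&
      any(vapply(new, `[[`, "", "severity_tier") == "urgent")) {
    session$halted <- TRUE  # stays in_progress; the 24-hour rule will reset it
    session <- add_event(session, "bot", "message",
                         list(text = "The checkup was paused by the safety protocol."),
                         now)
  }
  session
}

#' @export
print.checkup_risk_event <- function(x, ...) {
  cat(sprintf("<risk_event> %s (%s) from %s at %s\n", x$trigger,
              x$severity_tier, x$source, format_utc(x$timestamp)))
  invisible(x)
}
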