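## Conversation engine: a deterministic state machine over a checkup script.
##
## The cursor is fully derived from the answer map: because skipping is
## impossible, the answers of a live session are always exactly the first k
## items of the currently-included item sequence, so "position" is just
## length(answers) + 1. This makes every operation a pure function of
## (script, answers, timestamps) and gives determinism for free.

as_now <- function(now) {
  if (inherits(now, "POSIXct")) now else parse_utc(now)
}

branch_rule_for <- function(script, section_id) {
  for (r in script$branch_rules)
    if (r$target_section == section_id) return(r)
  NULL
}

## Section ids included given the current answers. Conditional sections with
## an unanswered predicate source are "pending": excluded from navigation,
## but counted in the progress denominator when `pending = TRUE` so that
## progress never decreases when a branch triggers.
included_section_ids <- function(script, answers, pending = FALSE) {
  ids <- character()
  for (sec in script$sections) {
    if (!sec$conditional) {
      ids <- c(ids, sec$id)
      next
    }
    rule <- branch_rule_for(script, sec$id)
    if (is.null(rule)) next  # unreachable conditional section
    v <- answers[rule$item_id]
    if (is.na(v)) {
      if (pending) ids <- c(ids, sec$id)
    } else if (v != rule$excluded_value) {
      ids <- c(ids, sec$id)
    }
  }
  ids
}

#' Evaluate branch rules
#'
#' Pure function of the answer map: returns the conditional sections that are
#' included given the answers so far. A rule whose source item is not yet
#' answered is deferred (its target is not included).
#'
#' @param script a `checkup_script`.
#' @param answers named integer vector of answers keyed by item id.
#' @return character vector of included conditional section ids.
#' @export
evaluate_branches <- function(script, answers) {
  inc <- included_section_ids(script, answers)
  cond <- vapply(script$sections, function(s) s$conditional, NA)
  intersect(inc, vapply(script$sections, `[[`, "", "id")[cond])
}

## Ordered item sequence over currently-included sections, as parallel
## vectors (this sits on the hot path of every engine operation). Memoized
## per script and inclusion set.
item_seq <- function(script, answers) {
  inc <- included_section_ids(script, answers)
  cache <- attr(script, "cache")
  key <- paste(inc, collapse = "|")
  if (!is.null(cache)) {
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
  }
  seq <- build_item_seq(script, inc)
  if (!is.null(cache)) cache[[key]] <- seq
  seq
}

build_item_seq <- function(script, inc) {
  section_id <- instrument_id <- item_id <- character()
  idx <- n_sec <- integer()
  for (sec in script$sections) {
    if (!sec$id %in% inc) next
    ins <- script$instruments[[sec$instrument_id]]
    n <- n_items(ins)
    section_id <- c(section_id, rep.int(sec$id, n))
    instrument_id <- c(instrument_id, rep.int(ins$id, n))
    item_id <- c(item_id, item_ids(ins))
    idx <- c(idx, seq_len(n))
    n_sec <- c(n_sec, rep.int(n, n))
  }
  list(section_id = section_id, instrument_id = instrument_id,
       item_id = item_id, idx = idx, n_sec = n_sec,
       n = length(item_id))
}

new_token <- function() sprintf("u%08x", sample.int(.Machine$integer.max, 1L))

add_event <- function(session, actor, kind, payload, now) {
  now <- as_now(now)
  if (length(session$transcript)) {
    last <- session$transcript[[length(session$transcript)]]$timestamp
    if (now <= last) now <- last + 0.001  # keep timestamps strictly increasing
  }
  session$transcript[[length(session$transcript) + 1L]] <-
    list(timestamp = now, actor = actor, kind = kind, payload = payload)
  session
}

#' Start a checkup session
#'
#' Registration gate: requires consent to the terms and a non-empty company
#' code, and rejects a token that already exists in the store (duplicates are
#' impossible by construction). The 24-hour expiry clock starts here.
#'
#' @param script a `checkup_script`.
#' @param company_code the organization's registration code.
#' @param consent logical; must be `TRUE`.
#' @param now session start time (POSIXct, or a string parsed as UTC).
#' @param token anonymous session key; generated when omitted. No personal
#'   identifiers are ever stored.
#' @param group_label reporting group (e.g. a department), default `"all"`.
#' @param existing_tokens tokens already registered in the store.
#' @return an object of class `checkup_session` with status `"in_progress"`.
#' @export
start_session <- function(script, company_code, consent, now = Sys.time(),
                          token = NULL, group_label = "all",
                          existing_tokens = character()) {
  if (!isTRUE(consent))
    stop_checkup("checkup_consent_error",
                 paste0("consent is required before the checkup can start.\n",
                        script$terms_text))
  if (is.null(company_code) || !nzchar(trimws(company_code)))
    stop_checkup("checkup_registration_error", "a company code is required to register")
  token <- token %||% new_token()
  if (token %in% existing_tokens)
    stop_checkup("checkup_registration_error",
                 sprintf("token '%s' is already registered; duplicates are not allowed", token))
  now <- as_now(now)
  session <- structure(
    list(token = token, company_code = as.character(company_code),
         consented = TRUE, group_label = as.character(group_label),
         started_at = now, updated_at = now, completed_at = NULL,
         status = "in_progress",
         answers = stats::setNames(integer(), character()),
         scores = list(), risk_events = list(), transcript = list(),
         feedback = NULL, can_go_back = FALSE),
    class = "checkup_session")
  session <- add_event(session, "bot", "message", list(text = script$terms_text), now)
  add_event(session, "user", "answer", list(item_id = ".consent", value = 1L), now)
}

encouragement_message <- function(script, descriptor) {
  for (e in script$encouragement)
    if (identical(e$at, descriptor)) return(e$message)
  NULL
}

#' The next prompt of a session
#'
#' Deterministic function of (script, answers): returns the current question
#' together with any messages due before it (section introductions and
#' configured encouragement). The prompt `kind` reflects the leading content:
#' `"section_intro"` when a section introduction is due, `"encouragement"`
#' when only an encouragement message is due, otherwise `"question"`.
#'
#' @param session a live `checkup_session`.
#' @param script the `checkup_script` the session runs on.
#' @return an object of class `checkup_prompt` with fields `kind`,
#'   `section_id`, `instrument_id`, `item_id`, `question`, `options`,
#'   `option_labels`, `preamble` and `progress`. Calling this on a completed
#'   or expired session is a state error.
#' @export
next_prompt <- function(session, script) {
  if (session$status != "in_progress")
    stop_checkup("checkup_state_error",
                 sprintf("session is %s; no further prompts", session$status))
  if (isTRUE(session$halted))
    stop_checkup("checkup_state_error",
                 "session was halted by the safety protocol")
  seq <- item_seq(script, session$answers)
  pos <- length(session$answers) + 1L
  if (pos > seq$n)
    stop_checkup("checkup_state_error", "no prompt pending")  # not reachable
  sec <- section_by_id(script, seq$section_id[pos])
  ins <- script$instruments[[seq$instrument_id[pos]]]
  item <- ins$items[[seq$idx[pos]]]

  preamble <- character()
  kind <- "question"
  if (pos > 1L && seq$section_id[pos - 1L] != seq$section_id[pos]) {
    m <- encouragement_message(script, paste0("section_end:", seq$section_id[pos - 1L]))
    if (!is.null(m)) {
      preamble <- c(preamble, m)
      kind <- "encouragement"
    }
  }
  if (seq$idx[pos] == 1L && length(sec$intro_messages)) {
    preamble <- c(preamble, sec$intro_messages)
    kind <- "section_intro"
  }
  if (seq$idx[pos] == floor(seq$n_sec[pos] / 2) + 1L && seq$n_sec[pos] >= 2L) {
    m <- encouragement_message(script, paste0("midpoint:", seq$instrument_id[pos]))
    if (!is.null(m)) {
      preamble <- c(preamble, m)
      if (kind == "question") kind <- "encouragement"
    }
  }
  structure(
    list(kind = kind, section_id = seq$section_id[pos],
         instrument_id = seq$instrument_id[pos], item_id = seq$item_id[pos],
         question = item$text, options = item$values,
         option_labels = item$labels, preamble = preamble,
         progress = progress(session, script)$fraction),
    class = "checkup_prompt")
}

## Drop answers (and cached scores) of sections that are no longer included,
## e.g. after the branch source changed on back-navigation.
drop_excluded_answers <- function(session, script) {
  seq <- item_seq(script, session$answers)
  keep <- names(session$answers) %in% seq$item_id
  if (!all(keep)) {
    dropped <- names(session$answers)[!keep]
    session$answers <- session$answers[keep]
    for (ins in script$instruments)
      if (any(dropped %in% item_ids(ins))) session$scores[[ins$id]] <- NULL
  }
  session
}

score_section <- function(session, script, instrument_id, now) {
  ins <- script$instruments[[instrument_id]]
  ans <- session$answers[item_ids(ins)]
  sc <- score_instrument(ins, ans)
  session$scores[[ins$id]] <- sc
  events <- assess_risk(session$scores, session$answers, script$risk, now = now)
  session <- record_risk_events(session, script, events, now)
  session
}

#' Submit an answer
#'
#' Records the answer for the current item and advances the cursor. There is
#' no way to skip: only the current item can be answered, and an illegal
#' option value raises a re-prompt error (of class `checkup_answer_error`)
#' without changing the session. Completing an instrument triggers scoring
#' and the risk checks; answering the final item completes the session and
#' attaches the personalized feedback.
#'
#' @param session a live `checkup_session`.
#' @param script the `checkup_script` the session runs on.
#' @param value integer option value for the current item.
#' @param now current time; the 24-hour expiry rule is applied first.
#' @return the updated session.
#' @export
submit_answer <- function(session, script, value, now = Sys.time()) {
  now <- as_now(now)
  session <- check_expiry(session, now)
  if (session$status != "in_progress")
    stop_checkup("checkup_state_error",
                 sprintf("cannot answer: session is %s", session$status))
  seq <- item_seq(script, session$answers)
  pos <- length(session$answers) + 1L
  ins <- script$instruments[[seq$instrument_id[pos]]]
  item <- ins$items[[seq$idx[pos]]]
  value <- suppressWarnings(as.integer(value))
  if (length(value) != 1L || is.na(value) || !value %in% item$values)
    stop_checkup("checkup_answer_error",
                 sprintf("item '%s': please choose one of the listed options (%d-%d)",
                         item$id, min(item$values), max(item$values)))

  session <- add_event(session, "bot", "question", list(item_id = item$id), now)
  session <- add_event(session, "user", "answer",
                       list(item_id = item$id, value = value), now)
  session$answers[item$id] <- value
  session$updated_at <- now
  session$can_go_back <- TRUE

  if (seq$idx[pos] == seq$n_sec[pos])
    session <- score_section(session, script, seq$instrument_id[pos], now)
  session <- drop_excluded_answers(session, script)

  seq2 <- item_seq(script, session$answers)
  if (length(session$answers) == seq2$n) {
    session$status <- "completed"
    session$completed_at <- now
    session$feedback <- personal_feedback(session$scores, script$feedback)
    session <- add_event(session, "bot", "message",
                         list(text = session$feedback), now)
  }
  session
}

#' Step back to the previous answer
#'
#' Returns the cursor to the immediately preceding answered item and clears
#' its stored answer so it can be answered again. Only a single step is
#' allowed: a second consecutive call (or a call before anything was
#' answered) is a no-op carrying a `"notice"` attribute. If the cleared item
#' is a branch source, the branch is re-evaluated after the re-answer and
#' answers in sections whose inclusion changed are dropped.
#'
#' @param session a live `checkup_session`.
#' @param script the `checkup_script` the session runs on.
#' @return the updated session.
#' @export
go_back <- function(session, script) {
  if (session$status != "in_progress")
    stop_checkup("checkup_state_error",
                 sprintf("cannot go back: session is %s", session$status))
  if (length(session$answers) == 0L || !isTRUE(session$can_go_back)) {
    attr(session, "notice") <- "nothing to go back to"
    return(session)
  }
  last_id <- names(session$answers)[length(session$answers)]
  session$answers <- session$answers[-length(session$answers)]
  for (ins in script$instruments)
    if (last_id %in% item_ids(ins)) session$scores[[ins$id]] <- NULL
  session <- drop_excluded_answers(session, script)
  session$can_go_back <- FALSE
  attr(session, "notice") <- NULL
  session
}

#' Apply the 24-hour reset rule
#'
#' An in-progress session older than 24 hours (strictly) expires: its status
#' becomes `"expired"` and all answers, scores, risk events, feedback and
#' transcript entries are erased — only the anonymous registration (token,
#' company code, start time) survives, so a restart creates a fresh session.
#' Completed sessions are immune; the boundary case of exactly 24 hours is
#' retained.
#'
#' @param session a `checkup_session`.
#' @param now current time.
#' @return the (possibly expired) session.
#' @export
check_expiry <- function(session, now = Sys.time()) {
  now <- as_now(now)
  if (session$status != "in_progress") return(session)
  age <- as.numeric(difftime(now, session$started_at, units = "secs"))
  if (age > 24 * 3600) {
    session$status <- "expired"
    session$answers <- stats::setNames(integer(), character())
    session$scores <- list()
    session$risk_events <- list()
    session$feedback <- NULL
    session$transcript <- list()
    session$can_go_back <- FALSE
    session <- add_event(session, "bot", "message",
                         list(text = "The 24-hour limit has passed; the checkup was reset and your answers were erased."),
                         now)
    session$updated_at <- now
  }
  session
}

#' Session progress
#'
#' Fraction of answered items over all items of the currently-relevant
#' sections, plus a revealed flag per section (a section is revealed once all
#' of its items are answered — the metaphor being that more of the iceberg
#' becomes visible as the expedition advances). A conditional section whose
#' trigger is still unanswered counts in the denominator, and one whose
#' trigger excluded it does not, so progress never decreases on a forward
#' move; back-navigation is the only operation that may reduce it.
#'
#' @param session a `checkup_session`.
#' @param script the `checkup_script` the session runs on.
#' @return `list(fraction, revealed)`; `fraction` is in `[0, 1]` and is
#'   exactly 1 at completion.
#' @export
progress <- function(session, script) {
  inc_denom <- included_section_ids(script, session$answers, pending = TRUE)
  denom <- sum(vapply(script$sections, function(sec) {
    if (sec$id %in% inc_denom) n_items(script$instruments[[sec$instrument_id]]) else 0L
  }, 0L))
  answered <- length(session$answers)
  seq <- item_seq(script, session$answers)
  revealed <- vapply(script$sections, function(sec) {
    ids <- seq$item_id[seq$section_id == sec$id]
    length(ids) > 0L && all(ids %in% names(session$answers))
  }, NA)
  names(revealed) <- vapply(script$sections, `[[`, "", "id")
  revealed <- revealed[vapply(script$sections, `[[`, "", "id") %in% seq$section_id]
  list(fraction = if (denom == 0L) 0 else answered / denom, revealed = revealed)
}

#' Hand free text to the safety scanner
#'
#' Free text typed at any prompt is not an answer: it is scanned against the
#' risk lexicon and, on a match, the safety flow is appended to the
#' transcript; the current question is then simply re-presented (the cursor
#' does not move).
#'
#' @param session a live `checkup_session`.
#' @param script the `checkup_script` the session runs on.
#' @param text the free text typed by the user.
#' @param now current time.
#' @return the updated session.
#' @export
submit_free_text <- function(session, script, text, now = Sys.time()) {
  now <- as_now(now)
  session <- check_expiry(session, now)
  if (session$status != "in_progress")
    stop_checkup("checkup_state_error",
                 sprintf("session is %s", session$status))
  session <- add_event(session, "user", "free_text",
                       list(hash = text_hash(text)), now)
  lex <- risk_lexicon(script$risk$lexicon %||% character())
  ev <- scan_free_text(text, lex, now = now)
  if (!is.null(ev))
    session <- record_risk_events(session, script, list(ev), now)
  session
}

#' @export
print.checkup_session <- function(x, ...) {
  cat(sprintf("<checkup_session> %s [%s] %s: %d answer(s), %d score(s), %d risk event(s)\n",
              x$token, x$company_code, x$status, length(x$answers),
              length(x$scores), length(x$risk_events)))
  invisible(x)
}

#' @export
print.checkup_prompt <- function(x, ...) {
  for (m in x$preamble) cat(sprintf("[bot] %s\n", m))
  cat(sprintf("[bot] %s\n", x$question))
  labs <- x$option_labels %||% as.character(x$options)
  cat(paste(sprintf("  (%d) %s", x$options, labs), collapse = "\n"), "\n")
  invisible(x)
}
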