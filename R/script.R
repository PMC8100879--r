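## Checkup script: the structured configuration binding instruments, story
## sections, branch rules, messages, risk settings and report settings into
## one deliverable flow. Scripts are plain YAML files; the bundled default
## reproduces the published six-instrument checkup.

frequency_labels <- c("Not at all", "Several days",
                      "More than half the days", "Nearly every day")
applied_labels <- c("Did not apply to me at all",
                    "Applied to me to some degree",
                    "Applied to me to a considerable degree",
                    "Applied to me very much")
agree_labels <- c("Strongly agree", "Agree", "Disagree", "Strongly disagree")
often_labels <- c("Almost never", "Rarely", "Sometimes", "Frequently")

#' Define a story section
#'
#' @param id section identifier; the canonical ids are `stress`, `anxiety`,
#'   `depression`, `insomnia`, `burnout`, `work_stress`.
#' @param instrument_id id of the instrument the section delivers.
#' @param intro_messages character vector of introduction messages.
#' @param conditional logical; conditional sections are delivered only when a
#'   branch rule includes them.
#' @return an object of class `checkup_section`.
#' @export
checkup_section <- function(id, instrument_id, intro_messages = character(),
                            conditional = FALSE) {
  structure(list(id = as.character(id),
                 instrument_id = as.character(instrument_id),
                 intro_messages = as.character(intro_messages),
                 conditional = isTRUE(conditional)),
            class = "checkup_section")
}

#' Define a branch rule
#'
#' A conditional section is included if and only if the referenced item was
#' answered with anything other than `excluded_value` (the insomnia block is
#' added for respondents who did not answer the PHQ-9 sleep item with
#' "Not at all").
#'
#' @param target_section id of the conditional section to include.
#' @param instrument_id,item_id the earlier item the predicate reads.
#' @param excluded_value the one option value that keeps the section out.
#' @return an object of class `checkup_branch_rule`.
#' @export
branch_rule <- function(target_section, instrument_id, item_id,
                        excluded_value = 0L) {
  structure(list(target_section = as.character(target_section),
                 instrument_id = as.character(instrument_id),
                 item_id = as.character(item_id),
                 excluded_value = as.integer(excluded_value)),
            class = "checkup_branch_rule")
}

#' Assemble a checkup script
#'
#' @param sections ordered list of [checkup_section()] objects.
#' @param instruments named list of [checkup_instrument()] objects keyed by id.
#' @param branch_rules list of [branch_rule()] objects.
#' @param encouragement list of `list(at, message)` records; `at` is a
#'   position descriptor, either `"section_end:<section id>"` (delivered after
#'   the last item of that section) or `"midpoint:<instrument id>"` (delivered
#'   before the item following the instrument's midpoint).
#' @param terms_text the terms-and-conditions text shown before consent.
#' @param feedback feedback configuration: `templates` (instrument ->
#'   category label -> message), `disclaimer`, `care_recommendation`,
#'   `care_categories` (instrument -> labels that add the care block).
#' @param risk risk configuration: `severe` (instrument -> category label that
#'   raises an elevated severity event), `suicide_item`
#'   (`list(instrument, item)`), `messages` (`emergency`, `care_network`),
#'   `halt_on_urgent`, `lexicon` (character vector of key phrases).
#' @param report report configuration: `k` (minimum reported group size).
#' @param version script format version.
#' @return an object of class `checkup_script`.
#' @export
checkup_script <- function(sections, instruments, branch_rules = list(),
                           encouragement = list(), terms_text = "",
                           feedback = list(), risk = list(),
                           report = list(k = 8L), version = 1L) {
  structure(list(version = as.integer(version), sections = sections,
                 instruments = instruments, branch_rules = branch_rules,
                 encouragement = encouragement, terms_text = terms_text,
                 feedback = feedback, risk = risk, report = report),
            class = "checkup_script",
            # item-sequence memo; scripts are treated as immutable once built
            cache = new.env(parent = emptyenv()))
}

script_instrument <- function(script, id) {
  ins <- script$instruments[[id]]
  if (is.null(ins))
    stop_checkup("checkup_validation_error",
                 sprintf("unknown instrument '%s'", id))
  ins
}

section_by_id <- function(script, id) {
  for (sec in script$sections) if (sec$id == id) return(sec)
  NULL
}

## ---- default script -------------------------------------------------------

default_gad7 <- function() {
  texts <- c(
    "Feeling nervous, anxious, or on edge",
    "Not being able to stop or control worrying",
    "Worrying too much about different things",
    "Trouble relaxing",
    "Being so restless that it is hard to sit still",
    "Becoming easily annoyed or irritable",
    "Feeling afraid as if something awful might happen")
  items <- lapply(seq_along(texts), function(i)
    checkup_item(sprintf("gad7_%d", i), texts[i], 0:3, frequency_labels))
  checkup_instrument("gad7", items, "identity", list(
    category_band("none", 0, 4), category_band("mild", 5, 9),
    category_band("moderate", 10, 14), category_band("severe", 15, Inf)))
}

default_phq9 <- function() {
  texts <- c(
    "Little interest or pleasure in doing things",
    "Feeling down, depressed, or hopeless",
    "Trouble falling or staying asleep, or sleeping too much",
    "Feeling tired or having little energy",
    "Poor appetite or overeating",
    "Feeling bad about yourself, or that you are a failure",
    "Trouble concentrating on things",
    "Moving or speaking slowly, or being fidgety or restless",
    "Thoughts that you would be better off dead or of hurting yourself")
  items <- lapply(seq_along(texts), function(i)
    checkup_item(sprintf("phq9_%d", i), texts[i], 0:3, frequency_labels))
  checkup_instrument("phq9", items, "identity", list(
    category_band("none", 0, 4), category_band("mild", 5, 9),
    category_band("moderate", 10, 14),
    category_band("moderately severe", 15, 19),
    category_band("severe", 20, Inf)))
}

default_dass21_stress <- function() {
  texts <- c(
    "I found it hard to wind down",
    "I tended to over-react to situations",
    "I felt that I was using a lot of nervous energy",
    "I found myself getting agitated",
    "I found it difficult to relax",
    "I was intolerant of anything that kept me from getting on with what I was doing",
    "I felt that I was rather touchy")
  items <- lapply(seq_along(texts), function(i)
    checkup_item(sprintf("dass_s%d", i), texts[i], 0:3, applied_labels))
  checkup_instrument("dass21_stress", items, "double", list(
    category_band("normal", 0, 14), category_band("mild", 15, 18),
    category_band("moderate", 19, 25), category_band("severe", 26, 33),
    category_band("extremely severe", 34, Inf)))
}

default_isi <- function() {
  texts <- c(
    "Difficulty falling asleep",
    "Difficulty staying asleep",
    "Problems waking up too early",
    "How dissatisfied are you with your current sleep pattern?",
    "How much does your sleep problem interfere with your daily functioning?",
    "How noticeable to others do you think your sleep problem is?",
    "How worried are you about your current sleep problem?")
  labels <- c("None", "Mild", "Moderate", "Severe", "Very severe")
  items <- lapply(seq_along(texts), function(i)
    checkup_item(sprintf("isi_%d", i), texts[i], 0:4, labels))
  checkup_instrument("isi", items, "identity", list(
    category_band("absence", 0, 7), category_band("subthreshold", 8, 14),
    category_band("moderate", 15, 21), category_band("severe", 22, Inf)))
}

## Negatively-worded items are reverse-keyed: with anchors running from
## 1 = strongly agree to 4 = strongly disagree, endorsing an exhaustion
## statement yields a low raw value, so reversing those items makes higher
## totals mean higher burnout risk throughout.
default_olbi <- function() {
  def <- list(
    list("There are days when I feel tired before I arrive at work", "exhaustion", TRUE),
    list("After work, I need more time than in the past to relax and feel better", "exhaustion", TRUE),
    list("I can tolerate the pressure of my work very well", "exhaustion", FALSE),
    list("During my work, I often feel emotionally drained", "exhaustion", TRUE),
    list("After working, I have enough energy for my leisure activities", "exhaustion", FALSE),
    list("After my work, I usually feel worn out and weary", "exhaustion", TRUE),
    list("Usually, I can manage the amount of my work well", "exhaustion", FALSE),
    list("When I work, I usually feel energized", "exhaustion", FALSE),
    list("I always find new and interesting aspects in my work", "disengagement", FALSE),
    list("It happens more and more often that I talk about my work in a negative way", "disengagement", TRUE),
    list("Lately, I tend to think less at work and do my job almost mechanically", "disengagement", TRUE),
    list("I find my work to be a positive challenge", "disengagement", FALSE),
    list("Over time, one can become disconnected from this type of work", "disengagement", TRUE),
    list("Sometimes I feel sickened by my work tasks", "disengagement", TRUE),
    list("This is the only type of work that I can imagine myself doing", "disengagement", FALSE),
    list("I feel more and more engaged in my work", "disengagement", FALSE))
  items <- lapply(seq_along(def), function(i)
    checkup_item(sprintf("olbi_%d", i), def[[i]][[1]], 1:4, agree_labels,
                 reverse = def[[i]][[3]], subscale = def[[i]][[2]]))
  checkup_instrument("olbi", items, "identity", list(
    category_band("very low", 0, 15), category_band("low", 16, 30),
    category_band("high", 31, 45), category_band("very high", 46, Inf)),
    subscales = c("exhaustion", "disengagement"))
}

## Demand items straight; control items reverse-keyed (frequent control is
## protective); support statements are anchored totally agree = 1, so
## disagreement already signals low support, i.e. higher risk.
default_jss <- function() {
  def <- list(
    list("Do you have to work very fast?", "demand", FALSE),
    list("Do you have to work very intensively?", "demand", FALSE),
    list("Does your work demand too much effort?", "demand", FALSE),
    list("Do you have enough time to do everything?", "demand", TRUE),
    list("Does your work often involve conflicting demands?", "demand", FALSE),
    list("Do you have the possibility of learning new things through your work?", "control", TRUE),
    list("Does your work demand a high level of skill or expertise?", "control", TRUE),
    list("Does your job require you to take the initiative?", "control", TRUE),
    list("Do you have a choice in deciding how you do your work?", "control", TRUE),
    list("Do you have a choice in deciding what you do at work?", "control", TRUE),
    list("There is a calm and pleasant atmosphere where I work", "support", FALSE),
    list("We get on well with each other where I work", "support", FALSE),
    list("My co-workers support me", "support", FALSE),
    list("People understand if I have a bad day", "support", FALSE),
    list("I get on well with my superiors", "support", FALSE))
  items <- lapply(seq_along(def), function(i)
    checkup_item(sprintf("jss_%d", i), def[[i]][[1]], 1:4, often_labels,
                 reverse = def[[i]][[3]], subscale = def[[i]][[2]]))
  checkup_instrument("jss", items, "identity", list(
    category_band("normal", 0, 15), category_band("slightly increased", 16, 30),
    category_band("increased", 31, 45),
    category_band("extremely increased", 46, Inf)),
    subscales = c("demand", "control", "support"))
}

#' The six canonical instrument definitions
#'
#' @return a named list of [checkup_instrument()] objects: `gad7`, `phq9`,
#'   `dass21_stress`, `isi`, `olbi`, `jss`.
#' @export
default_instruments <- function() {
  ins <- list(default_gad7(), default_phq9(), default_dass21_stress(),
              default_isi(), default_olbi(), default_jss())
  stats::setNames(ins, vapply(ins, `[[`, "", "id"))
}

default_feedback <- function(instruments) {
  tier <- function(label) {
    low <- c("none", "normal", "absence", "very low")
    mid <- c("mild", "subthreshold", "low", "slightly increased")
    if (label %in% low)
      "Your answers in this area suggest no sign of difficulty at the moment."
    else if (label %in% mid)
      "Your answers suggest some mild difficulty in this area; keeping an eye on it and simple self-care can help."
    else
      "Your answers suggest a meaningful level of difficulty in this area."
  }
  topic <- c(gad7 = "anxiety", phq9 = "mood", dass21_stress = "stress",
             isi = "sleep", olbi = "burnout", jss = "work-related stress")
  templates <- lapply(instruments, function(ins) {
    labs <- vapply(ins$bands, `[[`, "", "label")
    msgs <- vapply(labs, function(l)
      sprintf("About %s (%s): %s", topic[[ins$id]], l, tier(l)), "")
    as.list(stats::setNames(msgs, labs))
  })
  list(
    templates = templates,
    disclaimer = paste("Remember: these results do not offer a diagnosis,",
                       "but they may indicate the presence of an emotional",
                       "problem worth discussing with a professional."),
    care_recommendation = paste("Given your answers, we recommend reaching",
                                "out to the care network available to you",
                                "for further support."),
    care_categories = list(
      gad7 = "severe", phq9 = c("moderately severe", "severe"),
      dass21_stress = c("severe", "extremely severe"), isi = "severe",
      olbi = "very high", jss = "extremely increased")
  )
}

default_risk <- function() {
  list(
    severe = list(gad7 = "severe", phq9 = "severe"),
    suicide_item = list(instrument = "phq9", item = "phq9_9"),
    halt_on_urgent = FALSE,
    messages = list(
      emergency = paste("If you feel you may be in danger or are thinking",
                        "about hurting yourself, please contact emergency",
                        "services or a crisis line right now."),
      care_network = paste("Support is available: we recommend contacting",
                           "the care network so a professional can talk",
                           "things through with you.")),
    ## Placeholder key-phrase list; deployments supply their own lexicon.
    lexicon = c("quero morrer", "me matar", "suicidio", "tirar minha vida",
                "nao aguento mais viver", "kill myself", "end my life",
                "want to die")
  )
}

build_default_script <- function() {
  instruments <- default_instruments()
  sections <- list(
    checkup_section("stress", "dass21_stress", c(
      "Our first stop on the expedition is stress.",
      "Over the last week, how much did each statement apply to you?")),
    checkup_section("anxiety", "gad7", c(
      "Next we look at anxiety.",
      "Over the last 2 weeks, how often have you been bothered by the following?")),
    checkup_section("depression", "phq9", c(
      "Now a few questions about your mood.",
      "Over the last 2 weeks, how often have you been bothered by the following?")),
    checkup_section("insomnia", "isi", c(
      "You mentioned some difficulty with sleep, so let's take a closer look.",
      "Please rate your sleep over the last 2 weeks."), conditional = TRUE),
    checkup_section("burnout", "olbi", c(
      "We are getting closer to the end. The next topic is burnout.",
      "How much do you agree with each statement about your work?")),
    checkup_section("work_stress", "jss", c(
      "Last topic: how your work is organized.",
      "Please answer thinking about your current job."))
  )
  rules <- list(branch_rule("insomnia", "phq9", "phq9_3", excluded_value = 0L))
  cheer <- list(
    list(at = "section_end:stress",
         message = "Great start! The first part of the iceberg is visible."),
    list(at = "section_end:anxiety",
         message = "Well done, another section complete."),
    list(at = "section_end:depression",
         message = "You are doing great, keep going!"),
    list(at = "section_end:insomnia",
         message = "Thanks for telling us about your sleep."),
    list(at = "section_end:burnout",
         message = "Almost there, only one topic left!"),
    list(at = "midpoint:phq9",
         message = "Halfway through this section, keep it up!"),
    list(at = "midpoint:olbi",
         message = "You are doing very well, just a few more statements."),
    list(at = "midpoint:jss",
         message = "We are almost done, you are doing very well!")
  )
  checkup_script(
    sections = sections, instruments = instruments, branch_rules = rules,
    encouragement = cheer,
    terms_text = paste("This checkup is anonymous and voluntary. Your answers",
                       "are shared with your organization only in aggregated,",
                       "anonymized form. If you do not finish within 24 hours",
                       "the checkup resets and your answers are erased."),
    feedback = default_feedback(instruments),
    risk = default_risk(),
    report = list(k = 8L)
  )
}

#' The bundled default checkup script
#'
#' Loads the YAML script shipped with the package: six instruments, six story
#' sections (insomnia conditional on the PHQ-9 sleep item), default
#' encouragement cadence, feedback templates, risk settings and a reporting
#' pool size of k = 8.
#'
#' @return a validated `checkup_script`.
#' @export
default_script <- function() {
  load_script(system.file("extdata", "checkup_script.yaml", package = "checkup"))
}

## ---- validation ------------------------------------------------------------

#' Validate a checkup script
#'
#' Runs [validate_instrument()] on every instrument and checks the
#' cross-cutting invariants: each section binds an existing instrument,
#' exactly one section is conditional, branch rules target conditional
#' sections and read an item delivered before the target, feedback templates
#' cover every band of every delivered instrument, risk settings reference
#' real items, and the pooling threshold is at least 1.
#'
#' @param script a `checkup_script`.
#' @return list of violation records `list(level, message)`; empty when valid.
#' @export
validate_script <- function(script) {
  out <- list()
  note <- function(level, msg) out[[length(out) + 1L]] <<- list(level = level, message = msg)

  for (ins in script$instruments)
    for (v in validate_instrument(ins))
      note(v$level, sprintf("[%s] %s", ins$id, v$message))

  sec_ids <- vapply(script$sections, `[[`, "", "id")
  if (anyDuplicated(sec_ids)) note("error", "duplicate section ids")
  cond <- vapply(script$sections, `[[`, NA, "conditional")
  if (sum(cond) != 1L)
    note("error", sprintf("expected exactly 1 conditional section, found %d", sum(cond)))
  for (sec in script$sections)
    if (is.null(script$instruments[[sec$instrument_id]]))
      note("error", sprintf("section '%s' binds unknown instrument '%s'",
                            sec$id, sec$instrument_id))

  all_items <- unlist(lapply(script$instruments, item_ids))
  for (r in script$branch_rules) {
    tgt <- section_by_id(script, r$target_section)
    if (is.null(tgt) || !tgt$conditional) {
      note("error", sprintf("branch rule targets non-conditional section '%s'",
                            r$target_section))
      next
    }
    if (!r$item_id %in% all_items) {
      note("error", sprintf("branch rule reads unknown item '%s'", r$item_id))
      next
    }
    src_pos <- which(vapply(script$sections, `[[`, "", "instrument_id") == r$instrument_id)
    tgt_pos <- which(sec_ids == r$target_section)
    if (length(src_pos) && length(tgt_pos) && src_pos >= tgt_pos)
      note("error", sprintf("branch source '%s' is not delivered before section '%s'",
                            r$item_id, r$target_section))
  }

  tpl <- script$feedback$templates
  for (sec in script$sections) {
    ins <- script$instruments[[sec$instrument_id]]
    if (is.null(ins)) next
    for (b in ins$bands) {
      if (is.null(tpl[[ins$id]][[b$label]]))
        note("error", sprintf("missing feedback template for %s category '%s'",
                              ins$id, b$label))
    }
  }
  if (is.null(script$feedback$disclaimer))
    note("error", "missing feedback disclaimer")

  si <- script$risk$suicide_item
  if (!is.null(si)) {
    ins <- script$instruments[[si$instrument]]
    if (is.null(ins) || !si$item %in% item_ids(ins))
      note("error", sprintf("risk suicide_item references unknown item '%s'",
                            si$item %||% "?"))
  }
  for (id in names(script$risk$severe %||% list())) {
    ins <- script$instruments[[id]]
    labs <- if (is.null(ins)) character() else vapply(ins$bands, `[[`, "", "label")
    if (!(script$risk$severe[[id]] %in% labs))
      note("error", sprintf("risk severe category '%s' not a band of '%s'",
                            script$risk$severe[[id]], id))
  }

  k <- script$report$k %||% 8L
  if (!is.numeric(k) || k < 1) note("error", "report k must be >= 1")

  for (e in script$encouragement) {
    at <- e$at %||% ""
    if (!grepl("^(section_end|midpoint):", at))
      note("error", sprintf("unknown encouragement position descriptor '%s'", at))
  }
  out
}

script_errors <- function(violations) {
  Filter(function(v) identical(v$level, "error"), violations)
}

## ---- YAML serialization ----------------------------------------------------

item_to_list <- function(it) {
  out <- list(id = it$id, text = it$text,
              min = min(it$values), max = max(it$values))
  if (!is.null(it$labels)) out$labels <- as.list(it$labels)
  if (it$reverse) out$reverse <- TRUE
  if (!is.null(it$subscale)) out$subscale <- it$subscale
  out
}

band_to_list <- function(b)
  list(label = b$label, lower = b$lower,
       upper = if (is.finite(b$upper)) b$upper else ".inf")

band_from_list <- function(x, where) {
  for (f in c("label", "lower", "upper"))
    if (is.null(x[[f]]))
      stop_checkup("checkup_validation_error",
                   sprintf("%s: band missing field '%s'", where, f))
  upper <- if (identical(x$upper, ".inf")) Inf else x$upper
  category_band(x$label, x$lower, upper)
}

instrument_to_list <- function(ins) {
  out <- list(id = ins$id, transform = ins$transform,
              items = lapply(ins$items, item_to_list),
              bands = lapply(ins$bands, band_to_list))
  if (!is.null(ins$subscales)) out$subscales <- as.list(ins$subscales)
  if (!is.null(ins$subscale_bands))
    out$subscale_bands <- lapply(ins$subscale_bands,
                                 function(bs) lapply(bs, band_to_list))
  out
}

known_fields <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop_checkup("checkup_validation_error",
                 sprintf("%s: unknown field(s) %s", where,
                         paste(sprintf("'%s'", bad), collapse = ", ")))
}

instrument_from_list <- function(x) {
  known_fields(x, c("id", "transform", "items", "bands", "subscales",
                    "subscale_bands"), sprintf("instrument '%s'", x$id %||% "?"))
  items <- lapply(x$items, function(it) {
    known_fields(it, c("id", "text", "min", "max", "labels", "reverse",
                       "subscale"), sprintf("item '%s'", it$id %||% "?"))
    checkup_item(it$id, it$text, seq(it$min, it$max),
                 labels = if (is.null(it$labels)) NULL else unlist(it$labels),
                 reverse = isTRUE(it$reverse), subscale = it$subscale)
  })
  sb <- NULL
  if (!is.null(x$subscale_bands))
    sb <- lapply(x$subscale_bands, function(bs)
      lapply(bs, band_from_list, where = sprintf("instrument '%s'", x$id)))
  checkup_instrument(
    x$id, items, x$transform %||% "identity",
    bands = lapply(x$bands, band_from_list, where = sprintf("instrument '%s'", x$id)),
    subscales = if (is.null(x$subscales)) NULL else unlist(x$subscales),
    subscale_bands = sb)
}

script_to_list <- function(script) {
  list(
    version = script$version,
    terms_text = script$terms_text,
    instruments = lapply(unname(script$instruments), instrument_to_list),
    sections = lapply(script$sections, function(s) {
      out <- list(id = s$id, instrument = s$instrument_id,
                  intro = as.list(s$intro_messages))
      if (s$conditional) out$conditional <- TRUE
      out
    }),
    branch_rules = lapply(script$branch_rules, function(r)
      list(target = r$target_section, instrument = r$instrument_id,
           item = r$item_id, excluded_value = r$excluded_value)),
    encouragement = script$encouragement,
    feedback = script$feedback,
    risk = script$risk,
    report = script$report
  )
}

script_from_list <- function(x) {
  known_fields(x, c("version", "terms_text", "instruments", "sections",
                    "branch_rules", "encouragement", "feedback", "risk",
                    "report"), "script")
  instruments <- lapply(x$instruments, instrument_from_list)
  instruments <- stats::setNames(instruments,
                                 vapply(instruments, `[[`, "", "id"))
  sections <- lapply(x$sections, function(s) {
    known_fields(s, c("id", "instrument", "intro", "conditional"),
                 sprintf("section '%s'", s$id %||% "?"))
    checkup_section(s$id, s$instrument, unlist(s$intro) %||% character(),
                    conditional = isTRUE(s$conditional))
  })
  rules <- lapply(x$branch_rules %||% list(), function(r)
    branch_rule(r$target, r$instrument, r$item, r$excluded_value %||% 0L))
  risk <- x$risk %||% list()
  if (!is.null(risk$lexicon)) risk$lexicon <- unlist(risk$lexicon)
  checkup_script(
    sections = sections, instruments = instruments, branch_rules = rules,
    encouragement = x$encouragement %||% list(),
    terms_text = x$terms_text %||% "",
    feedback = x$feedback %||% list(),
    risk = risk,
    report = x$report %||% list(k = 8L),
    version = x$version %||% 1L)
}

#' Load and validate a checkup script file
#'
#' @param path path to a YAML script file.
#' @return a validated `checkup_script`; parse errors propagate with the
#'   parser's line information, and validation errors (of class
#'   `checkup_validation_error`) name the offending field. Unreachable-band
#'   warnings are attached as the `"warnings"` attribute rather than
#'   rejecting the script.
#' @export
load_script <- function(path) {
  if (!file.exists(path))
    stop_checkup("checkup_usage_error", sprintf("script file not found: %s", path))
  raw <- yaml::read_yaml(path)
  script <- script_from_list(raw)
  violations <- validate_script(script)
  errs <- script_errors(violations)
  if (length(errs))
    stop_checkup("checkup_validation_error",
                 paste0("invalid script:\n",
                        paste("  -", vapply(errs, `[[`, "", "message"),
                              collapse = "\n")))
  warns <- Filter(function(v) identical(v$level, "warning"), violations)
  if (length(warns))
    attr(script, "warnings") <- vapply(warns, `[[`, "", "message")
  script
}

#' Write a checkup script to a YAML file
#'
#' @param script a `checkup_script`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_script <- function(script, path) {
  yaml::write_yaml(script_to_list(script), path)
  invisible(path)
}

#' @export
print.checkup_script <- function(x, ...) {
  cat(sprintf("<checkup_script> v%d: %d sections, %d instruments, %d branch rule(s), k=%s\n",
              x$version, length(x$sections), length(x$instruments),
              length(x$branch_rules), x$report$k %||% 8))
  for (sec in x$sections)
    cat(sprintf("  %-12s -> %-14s%s\n", sec$id, sec$instrument_id,
                if (sec$conditional) " (conditional)" else ""))
  invisible(x)
}
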