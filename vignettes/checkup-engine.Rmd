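---
title: "The checkup engine: instruments, conversation flow, and synthetic respondents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The checkup engine: instruments, conversation flow, and synthetic respondents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(checkup)
```

## What this package models

Workplace mental-health surveys fail most often at engagement: employees do
not start them, or abandon them halfway. One remedy is to deliver the
standardized screeners as a scripted chatbot conversation — one question at a
time, with encouragement messages, a story-like progress metaphor, and
immediate personalized feedback — while the organization receives only
anonymized, aggregated results. `checkup` implements that delivery engine
end to end: six validated instruments with exact scoring and severity
banding, a deterministic conversational state machine, a safety protocol for
high-risk answers, organization-level reporting with small-group pooling,
and a simulator of synthetic respondents so that every stage can be tested
without collecting real data.

## Instruments and scoring

Six screeners are bundled, all structured the same way: ordered items on a
contiguous integer option scale, optional reverse keying, a total-score
transformation, and inclusive severity bands.

| id | construct | items | scale | bands (transformed total) |
|----|-----------|-------|-------|---------------------------|
| `gad7` | anxiety | 7 | 0–3 | none 0–4, mild 5–9, moderate 10–14, severe 15+ |
| `phq9` | depression | 9 | 0–3 | none 0–4, mild 5–9, moderate 10–14, moderately severe 15–19, severe 20+ |
| `dass21_stress` | stress | 7 | 0–3 | normal 0–14, mild 15–18, moderate 19–25, severe 26–33, extremely severe 34+ |
| `isi` | insomnia | 7 | 0–4 | absence 0–7, subthreshold 8–14, moderate 15–21, severe 22–28 |
| `olbi` | burnout | 16 | 1–4 | very low 0–15, low 16–30, high 31–45, very high 46+ |
| `jss` | work stress | 15 | 1–4 | normal 0–15, slightly increased 16–30, increased 31–45, extremely increased 46+ |

Reverse keying is fixed as `min + max - value` of the item's option scale.
The DASS-21 stress subscale total is doubled before banding so that the
7-item short form aligns with the 42-item parent scale; consequently its
transformed totals are always even, and the odd band edges (15, 19, ...)
are simply never hit exactly — the bands still partition every achievable
total. `score_instrument()` returns raw and transformed totals, subscale
sums, and the unique band containing the transformed total.

Two banding quirks deserve a note, because they are properties of the
published category tables, not bugs:

* The OLBI is answered on a 1–4 agreement scale, so its 16 items can never
  sum below 16, yet its printed band table starts at 0. We score the items
  exactly as anchored and keep the printed bands; `validate_instrument()`
  emits a *warning* (not an error) that the "very low (0–15)" band is
  unreachable. This keeps the reachable categories identical to the
  published ones (a cohort mean near 28 lands in "low").
* With anchors running 1 = strongly agree … 4 = strongly disagree,
  higher-total-means-higher-risk requires reverse-keying the *negatively*
  worded OLBI items (endorsing "I feel tired before I arrive at work" must
  raise the total). The reverse set is script-configurable; the bundled
  default follows this severity-direction logic. The same reasoning gives
  the JSS defaults: demand items straight, control items reversed (frequent
  control is protective), support items straight (they are anchored
  totally-agree = 1, so disagreement already signals low support, i.e.
  risk).
* The published 15-item job-stress short form does not print its
  item-to-subscale split; the bundled script uses 5 demand / 5 control / 5
  support, and the split is configuration, not code. Subscale bands are
  likewise optional configuration and absent by default — only the
  total-score bands are always applied.

## The conversation engine

A checkup script (a YAML file; see `inst/extdata/checkup_script.yaml`)
binds the instruments to six story sections — stress, anxiety, depression,
insomnia, burnout, work-related stress — with introduction messages,
encouragement messages, branch rules, risk settings and report settings.
The published description does not pin the delivery order beyond listing
the topics, so the bundled order places insomnia immediately after
depression (its trigger lives in the depression block); the order is
script-configurable.

The engine itself is a deterministic state machine with one load-bearing
simplification: because questions cannot be skipped, a live session's
answers are always exactly the first *k* items of the currently-included
item sequence, so the cursor is derived from the answer map rather than
stored. Every operation is then a pure function of (script, answers,
timestamps), which is what makes transcript-level determinism testable.

Design choices where the behaviour was genuinely open:

* **Branching.** The insomnia block is included if and only if the sleep
  item of the depression block was answered above "Not at all"
  (`value > 0`). While the sleep item is unanswered the branch is deferred.
* **Back-navigation** is one step: the immediately preceding answer is
  cleared and re-asked. This matches a rolling chat interface, where deeper
  history editing is not meaningful. If the cleared answer was the branch
  source, inclusion is re-evaluated after the re-answer and answers in
  sections that dropped out are erased.
* **Encouragement cadence** is unspecified upstream; the default script
  places one message at each section boundary plus the midpoint of every
  instrument with nine or more items. Cadence is fully script-configurable.
* **Expiry.** The 24-hour reset clock starts at registration and the
  boundary is strict: a session is reset only when more than 24 hours have
  elapsed. Expired sessions keep their anonymous registration (token,
  company code) but lose answers, scores, risk events, feedback and
  transcript — reporting can never see an expired session's data.
* **Progress.** Progress is answered items over the items of the relevant
  sections, and the iceberg "reveals" a section when it is fully answered.
  There is a genuine tension between keeping progress monotone and letting
  the denominator track section inclusion: if a pending conditional section
  were excluded from the denominator until triggered, triggering it
  mid-session would make the fraction drop. We resolved it in favour of
  monotonicity: a conditional section counts in the denominator while its
  trigger is pending or positive, and leaves it only when explicitly
  excluded. Forward moves therefore never decrease progress; `go_back()` is
  the only operation that can.
* **Prompt delivery.** Section introductions and encouragement messages are
  delivered as the preamble of the next question prompt (the prompt's
  `kind` reflects the leading message), because the engine only advances on
  answers. End-of-checkup feedback is attached to the session by the final
  `submit_answer()`; asking for another prompt on a completed or expired
  session is a state error.
* **Free text** typed at a prompt is never an answer: it is hashed into the
  transcript, scanned against the risk lexicon, and the current question is
  re-presented. This deliberately reduces "natural language understanding"
  to a keyword safety scan; everything else in the conversation is
  predefined options.

## The safety protocol

Risk events come from four triggers: a "severe" anxiety category, a
"severe" depression category, any non-zero answer on the depression
instrument's self-harm item, and a lexicon match in free text. The
self-harm rule is item-level on purpose — a respondent can score "none"
overall and still endorse the item. Published sources name "very high risk"
without a numeric cut, so the default maps it to the top printed band of
each instrument ("moderately severe" depression does not trigger by
default; both mappings are script-configurable). Suicide-item and keyword
events are urgent; severity events are elevated unless they co-occur with a
suicide-item event, which escalates the batch. The referral flow emits the
emergency-services message first for urgent events, then the care-network
referral; elevated events get the care-network referral alone, and
simultaneous events produce one merged flow at the highest tier. The
checkup resumes afterwards unless the script sets `halt_on_urgent`. Risk
handling never modifies scores or categories. Lexicon matching case-folds
and strips diacritics on both sides (via an explicit character map, so
behaviour does not depend on the locale); the bundled phrase list is a
small placeholder — deployments supply their own.

## Reporting and anonymity

`campaign_stats()` computes initiation (started/eligible), completion
(completed/started) and response (completed/eligible) rates at full
precision; rendering rounds half-up to one decimal. Whole-percent figures
(the symptomatic breakdowns) are rendered by rounding the one-decimal
value — the convention of the organization reports this engine reproduces —
so 10/22 renders as 45.45 → 45.5 → 46%.

`aggregate_distributions()` applies k-anonymity pooling before anything
leaves the engine: any reporting group with fewer than `k = 8` completed
respondents is merged into the smallest other group, repeatedly, until
every reported group reaches `k` (ties broken by label order, for
determinism); if everything collapses into one group that is still under
`k`, it is reported as `"all"`. Pooling runs per instrument because the
insomnia block is answered by a subset. Exports carry group labels,
categories and counts — never tokens, never item-level answers.

`symptomatic_breakdown()` restricts to respondents above the instrument's
no-symptom band ("none", "normal", "absence"); that definition of
"symptomatic" is itself configuration (`baseline =`), and the burnout and
job-stress instruments default to shares among all scored respondents, as
their published summaries do. `summary_table()` reports mean, SD and the
category of the half-up-rounded mean; with one respondent the SD is
reported as 0 with a degeneracy flag.

## Synthetic respondents

The simulator exists so the pipeline's statistical behaviour can be checked
against closed forms. Each respondent carries one latent severity per
construct, drawn multivariate normal: defaults are location 0 and spread 1
per construct, pairwise correlation 0.5, raised to 0.6 between depression
and insomnia (the branch conditions on a depression item). Item responses
follow a graded-threshold model: with K options and equally spaced
thresholds at 0.5, 1.5, …, the keyed response level is the number of
thresholds below latent + standard-normal noise. These defaults were chosen
once, on the grounds that they put most item mass on the lowest options —
the shape of a predominantly healthy working population (e.g. they imply a
mean depression total around 4 of 27) — and the threshold geometry is
configurable. Reverse-keyed items emit the mirrored raw option value, which
scoring keys back, so expected totals rise with severity everywhere.

The model is chosen for tractability: at fixed severity the total's
distribution is an exact convolution of item distributions, and
`band_probabilities()` integrates it over the latent distribution on a fine
quadrature grid. Tests compare empirical category distributions from
10,000 simulated respondents per instrument against these analytic band
probabilities within three Monte-Carlo standard errors.

Engagement is memoryless: a respondent initiates with probability 0.817 and
abandons each prompt with a constant hazard, calibrated by inverting the
geometric survival curve `completion = (1 - h)^prompts` for a 78.6%
completion target over the 54 prompts of the unconditional flow
(`calibrate_dropout()`). The true dropout shape of any real campaign is
unobserved; the geometric form is an explicitly illustrative choice.
Abandoned sessions are swept past the 24-hour limit and expire, so
simulated stores contain completed and expired records just as a real
store would.

What the simulator does **not** emulate: measurement error structure beyond
item-level noise (no differential item functioning, no response styles such
as acquiescence), demographic heterogeneity, time-of-day or campaign-wave
effects, and any dependence of dropout on severity. Passing tests therefore
demonstrate that the engine computes what it claims on data with known
structure — not that real employees behave like the model.

## Worked example

```{r example, eval = FALSE}
script <- default_script()
sess <- start_session(script, "ACME", consent = TRUE, token = "demo")
while (sess$status == "in_progress") {
  p <- next_prompt(sess, script)
  sess <- submit_answer(sess, script, min(p$options))
}
sess$scores$gad7

cfg <- population_config(n = 120, seed = 1)
camp <- run_campaign(generate_population(cfg), script)
camp$stats
aggregate_distributions(camp$sessions, k = 8, script = script)
```

## Problem sizes and numerical choices

The test suite and the acceptance script use the sizes at which the checks
are statistically meaningful yet quick: 1,000 random answer vectors per
instrument against the brute-force scoring oracle; 500 engine-driven
sessions for the branch-soundness property; 10,000 respondents per
instrument for the threshold-model recovery check; 30 replicate campaigns
of 120 employees for the engagement-rate distribution; and an exhaustive
sweep of all group-size partitions of n ≤ 20 into at most four groups for
the pooling guarantee. Latent integration uses a 401-point grid spanning ±8
SD; all percentage rendering is half-up as described above; ties in pooling
and in greedy answer construction are broken by label and item order.

## Limitations

The engine reproduces delivery, scoring, branching, safety routing and
reporting — it does not validate the instruments in conversational form
(chat delivery with gamification may shift psychometric properties), it
collects no demographics by design, and its keyword safety scan is a
deliberately minimal stand-in for clinical triage. The bundled item
wordings are compact English renderings for testing; a deployment supplies
its own validated translations in the script file, since scoring depends
only on option values.
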