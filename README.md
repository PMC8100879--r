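# checkup

A scripted conversational engine for workplace mental-health checkups.

Organizations that want to map the mental health of their workforce face a
trade-off: face-to-face assessment engages people but is neither anonymous
nor scalable, while conventional online surveys scale but are abandoned.
One remedy is to deliver the standardized screeners as a rule-based chatbot
conversation — one question at a time with predefined answer options,
encouragement messages, conditional branching, a strict no-skip rule, a
24-hour reset, a safety protocol for high-risk answers, and immediate
personalized feedback — while the employer only ever sees aggregated,
k-anonymized results. `checkup` is that engine, for people who build or
study such assessments: it contains no UI, no web transport, and no
personal identifiers anywhere in its data model.

## What it implements

**Instruments.** Six screeners with exact scoring and severity banding:
GAD-7 (anxiety, 7 items, 0–3; bands 0–4 / 5–9 / 10–14 / 15+), PHQ-9
(depression, 9 items, 0–3; 0–4 / 5–9 / 10–14 / 15–19 / 20+), the DASS-21
stress subscale (7 items, 0–3; the total is doubled, bands 0–14 / 15–18 /
19–25 / 26–33 / 34+), ISI (insomnia, 7 items, 0–4; 0–7 / 8–14 / 15–21 /
22–28), OLBI (burnout, 16 items, 1–4, exhaustion + disengagement
subscales; 0–15 / 16–30 / 31–45 / 46+), and a 15-item demand–control–support
job-stress scale (1–4; 0–15 / 16–30 / 31–45 / 46+). Scoring is
`total = sum of keyed item values` with reverse keying `min + max − value`,
an instrument-level transformation (identity, or ×2 for DASS-21 stress),
and the unique inclusive band containing the transformed total.

**Conversation.** A deterministic state machine over a YAML checkup script:
section introductions, one question per prompt, configurable encouragement,
single-step back-navigation, and a branch rule that adds the insomnia block
exactly when the PHQ-9 sleep item is answered above "Not at all". Sessions
expire strictly after 24 hours with all answers erased.

**Safety.** Severe anxiety/depression categories, any endorsement of the
PHQ-9 self-harm item, or a (case- and accent-insensitive) key-phrase match
in free text route the conversation into a referral flow — emergency
services first for urgent tiers, care network otherwise.

**Reporting.** Campaign rates (initiation = started/eligible, completion =
completed/started, response = completed/eligible), per-instrument category
distributions with greedy small-group pooling (no reported group under
k = 8), symptomatic breakdowns, and a per-instrument summary table.

**Synthetic respondents.** A graded-threshold ordinal response model on
correlated latent severities, with memoryless per-prompt dropout calibrated
by inverting the geometric survival curve, driven through the real engine —
plus closed-form band probabilities to check the simulator against.

## Worked example

```r
library(checkup)
script <- default_script()

# one respondent, minimum answers except a positive sleep item
sess <- start_session(script, "ACME", consent = TRUE, token = "demo")
while (sess$status == "in_progress") {
  p <- next_prompt(sess, script)
  v <- if (p$item_id == "phq9_3") 2L else min(p$options)
  sess <- submit_answer(sess, script, v)
}
sess$scores$phq9
#> <checkup_score> phq9: total 2 -> 'none'
sess$scores$isi       # administered because the sleep item was endorsed
#> <checkup_score> isi: total 0 -> 'absence'

# a synthetic campaign of 120 employees
camp <- run_campaign(generate_population(population_config(n = 120, seed = 1)),
                     script)
camp$stats
#> <campaign_stats> eligible 120, started 96, completed 69
#>   initiation 80.0%  completion 71.9%  response 57.5%
```

The per-respondent totals (2 on the PHQ-9 because the sleep item scored 2,
0 elsewhere) land in the lowest severity bands, and the insomnia block was
added by the branch rule. The campaign rates vary by seed around the
calibrated targets (start probability 0.817, per-prompt dropout solved for
78.6% completion over the 54-prompt unconditional flow).

There is also a small CLI (`inst/cli/checkup.R`) with subcommands
`run`, `simulate`, `report`, `stats` and `validate-script`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","checkup.R",package="checkup"))')" \
  simulate --n 120 --seed 1 --out store/
```

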