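# Shared fixtures: everything is built in code at test time.

T0 <- as.POSIXct("2019-10-07 09:00:00", tz = "UTC")

the_script <- default_script()
the_instruments <- default_instruments()

# Independent scoring oracle: plain loop, reverse-key then sum, then the
# declared transformation. Kept deliberately naive.
oracle_total <- function(instrument, answers) {
  tot <- 0L
  for (i in seq_along(instrument$items)) {
    it <- instrument$items[[i]]
    v <- answers[[i]]
    if (it$reverse) v <- min(it$values) + max(it$values) - v
    tot <- tot + v
  }
  if (identical(instrument$transform, "double")) tot <- tot * 2L
  as.integer(tot)
}

random_answers <- function(instrument) {
  vapply(instrument$items, function(it) sample(it$values, 1L), 0L)
}

# Drive a session to completion, choosing each answer with `value_for(prompt)`.
drive_session <- function(script, value_for, token = "t1", start = T0,
                          step = 20, company = "ACME") {
  sess <- start_session(script, company, TRUE, now = start, token = token)
  i <- 0L
  while (sess$status == "in_progress") {
    p <- next_prompt(sess, script)
    i <- i + 1L
    sess <- submit_answer(sess, script, value_for(p), now = start + i * step)
  }
  sess
}

# Constant-value responder with per-item overrides.
responder <- function(default = 0L, overrides = integer()) {
  function(p) {
    if (p$item_id %in% names(overrides)) overrides[[p$item_id]]
    else if (default %in% p$options) default
    else min(p$options)
  }
}

# Abandoned-then-expired sessions (registered, a few answers, > 24 h old).
make_abandoned <- function(script, n, start = T0, n_answers = 3L) {
  lapply(seq_len(n), function(i) {
    sess <- start_session(script, "ACME", TRUE, now = start,
                          token = sprintf("a%04d", i))
    for (j in seq_len(n_answers)) {
      p <- next_prompt(sess, script)
      sess <- submit_answer(sess, script, min(p$options), now = start + j * 20)
    }
    check_expiry(sess, start + 25 * 3600)
  })
}

# Cohort plan engineered to the pilot campaign's printed category counts
# (77 completers, 34 of whom endorse the sleep item and take the ISI).
pilot_plan <- function() {
  data.frame(
    gad7 = c(rep(2L, 37), rep(6L, 20), rep(11L, 12), rep(16L, 8)),
    phq9 = c(rep(2L, 49), rep(6L, 16), rep(11L, 7), rep(16L, 3), rep(21L, 2)),
    isi = c(rep(3L, 14), rep(10L, 14), rep(16L, 4), rep(23L, 2), rep(NA, 43)),
    dass21_stress = c(rep(4L, 55), rep(8L, 6), rep(10L, 10), rep(14L, 4),
                      rep(17L, 2)),
    olbi = c(rep(25L, 52), rep(35L, 20), rep(50L, 5)),
    jss = c(rep(25L, 14), rep(35L, 53), rep(50L, 10))
  )
}

.pilot_cache <- new.env(parent = emptyenv())

pilot_cohort <- function() {
  if (is.null(.pilot_cache$cohort))
    .pilot_cache$cohort <- build_cohort(the_script, pilot_plan())
  .pilot_cache$cohort
}

pilot_store <- function() {
  if (is.null(.pilot_cache$store))
    .pilot_cache$store <- c(pilot_cohort(), make_abandoned(the_script, 21))
  .pilot_cache$store
}
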