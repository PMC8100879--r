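test_that("registration gates: consent, company code, duplicates", {
  expect_error(start_session(the_script, "ACME", FALSE, now = T0),
               class = "checkup_consent_error")
  # the refusal re-displays the terms
  err <- tryCatch(start_session(the_script, "ACME", FALSE, now = T0),
                  error = identity)
  expect_match(conditionMessage(err), "anonymous and voluntary")
  expect_error(start_session(the_script, "", TRUE, now = T0),
               class = "checkup_registration_error")
  expect_error(start_session(the_script, "ACME", TRUE, now = T0, token = "t1",
                             existing_tokens = c("t1", "t2")),
               class = "checkup_registration_error")
  sess <- start_session(the_script, "ACME", TRUE, now = T0, token = "t9")
  expect_identical(sess$status, "in_progress")
  expect_identical(sess$started_at, T0)
})

test_that("prompts: section intro first, full options mid-instrument, encouragement at the midpoint", {
  sess <- start_session(the_script, "ACME", TRUE, now = T0, token = "t1")
  p <- next_prompt(sess, the_script)
  expect_identical(p$kind, "section_intro")
  expect_identical(p$section_id, "stress")
  expect_identical(p$item_id, "dass_s1")
  expect_true(length(p$preamble) >= 1)

  sess <- submit_answer(sess, the_script, 0L, now = T0 + 20)
  p <- next_prompt(sess, the_script)
  expect_identical(p$kind, "question")
  expect_identical(p$options, 0:3)
  expect_length(p$option_labels, 4)

  # PHQ-9 midpoint: items 1..4 of depression answered -> encouragement before item 5
  sess2 <- start_session(the_script, "ACME", TRUE, now = T0, token = "t2")
  i <- 0
  for (k in 1:18) {  # 7 stress + 7 anxiety + 4 depression
    i <- i + 1
    sess2 <- submit_answer(sess2, the_script, 0L, now = T0 + i * 20)
  }
  p <- next_prompt(sess2, the_script)
  expect_identical(p$item_id, "phq9_5")
  expect_identical(p$kind, "encouragement")
  expect_true(any(grepl("Halfway", p$preamble)))
})

test_that("illegal answers are rejected without moving the cursor", {
  sess <- start_session(the_script, "ACME", TRUE, now = T0, token = "t1")
  expect_error(submit_answer(sess, the_script, 9L, now = T0 + 20),
               class = "checkup_answer_error")
  expect_length(sess$answers, 0)
  expect_identical(next_prompt(sess, the_script)$item_id, "dass_s1")
})

test_that("the insomnia branch is a pure monotone function of the sleep item", {
  expect_identical(evaluate_branches(the_script, c(phq9_3 = 0L)), character(0))
  expect_identical(evaluate_branches(the_script, c(phq9_3 = 1L)), "insomnia")
  expect_identical(evaluate_branches(the_script, c(phq9_3 = 3L)), "insomnia")
  # deferred while unanswered
  expect_identical(evaluate_branches(the_script, c(gad7_1 = 2L)), character(0))

  with_sleep <- drive_session(the_script, responder(0L, c(phq9_3 = 2L)), "s1")
  without <- drive_session(the_script, responder(0L), "s0")
  expect_true(!is.null(with_sleep$scores$isi))
  expect_null(without$scores$isi)
  expect_length(with_sleep$answers, 61)
  expect_length(without$answers, 54)
})

test_that("completed sessions satisfy the no-skip invariant", {
  sess <- drive_session(the_script, responder(1L, c(phq9_3 = 2L)), "t1")
  expect_identical(sess$status, "completed")
  seqd <- checkup:::item_seq(the_script, sess$answers)
  expect_setequal(names(sess$answers), seqd$item_id)
  expect_length(sess$answers, seqd$n)
})

test_that("go_back steps exactly one answer and re-evaluates the branch", {
  sess <- start_session(the_script, "ACME", TRUE, now = T0, token = "t1")
  for (i in 1:16) sess <- submit_answer(sess, the_script, 0L, now = T0 + i * 20)
  # answer the sleep item positively -> insomnia pending
  sess <- submit_answer(sess, the_script, 2L, now = T0 + 17 * 20)
  expect_identical(evaluate_branches(the_script, sess$answers), "insomnia")

  sess <- go_back(sess, the_script)
  expect_length(sess$answers, 16)
  expect_identical(next_prompt(sess, the_script)$item_id, "phq9_3")
  # only one step back is allowed
  sess2 <- go_back(sess, the_script)
  expect_identical(attr(sess2, "notice"), "nothing to go back to")
  expect_length(sess2$answers, 16)

  # change the answer to "Not at all" -> insomnia removed
  sess <- submit_answer(sess, the_script, 0L, now = T0 + 18 * 20)
  expect_identical(evaluate_branches(the_script, sess$answers), character(0))
  done <- local({
    s <- sess; i <- 20
    while (s$status == "in_progress") {
      i <- i + 1
      opts <- next_prompt(s, the_script)$options
      s <- submit_answer(s, the_script, min(opts), now = T0 + i * 20)
    }
    s
  })
  expect_null(done$scores$isi)
  expect_false(any(grepl("^isi_", names(done$answers))))

  # go_back at the very first prompt is a no-op notice
  fresh <- start_session(the_script, "ACME", TRUE, now = T0, token = "t2")
  fresh <- go_back(fresh, the_script)
  expect_identical(attr(fresh, "notice"), "nothing to go back to")
})

test_that("clearing an answered section invalidates its cached score", {
  sess <- start_session(the_script, "ACME", TRUE, now = T0, token = "t1")
  for (i in 1:7) sess <- submit_answer(sess, the_script, 1L, now = T0 + i * 20)
  expect_false(is.null(sess$scores$dass21_stress))
  sess <- go_back(sess, the_script)
  expect_null(sess$scores$dass21_stress)
  sess <- submit_answer(sess, the_script, 2L, now = T0 + 200)
  expect_equal(sess$scores$dass21_stress$raw_total, 8L)
})

test_that("the 24-hour rule expires strictly after the boundary and erases answers", {
  sess <- start_session(the_script, "ACME", TRUE, now = T0, token = "t1")
  for (i in 1:10) sess <- submit_answer(sess, the_script, 1L, now = T0 + i * 20)

  just_under <- check_expiry(sess, T0 + 23 * 3600 + 59 * 60)
  expect_identical(just_under$status, "in_progress")
  expect_length(just_under$answers, 10)

  at_bound <- check_expiry(sess, T0 + 24 * 3600)
  expect_identical(at_bound$status, "in_progress")

  over <- check_expiry(sess, T0 + 24 * 3600 + 60)
  expect_identical(over$status, "expired")
  expect_length(over$answers, 0)
  expect_length(over$scores, 0)
  expect_null(over$feedback)
  # registration survives so a restart is possible
  expect_identical(over$token, "t1")

  expect_error(submit_answer(over, the_script, 1L, now = T0 + 25 * 3600),
               class = "checkup_state_error")
  expect_error(next_prompt(over, the_script), class = "checkup_state_error")

  done <- drive_session(the_script, responder(0L), "t2")
  expect_identical(check_expiry(done, T0 + 48 * 3600)$status, "completed")
})

test_that("progress is monotone under forward moves and 1.0 exactly at completion", {
  sess <- start_session(the_script, "ACME", TRUE, now = T0, token = "t1")
  pr <- progress(sess, the_script)
  expect_equal(pr$fraction, 0)
  expect_equal(sum(pr$revealed), 0)
  last <- 0
  i <- 0
  while (sess$status == "in_progress") {
    p <- next_prompt(sess, the_script)
    i <- i + 1
    v <- if (p$item_id == "phq9_3") 2L else min(p$options)
    sess <- submit_answer(sess, the_script, v, now = T0 + i * 20)
    cur <- progress(sess, the_script)$fraction
    expect_gte(cur, last)
    last <- cur
  }
  pr <- progress(sess, the_script)
  expect_equal(pr$fraction, 1)
  expect_true(all(pr$revealed))

  # go_back is the only operation that may reduce progress
  s2 <- start_session(the_script, "ACME", TRUE, now = T0, token = "t2")
  s2 <- submit_answer(s2, the_script, 1L, now = T0 + 20)
  before <- progress(s2, the_script)$fraction
  s2 <- go_back(s2, the_script)
  expect_lt(progress(s2, the_script)$fraction, before)
})

test_that("identical scripts and answer sequences give identical transcripts and scores", {
  run <- function() drive_session(the_script, responder(1L, c(phq9_3 = 2L, phq9_9 = 1L)), "tx")
  a <- run(); b <- run()
  strip <- function(s) {
    s$transcript <- lapply(s$transcript, function(e) e[c("actor", "kind", "payload")])
    s
  }
  expect_identical(strip(a), strip(b))
  expect_identical(lapply(a$transcript, `[[`, "timestamp"),
                   lapply(b$transcript, `[[`, "timestamp"))
})

test_that("free text is scanned but never advances the conversation", {
  sess <- start_session(the_script, "ACME", TRUE, now = T0, token = "t1")
  sess <- submit_answer(sess, the_script, 1L, now = T0 + 20)
  before <- next_prompt(sess, the_script)$item_id
  sess <- submit_free_text(sess, the_script, "I just wanted to say hi", now = T0 + 40)
  expect_length(sess$risk_events, 0)
  expect_identical(next_prompt(sess, the_script)$item_id, before)

  sess <- submit_free_text(sess, the_script, "as vezes QUERO MORRER", now = T0 + 60)
  expect_length(sess$risk_events, 1)
  expect_identical(sess$risk_events[[1]]$trigger, "keyword")
  kinds <- vapply(sess$transcript, `[[`, "", "kind")
  expect_true("risk_referral" %in% kinds)
  expect_identical(next_prompt(sess, the_script)$item_id, before)
})

test_that("transcript timestamps are strictly increasing", {
  sess <- drive_session(the_script, responder(0L, c(phq9_3 = 1L)), "t1")
  ts <- vapply(sess$transcript, function(e) as.numeric(e$timestamp), 0)
  expect_true(all(diff(ts) > 0))
})
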