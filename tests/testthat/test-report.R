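small_cohort <- function(n, gad7_totals, groups = NULL) {
  plan <- data.frame(
    gad7 = gad7_totals,
    phq9 = rep(2L, n), isi = rep(NA_integer_, n),
    dass21_stress = rep(4L, n), olbi = rep(25L, n), jss = rep(25L, n))
  plan$sleep <- 0L
  if (!is.null(groups)) plan$group <- groups
  build_cohort(the_script, plan)
}

test_that("campaign rates follow their definitions with half-up rendering", {
  sessions <- c(small_cohort(5, rep(6L, 5)), make_abandoned(the_script, 2))
  st <- campaign_stats(10, sessions)
  expect_equal(st$started_n, 7L)
  expect_equal(st$completed_n, 5L)
  expect_equal(st$initiation_rate, 70)
  expect_equal(st$completion_rate, 100 * 5 / 7)
  expect_equal(st$response_rate, 50)
  # rate identity: response = initiation x completion
  expect_equal(st$response_rate,
               st$initiation_rate * st$completion_rate / 100)

  expect_error(campaign_stats(0, sessions), class = "checkup_validation_error")
  expect_error(campaign_stats(3, sessions), class = "checkup_validation_error")
  empty <- campaign_stats(50, list())
  expect_equal(empty$initiation_rate, 0)
  expect_equal(empty$completion_rate, 0)
  expect_equal(empty$response_rate, 0)
})

test_that("half-up percentage rendering", {
  expect_equal(round_half_up(78.571, 1), 78.6)
  expect_equal(round_half_up(81.666, 1), 81.7)
  expect_equal(round_half_up(0.5), 1)
  expect_equal(checkup:::pct_whole(100 * 10 / 22), 46)  # 45.45 -> 45.5 -> 46
  expect_equal(checkup:::pct_whole(100 * 16 / 28), 57)
})

test_that("small groups pool greedily until every reported group reaches k", {
  p <- checkup:::pool_groups(c(a = 9, b = 12), 8)
  expect_identical(unname(p), c("a", "b"))

  p <- checkup:::pool_groups(c(a = 5, b = 9, c = 12), 8)
  expect_identical(p[["a"]], p[["b"]])  # 5 merged into the smaller neighbor
  expect_identical(p[["c"]], "c")

  p <- checkup:::pool_groups(c(a = 3, b = 4), 8)
  expect_identical(unname(p), c("all", "all"))
})

test_that("pooled distributions hide small groups and conserve counts", {
  groups <- c(rep("plant", 9), rep("office", 3))
  sessions <- small_cohort(12, c(rep(2L, 6), rep(6L, 6)), groups = groups)
  dists <- aggregate_distributions(sessions, k = 8, script = the_script)
  d <- dists$gad7
  sizes <- rowSums(d$counts)
  expect_true(all(sizes >= 8 | nrow(d$counts) == 1))
  expect_equal(sum(d$counts), 12)
  expect_identical(sort(unique(unname(d$pooled_from))), "office+plant")
  # conservation per instrument, ISI counted only where administered
  expect_equal(sum(dists$olbi$counts), 12)
  expect_null(dists$isi)

  # serialized report exposes no tokens
  tmp <- tempfile(fileext = ".csv")
  write_report(dists, tmp)
  txt <- readLines(tmp)
  expect_false(any(grepl("c000", txt)))
  back <- read_report(tmp)
  expect_equal(sum(back$gad7), 12)
  expect_equal(unname(back$gad7["office+plant", "mild"]), 6)
})

test_that("expired sessions surface in no report", {
  sessions <- c(small_cohort(9, rep(2L, 9)), make_abandoned(the_script, 3))
  dists <- aggregate_distributions(sessions, k = 8, script = the_script)
  expect_equal(sum(dists$gad7$counts), 9)
  bd <- symptomatic_breakdown(sessions, "gad7", script = the_script)
  expect_equal(bd$n_scored, 9)
})

test_that("symptomatic breakdowns exclude the baseline band and render whole percents", {
  totals <- c(rep(2L, 5), rep(6L, 2), rep(11L, 1), rep(16L, 1))
  sessions <- small_cohort(9, totals)
  bd <- symptomatic_breakdown(sessions, "gad7", script = the_script)
  expect_identical(bd$baseline_label, "none")
  expect_equal(bd$n_scored, 9)
  expect_equal(bd$symptomatic_n, 4)
  expect_false("none" %in% bd$table$category)
  expect_equal(bd$table$count[bd$table$category == "mild"], 2)
  expect_equal(bd$table$pct_display[bd$table$category == "mild"], 50)
  expect_equal(sum(bd$table$pct), 100, tolerance = 0.2)

  # all respondents in the baseline band -> empty breakdown
  bd0 <- symptomatic_breakdown(small_cohort(3, rep(2L, 3)), "gad7",
                               script = the_script)
  expect_equal(bd0$symptomatic_n, 0)
  expect_equal(nrow(bd0$table), 0)

  # baseline = NULL tabulates shares among all scored respondents
  bd_all <- symptomatic_breakdown(sessions, "olbi", script = the_script)
  expect_null(bd_all$baseline_label)
  expect_equal(sum(bd_all$table$count), 9)
})

test_that("summary_table reports means, degenerate SDs and the category of the mean", {
  sessions <- small_cohort(4, rep(6L, 4))
  tab <- summary_table(sessions, the_script)
  g <- tab[tab$instrument_id == "gad7", ]
  expect_equal(g$n, 4)
  expect_equal(g$mean, 6)
  expect_equal(g$sd, 0)
  expect_false(g$sd_degenerate)
  expect_identical(g$category, "mild")
  expect_false("isi" %in% tab$instrument_id)

  one <- summary_table(small_cohort(1, 6L), the_script)
  expect_true(all(one$sd_degenerate))
  expect_true(all(one$sd == 0))
})

test_that("personalized feedback covers every scored instrument and always ends with the disclaimer", {
  low <- drive_session(the_script, responder(0L), "fb1")
  fb <- personal_feedback(low$scores, the_script$feedback)
  expect_length(fb, 6)  # 5 instruments (no ISI) + disclaimer
  expect_match(fb[length(fb)], "do not offer a diagnosis")

  hi <- drive_session(the_script, responder(3L, c(phq9_3 = 3L)), "fb2")
  fb <- personal_feedback(hi$scores, the_script$feedback)
  expect_true(any(grepl("care network", fb)))
  expect_match(fb[length(fb)], "do not offer a diagnosis")

  broken <- the_script$feedback
  broken$templates$gad7$severe <- NULL
  expect_error(personal_feedback(hi$scores, broken),
               class = "checkup_validation_error")
})

test_that("the dashboard payload carries rates and counts but no tokens", {
  sessions <- small_cohort(9, rep(6L, 9))
  st <- campaign_stats(12, sessions)
  dists <- aggregate_distributions(sessions, k = 8, script = the_script)
  payload <- dashboard_payload(st, dists,
                               list(symptomatic_breakdown(sessions, "gad7",
                                                          script = the_script)))
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE)
  expect_false(grepl("c000", js))
  expect_equal(payload$campaign$completed_n, 9)
})
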