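test_that("scoring reproduces the published worked examples", {
  gad7 <- the_instruments$gad7
  sc <- score_instrument(gad7, rep(0L, 7))
  expect_equal(sc$transformed_total, 0L)
  expect_equal(sc$category, "none")

  phq9 <- the_instruments$phq9
  sc <- score_instrument(phq9, c(3, 3, 3, 1, 0, 0, 0, 0, 0))
  expect_equal(sc$raw_total, 10L)
  expect_equal(sc$category, "moderate")

  dass <- the_instruments$dass21_stress
  sc <- score_instrument(dass, c(2, 2, 2, 2, 2, 0, 0))
  expect_equal(sc$raw_total, 10L)
  expect_equal(sc$transformed_total, 20L)
  expect_equal(sc$category, "moderate")

  isi <- the_instruments$isi
  sc <- score_instrument(isi, c(4, 4, 0, 0, 0, 0, 0))
  expect_equal(sc$transformed_total, 8L)
  expect_equal(sc$category, "subthreshold")
})

test_that("every printed band boundary categorizes exactly", {
  cases <- list(
    gad7 = list(c(0, "none"), c(4, "none"), c(5, "mild"), c(9, "mild"),
                c(10, "moderate"), c(14, "moderate"), c(15, "severe"),
                c(21, "severe")),
    phq9 = list(c(4, "none"), c(5, "mild"), c(9, "mild"), c(10, "moderate"),
                c(14, "moderate"), c(15, "moderately severe"),
                c(19, "moderately severe"), c(20, "severe"), c(27, "severe")),
    dass21_stress = list(c(0, "normal"), c(14, "normal"), c(15, "mild"),
                         c(18, "mild"), c(19, "moderate"), c(25, "moderate"),
                         c(26, "severe"), c(33, "severe"),
                         c(34, "extremely severe"), c(42, "extremely severe")),
    isi = list(c(0, "absence"), c(7, "absence"), c(8, "subthreshold"),
               c(14, "subthreshold"), c(15, "moderate"), c(21, "moderate"),
               c(22, "severe"), c(28, "severe")),
    olbi = list(c(15, "very low"), c(16, "low"), c(30, "low"), c(31, "high"),
                c(45, "high"), c(46, "very high"), c(64, "very high")),
    jss = list(c(15, "normal"), c(16, "slightly increased"),
               c(30, "slightly increased"), c(31, "increased"),
               c(45, "increased"), c(46, "extremely increased"),
               c(60, "extremely increased"))
  )
  for (id in names(cases)) {
    bands <- the_instruments[[id]]$bands
    for (cs in cases[[id]]) {
      expect_identical(categorize(as.integer(cs[1]), bands), cs[2],
                       label = sprintf("%s total %s", id, cs[1]))
    }
  }
  expect_error(categorize(-1, the_instruments$gad7$bands),
               class = "checkup_coverage_error")
})

test_that("reverse-keyed items contribute min+max-value", {
  olbi <- the_instruments$olbi
  base <- rep(2L, 16)
  rev_idx <- which(vapply(olbi$items, `[[`, NA, "reverse"))[1]
  fwd_idx <- which(!vapply(olbi$items, `[[`, NA, "reverse"))[1]
  up_rev <- base; up_rev[rev_idx] <- 3L
  up_fwd <- base; up_fwd[fwd_idx] <- 3L
  s0 <- score_instrument(olbi, base)$raw_total
  expect_equal(score_instrument(olbi, up_rev)$raw_total, s0 - 1L)
  expect_equal(score_instrument(olbi, up_fwd)$raw_total, s0 + 1L)
})

test_that("subscale totals follow the item tags and sum to the raw total", {
  jss <- the_instruments$jss
  ans <- random_answers(jss)
  sub <- subscale_totals(jss, ans)
  expect_named(sub, c("demand", "control", "support"))
  expect_equal(sum(sub), score_instrument(jss, ans)$raw_total)

  # uniform-response example on an untransformed, non-reversed two-scale
  # instrument: each subscale total is just (value x item count)
  plain <- checkup_instrument(
    "olbi",
    lapply(1:16, function(i)
      checkup_item(sprintf("p%d", i), "stmt", 1:4,
                   subscale = if (i <= 8) "exhaustion" else "disengagement")),
    "identity",
    list(category_band("very low", 0, 15), category_band("low", 16, 30),
         category_band("high", 31, 45), category_band("very high", 46, Inf)),
    subscales = c("exhaustion", "disengagement"))
  expect_equal(unname(subscale_totals(plain, rep(2L, 16))), c(16L, 16L))
  expect_equal(unname(subscale_totals(plain, rep(4L, 16))), c(32L, 32L))

  untagged <- checkup_instrument(
    "x", list(checkup_item("a", "q", 0:3), checkup_item("b", "q", 0:3)),
    "identity", list(category_band("all", 0, 6)))
  expect_error(subscale_totals(untagged, c(1L, 1L)),
               class = "checkup_validation_error")
})

test_that("validate_instrument flags constructed defects and unreachable bands", {
  expect_length(validate_instrument(the_instruments$gad7), 0)

  gapped <- the_instruments$gad7
  gapped$bands <- list(category_band("none", 0, 4), category_band("mild", 5, 9),
                       category_band("moderate", 11, 14),
                       category_band("severe", 15, Inf))
  v <- validate_instrument(gapped)
  expect_true(any(grepl("gap", vapply(v, `[[`, "", "message"))))

  # OLBI as printed: band 0-15 cannot be reached when 16 items score 1-4
  v <- validate_instrument(the_instruments$olbi)
  expect_true(all(vapply(v, `[[`, "", "level") == "warning"))
  expect_true(any(grepl("unreachable", vapply(v, `[[`, "", "message"))))

  short <- the_instruments$gad7
  short$items <- short$items[1:6]
  v <- validate_instrument(short)
  expect_true(any(vapply(v, `[[`, "", "level") == "error"))
})

test_that("validation errors name the offending item", {
  gad7 <- the_instruments$gad7
  expect_error(score_instrument(gad7, rep(0L, 6)), "expected 7",
               class = "checkup_validation_error")
  expect_error(score_instrument(gad7, c(0, 0, 0, 4, 0, 0, 0)), "gad7_4",
               class = "checkup_validation_error")
})

test_that("raising a non-reversed answer never lowers the total or the category", {
  set.seed(7)
  for (id in names(the_instruments)) {
    ins <- the_instruments[[id]]
    labels <- vapply(ins$bands, `[[`, "", "label")
    for (rep_i in 1:25) {
      ans <- random_answers(ins)
      fwd <- which(!vapply(ins$items, `[[`, NA, "reverse"))
      fwd <- fwd[ans[fwd] < vapply(ins$items[fwd], function(it) max(it$values), 0L)]
      if (!length(fwd)) next
      j <- sample(fwd, 1L)
      up <- ans; up[j] <- up[j] + 1L
      s0 <- score_instrument(ins, ans)
      s1 <- score_instrument(ins, up)
      expect_gte(s1$raw_total, s0$raw_total)
      expect_gte(match(s1$category, labels), match(s0$category, labels))
    }
  }
})

test_that("batch scoring matches per-vector scoring through a CSV round trip", {
  gad7 <- the_instruments$gad7
  set.seed(3)
  mat <- t(replicate(12, random_answers(gad7)))
  colnames(mat) <- rev(item_ids(gad7))  # column order must not matter
  tmp <- tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(mat), tmp, row.names = FALSE)
  out <- tempfile(fileext = ".csv")
  df <- score_batch(gad7, tmp, out = out)
  expect_equal(nrow(df), 12)
  for (i in 1:12) {
    sc <- score_instrument(gad7, as.integer(mat[i, item_ids(gad7)]))
    expect_equal(df$transformed_total[i], sc$transformed_total)
    expect_identical(df$category[i], sc$category)
  }
  back <- utils::read.csv(out)
  expect_equal(back$raw_total, df$raw_total)

  jss <- the_instruments$jss
  d <- as.data.frame(t(replicate(3, random_answers(jss))))
  names(d) <- item_ids(jss)
  dfj <- score_batch(jss, d)
  expect_true(all(c("demand", "control", "support") %in% names(dfj)))
  expect_equal(dfj$demand + dfj$control + dfj$support, dfj$raw_total)
  expect_error(score_batch(jss, d[, -1]), class = "checkup_validation_error")
})

test_that("DASS-21 stress totals are doubled and therefore even", {
  dass <- the_instruments$dass21_stress
  set.seed(11)
  for (i in 1:100) {
    sc <- score_instrument(dass, random_answers(dass))
    expect_equal(sc$transformed_total, 2L * sc$raw_total)
    expect_equal(sc$transformed_total %% 2L, 0L)
  }
})
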