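## Synthetic respondents: a graded-threshold (cumulative probit) ordinal
## response model on per-construct latent severities, plus memoryless
## per-prompt dropout, so the entire pipeline can be exercised and checked
## against analytic band probabilities without any real data.
##
## Response model: an item with K options has K-1 equally spaced thresholds
## tau_j = base + (j-1)*spacing on the latent scale. Given construct severity
## theta and standard normal item noise e, the severity-aligned (keyed) level
## is the number of thresholds below theta + e; reverse-keyed items emit the
## mirrored raw option value and scoring restores the keyed level, so
## expected totals are non-decreasing in severity throughout. Constructs are
## named after the script sections (stress, anxiety, depression, insomnia,
## burnout, work_stress).

#' Default latent-severity settings
#'
#' One row per construct with the population location and spread of the
#' latent severity. The defaults (location 0, spread 1 with thresholds at
#' 0.5, 1.5, ...) put most of the mass in the lowest response options,
#' emulating a predominantly low-severity working population.
#'
#' @return data frame with columns `construct`, `location`, `spread`.
#' @export
default_constructs <- function() {
  data.frame(
    construct = c("stress", "anxiety", "depression", "insomnia",
                  "burnout", "work_stress"),
    location = 0, spread = 1, stringsAsFactors = FALSE)
}

#' Default inter-construct correlation
#'
#' Compound correlation of 0.5 between all latent severities, raised to 0.6
#' between depression and insomnia (the insomnia branch conditions on a
#' depression item, so their latents should co-vary more strongly).
#'
#' @return a 6x6 correlation matrix.
#' @export
default_correlation <- function() {
  ids <- default_constructs()$construct
  R <- matrix(0.5, length(ids), length(ids), dimnames = list(ids, ids))
  diag(R) <- 1
  R["depression", "insomnia"] <- R["insomnia", "depression"] <- 0.6
  R
}

#' Calibrate the per-prompt dropout hazard
#'
#' Under memoryless per-prompt dropout, survival over `n_prompts` prompts is
#' geometric: completion = (1 - hazard)^n_prompts. This solves the curve for
#' the hazard that yields a target completion rate.
#'
#' @param completion_rate target completion proportion in (0, 1].
#' @param n_prompts number of prompts a completer answers.
#' @return the per-prompt abandonment probability.
#' @export
calibrate_dropout <- function(completion_rate, n_prompts) {
  if (completion_rate <= 0 || completion_rate > 1)
    stop_checkup("checkup_validation_error", "completion_rate must be in (0, 1]")
  1 - completion_rate^(1 / n_prompts)
}

#' Configure a synthetic population
#'
#' @param n population size (the campaign's eligible count).
#' @param constructs data frame as [default_constructs()].
#' @param correlation positive semi-definite correlation matrix over the
#'   constructs.
#' @param start_probability probability that an employee initiates the
#'   checkup; default 0.817, the initiation rate the engine emulates.
#' @param dropout_hazard per-prompt abandonment probability; by default
#'   calibrated with [calibrate_dropout()] so that survival over the 54
#'   prompts of the default unconditional flow matches a 78.6% completion
#'   rate.
#' @param threshold_base,threshold_spacing graded-threshold locations
#'   `base + (j-1)*spacing`.
#' @param seed integer RNG seed; every derived stream comes from it.
#' @return an object of class `checkup_population_config`.
#' @export
population_config <- function(n, constructs = default_constructs(),
                              correlation = default_correlation(),
                              start_probability = 0.817,
                              dropout_hazard = NULL,
                              threshold_base = 0.5, threshold_spacing = 1,
                              seed = 1L) {
  if (n < 1) stop_checkup("checkup_validation_error", "n must be >= 1")
  if (start_probability < 0 || start_probability > 1)
    stop_checkup("checkup_validation_error", "start_probability must be in [0, 1]")
  k <- nrow(constructs)
  if (!is.matrix(correlation) || any(dim(correlation) != k))
    stop_checkup("checkup_validation_error", "correlation must be a square matrix over the constructs")
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop_checkup("checkup_validation_error", "correlation matrix is not positive semi-definite")
  dropout_hazard <- dropout_hazard %||% calibrate_dropout(77 / 98, 54L)
  if (dropout_hazard < 0 || dropout_hazard > 1)
    stop_checkup("checkup_validation_error", "dropout_hazard must be in [0, 1]")
  structure(list(n = as.integer(n), constructs = constructs,
                 correlation = correlation,
                 start_probability = start_probability,
                 dropout_hazard = dropout_hazard,
                 threshold_base = threshold_base,
                 threshold_spacing = threshold_spacing,
                 seed = as.integer(seed)),
            class = "checkup_population_config")
}

#' Draw a synthetic population
#'
#' Latent severities are multivariate normal with the configured locations,
#' spreads and correlation; each profile also carries the dropout and start
#' parameters and its own derived seed, so item responses are reproducible
#' per respondent.
#'
#' @param config a [population_config()].
#' @return a list of `checkup_profile` objects (class `checkup_population`),
#'   with the config attached as an attribute.
#' @export
generate_population <- function(config) {
  cs <- config$constructs
  D <- diag(cs$spread, nrow(cs))
  Sigma <- D %*% config$correlation %*% D
  lat <- with_seed(config$seed,
                   MASS::mvrnorm(config$n, mu = cs$location, Sigma = Sigma,
                                 tol = 1e-6))
  lat <- matrix(lat, nrow = config$n)
  colnames(lat) <- cs$construct
  profiles <- lapply(seq_len(config$n), function(i) {
    structure(list(latent = lat[i, ],
                   dropout_hazard = config$dropout_hazard,
                   start_probability = config$start_probability,
                   threshold_base = config$threshold_base,
                   threshold_spacing = config$threshold_spacing,
                   seed = mix_seed(config$seed, i)),
              class = "checkup_profile")
  })
  structure(profiles, class = "checkup_population", config = config)
}

item_thresholds <- function(n_options, base = 0.5, spacing = 1) {
  base + (seq_len(n_options - 1L) - 1L) * spacing
}

#' Simulate one item response
#'
#' Graded-threshold draw: the keyed (severity-aligned) level is the number of
#' thresholds exceeded by `latent + noise`; reverse-keyed items emit the
#' mirrored raw option value, which scoring keys back. Deterministic given
#' the profile seed and item index. As severity tends to -Inf / +Inf the
#' response tends to the scale's extreme options.
#'
#' @param profile a `checkup_profile`.
#' @param item a [checkup_item()].
#' @param construct which latent severity drives the item.
#' @param item_index position of the item in the session's prompt stream
#'   (part of the per-draw seed).
#' @param noise optional fixed noise value (bypasses the RNG).
#' @return an integer option value.
#' @export
simulate_item_response <- function(profile, item, construct, item_index = 1L,
                                   noise = NULL) {
  theta <- profile$latent[[construct]]
  if (is.null(theta) || is.na(theta))
    stop_checkup("checkup_validation_error",
                 sprintf("profile has no latent severity for construct '%s'", construct))
  tau <- item_thresholds(length(item$values), profile$threshold_base,
                         profile$threshold_spacing)
  eps <- noise %||%
    with_seed(mix_seed(profile$seed, item_index), stats::rnorm(1))
  level <- sum(theta + eps > tau)
  keyed <- min(item$values) + level
  if (item$reverse) min(item$values) + max(item$values) - keyed else keyed
}

## pmf over keyed levels 0..K-1 for one item at severity theta
item_level_pmf <- function(n_options, theta, base = 0.5, spacing = 1) {
  tau <- c(-Inf, item_thresholds(n_options, base, spacing), Inf)
  diff(stats::pnorm(tau - theta))
}

conv <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a))
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  out
}

## pmf of the keyed raw total at fixed severity theta (totals from
## n*vmin upward, by convolution over items).
instrument_total_pmf <- function(instrument, theta, base = 0.5, spacing = 1) {
  p <- 1
  for (it in instrument$items)
    p <- conv(p, item_level_pmf(length(it$values), theta, base, spacing))
  offset <- sum(vapply(instrument$items, function(it) min(it$values), 0L))
  list(totals = offset + seq_along(p) - 1L, prob = p)
}

#' Analytic band probabilities of the response model
#'
#' Integrates the graded-threshold model over the latent severity
#' distribution (normal with the given location and spread, numerically on a
#' fine grid) and returns the probability that the transformed total falls
#' in each severity band. This is the closed-form counterpart against which
#' the simulator's empirical category distributions can be checked.
#'
#' @param instrument a [checkup_instrument()].
#' @param location,spread latent severity distribution parameters.
#' @param threshold_base,threshold_spacing threshold layout.
#' @param grid_n,grid_width integration grid resolution and half-width (in
#'   SDs).
#' @return named numeric vector of band probabilities (sums to 1).
#' @export
band_probabilities <- function(instrument, location = 0, spread = 1,
                               threshold_base = 0.5, threshold_spacing = 1,
                               grid_n = 401L, grid_width = 8) {
  labels <- vapply(instrument$bands, `[[`, "", "label")
  acc <- stats::setNames(numeric(length(labels)), labels)
  if (spread == 0) {
    thetas <- location
    w <- 1
  } else {
    z <- seq(-grid_width, grid_width, length.out = grid_n)
    thetas <- location + spread * z
    w <- stats::dnorm(z)
    w <- w / sum(w)
  }
  for (i in seq_along(thetas)) {
    pmf <- instrument_total_pmf(instrument, thetas[i], threshold_base,
                                threshold_spacing)
    tt <- apply_transform(pmf$totals, instrument$transform)
    for (j in seq_along(labels)) {
      b <- instrument$bands[[j]]
      acc[j] <- acc[j] + w[i] * sum(pmf$prob[tt >= b$lower & tt <= b$upper])
    }
  }
  acc
}

#' Vectorized simulation of instrument totals
#'
#' Draws `n` respondents' latent severities and item noise and returns their
#' transformed totals — the fast path for checking the simulator against
#' [band_probabilities()] at large n.
#'
#' @param instrument a [checkup_instrument()].
#' @param n number of respondents.
#' @param location,spread latent severity distribution parameters.
#' @param threshold_base,threshold_spacing threshold layout.
#' @param seed RNG seed.
#' @return integer vector of transformed totals.
#' @export
simulate_instrument_totals <- function(instrument, n, location = 0, spread = 1,
                                       threshold_base = 0.5,
                                       threshold_spacing = 1, seed = 1L) {
  with_seed(seed, {
    theta <- stats::rnorm(n, location, spread)
    raw <- integer(n)
    for (it in instrument$items) {
      tau <- item_thresholds(length(it$values), threshold_base,
                             threshold_spacing)
      x <- theta + stats::rnorm(n)
      level <- rowSums(outer(x, tau, `>`))
      raw <- raw + min(it$values) + level
    }
    as.integer(apply_transform(raw, instrument$transform))
  })
}

section_construct <- function(section_id) section_id

#' Drive one synthetic respondent through the engine
#'
#' @param profile a `checkup_profile`.
#' @param script the `checkup_script`.
#' @param token session token.
#' @param start_time session start.
#' @param step_seconds simulated seconds per answered prompt.
#' @return a `checkup_session` (completed, or in progress if the respondent
#'   abandoned). Dropout draws come from the caller's RNG stream; item
#'   responses are driven by the profile seed.
#' @export
simulate_session <- function(profile, script, token, start_time,
                             step_seconds = 20) {
  sess <- start_session(script, "SIM", TRUE, now = start_time, token = token)
  idx <- 0L
  repeat {
    if (sess$status != "in_progress") break
    seqd <- item_seq(script, sess$answers)
    pos <- length(sess$answers) + 1L
    if (pos > seqd$n) break
    if (stats::runif(1) < profile$dropout_hazard) break  # mid-session dropout
    idx <- idx + 1L
    ins <- script$instruments[[seqd$instrument_id[pos]]]
    val <- simulate_item_response(profile, ins$items[[seqd$idx[pos]]],
                                  section_construct(seqd$section_id[pos]),
                                  item_index = idx)
    sess <- submit_answer(sess, script, val,
                          now = start_time + idx * step_seconds)
  }
  sess
}

#' Run a synthetic campaign
#'
#' Each profile initiates with its start probability; starters abandon each
#' prompt with the dropout hazard; abandoners are advanced past the 24-hour
#' limit and expire (their data are overwritten, as in the engine's reset
#' rule). Returns the session store plus the campaign statistics.
#'
#' @param population a `checkup_population`.
#' @param script the `checkup_script`.
#' @param start_time campaign start time.
#' @param step_seconds simulated seconds per answered prompt.
#' @param expire_after_hours when to run the expiry sweep over abandoned
#'   sessions (default 25 h after start).
#' @param seed RNG seed for the start/dropout draws; derived from the
#'   population seed when omitted.
#' @return `list(sessions, stats)`.
#' @export
run_campaign <- function(population, script,
                         start_time = parse_utc("2019-10-07 09:00:00"),
                         step_seconds = 20, expire_after_hours = 25,
                         seed = NULL) {
  config <- attr(population, "config")
  seed <- seed %||% mix_seed(config$seed, 424243L)
  sessions <- with_seed(seed, {
    out <- list()
    for (i in seq_along(population)) {
      profile <- population[[i]]
      if (stats::runif(1) >= profile$start_probability) next
      sess <- simulate_session(profile, script, sprintf("sim%06d", i),
                               start_time, step_seconds)
      if (sess$status == "in_progress")
        sess <- check_expiry(sess, start_time + expire_after_hours * 3600)
      out[[length(out) + 1L]] <- sess
    }
    out
  })
  list(sessions = sessions,
       stats = campaign_stats(length(population), sessions))
}

## ---- deterministic cohorts ------------------------------------------------

#' Construct an answer vector with a prescribed total
#'
#' Greedy fill in keyed (severity-aligned) space: items start at their keyed
#' minimum and are raised left to right until the keyed raw total (before
#' any transformation) reaches `total`. `fixed` pins raw option values for
#' specific items (e.g. the PHQ-9 sleep item when engineering branch
#' behaviour). Used to build deterministic cohorts with known score
#' distributions.
#'
#' @param instrument a [checkup_instrument()].
#' @param total target keyed raw total (pre-transform).
#' @param fixed named integer vector of raw option values to hold fixed.
#' @return named integer vector of raw option values in item order.
#' @export
answers_for_total <- function(instrument, total, fixed = integer()) {
  ids <- item_ids(instrument)
  bad <- setdiff(names(fixed), ids)
  if (length(bad))
    stop_checkup("checkup_validation_error",
                 sprintf("fixed values for unknown item(s): %s",
                         paste(bad, collapse = ", ")))
  keyed <- vapply(instrument$items, function(it) {
    if (it$id %in% names(fixed)) keyed_value(it, as.integer(fixed[[it$id]]))
    else min(it$values)
  }, 0L)
  caps <- vapply(instrument$items, function(it) max(it$values), 0L)
  free <- !(ids %in% names(fixed))
  need <- total - sum(keyed)
  for (i in which(free)) {
    if (need <= 0L) break
    add <- min(caps[i] - keyed[i], need)
    keyed[i] <- keyed[i] + add
    need <- need - add
  }
  if (need != 0L)
    stop_checkup("checkup_validation_error",
                 sprintf("total %d is not achievable for '%s' with the given fixed values",
                         total, instrument$id))
  raw <- vapply(seq_along(instrument$items), function(i) {
    it <- instrument$items[[i]]
    if (it$reverse) min(it$values) + max(it$values) - keyed[i] else keyed[i]
  }, 0L)
  stats::setNames(raw, ids)
}

#' Build a cohort of completed sessions with prescribed totals
#'
#' Drives the engine end to end for each plan row, so every session respects
#' the branch rules, risk protocol and no-skip invariant. The plan has one
#' column per instrument id holding the target keyed raw total
#' (pre-transform); an `NA` in the `isi` column means the respondent answers
#' the sleep item "Not at all" and is never routed to the insomnia block,
#' otherwise the sleep item is pinned to 1 (or use a `sleep` column for
#' other values). An optional `group` column sets the reporting group.
#'
#' @param script the `checkup_script`.
#' @param plan data frame as described above.
#' @param start_time first session start; sessions are spaced a minute apart.
#' @param step_seconds simulated seconds per answered prompt.
#' @return list of completed `checkup_session` objects.
#' @export
build_cohort <- function(script, plan,
                         start_time = parse_utc("2019-10-07 09:00:00"),
                         step_seconds = 20) {
  sections <- script$sections
  sessions <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    sleep <- if ("sleep" %in% names(plan)) plan$sleep[i]
             else if (!is.na(plan$isi[i] %||% NA)) 1L else 0L
    answer_of <- list()
    for (sec in sections) {
      ins <- script$instruments[[sec$instrument_id]]
      tgt <- plan[[ins$id]][i]
      if (is.null(tgt) || is.na(tgt)) next
      fixed <- integer()
      rule <- branch_rule_for(script, "insomnia")
      if (!is.null(rule) && rule$instrument_id == ins$id)
        fixed <- stats::setNames(as.integer(sleep), rule$item_id)
      answer_of[[ins$id]] <- answers_for_total(ins, tgt, fixed)
    }
    t0 <- start_time + (i - 1) * 60
    sess <- start_session(script, "COHORT", TRUE, now = t0,
                          token = sprintf("c%05d", i),
                          group_label = if ("group" %in% names(plan))
                            plan$group[i] else "all")
    idx <- 0L
    while (sess$status == "in_progress") {
      seqd <- item_seq(script, sess$answers)
      pos <- length(sess$answers) + 1L
      if (pos > seqd$n) break
      vals <- answer_of[[seqd$instrument_id[pos]]]
      if (is.null(vals))
        stop_checkup("checkup_validation_error",
                     sprintf("plan row %d reaches '%s' without a target total",
                             i, seqd$instrument_id[pos]))
      idx <- idx + 1L
      sess <- submit_answer(sess, script, vals[[seqd$item_id[pos]]],
                            now = t0 + idx * step_seconds)
    }
    sessions[[i]] <- sess
  }
  sessions
}

#' @export
print.checkup_population <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<checkup_population> n=%d, start p=%.3f, dropout hazard=%.4f, seed=%d\n",
              length(x), cfg$start_probability, cfg$dropout_hazard, cfg$seed))
  invisible(x)
}
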