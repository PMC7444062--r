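test_that("VAS summaries are per-category arithmetic means", {
  cat16 <- apa_catalog()
  vas <- tibble::tibble(activity_id = cat16$id, liking = 100, wanting = 100)
  prof <- summarize_vas(vas)
  expect_equal(prof$sed_liking, 100)
  expect_equal(prof$pa_liking, 100)

  vas0 <- tibble::tibble(activity_id = cat16$id, liking = 0, wanting = 0)
  prof0 <- summarize_vas(vas0)
  expect_equal(unlist(prof0[, c("sed_liking", "pa_liking", "sed_wanting",
                                "pa_wanting")], use.names = FALSE),
               rep(0, 4))

  toy <- toy_catalog()
  vas2 <- tibble::tibble(activity_id = toy$id,
                         liking = c(60, 80, 10, 30), wanting = 50)
  prof2 <- summarize_vas(vas2, toy)
  expect_equal(prof2$sed_liking, 70)
  expect_equal(prof2$pa_liking, 20)
  expect_equal(prof2$n_rated_sed, 2)
})

test_that("VAS summaries reject bad ids, ranges and empty categories", {
  toy <- toy_catalog()
  expect_error(summarize_vas(
    tibble::tibble(activity_id = "nope", liking = 5, wanting = 5), toy),
    "unknown activity")
  expect_error(summarize_vas(
    tibble::tibble(activity_id = toy$id[1], liking = 105, wanting = 5), toy),
    "\\[0, 100\\]")
  expect_error(summarize_vas(
    tibble::tibble(activity_id = toy$id[1:2], liking = 5, wanting = 5), toy),
    "per category")
})

test_that("trial cleaning drops non-responses and out-of-window RTs", {
  trials <- tibble::tibble(pair_id = 1:4,
                           chosen_id = "a",
                           rt = c(0.1, 0.5, 12, NA),
                           responded = c(TRUE, TRUE, TRUE, FALSE))
  kept <- clean_trials(trials)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$rt, 0.5)
  removals <- attr(kept, "removals")
  expect_equal(removals$n[removals$reason == "non_response"], 1)
  expect_equal(removals$n[removals$reason == "too_fast"], 1)
  expect_equal(removals$n[removals$reason == "too_slow"], 1)

  # no-cleaning mode keeps every responded trial unchanged
  kept_all <- clean_trials(trials, clean = FALSE)
  expect_equal(nrow(kept_all), 3)

  none <- clean_trials(trials[4, ])
  expect_equal(nrow(none), 0)
  expect_equal(sum(attr(none, "removals")$n), 1)
})

test_that("forced-choice summary counts wins and RT means over cross trials", {
  pairs <- apa_pairs()
  log <- cross_log(pairs, n_sed = 40, n_pa = 24, rt_sed = 1, rt_pa = 1.5)
  s <- summarize_forced_choice(log, pairs)
  expect_equal(s$win_sed, 40)
  expect_equal(s$win_pa, 24)
  expect_equal(s$rt_sed, 1)
  expect_equal(s$rt_pa, 1.5)
  expect_equal(s$rt_all, (40 * 1 + 24 * 1.5) / 64)
  expect_equal(s$n_cross_responded, 64)
  expect_equal(s$win_sed + s$win_pa, s$n_cross_responded)
})

test_that("within-category trials never enter the summary", {
  pairs <- apa_pairs()
  log <- cross_log(pairs, 10, 10)
  within <- pairs[pairs$pair_type == "WITHIN_SED", ][1:5, ]
  log_w <- dplyr::bind_rows(log, tibble::tibble(
    pair_id = within$pair_id, chosen_id = within$left_id,
    rt = 0.01, responded = TRUE))
  expect_equal(summarize_forced_choice(log_w, pairs),
               summarize_forced_choice(log, pairs))
})

test_that("degenerate forced-choice logs behave as specified", {
  pairs <- apa_pairs()
  all_sed <- cross_log(pairs, 64, 0)
  s <- summarize_forced_choice(all_sed, pairs)
  expect_equal(s$win_sed, 64)
  expect_equal(s$win_pa, 0)
  expect_true(is.na(s$rt_pa))
  empty <- tibble::tibble(pair_id = integer(), chosen_id = character(),
                          rt = numeric(), responded = logical())
  expect_error(summarize_forced_choice(empty, pairs), "undefined")
  bad <- tibble::tibble(pair_id = pairs$pair_id[pairs$pair_type == "CROSS"][1],
                        chosen_id = "walking_on_mars", rt = 1,
                        responded = TRUE)
  expect_error(summarize_forced_choice(bad, pairs), "not a member")
})

test_that("bias score reproduces the hand-worked example", {
  s <- tibble::tibble(win_sed = 40, win_pa = 24, rt_all = 1.1875,
                      rt_sed = 1, rt_pa = 1.5, n_cross_responded = 64)
  b <- compute_bias(s)
  expect_equal(b$iw_sed, 28.5)
  expect_equal(b$iw_pa, -28.5)
  expect_equal(b$raw, 57)
  expect_equal(b$bias, 44.53125)
  expect_false(b$clipped)
})

test_that("bias score hits its exact anchors", {
  mk <- function(ws, wp, rs, rp, ra) {
    tibble::tibble(win_sed = ws, win_pa = wp, rt_all = ra, rt_sed = rs,
                   rt_pa = rp, n_cross_responded = ws + wp)
  }
  expect_equal(compute_bias(mk(32, 32, 1, 1, 1))$bias, 0)
  expect_equal(compute_bias(mk(64, 0, 1, NA, 1))$bias, 100)
  expect_equal(compute_bias(mk(0, 64, NA, 1, 1))$bias, -100)
  expect_error(compute_bias(mk(0, 0, NA, NA, NA)), "undefined")
})

test_that("bias matches the independent formula transliteration", {
  set.seed(401)
  for (i in 1:1000) {
    n <- sample(10:64, 1)
    ws <- sample(0:n, 1)
    wp <- n - ws
    rs <- if (ws > 0) runif(1, 0.3, 3) else NA_real_
    rp <- if (wp > 0) runif(1, 0.3, 3) else NA_real_
    ra <- sum(c(ws * rs, wp * rp), na.rm = TRUE) / n
    got <- compute_bias(tibble::tibble(
      win_sed = ws, win_pa = wp, rt_all = ra, rt_sed = rs, rt_pa = rp,
      n_cross_responded = n))
    want <- oracle_bias(ws, wp, ra, rs, rp, n)
    expect_equal(got$bias, want$bias, tolerance = 1e-12)
    expect_identical(got$iw_pa, -got$iw_sed)
  }
})

test_that("bias is antisymmetric under category relabeling", {
  pairs <- apa_pairs()
  set.seed(42)
  sched <- apa_schedule(pairs, seed = 11)
  resp <- simulate_respondent(apa_profile(theta = 0.5, seed = 3), sched,
                              seed = 4)
  b <- score_bias(resp$trials, sched)$bias
  # swap every activity's category
  flipped <- apa_catalog()
  flipped$category <- ifelse(flipped$category == "SEDENTARY",
                             "PHYSICAL", "SEDENTARY")
  b_flipped <- score_bias(resp$trials, sched, catalog = flipped)$bias
  expect_equal(b_flipped, -b, tolerance = 1e-12)
})

test_that("bias is monotone in win counts and RT advantages", {
  mk <- function(ws, wp, rs, rp) {
    ra <- (ws * rs + wp * rp) / (ws + wp)
    tibble::tibble(win_sed = ws, win_pa = wp, rt_all = ra, rt_sed = rs,
                   rt_pa = rp, n_cross_responded = 64)
  }
  # increasing sedentary wins (RT means fixed) increases bias
  biases <- vapply(10:54, function(ws)
    compute_bias(mk(ws, 64 - ws, 1.1, 1.3))$bias, numeric(1))
  expect_true(all(diff(biases) > 0))
  # faster sedentary wins do not decrease bias
  b_slow <- compute_bias(mk(40, 24, 1.4, 1.2))$bias
  b_fast <- compute_bias(mk(40, 24, 0.9, 1.2))$bias
  expect_gte(b_fast, b_slow)
})

test_that("bias is invariant to rescaling all reaction times", {
  set.seed(77)
  for (i in 1:50) {
    ws <- sample(1:63, 1)
    wp <- 64 - ws
    rs <- runif(1, 0.3, 3)
    rp <- runif(1, 0.3, 3)
    ra <- (ws * rs + wp * rp) / 64
    k <- runif(1, 0.1, 10)
    b1 <- compute_bias(tibble::tibble(
      win_sed = ws, win_pa = wp, rt_all = ra, rt_sed = rs, rt_pa = rp,
      n_cross_responded = 64))$bias
    b2 <- compute_bias(tibble::tibble(
      win_sed = ws, win_pa = wp, rt_all = k * ra, rt_sed = k * rs,
      rt_pa = k * rp, n_cross_responded = 64))$bias
    expect_equal(b1, b2, tolerance = 1e-12)
  }
})

test_that("score_bias groups by participant and session", {
  pairs <- apa_pairs()
  sched <- apa_schedule(pairs, seed = 2)
  logs <- purrr::map_dfr(c("P1", "P2"), function(pid) {
    resp <- simulate_respondent(
      apa_profile(theta = ifelse(pid == "P1", 1, -1), seed = 5), sched,
      seed = match(pid, c("P1", "P2")))
    dplyr::mutate(resp$trials, participant_id = pid, session = 1L)
  })
  scores <- score_bias(logs, sched)
  expect_equal(nrow(scores), 2)
  expect_true(all(c("participant_id", "session", "bias") %in% names(scores)))
  expect_gt(scores$bias[scores$participant_id == "P1"],
            scores$bias[scores$participant_id == "P2"])
})
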