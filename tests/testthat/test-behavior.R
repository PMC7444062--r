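test_that("epoch classifier reproduces the printed cut-point boundaries", {
  expect_equal(classify_epoch(c(0, 25, 26, 573, 574, 1002, 1003, 50000)),
               c("SEDENTARY", "SEDENTARY", "LIGHT", "LIGHT",
                 "MODERATE", "MODERATE", "VIGOROUS", "VIGOROUS"))
  expect_error(classify_epoch(-1), "non-negative")
})

test_that("epoch classes partition the non-negative integers", {
  counts <- 0:2000
  got <- classify_epoch(counts)
  # independent interval-lookup oracle
  want <- c("SEDENTARY", "LIGHT", "MODERATE", "VIGOROUS")[
    findInterval(counts, c(0, 26, 574, 1003))]
  expect_identical(got, want)
})

mk_epochs <- function(date, counts, state = "AWAKE_WEAR") {
  n <- length(counts)
  tibble::tibble(
    timestamp = as.POSIXct(date, tz = "UTC") + 15 * (seq_len(n) - 1),
    counts = counts,
    wear_state = state
  )
}

test_that("daily summaries convert epoch counts to intensity minutes", {
  day <- mk_epochs("2024-03-04 08:00:00", rep(0L, 2400))
  s <- summarize_days(day)
  expect_equal(s$sedentary_min, 600)
  expect_equal(s$awake_wear_min, 600)
  expect_equal(s$mvpa_min, 0)
  expect_false(s$is_weekend)

  day2 <- mk_epochs("2024-03-09 08:00:00", c(rep(1200L, 40), rep(0L, 2360)))
  s2 <- summarize_days(day2)
  expect_equal(s2$mvpa_min, 10)
  expect_equal(s2$vigorous_min, 10)
  expect_true(s2$is_weekend)
})

test_that("sleep and non-wear epochs are excluded from all minutes", {
  awake <- mk_epochs("2024-03-04 08:00:00", rep(600L, 100))
  sleep <- mk_epochs("2024-03-04 23:00:00", rep(5000L, 100), "SLEEP")
  nonwear <- mk_epochs("2024-03-04 12:00:00", rep(700L, 50), "NON_WEAR")
  s <- summarize_days(dplyr::bind_rows(awake, sleep, nonwear))
  expect_equal(s$awake_wear_min, 25)
  expect_equal(s$moderate_min, 25)
  expect_equal(s$vigorous_min, 0)
})

test_that("intensity minutes always sum to awake-wear minutes", {
  set.seed(31)
  days <- purrr::map_dfr(1:5, function(d) {
    mk_epochs(sprintf("2024-03-%02d 08:00:00", d),
              sample(0:2000, 500, replace = TRUE),
              sample(c("AWAKE_WEAR", "SLEEP", "NON_WEAR"), 500, TRUE,
                     prob = c(0.7, 0.2, 0.1)))
  })
  s <- summarize_days(days)
  expect_equal(s$sedentary_min + s$light_min + s$moderate_min +
                 s$vigorous_min, s$awake_wear_min)
  expect_equal(s$mvpa_min, s$moderate_min + s$vigorous_min)
})

mk_day <- function(date, hours) {
  tibble::tibble(
    date = as.Date(date), awake_wear_min = hours * 60,
    sedentary_min = hours * 60, light_min = 0, moderate_min = 0,
    vigorous_min = 0, mvpa_min = 0,
    is_weekend = format(as.Date(date), "%u") %in% c("6", "7")
  )
}

test_that("wear validity needs 4 x 10h days including a weekend day", {
  # Mon-Thu + Sat, all 10h
  ok <- dplyr::bind_rows(
    purrr::map(c("2024-03-04", "2024-03-05", "2024-03-06", "2024-03-07",
                 "2024-03-09"), mk_day, hours = 10))
  expect_true(check_wear_validity(ok)$valid)

  # six valid weekdays, no weekend
  wk <- dplyr::bind_rows(purrr::map(sprintf("2024-03-%02d", 4:8), mk_day,
                                    hours = 11))
  wk <- dplyr::bind_rows(wk, mk_day("2024-03-11", 11))
  v <- check_wear_validity(wk)
  expect_equal(v$n_valid_days, 6)
  expect_false(v$valid)

  # a 9.9-hour day is itself invalid
  short <- check_wear_validity(mk_day("2024-03-04", 9.9))
  expect_false(short$days$valid_day)
})

test_that("adding a valid day never invalidates an overall-valid period", {
  base <- dplyr::bind_rows(
    purrr::map(c("2024-03-04", "2024-03-05", "2024-03-06", "2024-03-09"),
               mk_day, hours = 10))
  expect_true(check_wear_validity(base)$valid)
  more <- dplyr::bind_rows(base, mk_day("2024-03-07", 12))
  expect_true(check_wear_validity(more)$valid)
})

test_that("free-play scoring is the percent of sedentary intervals", {
  log <- rep(c("SEDENTARY", "MOVING"), c(68, 52))
  expect_equal(score_free_play(log), 100 * 68 / 120)
  expect_equal(score_free_play(rep("SEDENTARY", 10)), 100)
  expect_equal(score_free_play(rep("STANDING", 10)), 0)
  expect_equal(score_free_play(sample(log)), score_free_play(log))
  expect_error(score_free_play(character()), "empty")
  expect_error(score_free_play(c("SEDENTARY", "NAPPING")), "unknown")
})

test_that("inter-rater agreement is percent matching intervals", {
  a <- rep(c("SEDENTARY", "MOVING", "STANDING"), 40)
  expect_equal(interrater_agreement(a, a), 100)
  b <- a
  b[1:10] <- ifelse(a[1:10] == "MOVING", "STANDING", "MOVING")
  expect_equal(interrater_agreement(a, b), 100 * 110 / 120)
  expect_equal(interrater_agreement(c("MOVING", "MOVING"),
                                    c("SEDENTARY", "STANDING")), 0)
  expect_error(interrater_agreement(a, a[-1]), "length")
})

test_that("VO2peak attainment requires two of the four criteria", {
  base <- tibble::tibble(
    watts = c(0, 20, 40, 60), vo2_ml_kg_min = c(8, 18, 28, 38),
    rer = c(0.85, 0.9, 0.95, 1.05), hr = c(90, 120, 150, 185),
    rpe = c(6, 8, 11, 15))
  # RER >= 1 and HR >= 0.9 * (208 - 0.7 * 12) = 179.6; no plateau, RPE < 19
  res <- check_vo2peak(base, age = 12)
  expect_true(res$attained)
  expect_equal(res$n_met, 2)
  expect_false(res$criteria[["plateau"]])

  only_rer <- dplyr::mutate(base, hr = c(90, 110, 130, 150))
  res1 <- check_vo2peak(only_rer, age = 12)
  expect_false(res1$attained)
  expect_equal(res1$n_met, 1)

  # plateau: gain < 2.1 mL/kg/min across a loaded stage increase
  plat <- dplyr::mutate(base, vo2_ml_kg_min = c(8, 18, 28, 29.5))
  expect_true(check_vo2peak(plat, age = 12)$criteria[["plateau"]])
})

test_that("missing channels disable only their criteria", {
  test <- tibble::tibble(watts = c(0, 20, 40), vo2_ml_kg_min = c(8, 20, 32),
                         rer = c(0.9, 1.0, 1.1))
  res <- check_vo2peak(test, age = 10)
  expect_true(is.na(res$criteria[["hr"]]))
  expect_true(is.na(res$criteria[["rpe"]]))
  expect_true(res$criteria[["rer"]])
  expect_error(check_vo2peak(test[1, ], age = 10), "2 stages")
})

test_that("VO2 per kg fat-free mass is plain unit arithmetic", {
  expect_equal(vo2_per_ffm(2.0, 50), 40)
  test <- tibble::tibble(watts = c(0, 30), vo2_ml_kg_min = c(10, 30),
                         vo2_l_min = c(1.0, 2.0))
  expect_equal(check_vo2peak(test, age = 12, ffm_kg = 50)$vo2peak_ffm, 40)
})

test_that("criterion count is monotone in threshold relaxation", {
  test <- tibble::tibble(
    watts = c(0, 20, 40), vo2_ml_kg_min = c(8, 20, 30),
    rer = c(0.85, 0.9, 0.97), hr = c(100, 140, 170), rpe = c(6, 10, 16))
  strict <- check_vo2peak(test, age = 12)$n_met
  relaxed <- check_vo2peak(test, age = 12, rer_min = 0.95, hr_frac = 0.8,
                           rpe_min = 15, plateau_delta = 15)$n_met
  expect_gte(relaxed, strict)
})

test_that("body-composition indices follow the two printed formulas", {
  bc <- body_composition(15, 50, 1.5)
  expect_equal(bc$pct_body_fat, 30)
  expect_equal(bc$fmi, 15 / 1.5^2)
  expect_equal(body_composition(50, 50, 1.6)$pct_body_fat, 100)
  expect_error(body_composition(60, 50, 1.5), "exceed")
  expect_error(body_composition(-1, 50, 1.5), "positive")
})

test_that("FMI equals %BF x BMI / 100 on random valid inputs", {
  set.seed(91)
  for (i in 1:100) {
    w <- runif(1, 20, 120)
    h <- runif(1, 1.1, 1.9)
    f <- runif(1, 0.05, 0.55) * w
    bc <- body_composition(f, w, h)
    # both sides computed independently of body_composition internals
    lhs <- f / h^2
    rhs <- (100 * f / w) * (w / h^2) / 100
    expect_equal(bc$fmi, lhs, tolerance = 1e-12)
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("weight-status classes follow the percentile cut-offs", {
  expect_equal(classify_weight_status(20, 90), "OVERWEIGHT")
  expect_equal(classify_weight_status(18, 50), "HEALTHY")
  expect_equal(classify_weight_status(13, 3), "UNDERWEIGHT")
  expect_equal(classify_weight_status(26, 96, bmi_at_p95 = 25), "OBESITY")
  expect_equal(classify_weight_status(1.25 * 25, 97, bmi_at_p95 = 25),
               "SEVERE_OBESITY")
  # exactly at the 85th and 95th boundaries
  expect_equal(classify_weight_status(20, 85), "OVERWEIGHT")
  expect_equal(classify_weight_status(30, 95, bmi_at_p95 = 31), "OBESITY")
  res <- classify_weight_status(bmi_percentile = 97)
  expect_equal(as.character(res), "OBESITY")
  expect_true(attr(res, "severe_undetermined"))
  expect_error(classify_weight_status(20, 105), "\\[0, 100\\]")
})
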