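#' Define a simulated respondent
#'
#' A respondent is described by a latent utility for each activity. The
#' latent sedentary-preference `theta` is the mean sedentary utility minus
#' the mean physical utility; the choice and reaction-time mechanism below
#' turns utilities into trial logs.
#'
#' Utilities are drawn as `N(theta/2, utility_sd)` for sedentary and
#' `N(-theta/2, utility_sd)` for physical activities, so the category-mean
#' gap is centred on `theta`. The default within-category spread
#' (`utility_sd = 0.3`) keeps individual activities distinguishable while
#' the category contrast still dominates cross-category choices.
#'
#' @param theta Latent sedentary preference; 0 is indifferent, positive
#'   prefers sedentary.
#' @param beta Choice sensitivity (inverse temperature) of the logistic
#'   choice rule; 0 is random choice, large values are near-deterministic.
#' @param rt_base Baseline reaction time in seconds.
#' @param rt_slope Speed-up per unit of absolute utility gap (easy choices
#'   are faster).
#' @param rt_sigma Lognormal reaction-time noise SD.
#' @param utility_sd Within-category spread of activity utilities.
#' @param catalog Activity catalog the utilities cover.
#' @param seed Integer seed for the utility draw.
#' @return An object of class `apa_profile`: a list with the parameter
#'   values, a named `utilities` vector, and the realized `theta`.
#' @export
apa_profile <- function(theta = 0, beta = 4, rt_base = 1.2, rt_slope = 0.3,
                        rt_sigma = 0.25, utility_sd = 0.3,
                        catalog = apa_catalog(), seed = NULL) {
  stopifnot(beta >= 0, rt_base > 0, rt_slope >= 0, rt_sigma >= 0,
            utility_sd >= 0)
  validate_catalog(catalog)
  utilities <- with_seed(seed, {
    mu <- ifelse(catalog$category == "SEDENTARY", theta / 2, -theta / 2)
    stats::setNames(stats::rnorm(nrow(catalog), mu, utility_sd), catalog$id)
  })
  sed <- catalog$id[catalog$category == "SEDENTARY"]
  pa <- catalog$id[catalog$category == "PHYSICAL"]
  structure(
    list(
      utilities = utilities,
      theta = mean(utilities[sed]) - mean(utilities[pa]),
      theta_target = theta,
      beta = beta, rt_base = rt_base, rt_slope = rt_slope,
      rt_sigma = rt_sigma, catalog = tibble::as_tibble(catalog)
    ),
    class = "apa_profile"
  )
}

#' @export
print.apa_profile <- function(x, ...) {
  cat("<apa_profile> theta =", signif(x$theta, 3),
      "beta =", x$beta, "rt_base =", x$rt_base, "s\n")
  invisible(x)
}

#' Simulate one respondent's session
#'
#' Generates a full trial log and VAS ratings from a latent-utility
#' respondent. On each trial the left option is chosen with probability
#' `plogis(beta * (u_left - u_right))`; the reaction time is
#' `rt_base * exp(-rt_slope * |u_left - u_right|)` times lognormal noise,
#' so easy (large-gap) choices are faster — which is exactly the signal the
#' RT-weighted bias score exploits. VAS liking and wanting are affine maps
#' of utility (`50 + 25 u`) plus noise, clipped to 0-100.
#'
#' @param profile An [apa_profile()].
#' @param schedule A schedule from [apa_schedule()].
#' @param seed Integer seed; same profile + schedule + seed reproduces the
#'   log exactly.
#' @return A list with elements `trials` (tibble: schedule columns plus
#'   `chosen_id`, `rt`, `responded`) and `vas` (tibble: `activity_id`,
#'   `liking`, `wanting`).
#' @examples
#' sched <- apa_schedule(apa_pairs(), seed = 1)
#' resp <- simulate_respondent(apa_profile(theta = 0.8, seed = 1), sched,
#'                             seed = 2)
#' score_bias(resp$trials, sched)$bias
#' @export
simulate_respondent <- function(profile, schedule, seed = NULL) {
  stopifnot(inherits(profile, "apa_profile"))
  schedule <- tibble::as_tibble(schedule)
  u <- profile$utilities
  need <- unique(c(schedule$left_id, schedule$right_id))
  missing <- setdiff(need, names(u))
  if (length(missing) > 0) {
    stop("profile lacks utilities for scheduled activity(ies): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  with_seed(seed, {
    gap <- u[schedule$left_id] - u[schedule$right_id]
    p_left <- stats::plogis(profile$beta * gap)
    # beta = Inf gives NaN at gap 0; resolve ties fairly
    p_left[is.nan(p_left)] <- 0.5
    pick_left <- unname(stats::runif(nrow(schedule)) < p_left)
    rt <- profile$rt_base * exp(-profile$rt_slope * abs(gap)) *
      stats::rlnorm(nrow(schedule), 0, profile$rt_sigma)
    trials <- dplyr::mutate(schedule,
      chosen_id = ifelse(pick_left, .data$left_id, .data$right_id),
      rt = unname(rt),
      responded = TRUE
    )
    cat_tbl <- profile$catalog
    vas_noise <- matrix(stats::rnorm(2 * nrow(cat_tbl), 0, 8), ncol = 2)
    clip01 <- function(x) pmin(pmax(x, 0), 100)
    vas <- tibble::tibble(
      activity_id = cat_tbl$id,
      liking = clip01(50 + 25 * unname(u[cat_tbl$id]) + vas_noise[, 1]),
      wanting = clip01(50 + 25 * unname(u[cat_tbl$id]) + vas_noise[, 2])
    )
    list(trials = trials, vas = vas)
  })
}
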