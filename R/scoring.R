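#' Summarize explicit liking and wanting ratings
#'
#' Before the forced-choice block, each activity is rated on 0-100 visual
#' analog scales for how much the child *likes* and *wants* to do it. The
#' category summaries are plain arithmetic means.
#'
#' @param vas A data frame with columns `activity_id`, `liking`, `wanting`
#'   (both in 0-100), and optionally `participant_id`/`session` grouping
#'   columns.
#' @param catalog Activity catalog (default [apa_catalog()]).
#' @return A tibble (one row per participant/session group if those columns
#'   are present, otherwise a single row) with `sed_liking`, `pa_liking`,
#'   `sed_wanting`, `pa_wanting`, `n_rated_sed`, `n_rated_pa`.
#' @examples
#' vas <- tibble::tibble(activity_id = apa_catalog()$id,
#'                       liking = 80, wanting = 60)
#' summarize_vas(vas)
#' @export
summarize_vas <- function(vas, catalog = apa_catalog()) {
  validate_catalog(catalog)
  vas <- tibble::as_tibble(vas)
  unknown <- setdiff(unique(vas$activity_id), catalog$id)
  if (length(unknown) > 0) {
    stop("unknown activity id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (any(vas$liking < 0 | vas$liking > 100 |
          vas$wanting < 0 | vas$wanting > 100, na.rm = TRUE)) {
    stop("VAS ratings must lie in [0, 100]", call. = FALSE)
  }
  keys <- intersect(c("participant_id", "session"), names(vas))
  vas <- dplyr::left_join(vas, catalog[, c("id", "category")],
                          by = c(activity_id = "id"))
  out <- vas %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) %>%
    dplyr::summarise(
      sed_liking = mean(.data$liking[.data$category == "SEDENTARY"]),
      pa_liking = mean(.data$liking[.data$category == "PHYSICAL"]),
      sed_wanting = mean(.data$wanting[.data$category == "SEDENTARY"]),
      pa_wanting = mean(.data$wanting[.data$category == "PHYSICAL"]),
      n_rated_sed = sum(.data$category == "SEDENTARY"),
      n_rated_pa = sum(.data$category == "PHYSICAL"),
      .groups = "drop"
    )
  if (any(out$n_rated_sed == 0 | out$n_rated_pa == 0)) {
    stop("at least one rating per category is required", call. = FALSE)
  }
  out
}

#' Screen forced-choice trials on response and reaction time
#'
#' Drops trials with no response and trials whose reaction time falls
#' outside `[min_rt, max_rt]` seconds. The thresholds are study-level
#' plumbing, not part of the task definition, so they are fully
#' configurable and `clean = FALSE` keeps every responded trial.
#'
#' @param trials Trial data frame with at least `rt` (seconds) and
#'   `responded` (logical) columns.
#' @param min_rt,max_rt Retention window in seconds (defaults 0.2 and 10).
#' @param clean If `FALSE`, only non-responses are dropped.
#' @return The retained trials, with attribute `"removals"`: a tibble
#'   counting removed trials by reason (`non_response`, `too_fast`,
#'   `too_slow`).
#' @export
clean_trials <- function(trials, min_rt = 0.2, max_rt = 10, clean = TRUE) {
  stopifnot(min_rt < max_rt)
  trials <- tibble::as_tibble(trials)
  responded <- !is.na(trials$responded) & as.logical(trials$responded)
  too_fast <- clean & responded & trials$rt < min_rt
  too_slow <- clean & responded & trials$rt > max_rt
  keep <- responded & !too_fast & !too_slow
  out <- trials[keep, ]
  attr(out, "removals") <- tibble::tibble(
    reason = c("non_response", "too_fast", "too_slow"),
    n = c(sum(!responded), sum(too_fast, na.rm = TRUE),
          sum(too_slow, na.rm = TRUE))
  )
  out
}

#' Summarize cross-category forced-choice trials
#'
#' Only head-to-head sedentary-versus-physical comparisons enter the bias
#' score; within-category trials in the log are ignored. Wins are counted by
#' the category of the chosen activity and reaction-time means are taken
#' over responded cross-category trials: `rt_all` over all of them, `rt_sed`
#' over trials where the sedentary activity won, `rt_pa` where the physical
#' activity won (`NA` when that category never won).
#'
#' @param trials Trial data frame with `pair_id`, `chosen_id`, `rt`
#'   (seconds) and `responded`; may carry `participant_id`/`session`.
#' @param pairs Pair tibble from [apa_pairs()] or a schedule from
#'   [apa_schedule()].
#' @param catalog Activity catalog used to look up the chosen activity's
#'   category.
#' @return A tibble with `win_sed`, `win_pa`, `rt_all`, `rt_sed`, `rt_pa`,
#'   `n_cross_responded`, one row per participant/session group.
#' @export
summarize_forced_choice <- function(trials, pairs, catalog = apa_catalog()) {
  validate_catalog(catalog)
  trials <- tibble::as_tibble(trials)
  pairs <- tibble::as_tibble(pairs)
  unknown <- setdiff(unique(trials$pair_id), pairs$pair_id)
  if (length(unknown) > 0) {
    stop("trial log references unknown pair_id(s): ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  keys <- intersect(c("participant_id", "session"), names(trials))
  dat <- trials %>%
    dplyr::left_join(pairs[, c("pair_id", "left_id", "right_id", "pair_type")],
                     by = "pair_id", suffix = c("", ".pair")) %>%
    dplyr::filter(.data$pair_type == "CROSS",
                  !is.na(.data$responded) & as.logical(.data$responded))
  if (nrow(dat) > 0) {
    bad <- dat$chosen_id != dat$left_id & dat$chosen_id != dat$right_id
    if (any(bad)) {
      stop("chosen activity is not a member of its pair in ",
           sum(bad), " trial(s)", call. = FALSE)
    }
  }
  cat_of <- stats::setNames(catalog$category, catalog$id)
  dat$chosen_category <- unname(cat_of[dat$chosen_id])
  out <- dat %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) %>%
    dplyr::summarise(
      win_sed = sum(.data$chosen_category == "SEDENTARY"),
      win_pa = sum(.data$chosen_category == "PHYSICAL"),
      rt_all = mean(.data$rt),
      rt_sed = if (any(.data$chosen_category == "SEDENTARY"))
        mean(.data$rt[.data$chosen_category == "SEDENTARY"]) else NA_real_,
      rt_pa = if (any(.data$chosen_category == "PHYSICAL"))
        mean(.data$rt[.data$chosen_category == "PHYSICAL"]) else NA_real_,
      n_cross_responded = dplyr::n(),
      .groups = "drop"
    )
  out$rt_sed <- as.numeric(out$rt_sed)
  out$rt_pa <- as.numeric(out$rt_pa)
  if (nrow(out) == 0 || any(out$n_cross_responded == 0)) {
    stop("no responded cross-category trials: bias score undefined",
         call. = FALSE)
  }
  out
}

#' Compute the implicit bias score
#'
#' The implicit-wanting construct weights each category's win count by how
#' fast those wins were relative to the overall pace:
#' \deqn{IW_{SED} = WIN_{SED}\frac{RT_{ALL}}{RT_{SED}} -
#'       WIN_{PA}\frac{RT_{ALL}}{RT_{PA}}, \qquad IW_{PA} = -IW_{SED}}
#' and the raw score is \eqn{IW_{SED} - IW_{PA}}. A term whose win count is
#' zero contributes exactly zero (its undefined RT mean is never evaluated).
#' The raw score spans about \eqn{[-2N, 2N]} for \eqn{N} responded
#' cross-category trials, so it is scaled by \eqn{100/(2N)}: a respondent
#' who always picks the sedentary option at a constant pace scores exactly
#' +100, the mirror image -100, an indifferent equal-pace respondent 0.
#' Faster-than-average wins can push the scaled score slightly past the
#' nominal bounds; those values are clipped to \eqn{[-100, 100]} and
#' flagged. Positive scores mean a relative preference for sedentary
#' activities.
#'
#' @param summary A tibble from [summarize_forced_choice()] (any extra
#'   columns such as `participant_id` are carried through).
#' @return The input with columns `iw_sed`, `iw_pa`, `raw`, `bias`,
#'   `clipped` appended.
#' @examples
#' s <- tibble::tibble(win_sed = 40, win_pa = 24, rt_all = 1.1875,
#'                     rt_sed = 1, rt_pa = 1.5, n_cross_responded = 64)
#' compute_bias(s)$bias
#' @export
compute_bias <- function(summary) {
  summary <- tibble::as_tibble(summary)
  needed <- c("win_sed", "win_pa", "rt_all", "rt_sed", "rt_pa",
              "n_cross_responded")
  missing <- setdiff(needed, names(summary))
  if (length(missing) > 0) {
    stop("summary is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(summary$n_cross_responded <= 0)) {
    stop("bias score undefined with zero responded cross-category trials",
         call. = FALSE)
  }
  term_sed <- ifelse(summary$win_sed > 0,
                     summary$win_sed * summary$rt_all / summary$rt_sed, 0)
  term_pa <- ifelse(summary$win_pa > 0,
                    summary$win_pa * summary$rt_all / summary$rt_pa, 0)
  iw_sed <- term_sed - term_pa
  raw <- 2 * iw_sed
  bias_unclipped <- raw * 100 / (2 * summary$n_cross_responded)
  out <- summary
  out$iw_sed <- iw_sed
  out$iw_pa <- -iw_sed
  out$raw <- raw
  out$bias <- pmin(pmax(bias_unclipped, -100), 100)
  out$clipped <- abs(bias_unclipped) > 100
  out
}

#' Score a forced-choice trial log end-to-end
#'
#' Convenience pipeline: [clean_trials()] then [summarize_forced_choice()]
#' then [compute_bias()], preserving per-participant grouping.
#'
#' @inheritParams summarize_forced_choice
#' @inheritParams clean_trials
#' @return A tibble of bias scores, one row per participant/session group.
#' @export
score_bias <- function(trials, pairs, catalog = apa_catalog(),
                       min_rt = 0.2, max_rt = 10, clean = TRUE) {
  trials %>%
    clean_trials(min_rt = min_rt, max_rt = max_rt, clean = clean) %>%
    summarize_forced_choice(pairs, catalog) %>%
    compute_bias()
}
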