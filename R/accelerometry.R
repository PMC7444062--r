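#' Classify 15-s accelerometer epochs into intensity levels
#'
#' Applies the pediatric Evenson cut-points on counts per 15-s epoch (CPE):
#' 0-25 sedentary, 26-573 light, 574-1002 moderate, >= 1003 vigorous. The
#' bounds are inclusive, so the classes partition the non-negative
#' integers.
#'
#' @param counts Non-negative integer vector of counts per 15-s epoch.
#' @return Character vector of `"SEDENTARY"`, `"LIGHT"`, `"MODERATE"`,
#'   `"VIGOROUS"`.
#' @examples
#' classify_epoch(c(0, 25, 26, 573, 574, 1002, 1003))
#' @export
classify_epoch <- function(counts) {
  if (any(counts < 0, na.rm = TRUE)) {
    stop("epoch counts must be non-negative", call. = FALSE)
  }
  dplyr::case_when(
    counts <= 25 ~ "SEDENTARY",
    counts <= 573 ~ "LIGHT",
    counts <= 1002 ~ "MODERATE",
    TRUE ~ "VIGOROUS"
  )
}

#' Summarize an epoch series into daily activity totals
#'
#' Aggregates a 15-s epoch series to one row per calendar day, counting
#' minutes per intensity over awake-wear epochs only (each epoch is 0.25
#' min); sleep and non-wear epochs contribute nothing. MVPA is moderate
#' plus vigorous minutes; weekend days are Saturday and Sunday.
#'
#' @param epochs A data frame with columns `timestamp` (POSIXct or
#'   parseable datetime string), `counts`, `wear_state` (`"AWAKE_WEAR"`,
#'   `"NON_WEAR"`, `"SLEEP"`).
#' @return A tibble with `date`, `awake_wear_min`, `sedentary_min`,
#'   `light_min`, `moderate_min`, `vigorous_min`, `mvpa_min`, `is_weekend`.
#' @export
summarize_days <- function(epochs) {
  epochs <- tibble::as_tibble(epochs)
  if (is.character(epochs$timestamp)) {
    epochs$timestamp <- as.POSIXct(epochs$timestamp, tz = "UTC")
  }
  bad_state <- setdiff(unique(epochs$wear_state),
                       c("AWAKE_WEAR", "NON_WEAR", "SLEEP"))
  if (length(bad_state) > 0) {
    stop("unknown wear_state value(s): ", paste(bad_state, collapse = ", "),
         call. = FALSE)
  }
  epochs$date <- as.Date(epochs$timestamp, tz = "UTC")
  awake <- epochs[epochs$wear_state == "AWAKE_WEAR", ]
  awake$intensity <- classify_epoch(awake$counts)
  mins <- function(x) 0.25 * x
  out <- awake %>%
    dplyr::group_by(date = .data$date) %>%
    dplyr::summarise(
      awake_wear_min = mins(dplyr::n()),
      sedentary_min = mins(sum(.data$intensity == "SEDENTARY")),
      light_min = mins(sum(.data$intensity == "LIGHT")),
      moderate_min = mins(sum(.data$intensity == "MODERATE")),
      vigorous_min = mins(sum(.data$intensity == "VIGOROUS")),
      .groups = "drop"
    )
  # days present in the series but with no awake wear get a zeroed row
  all_days <- tibble::tibble(date = sort(unique(epochs$date)))
  out <- dplyr::left_join(all_days, out, by = "date") %>%
    dplyr::mutate(dplyr::across(dplyr::where(is.numeric),
                                ~ tidyr::replace_na(.x, 0)))
  out %>%
    dplyr::mutate(
      mvpa_min = .data$moderate_min + .data$vigorous_min,
      is_weekend = format(.data$date, "%u") %in% c("6", "7")
    )
}

#' Check accelerometer wear validity
#'
#' The measurement period counts as valid when at least `min_days` days
#' have at least `min_hours` hours of awake wear (sleep excluded), of which
#' at least `min_weekend_days` fall on a weekend.
#'
#' @param summaries Daily summaries from [summarize_days()].
#' @param min_days Minimum number of valid days (default 4).
#' @param min_hours Minimum awake-wear hours for a day to be valid
#'   (default 10).
#' @param min_weekend_days Minimum valid weekend days (default 1).
#' @return A list with `days` (the summaries plus a `valid_day` flag),
#'   `n_valid_days`, `n_valid_weekend_days`, and the overall `valid` flag.
#' @export
check_wear_validity <- function(summaries, min_days = 4, min_hours = 10,
                                min_weekend_days = 1) {
  summaries <- tibble::as_tibble(summaries)
  days <- dplyr::mutate(summaries,
                        valid_day = .data$awake_wear_min >= min_hours * 60)
  n_valid <- sum(days$valid_day)
  n_valid_we <- sum(days$valid_day & days$is_weekend)
  list(
    days = days,
    n_valid_days = n_valid,
    n_valid_weekend_days = n_valid_we,
    valid = n_valid >= min_days && n_valid_we >= min_weekend_days
  )
}
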