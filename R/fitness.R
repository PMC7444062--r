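#' Evaluate VO2peak attainment criteria
#'
#' A graded cycle-ergometer test to volitional fatigue counts as a true
#' VO2peak when at least two of four criteria hold: (1) a plateau in VO2 —
#' change < 2.1 mL/kg/min across an increase in workload, evaluated
#' between consecutive stages with increased watts; (2) respiratory
#' exchange ratio >= 1.0; (3) heart rate >= 90% of the predicted maximum;
#' (4) rating of perceived exertion >= 19 on the 6-20 Borg scale. Because
#' adiposity confounds weight-relative fitness in children, the peak is
#' also expressed per kg fat-free mass.
#'
#' A criterion whose channel is absent from the data (e.g. no RPE column)
#' is reported as not evaluable (`NA`) and does not count toward the two
#' required.
#'
#' @param test A data frame with one row per stage, in order: `watts`,
#'   `vo2_ml_kg_min` and optionally `vo2_l_min`, `rer`, `hr`, `rpe`.
#' @param age Participant age in years, used for predicted maximal HR.
#' @param ffm_kg Fat-free mass in kg; needed for the per-FFM expression
#'   (supply `vo2_l_min` on at least the peak stage).
#' @param hrmax_model Function mapping age to predicted maximal heart rate;
#'   default `208 - 0.7 * age`.
#' @param plateau_delta Plateau threshold in mL/kg/min (default 2.1).
#' @param rer_min,hr_frac,rpe_min The other criterion thresholds.
#' @return A list with `criteria` (named logical, `NA` = not evaluable),
#'   `n_met`, `attained`, `vo2peak_ml_kg_min`, and `vo2peak_ffm` (mL/kg
#'   FFM/min, `NA` when absolute VO2 or FFM is unavailable).
#' @examples
#' test <- tibble::tibble(watts = c(0, 20, 40, 60),
#'                        vo2_ml_kg_min = c(8, 20, 30, 31),
#'                        rer = c(0.8, 0.9, 1.0, 1.08),
#'                        hr = c(90, 130, 170, 190),
#'                        rpe = c(6, 9, 14, 18))
#' check_vo2peak(test, age = 12)$attained
#' @export
check_vo2peak <- function(test, age, ffm_kg = NULL,
                          hrmax_model = function(age) 208 - 0.7 * age,
                          plateau_delta = 2.1, rer_min = 1.0,
                          hr_frac = 0.9, rpe_min = 19) {
  test <- tibble::as_tibble(test)
  if (nrow(test) < 2) stop("need at least 2 stages", call. = FALSE)
  has <- function(col) col %in% names(test) && any(!is.na(test[[col]]))

  plateau <- NA
  if (has("vo2_ml_kg_min") && has("watts")) {
    dv <- diff(test$vo2_ml_kg_min)
    dw <- diff(test$watts)
    loaded <- which(dw > 0)
    if (length(loaded) > 0) {
      plateau <- any(dv[loaded] < plateau_delta, na.rm = TRUE)
    }
  }
  rer_ok <- if (has("rer")) max(test$rer, na.rm = TRUE) >= rer_min else NA
  hr_ok <- if (has("hr")) {
    max(test$hr, na.rm = TRUE) >= hr_frac * hrmax_model(age)
  } else NA
  rpe_ok <- if (has("rpe")) max(test$rpe, na.rm = TRUE) >= rpe_min else NA

  criteria <- c(plateau = plateau, rer = rer_ok, hr = hr_ok, rpe = rpe_ok)
  n_met <- sum(criteria, na.rm = TRUE)

  vo2peak <- if (has("vo2_ml_kg_min")) {
    max(test$vo2_ml_kg_min, na.rm = TRUE)
  } else NA_real_
  vo2_ffm <- NA_real_
  if (!is.null(ffm_kg) && has("vo2_l_min")) {
    vo2_ffm <- 1000 * max(test$vo2_l_min, na.rm = TRUE) / ffm_kg
  }
  list(criteria = criteria, n_met = n_met, attained = n_met >= 2,
       vo2peak_ml_kg_min = vo2peak, vo2peak_ffm = vo2_ffm)
}

#' Express an absolute VO2 per kilogram of fat-free mass
#'
#' @param vo2_l_min Absolute oxygen uptake in L/min.
#' @param ffm_kg Fat-free mass in kg.
#' @return VO2 in mL/kg FFM/min.
#' @examples
#' vo2_per_ffm(2.0, 50) # 40
#' @export
vo2_per_ffm <- function(vo2_l_min, ffm_kg) {
  stopifnot(all(vo2_l_min > 0), all(ffm_kg > 0))
  1000 * vo2_l_min / ffm_kg
}
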