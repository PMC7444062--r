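#' Body-composition indices from DXA fat mass
#'
#' Percent body fat is total body fat (kg) divided by weight (kg) times
#' 100; fat mass index is total body fat (kg) divided by height (m)
#' squared. Note the algebraic identity `fmi = pct_body_fat * bmi / 100`.
#'
#' @param fat_kg Total body fat mass in kg.
#' @param weight_kg Body weight in kg (must be >= `fat_kg`).
#' @param height_m Height in metres.
#' @return A tibble with `pct_body_fat` (%) and `fmi` (kg/m^2).
#' @examples
#' body_composition(15, 50, 1.5)
#' @export
body_composition <- function(fat_kg, weight_kg, height_m) {
  if (any(fat_kg <= 0) || any(weight_kg <= 0) || any(height_m <= 0)) {
    stop("fat mass, weight and height must all be positive", call. = FALSE)
  }
  if (any(fat_kg > weight_kg)) {
    stop("fat mass cannot exceed body weight", call. = FALSE)
  }
  tibble::tibble(
    pct_body_fat = 100 * fat_kg / weight_kg,
    fmi = fat_kg / height_m^2
  )
}

#' Classify weight status from BMI percentile
#'
#' CDC-style pediatric categories: overweight is a BMI percentile >= 85
#' but < 95, obesity is >= 95, and severe obesity is a BMI of at least
#' 120% of the 95th-percentile BMI for age and sex. The underweight bound
#' is configurable (default percentile < 5). Percentiles and the
#' 95th-percentile BMI come from an external growth reference and are
#' consumed as inputs.
#'
#' @param bmi BMI in kg/m^2 (needed only to resolve severe obesity).
#' @param bmi_percentile Age- and sex-specific BMI percentile in `[0, 100]`.
#' @param bmi_at_p95 BMI value at the 95th percentile for the child's age
#'   and sex; when missing and `bmi_percentile >= 95`, the result is
#'   `"OBESITY"` with attribute `severe_undetermined = TRUE`.
#' @param underweight_percentile Lower cut-off (default 5).
#' @return One of `"UNDERWEIGHT"`, `"HEALTHY"`, `"OVERWEIGHT"`,
#'   `"OBESITY"`, `"SEVERE_OBESITY"`.
#' @examples
#' classify_weight_status(25, 90)
#' classify_weight_status(32, 97, bmi_at_p95 = 25)
#' @export
classify_weight_status <- function(bmi = NA_real_, bmi_percentile,
                                   bmi_at_p95 = NA_real_,
                                   underweight_percentile = 5) {
  stopifnot(length(bmi_percentile) == 1)
  if (is.na(bmi_percentile) || bmi_percentile < 0 || bmi_percentile > 100) {
    stop("bmi_percentile must lie in [0, 100]", call. = FALSE)
  }
  if (bmi_percentile < underweight_percentile) return("UNDERWEIGHT")
  if (bmi_percentile < 85) return("HEALTHY")
  if (bmi_percentile < 95) return("OVERWEIGHT")
  if (is.na(bmi_at_p95) || is.na(bmi)) {
    return(structure("OBESITY", severe_undetermined = TRUE))
  }
  if (bmi >= 1.2 * bmi_at_p95) return("SEVERE_OBESITY")
  "OBESITY"
}
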