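#' Run the full validation analysis grid on a cohort table
#'
#' Reproduces the validation study's analysis plan on any cohort table
#' (real or simulated): the correlation of the bias score with each
#' validation measure, raw and adjusted for age, sex and race/ethnicity;
#' sex-stratified accelerometry correlations; test-retest reliability of
#' the bias score (two-way mixed, absolute-agreement, single-measure ICC);
#' descriptive statistics; and the fraction of the cohort with a
#' sedentary-leaning (positive) bias. A failing cell (e.g. a missing
#' column or too few complete pairs) is reported as `NA` with the error
#' message attached — the grid never aborts as a whole.
#'
#' @param cohort A data frame with a `bias` column and any of:
#'   `bias_retest`, `freeplay_sed_pct`, `daily_sed_min`, `daily_mvpa_min`,
#'   `vo2peak_ffm`, `bmi_z`, `pct_body_fat`, `fmi`; covariates `age`,
#'   `sex`, `race_group` enable the adjusted column.
#' @param measures Character vector of measure columns to correlate with
#'   `bias` (default: the standard validation set intersected with the
#'   cohort's columns).
#' @return An object of class `apa_validation`: a list with tibbles
#'   `correlations` (measure, raw and adjusted r/p/n), `sex_stratified`
#'   (accelerometry measures by sex), `reliability` (ICC row or NULL),
#'   `descriptives`, and scalars `n`, `pct_sed_pref`.
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n = 60), seed = 1)
#' rep <- run_validation_report(cohort)
#' tidy(rep)
#' @export
run_validation_report <- function(cohort, measures = NULL) {
  cohort <- tibble::as_tibble(cohort)
  if (!"bias" %in% names(cohort)) {
    stop("cohort must contain a `bias` column", call. = FALSE)
  }
  standard <- c("freeplay_sed_pct", "daily_sed_min", "daily_mvpa_min",
                "vo2peak_ffm", "bmi_z", "pct_body_fat", "fmi")
  if (is.null(measures)) measures <- intersect(standard, names(cohort))
  covars <- intersect(c("age", "sex", "race_group"), names(cohort))

  cell <- function(f) {
    tryCatch(f(), error = function(e) {
      tibble::tibble(r = NA_real_, p = NA_real_, n = NA_integer_,
                     note = conditionMessage(e))
    })
  }
  one_measure <- function(m) {
    raw <- cell(function() apa_pearson(cohort$bias, cohort[[m]]))
    adj <- if (length(covars) > 0) {
      cell(function() {
        out <- apa_partial_correlation(cohort$bias, cohort[[m]],
                                       cohort[, covars])
        out[, c("r", "p", "n")]
      })
    } else {
      tibble::tibble(r = NA_real_, p = NA_real_, n = NA_integer_,
                     note = "no covariate columns")
    }
    tibble::tibble(
      measure = m,
      r = raw$r, p = raw$p, n = raw$n,
      r_adjusted = adj$r, p_adjusted = adj$p, n_adjusted = adj$n,
      note = dplyr::coalesce(
        if ("note" %in% names(raw)) raw$note else NA_character_,
        if ("note" %in% names(adj)) adj$note else NA_character_)
    )
  }
  correlations <- purrr::map_dfr(measures, one_measure)

  accel <- intersect(c("daily_sed_min", "daily_mvpa_min"), measures)
  sex_stratified <- NULL
  if ("sex" %in% names(cohort) && length(accel) > 0) {
    sex_stratified <- purrr::map_dfr(accel, function(m) {
      purrr::map_dfr(sort(unique(cohort$sex)), function(s) {
        sub <- cohort[cohort$sex == s, ]
        res <- cell(function() apa_pearson(sub$bias, sub[[m]]))
        tibble::tibble(measure = m, sex = s, r = res$r, p = res$p, n = res$n)
      })
    })
  }

  reliability <- NULL
  if ("bias_retest" %in% names(cohort)) {
    reliability <- tryCatch(
      apa_icc(cbind(cohort$bias, cohort$bias_retest)),
      error = function(e) tibble::tibble(icc = NA_real_, lower = NA_real_,
                                         upper = NA_real_, n = NA_integer_,
                                         k = 2L, note = conditionMessage(e))
    )
  }

  num_cols <- intersect(c("bias", "bias_retest", measures), names(cohort))
  descriptives <- purrr::map_dfr(num_cols, function(m) {
    x <- cohort[[m]]
    tibble::tibble(
      variable = m, n = sum(!is.na(x)),
      mean = mean(x, na.rm = TRUE), sd = stats::sd(x, na.rm = TRUE),
      min = suppressWarnings(min(x, na.rm = TRUE)),
      max = suppressWarnings(max(x, na.rm = TRUE))
    )
  })

  structure(
    list(correlations = correlations, sex_stratified = sex_stratified,
         reliability = reliability, descriptives = descriptives,
         n = nrow(cohort),
         pct_sed_pref = 100 * mean(cohort$bias > 0, na.rm = TRUE)),
    class = "apa_validation"
  )
}

#' @export
print.apa_validation <- function(x, digits = 3, ...) {
  cat("Activity Preference Assessment validation report\n")
  cat("  n =", x$n, "|", format(round(x$pct_sed_pref, 1)),
      "% sedentary-preferring (bias > 0)\n")
  if (!is.null(x$reliability) && !is.na(x$reliability$icc[1])) {
    cat("  retest ICC(A,1) =", round(x$reliability$icc, digits),
        sprintf("[%s, %s]\n", round(x$reliability$lower, digits),
                round(x$reliability$upper, digits)))
  }
  cat("\nBias-score correlations (raw | adjusted for",
      "age/sex/race):\n")
  print(as.data.frame(x$correlations[, c("measure", "r", "p",
                                         "r_adjusted", "p_adjusted")]),
        digits = digits, row.names = FALSE)
  if (!is.null(x$sex_stratified)) {
    cat("\nSex-stratified accelerometry correlations:\n")
    print(as.data.frame(x$sex_stratified), digits = digits,
          row.names = FALSE)
  }
  invisible(x)
}

#' @describeIn run_validation_report Tidy the correlation grid into one row
#'   per measure-by-adjustment cell.
#' @param x An `apa_validation` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.apa_validation <- function(x, ...) {
  raw <- dplyr::transmute(x$correlations, measure = .data$measure,
                          adjusted = FALSE, r = .data$r, p = .data$p,
                          n = .data$n)
  adj <- dplyr::transmute(x$correlations, measure = .data$measure,
                          adjusted = TRUE, r = .data$r_adjusted,
                          p = .data$p_adjusted, n = .data$n_adjusted)
  dplyr::bind_rows(raw, adj)
}

#' @describeIn run_validation_report One-row cohort-level summary.
#' @exportS3Method generics::glance
glance.apa_validation <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    pct_sed_pref = x$pct_sed_pref,
    icc = if (is.null(x$reliability)) NA_real_ else x$reliability$icc[1],
    n_measures = nrow(x$correlations)
  )
}
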