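#' Default latent correlation targets for simulated validation cohorts
#'
#' The matrix encodes the validation-study associations the cohort
#' simulator reproduces: bias with free-play sedentary time (r = 0.38),
#' VO2peak per kg fat-free mass (r = -0.52), BMI z-score (0.35), percent
#' body fat (0.43) and fat mass index (0.44); a test-retest correlation of
#' 0.59 between the two bias administrations; and near-zero association
#' with habitual accelerometer-measured activity. The remaining cells
#' (among the validation measures themselves) are plausible values for a
#' pediatric cohort — adiposity indices correlate strongly with one another
#' and negatively with fitness — chosen to make the matrix positive
#' definite; they are not study estimates. The bias-MVPA cell is
#' sex-dependent and set per stratum by [cohort_spec()].
#'
#' @return A 9x9 symmetric correlation matrix over `bias`, `bias_retest`,
#'   `freeplay_sed_pct`, `daily_sed_min`, `daily_mvpa_min`, `vo2peak_ffm`,
#'   `bmi_z`, `pct_body_fat`, `fmi`.
#' @export
default_cohort_correlations <- function() {
  v <- c("bias", "bias_retest", "freeplay_sed_pct", "daily_sed_min",
         "daily_mvpa_min", "vo2peak_ffm", "bmi_z", "pct_body_fat", "fmi")
  R <- diag(length(v))
  dimnames(R) <- list(v, v)
  set_r <- function(a, b, r) {
    R[a, b] <<- r
    R[b, a] <<- r
  }
  set_r("bias", "bias_retest", 0.59)
  set_r("bias", "freeplay_sed_pct", 0.38)
  set_r("bias", "daily_sed_min", 0.05)
  set_r("bias", "daily_mvpa_min", 0)
  set_r("bias", "vo2peak_ffm", -0.52)
  set_r("bias", "bmi_z", 0.35)
  set_r("bias", "pct_body_fat", 0.43)
  set_r("bias", "fmi", 0.44)
  # second administration relates to the measures only through the first
  for (x in v[-(1:2)]) set_r("bias_retest", x, 0.59 * R["bias", x])
  set_r("freeplay_sed_pct", "daily_sed_min", 0.10)
  set_r("freeplay_sed_pct", "daily_mvpa_min", -0.10)
  set_r("freeplay_sed_pct", "vo2peak_ffm", -0.20)
  set_r("freeplay_sed_pct", "bmi_z", 0.15)
  set_r("freeplay_sed_pct", "pct_body_fat", 0.20)
  set_r("freeplay_sed_pct", "fmi", 0.20)
  set_r("daily_sed_min", "daily_mvpa_min", -0.25)
  set_r("daily_sed_min", "vo2peak_ffm", -0.15)
  set_r("daily_sed_min", "bmi_z", 0.15)
  set_r("daily_sed_min", "pct_body_fat", 0.20)
  set_r("daily_sed_min", "fmi", 0.20)
  set_r("daily_mvpa_min", "vo2peak_ffm", 0.40)
  set_r("daily_mvpa_min", "bmi_z", -0.20)
  set_r("daily_mvpa_min", "pct_body_fat", -0.30)
  set_r("daily_mvpa_min", "fmi", -0.30)
  set_r("vo2peak_ffm", "bmi_z", -0.40)
  set_r("vo2peak_ffm", "pct_body_fat", -0.55)
  set_r("vo2peak_ffm", "fmi", -0.55)
  set_r("bmi_z", "pct_body_fat", 0.80)
  set_r("bmi_z", "fmi", 0.85)
  set_r("pct_body_fat", "fmi", 0.90)
  R
}

#' Default marginal means and SDs for simulated cohorts
#'
#' Cohort descriptives of the validation sample: bias 18.8 (46.2),
#' free-play percent sedentary 57 (36), daily sedentary 151 (49) min, daily
#' MVPA 45 (17) min, VO2peak 40.5 (8.1) mL/kg FFM/min, BMI z 0.69 (1.24),
#' percent body fat 31.5 (9.0). Fat mass index descriptives are not
#' reported, so a plausible pediatric value of 7.5 (3.6) kg/m^2 is used.
#' The retest bias shares the first administration's marginal.
#'
#' @return A tibble with columns `variable`, `mean`, `sd`.
#' @export
default_cohort_marginals <- function() {
  tibble::tribble(
    ~variable, ~mean, ~sd,
    "bias", 18.8, 46.2,
    "bias_retest", 18.8, 46.2,
    "freeplay_sed_pct", 57, 36,
    "daily_sed_min", 151, 49,
    "daily_mvpa_min", 45, 17,
    "vo2peak_ffm", 40.5, 8.1,
    "bmi_z", 0.69, 1.24,
    "pct_body_fat", 31.5, 9.0,
    "fmi", 7.5, 3.6
  )
}

check_corr_matrix <- function(R, label) {
  if (!isTRUE(all.equal(R, t(R)))) {
    stop(label, " correlation matrix is not symmetric", call. = FALSE)
  }
  if (any(abs(diag(R) - 1) > 1e-12)) {
    stop(label, " correlation matrix must have a unit diagonal",
         call. = FALSE)
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    stop(label, " correlation matrix is not positive semidefinite ",
         "(smallest eigenvalue ", signif(min(ev), 4), ")", call. = FALSE)
  }
  invisible(R)
}

#' Specify a synthetic validation cohort
#'
#' Bundles everything [simulate_cohort()] needs: cohort size, marginal
#' means/SDs, the latent correlation matrix, and the sex-dependent
#' bias-MVPA association (the accelerometer association is present in girls
#' only, r = -0.41, and absent in boys). Measures are drawn from a
#' multivariate normal per sex stratum with the stated margins; covariates
#' (age 8-17, a 50/50 sex split, and a 42% white / 58% racial-ethnic
#' minority split) are drawn independently of the measures.
#'
#' @param n Cohort size (default 60).
#' @param correlations Base correlation matrix (default
#'   [default_cohort_correlations()]).
#' @param marginals Tibble of `variable`, `mean`, `sd` (default
#'   [default_cohort_marginals()]).
#' @param mvpa_r_girls,mvpa_r_boys Latent bias-MVPA correlation per sex
#'   stratum (defaults -0.41 and 0).
#' @param prop_female,prop_white Covariate mixture proportions.
#' @return An object of class `apa_cohort_spec`. Both per-stratum matrices
#'   are validated (symmetry, unit diagonal, positive semidefiniteness).
#' @export
cohort_spec <- function(n = 60, correlations = default_cohort_correlations(),
                        marginals = default_cohort_marginals(),
                        mvpa_r_girls = -0.41, mvpa_r_boys = 0,
                        prop_female = 0.5, prop_white = 0.42) {
  stopifnot(n >= 2, prop_female >= 0, prop_female <= 1,
            prop_white >= 0, prop_white <= 1)
  marginals <- tibble::as_tibble(marginals)
  vars <- rownames(correlations)
  if (!setequal(vars, marginals$variable)) {
    stop("correlation matrix and marginals must cover the same variables",
         call. = FALSE)
  }
  marginals <- marginals[match(vars, marginals$variable), ]
  mk_sex <- function(r_mvpa) {
    R <- correlations
    if (all(c("bias", "daily_mvpa_min") %in% vars)) {
      R["bias", "daily_mvpa_min"] <- R["daily_mvpa_min", "bias"] <- r_mvpa
      if ("bias_retest" %in% vars) {
        retest_r <- R["bias", "bias_retest"]
        R["bias_retest", "daily_mvpa_min"] <-
          R["daily_mvpa_min", "bias_retest"] <- retest_r * r_mvpa
      }
    }
    R
  }
  cor_girls <- check_corr_matrix(mk_sex(mvpa_r_girls), "girls")
  cor_boys <- check_corr_matrix(mk_sex(mvpa_r_boys), "boys")
  structure(
    list(n = as.integer(n), variables = vars, marginals = marginals,
         cor_girls = cor_girls, cor_boys = cor_boys,
         prop_female = prop_female, prop_white = prop_white),
    class = "apa_cohort_spec"
  )
}

#' @export
print.apa_cohort_spec <- function(x, ...) {
  cat("<apa_cohort_spec> n =", x$n, "|", length(x$variables), "measures |",
      "bias-MVPA r:", x$cor_girls["bias", "daily_mvpa_min"], "(girls),",
      x$cor_boys["bias", "daily_mvpa_min"], "(boys)\n")
  invisible(x)
}

#' Simulate a validation cohort
#'
#' Draws a cohort table from a [cohort_spec()]: per sex stratum, measures
#' come from a multivariate normal with the spec's correlation matrix and
#' margins (a Gaussian-copula-style construction with normal margins);
#' covariates are attached independently. The empirical correlation matrix
#' converges to the spec's targets as `n` grows.
#'
#' @param spec An [cohort_spec()] object.
#' @param seed Integer seed.
#' @return A tibble with `participant_id`, `age`, `sex` (`"F"`/`"M"`),
#'   `race_group` (`"white"`/`"minority"`), and one column per measure.
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n = 60), seed = 1)
#' cor(cohort$bias, cohort$pct_body_fat)
#' @export
simulate_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "apa_cohort_spec"))
  with_seed(seed, {
    n <- spec$n
    n_f <- round(n * spec$prop_female)
    sex <- shuffle(rep(c("F", "M"), c(n_f, n - n_f)))
    draw <- function(m, R) {
      if (m == 0) {
        return(matrix(numeric(0), 0, length(spec$variables),
                      dimnames = list(NULL, spec$variables)))
      }
      Z <- MASS::mvrnorm(m, mu = rep(0, length(spec$variables)), Sigma = R)
      if (m == 1) Z <- matrix(Z, nrow = 1)
      colnames(Z) <- spec$variables
      Z
    }
    Z <- matrix(NA_real_, n, length(spec$variables),
                dimnames = list(NULL, spec$variables))
    Z[sex == "F", ] <- draw(sum(sex == "F"), spec$cor_girls)
    Z[sex == "M", ] <- draw(sum(sex == "M"), spec$cor_boys)
    X <- sweep(sweep(Z, 2, spec$marginals$sd, `*`), 2,
               spec$marginals$mean, `+`)
    out <- tibble::tibble(
      participant_id = sprintf("P%03d", seq_len(n)),
      age = sample(8:17, n, replace = TRUE),
      sex = sex,
      race_group = ifelse(stats::runif(n) < spec$prop_white,
                          "white", "minority")
    )
    dplyr::bind_cols(out, tibble::as_tibble(X))
  })
}
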