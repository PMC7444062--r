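#' Waterfall plot of cohort bias scores
#'
#' The study's signature figure: every child's bias score as a ranked bar,
#' positive (sedentary-leaning) scores to one side, colored by preference
#' direction.
#'
#' @param cohort A data frame with a `bias` column.
#' @return A ggplot object.
#' @examples
#' plot_bias_waterfall(simulate_cohort(cohort_spec(n = 60), seed = 1))
#' @export
plot_bias_waterfall <- function(cohort) {
  dat <- tibble::tibble(bias = sort(cohort$bias, decreasing = TRUE))
  dat$rank <- seq_len(nrow(dat))
  dat$pref <- ifelse(dat$bias > 0, "Sedentary", "Physical")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$rank, y = .data$bias,
                                    fill = .data$pref)) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::scale_fill_manual(
      values = c(Sedentary = "#D55E00", Physical = "#0072B2"),
      name = "Preference") +
    ggplot2::labs(x = "Participant (ranked)", y = "Implicit bias score") +
    ggplot2::ylim(-100, 100) +
    ggplot2::theme_minimal()
}

#' Dot plot of the validation correlation grid
#'
#' @param object An `apa_validation` report.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.apa_validation <- function(object, ...) {
  dat <- tidy(object)
  dat <- dat[!is.na(dat$r), ]
  dat$which <- ifelse(dat$adjusted, "Adjusted (age/sex/race)", "Raw")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$r, y = .data$measure,
                                    color = .data$which)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, color = "grey60") +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5),
                        size = 2) +
    ggplot2::xlim(-1, 1) +
    ggplot2::labs(x = "Correlation with bias score", y = NULL,
                  color = NULL) +
    ggplot2::theme_minimal()
}
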