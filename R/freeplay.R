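#' Score a free-choice play observation
#'
#' During the 30-minute free-choice play period an observer codes the
#' child's activity in 15-s intervals as `SEDENTARY`, `STANDING` or
#' `MOVING`; sedentary is defined as not standing or moving. The headline
#' metric is the percent of coded intervals spent sedentary.
#'
#' @param obs A data frame with a `code` column, one row per 15-s interval
#'   (at most 120 for the 30-min session), or a character vector of codes.
#' @return Percent of intervals coded sedentary, in `[0, 100]`.
#' @examples
#' score_free_play(rep(c("SEDENTARY", "MOVING"), c(68, 52)))
#' @export
score_free_play <- function(obs) {
  codes <- if (is.data.frame(obs)) obs$code else obs
  if (length(codes) == 0) {
    stop("observation log is empty", call. = FALSE)
  }
  bad <- setdiff(unique(codes), c("SEDENTARY", "STANDING", "MOVING"))
  if (length(bad) > 0) {
    stop("unknown observation code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  100 * sum(codes == "SEDENTARY") / length(codes)
}

#' Inter-rater agreement between two observation logs
#'
#' Simple percent agreement: the share of intervals on which two observers
#' assigned the same code.
#'
#' @param obs_a,obs_b Observation logs of equal length (data frames with a
#'   `code` column, or code vectors).
#' @return Percent agreement in `[0, 100]`.
#' @export
interrater_agreement <- function(obs_a, obs_b) {
  a <- if (is.data.frame(obs_a)) obs_a$code else obs_a
  b <- if (is.data.frame(obs_b)) obs_b$code else obs_b
  if (length(a) != length(b)) {
    stop("observation logs differ in length (", length(a), " vs ",
         length(b), ")", call. = FALSE)
  }
  if (length(a) == 0) stop("observation logs are empty", call. = FALSE)
  100 * sum(a == b) / length(a)
}
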