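#' Define a questionnaire scale
#'
#' A scale definition records the item count, the response range, the
#' item-to-subscale map, which items are reverse-keyed, and whether
#' subscale scores are item means (typical for Likert scales) or sums.
#'
#' @param name Scale name.
#' @param n_items Number of items.
#' @param response_min,response_max Response range (inclusive integers).
#' @param subscales Named list mapping subscale name to integer item
#'   indices; a subscale with `NULL` indices is *declared but
#'   unconfigured* and cannot be scored until a map is supplied.
#' @param reversed Integer indices of reverse-keyed items.
#' @param aggregate `"mean"` or `"sum"`.
#' @return An object of class `apa_scale`.
#' @export
scale_definition <- function(name, n_items, response_min, response_max,
                             subscales = list(), reversed = integer(),
                             aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  stopifnot(n_items >= 1, response_min < response_max)
  idx <- c(unlist(subscales), reversed)
  if (length(idx) > 0 && (any(idx < 1) || any(idx > n_items))) {
    stop("item indices must lie in 1..", n_items, call. = FALSE)
  }
  structure(
    list(name = name, n_items = as.integer(n_items),
         response_min = response_min, response_max = response_max,
         subscales = subscales, reversed = as.integer(reversed),
         aggregate = aggregate),
    class = "apa_scale"
  )
}

#' @export
print.apa_scale <- function(x, ...) {
  unconf <- sum(vapply(x$subscales, is.null, logical(1)))
  cat("<apa_scale>", x$name, "-", x$n_items, "items,",
      x$response_min, "-", x$response_max, ",",
      length(x$subscales), "subscale(s)",
      if (unconf > 0) paste0("(", unconf, " unconfigured)"), "\n")
  invisible(x)
}

#' Built-in scale definitions
#'
#' Ships the three child-report instruments used alongside the task:
#'
#' * **PSDQ-S** — Physical Self Description Questionnaire Short Form: 40
#'   items on a 6-point scale (1 = False, 6 = True) with 11 subscales
#'   (Health, Coordination, Activity, Body Fat, Sport, Global Physical,
#'   Appearance, Strength, Flexibility, Endurance, Global Esteem).
#' * **BES** — Body Esteem Scale: 23 items on a 5-point scale (1 = Never,
#'   5 = Always) with subscales Appearance, Weight, Attribution.
#' * **MFQ** — Mood and Feelings Questionnaire short version: 13 items
#'   scored 0-2 and summed to a 0-26 total.
#'
#' The PSDQ-S and BES item-to-subscale keys are published with the
#' instruments themselves, not here; their subscales are declared but
#' unconfigured, and scoring them without a user-supplied item map raises
#' an explicit error. The MFQ needs no map (single summed total) and is
#' scoreable as shipped.
#'
#' @return A named list of [scale_definition()] objects: `psdq_s`, `bes`,
#'   `mfq`.
#' @export
apa_scales <- function() {
  psdq_subscales <- stats::setNames(
    rep(list(NULL), 11),
    c("health", "coordination", "activity", "body_fat", "sport",
      "global_physical", "appearance", "strength", "flexibility",
      "endurance", "global_esteem")
  )
  bes_subscales <- stats::setNames(rep(list(NULL), 3),
                                   c("appearance", "weight", "attribution"))
  list(
    psdq_s = scale_definition("PSDQ-S", 40, 1, 6,
                              subscales = psdq_subscales),
    bes = scale_definition("BES", 23, 1, 5, subscales = bes_subscales),
    mfq = scale_definition("MFQ", 13, 0, 2,
                           subscales = list(total = 1:13),
                           aggregate = "sum")
  )
}

#' Score questionnaire responses against a scale definition
#'
#' Reverse-keyed items are mapped `response -> min + max - response`, then
#' each subscale is the mean (or, for summed scales, the sum) of its member
#' items. A subscale is scored when at least `min_prop_present` of its
#' items are answered; partial subscales are prorated (mean of present
#' items; for sums, scaled up to the full item count), otherwise `NA`.
#'
#' @param definition An [scale_definition()] with configured subscales.
#' @param responses A wide data frame: `participant_id` plus columns
#'   `item_1` .. `item_k` (missing values allowed).
#' @param min_prop_present Minimum proportion of items required per
#'   subscale (default 0.8).
#' @return A tibble: `participant_id` plus one column per subscale.
#' @examples
#' mfq <- apa_scales()$mfq
#' resp <- tibble::tibble(participant_id = "P001",
#'                        !!!stats::setNames(as.list(rep(2, 13)),
#'                                           paste0("item_", 1:13)))
#' score_scale(mfq, resp)
#' @export
score_scale <- function(definition, responses, min_prop_present = 0.8) {
  stopifnot(inherits(definition, "apa_scale"))
  unconf <- names(definition$subscales)[
    vapply(definition$subscales, is.null, logical(1))]
  if (length(unconf) > 0) {
    stop(definition$name, " subscale(s) unconfigured (no item map): ",
         paste(unconf, collapse = ", "),
         "; supply item indices via scale_definition()", call. = FALSE)
  }
  if (length(definition$subscales) == 0) {
    stop(definition$name, " declares no subscales", call. = FALSE)
  }
  responses <- tibble::as_tibble(responses)
  item_cols <- paste0("item_", seq_len(definition$n_items))
  missing_cols <- setdiff(item_cols, names(responses))
  if (length(missing_cols) > 0) {
    stop("responses missing item column(s): ",
         paste(utils::head(missing_cols, 5), collapse = ", "),
         call. = FALSE)
  }
  items <- as.matrix(responses[, item_cols])
  rng_bad <- items < definition$response_min | items > definition$response_max
  if (any(rng_bad, na.rm = TRUE)) {
    stop("response value(s) outside [", definition$response_min, ", ",
         definition$response_max, "]", call. = FALSE)
  }
  items[, definition$reversed] <-
    definition$response_min + definition$response_max -
    items[, definition$reversed]
  score_one <- function(idx) {
    sub <- items[, idx, drop = FALSE]
    prop <- rowMeans(!is.na(sub))
    m <- rowMeans(sub, na.rm = TRUE)
    val <- if (definition$aggregate == "mean") m else m * length(idx)
    ifelse(prop >= min_prop_present, val, NA_real_)
  }
  scores <- purrr::map(definition$subscales, score_one)
  out <- tibble::tibble(
    participant_id = responses[["participant_id"]] %||%
      seq_len(nrow(responses))
  )
  dplyr::bind_cols(out, tibble::as_tibble(scores))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
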