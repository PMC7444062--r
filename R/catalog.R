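#' The default APA activity catalog
#'
#' The Activity Preference Assessment presents 16 common leisure activities:
#' 8 physical (ball sports, biking, dancing, gymnastics/tumbling, outdoor
#' play, running, swimming, walking) and 8 sedentary (arts and crafts, board
#' games, tablet, listening to music, reading, talking, watching TV, video
#' games). Activity ids are lower-snake tokens of the display labels so they
#' can serve as stable CSV keys.
#'
#' @return A tibble with columns `id` (character, unique), `label`
#'   (character) and `category` (`"PHYSICAL"` or `"SEDENTARY"`), one row per
#'   activity, in the task's listed order.
#' @examples
#' apa_catalog()
#' @export
apa_catalog <- function() {
  physical <- c(
    ball_sports = "ball sports", biking = "biking", dancing = "dancing",
    gymnastics_tumbling = "gymnastics/tumbling", outdoor_play = "outdoor play",
    running = "running", swimming = "swimming", walking = "walking"
  )
  sedentary <- c(
    arts_and_crafts = "arts and crafts", board_games = "board games",
    tablet = "tablet", listening_to_music = "listening to music",
    reading = "reading", talking = "talking", watching_tv = "watching TV",
    video_games = "video games"
  )
  tibble::tibble(
    id = c(names(physical), names(sedentary)),
    label = unname(c(physical, sedentary)),
    category = rep(c("PHYSICAL", "SEDENTARY"), each = 8L)
  )
}

#' Validate an activity catalog
#'
#' A catalog is a data frame with columns `id`, `label`, `category`; ids must
#' be unique, categories must be `"SEDENTARY"` or `"PHYSICAL"`, and each
#' category needs at least two activities (otherwise no within-category pair
#' exists).
#'
#' @param catalog A data frame as returned by [apa_catalog()].
#' @return The catalog, invisibly, as a tibble; errors describe the violation.
#' @export
validate_catalog <- function(catalog) {
  catalog <- tibble::as_tibble(catalog)
  required <- c("id", "label", "category")
  missing <- setdiff(required, names(catalog))
  if (length(missing) > 0) {
    stop("catalog is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(catalog$id) > 0) {
    dup <- unique(catalog$id[duplicated(catalog$id)])
    stop("duplicate activity id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(catalog$category), c("SEDENTARY", "PHYSICAL"))
  if (length(bad) > 0) {
    stop("unknown category value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  n_cat <- table(factor(catalog$category, c("SEDENTARY", "PHYSICAL")))
  if (any(n_cat < 2)) {
    stop("catalog needs at least 2 activities per category; got ",
         n_cat[["SEDENTARY"]], " sedentary and ", n_cat[["PHYSICAL"]],
         " physical", call. = FALSE)
  }
  invisible(catalog)
}
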