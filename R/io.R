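#' Table schemas used by the file interface
#'
#' All files are UTF-8 CSV with required headers (order-insensitive).
#' Reaction times are stored as integer milliseconds (`rt_ms`) on disk and
#' converted to seconds (`rt`) in memory. `apa_schemas()` lists the known
#' formats and their required and optional columns.
#'
#' @return A named list of schema descriptions.
#' @export
apa_schemas <- function() {
  list(
    catalog = list(required = c("id", "label", "category")),
    schedule = list(required = c("block", "trial_index", "pair_id",
                                 "left_id", "right_id", "pair_type"),
                    optional = c("left_category", "right_category")),
    trials = list(required = c("pair_id", "chosen_id", "rt_ms", "responded"),
                  optional = c("participant_id", "session", "block",
                               "trial_index", "left_id", "right_id")),
    vas = list(required = c("activity_id", "liking", "wanting"),
               optional = c("participant_id", "session")),
    epochs = list(required = c("timestamp", "counts", "wear_state")),
    observation = list(required = c("interval_index", "code"),
                       optional = c("code_b")),
    fitness = list(required = c("stage", "watts", "vo2_ml_kg_min"),
                   optional = c("vo2_l_min", "rer", "hr", "rpe")),
    cohort = list(required = c("participant_id", "bias"),
                  optional = c("bias_retest", "freeplay_sed_pct",
                               "daily_sed_min", "daily_mvpa_min",
                               "vo2peak_ffm", "bmi_z", "pct_body_fat",
                               "fmi", "age", "sex", "race_group"))
  )
}

#' Read a validated APA table
#'
#' Reads one of the package's CSV formats, checks that every required
#' column is present (naming any that are missing), and collects row-level
#' violations (non-positive or non-finite reaction times, negative counts,
#' out-of-range ratings) with their line numbers; offending rows are
#' dropped and reported via the `"problems"` attribute rather than
#' aborting the load. Trial files have `rt_ms` converted to an `rt`
#' column in seconds.
#'
#' @param path CSV file path.
#' @param format One of `names(apa_schemas())`.
#' @return A tibble; attribute `"problems"` holds a tibble of dropped rows
#'   (`row`, `message`), empty when the file is clean.
#' @export
apa_read <- function(path, format) {
  schemas <- apa_schemas()
  format <- match.arg(format, names(schemas))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(schemas[[format]]$required, names(dat))
  if (length(missing) > 0) {
    stop(format, " file is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  problems <- tibble::tibble(row = integer(), message = character())
  flag <- function(bad, msg) {
    bad <- which(!is.na(bad) & bad)
    if (length(bad) > 0) {
      # +1 for the header line
      problems <<- dplyr::bind_rows(
        problems, tibble::tibble(row = bad + 1L, message = msg))
    }
    bad
  }
  drop <- integer()
  if (format == "trials") {
    drop <- c(drop, flag(dat$rt_ms <= 0, "non-positive rt_ms"))
    dat$rt <- dat$rt_ms / 1000
    if (!is.logical(dat$responded)) {
      dat$responded <- dat$responded %in% c(TRUE, 1, "1", "TRUE", "true")
    }
  }
  if (format == "vas") {
    drop <- c(drop, flag(dat$liking < 0 | dat$liking > 100 |
                           dat$wanting < 0 | dat$wanting > 100,
                         "rating outside [0, 100]"))
  }
  if (format == "epochs") {
    drop <- c(drop, flag(dat$counts < 0, "negative counts"))
  }
  if (length(drop) > 0) dat <- dat[-unique(drop), ]
  attr(dat, "problems") <- problems
  dat
}

#' Write an APA table to CSV
#'
#' Inverse of [apa_read()]: trial tables with an `rt` seconds column get it
#' serialized as integer `rt_ms`. Writing then reading is lossless for
#' finite values (up to the millisecond resolution of stored reaction
#' times).
#'
#' @param x A tibble in one of the package's formats.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
apa_write <- function(x, path) {
  x <- tibble::as_tibble(x)
  if ("rt" %in% names(x) && !"rt_ms" %in% names(x)) {
    x$rt_ms <- as.integer(round(x$rt * 1000))
    x$rt <- NULL
  }
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}
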