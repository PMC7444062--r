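#' Enumerate every unique activity pair
#'
#' The forced-choice paradigm shows every unordered pair of catalog
#' activities exactly once. With the default 8 + 8 catalog this yields 120
#' pairs: 64 cross-category (one sedentary, one physical — the only pairs
#' that enter the bias score), 28 within-sedentary and 28 within-physical.
#'
#' @param catalog Activity catalog data frame (default [apa_catalog()]).
#' @return A tibble with one row per unordered pair: `pair_id` (integer,
#'   assigned after sorting pairs by their id tuple), `left_id`, `right_id`,
#'   `left_category`, `right_category`, and `pair_type` (`"CROSS"`,
#'   `"WITHIN_SED"` or `"WITHIN_PA"`). `left`/`right` here is a canonical
#'   ordering, not a screen side; [apa_schedule()] assigns sides.
#' @examples
#' pairs <- apa_pairs()
#' dplyr::count(pairs, pair_type)
#' @export
apa_pairs <- function(catalog = apa_catalog()) {
  validate_catalog(catalog)
  catalog <- tibble::as_tibble(catalog)
  ids <- sort(catalog$id)
  cat_of <- stats::setNames(catalog$category, catalog$id)
  idx <- utils::combn(length(ids), 2L)
  a <- ids[idx[1L, ]]
  b <- ids[idx[2L, ]]
  ord <- order(a, b)
  a <- a[ord]
  b <- b[ord]
  type <- dplyr::case_when(
    cat_of[a] != cat_of[b] ~ "CROSS",
    cat_of[a] == "SEDENTARY" ~ "WITHIN_SED",
    TRUE ~ "WITHIN_PA"
  )
  tibble::tibble(
    pair_id = seq_along(a),
    left_id = a, right_id = b,
    left_category = unname(cat_of[a]), right_category = unname(cat_of[b]),
    pair_type = type
  )
}

#' Build a blocked, counterbalanced trial schedule
#'
#' Partitions the pair set into `n_blocks` equally sized blocks (stratified
#' by pair type so each block mixes cross- and within-category comparisons;
#' with the default catalog each of the 4 blocks holds 16 cross + 7 + 7
#' within pairs), shuffles trial order within block, and assigns each pair's
#' screen side at random with the sedentary-on-left count balanced to within
#' one trial over cross-category pairs.
#'
#' @param pairs Pair tibble from [apa_pairs()].
#' @param n_blocks Number of blocks (default 4, the task's "four sets of 30
#'   pairs").
#' @param seed Integer seed; the same seed reproduces the schedule exactly.
#' @return A tibble with columns `block`, `trial_index` (within block),
#'   `pair_id`, `left_id`, `right_id`, `left_category`, `right_category`,
#'   `pair_type`.
#' @examples
#' sched <- apa_schedule(apa_pairs(), seed = 7)
#' dplyr::count(sched, block)
#' @export
apa_schedule <- function(pairs, n_blocks = 4L, seed = NULL) {
  pairs <- tibble::as_tibble(pairs)
  n <- nrow(pairs)
  if (n %% n_blocks != 0) {
    stop(n, " pairs cannot be split into ", n_blocks, " equal blocks",
         call. = FALSE)
  }
  with_seed(seed, {
    per_block <- n %/% n_blocks
    # stratified deal: shuffle within type, round-robin across blocks with a
    # random starting block per type, then repair any size imbalance
    block_of <- integer(n)
    for (tp in shuffle(unique(pairs$pair_type))) {
      rows <- shuffle(which(pairs$pair_type == tp))
      start <- sample.int(n_blocks, 1L)
      block_of[rows] <- ((seq_along(rows) - 1L + start - 1L) %% n_blocks) + 1L
    }
    sizes <- tabulate(block_of, n_blocks)
    while (any(sizes != per_block)) {
      from <- which.max(sizes)
      to <- which.min(sizes)
      mv <- sample(which(block_of == from), 1L)
      block_of[mv] <- to
      sizes <- tabulate(block_of, n_blocks)
    }

    # side assignment: over CROSS pairs, sedentary goes left on exactly
    # floor(n/2) or ceiling(n/2) trials (tie side chosen at random)
    cross <- which(pairs$pair_type == "CROSS")
    flip <- logical(n) # TRUE = swap canonical left/right
    if (length(cross) > 0) {
      sed_left_n <- length(cross) %/% 2L +
        (length(cross) %% 2L) * sample(0:1, 1L)
      sed_left_rows <- sample(cross, sed_left_n)
      sed_is_left <- pairs$left_category == "SEDENTARY"
      flip[cross] <- ifelse(cross %in% sed_left_rows,
                            !sed_is_left[cross], sed_is_left[cross])
    }
    within <- which(pairs$pair_type != "CROSS")
    flip[within] <- sample(c(TRUE, FALSE), length(within), replace = TRUE)

    out <- pairs
    out$block <- block_of
    swap <- function(l, r) ifelse(flip, r, l)
    out <- dplyr::mutate(out,
      new_left_id = swap(.data$left_id, .data$right_id),
      new_right_id = swap(.data$right_id, .data$left_id),
      new_left_cat = swap(.data$left_category, .data$right_category),
      new_right_cat = swap(.data$right_category, .data$left_category),
      left_id = .data$new_left_id, right_id = .data$new_right_id,
      left_category = .data$new_left_cat, right_category = .data$new_right_cat
    )
    out <- out[, c("block", "pair_id", "left_id", "right_id",
                   "left_category", "right_category", "pair_type")]
    out <- out[order(out$block, sample.int(n)), ]
    out <- dplyr::mutate(dplyr::group_by(out, .data$block),
                         trial_index = dplyr::row_number())
    dplyr::relocate(dplyr::ungroup(out), "block", "trial_index")
  })
}
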