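#' @importFrom rlang .data
#' @importFrom dplyr %>%
NULL

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. A NULL seed uses (and advances) the global stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# shuffle that is safe for length-1 input (sample(5L) would permute 1:5)
shuffle <- function(x) x[sample.int(length(x))]

#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
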