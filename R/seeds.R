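#' Derive child seeds from a master seed
#'
#' All stochastic entry points in zilnet accept a single integer seed.
#' Experiments needing several independent streams (e.g. one per benchmark
#' replicate) derive child seeds with this helper, so that any figure-level
#' run is replayable from one number.
#'
#' @param seed master integer seed.
#' @param n number of child seeds.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' split_seed(1, 3)
split_seed <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 1)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# Run expr under a locally-set seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old))
  set.seed(as.integer(seed))
  expr
}
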