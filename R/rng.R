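#' Hierarchical random-number streams
#'
#' All randomness in the toolkit flows from a single integer root seed through
#' named substreams, so that any part of a run (one image, one style draw, one
#' condition sample) can be reproduced in isolation. A stream is identified by
#' `(root_seed, path)`; the same pair always yields the same draws, and sibling
#' streams are statistically independent for practical purposes.
#'
#' @param root_seed Integer root seed (< 2^31).
#' @param path Integer vector identifying the substream (possibly empty).
#' @return An object of class `rxn_rng`.
#' @examples
#' r <- rng_stream(42)
#' r1 <- rng_fork(r, 1)
#' @export
rng_stream <- function(root_seed, path = integer(0)) {
  stopifnot(is.numeric(root_seed), length(root_seed) == 1, is.finite(root_seed))
  structure(list(root_seed = as.integer(root_seed), path = as.integer(path)),
            class = "rxn_rng")
}

#' Derive a child stream
#'
#' @param rng An `rxn_rng` stream.
#' @param i Integer label of the child substream.
#' @return A new `rxn_rng` whose path is `c(rng$path, i)`.
#' @export
rng_fork <- function(rng, i) {
  stopifnot(inherits(rng, "rxn_rng"))
  rng_stream(rng$root_seed, c(rng$path, as.integer(i)))
}

# Scalar seed for a stream: chain R's own generator through the path so that
# nearby (seed, path) pairs land far apart. Kept strictly below 2^31.
rng_seed <- function(rng) {
  stopifnot(inherits(rng, "rxn_rng"))
  old <- .get_global_seed()
  on.exit(.restore_global_seed(old), add = TRUE)
  x <- abs(as.numeric(rng$root_seed)) %% 2147483647
  for (p in c(0L, rng$path)) {
    # double arithmetic stays exact: both addends < 2^31
    mix <- (x + 104729 * ((abs(as.numeric(p)) %% 20011) + 1)) %% 2147483647
    set.seed(as.integer(mix))
    x <- as.numeric(sample.int(2147483646L, 1L))
  }
  as.integer(x)
}

#' Evaluate code under a stream's seed
#'
#' Runs `expr` with R's RNG seeded from `rng`, restoring the caller's RNG
#' state afterwards; repeated calls with the same stream repeat the draws.
#'
#' @param rng An `rxn_rng` stream.
#' @param expr Expression drawing random numbers.
#' @return The value of `expr`.
#' @export
with_rng <- function(rng, expr) {
  old <- .get_global_seed()
  on.exit(.restore_global_seed(old), add = TRUE)
  set.seed(rng_seed(rng))
  expr
}

.get_global_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_global_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
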