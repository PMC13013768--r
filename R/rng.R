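#' Create a deterministic random stream
#'
#' All randomised operations in the package take an explicit stream object so
#' that no function touches the caller's global random state. Two streams
#' created with the same seed produce identical draw sequences; a stream
#' advances only when it is used.
#'
#' @param seed Non-negative integer seed.
#' @return An object of class `specaug_rng` holding an independent
#'   Mersenne-Twister state.
#' @examples
#' r1 <- seeded_rng(42)
#' r2 <- seeded_rng(42)
#' identical(rng_unif(r1, 5), rng_unif(r2, 5))
#' @export
seeded_rng <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed < 0)
    stop("'seed' must be a single non-negative integer")
  e <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  e$state <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  class(e) <- "specaug_rng"
  e
}

# Evaluate `expr` under the stream's RNG state, advancing the stream and
# restoring the caller's global state afterwards.
rng_eval <- function(rng, expr) {
  if (!inherits(rng, "specaug_rng")) stop("'rng' must come from seeded_rng()")
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", rng$state, envir = globalenv())
  on.exit({
    rng$state <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  expr
}

#' Draws from a random stream
#'
#' Thin wrappers over the base generators that consume an explicit
#' [seeded_rng()] stream instead of the global state.
#'
#' @param rng A stream from [seeded_rng()].
#' @param n Number of draws.
#' @param min,max Uniform bounds.
#' @param sd Normal standard deviation.
#' @param lo,hi Inclusive integer bounds.
#' @param x Vector to sample from.
#' @param size Number of elements to sample.
#' @param replace Sample with replacement?
#' @param p Bernoulli success probability.
#' @return Numeric, integer or logical draws of length `n`/`size`.
#' @name rng-draws
NULL

#' @rdname rng-draws
#' @export
rng_unif <- function(rng, n, min = 0, max = 1) rng_eval(rng, stats::runif(n, min, max))

#' @rdname rng-draws
#' @export
rng_norm <- function(rng, n, sd = 1) rng_eval(rng, stats::rnorm(n, 0, sd))

#' @rdname rng-draws
#' @export
rng_int <- function(rng, n, lo, hi) rng_eval(rng, sample.int(hi - lo + 1L, n, replace = TRUE) + lo - 1L)

#' @rdname rng-draws
#' @export
rng_pick <- function(rng, x, size = 1L, replace = FALSE) {
  idx <- rng_eval(rng, sample.int(length(x), size, replace = replace))
  x[idx]
}

#' @rdname rng-draws
#' @export
rng_bern <- function(rng, n, p = 0.5) rng_unif(rng, n) < p
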