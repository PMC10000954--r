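#' Seeded uniform random stream
#'
#' A self-contained stream of uniform draws on `[0, 1)`. The stream keeps its
#' own RNG state, saved and restored around every draw, so interleaved calls
#' to `set.seed()` elsewhere (e.g. inside classifier fits) cannot perturb an
#' optimizer trajectory. Identical seeds produce identical draw sequences.
#'
#' @param seed Integer seed.
#' @return An object of class `rng_stream` with a single function `$unif(n)`
#'   returning `n` uniform draws.
#' @examples
#' r <- rng_stream(7)
#' r$unif(3)
#' @export
rng_stream <- function(seed) {
  seed <- as.integer(seed)
  state <- NULL
  unif <- function(n) {
    genv <- globalenv()
    old <- get0(".Random.seed", envir = genv, inherits = FALSE)
    if (is.null(state)) set.seed(seed)
    else assign(".Random.seed", state, envir = genv)
    x <- stats::runif(n)
    state <<- get(".Random.seed", envir = genv, inherits = FALSE)
    if (is.null(old)) rm(".Random.seed", envir = genv)
    else assign(".Random.seed", old, envir = genv)
    x
  }
  structure(list(unif = unif, seed = seed), class = "rng_stream")
}
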