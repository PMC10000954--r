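# Shared small fixtures, generated in code. Memoised per test session so
# repeated use across files costs one generation each.

small_ds <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_embedding_dataset(n = 120, dim = 8, k_informative = 3,
                                           n_classes = 2, class_sep = 4,
                                           noise_sd = 0.5, seed = 42)
    cache
  }
})

tiny_params <- function(seed = 1, ...) {
  optimizer_params(pop_size = 10, max_iter = 4, seed = seed, ...)
}

# Two well-separated Gaussian blobs in 4 dims.
blobs <- function(n = 80, seed = 3) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  X <- matrix(rnorm(n * 4, sd = 0.3), n, 4) + 5 * y
  list(X = X, y = y)
}
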