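# Synthetic embedding generator: class-separable Gaussian data with a
# planted informative subset, emulating deep image embeddings (128-wide
# feature vectors) so the optimizers are testable without any image data.

#' Generate a synthetic embedding dataset with a planted informative subset
#'
#' Emulates deep-CNN image embeddings: `k_informative` columns carry
#' class-conditional Gaussian means placed at vertices of a scaled simplex
#' (all pairwise class separations equal `class_sep`), jittered with
#' `noise_sd`; the remaining columns are pure standard Gaussian noise. A
#' stratified train/test split and a stratified fit/validation sub-split of
#' the training partition (80/20, used by the wrapper fitness) are recorded
#' on the object.
#'
#' @param n Number of samples (>= 4 * `n_classes`).
#' @param dim Embedding width (default 128, a typical deep-descriptor size).
#' @param k_informative Number of informative columns, between `n_classes`
#'   and `dim` (the simplex construction needs at least one coordinate per
#'   class).
#' @param n_classes Number of classes (>= 2).
#' @param class_sep Euclidean distance between any two class means.
#' @param noise_sd Standard deviation of the jitter on informative columns.
#' @param train_frac Fraction of samples in the training partition.
#' @param seed Integer seed; identical seeds give bit-identical datasets.
#' @return An object of class `embedding_dataset`: a list with matrix `X`
#'   (columns named `f001`, ...), integer labels `y` in `0 ... n_classes-1`,
#'   0/1 vector `informative_mask`, index vectors `train_idx`, `test_idx`,
#'   `fit_idx`, `val_idx`, and `meta` (the generation parameters).
#' @examples
#' d <- generate_embedding_dataset(n = 60, dim = 16, k_informative = 4,
#'                                 n_classes = 2, seed = 1)
#' dim(d$X)
#' sum(d$informative_mask)
#' @export
generate_embedding_dataset <- function(n = 400, dim = 128, k_informative = 10,
                                       n_classes = 2, class_sep = 3,
                                       noise_sd = 1, train_frac = 0.8,
                                       seed = 1L) {
  if (k_informative < 1 || k_informative > dim)
    stop("k_informative must lie in [1, dim]")
  if (n_classes < 2) stop("n_classes must be >= 2")
  if (k_informative < n_classes)
    stop("k_informative must be >= n_classes for the simplex construction")
  if (n < 4 * n_classes) stop("n must be >= 4 * n_classes")
  if (train_frac <= 0 || train_frac >= 1)
    stop("train_frac must lie strictly in (0, 1)")

  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))

  y <- sample(rep(seq_len(n_classes) - 1L, length.out = n))
  informative <- sort(sample(dim, k_informative))

  # Class means at vertices of a regular simplex (centered a * (e_c - 1/C),
  # pairwise distance exactly class_sep), with each simplex coordinate
  # spread over a block of informative columns (scaled 1/sqrt(block size),
  # which preserves all pairwise distances). Every informative column then
  # carries genuine class signal instead of piling the whole separation
  # onto n_classes coordinates.
  a <- class_sep / sqrt(2)
  V <- a * (diag(n_classes) - 1 / n_classes)
  M <- matrix(0, n_classes, k_informative)
  block <- (seq_len(k_informative) - 1L) %% n_classes + 1L
  for (r in seq_len(n_classes)) {
    cols <- which(block == r)
    M[, cols] <- V[, r] / sqrt(length(cols))
  }

  X <- matrix(stats::rnorm(n * dim), n, dim)
  X[, informative] <- M[y + 1L, , drop = FALSE] +
    noise_sd * matrix(stats::rnorm(n * k_informative), n, k_informative)
  colnames(X) <- sprintf("f%03d", seq_len(dim))

  mask <- integer(dim)
  mask[informative] <- 1L

  train_idx <- stratified_indices(y, train_frac)
  test_idx <- setdiff(seq_len(n), train_idx)
  fit_idx <- train_idx[stratified_indices(y[train_idx], 0.8)]
  val_idx <- setdiff(train_idx, fit_idx)

  structure(list(
    X = X, y = y, informative_mask = mask,
    train_idx = train_idx, test_idx = test_idx,
    fit_idx = fit_idx, val_idx = val_idx,
    meta = list(n = n, dim = dim, k_informative = k_informative,
                n_classes = n_classes, class_sep = class_sep,
                noise_sd = noise_sd, train_frac = train_frac,
                seed = as.integer(seed))
  ), class = "embedding_dataset")
}

# Stratified sample of positions: round(frac * n_c) per class (at least 1,
# at most n_c - 1 so both partitions see every class).
stratified_indices <- function(y, frac) {
  picked <- lapply(unique(y), function(cl) {
    idx <- which(y == cl)
    k <- round(frac * length(idx))
    k <- max(1L, min(length(idx) - 1L, k))
    sample(idx, k)
  })
  sort(unlist(picked))
}

#' @export
print.embedding_dataset <- function(x, ...) {
  m <- x$meta
  cat(sprintf("Synthetic embedding dataset: %d samples x %d features\n",
              m$n, m$dim))
  cat(sprintf("  classes: %d   informative: %d   class_sep: %.3g   noise_sd: %.3g\n",
              m$n_classes, m$k_informative, m$class_sep, m$noise_sd))
  cat(sprintf("  train/test: %d/%d   fit/val: %d/%d   seed: %d\n",
              length(x$train_idx), length(x$test_idx),
              length(x$fit_idx), length(x$val_idx), m$seed))
  invisible(x)
}

#' Recovery of the planted informative subset
#'
#' Compares a selected feature mask against the ground-truth informative
#' mask of a synthetic dataset.
#'
#' @param selected 0/1 vector of selected features.
#' @param truth 0/1 vector of truly informative features (same length).
#' @return A list with `recall` (fraction of true features selected) and
#'   `precision` (fraction of selected features that are true; 0 for an
#'   empty selection).
#' @examples
#' informative_recovery(c(1, 1, 0, 0), c(1, 0, 1, 0))
#' @export
informative_recovery <- function(selected, truth) {
  if (length(selected) != length(truth))
    stop("selected and truth must have the same length")
  selected <- as.integer(selected != 0)
  truth <- as.integer(truth != 0)
  hit <- sum(selected & truth)
  list(
    recall = if (sum(truth) == 0) 0 else hit / sum(truth),
    precision = if (sum(selected) == 0) 0 else hit / sum(selected)
  )
}
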