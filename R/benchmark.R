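# Benchmark harness: crosses optimizers with classifier back-ends over
# seeds and reports the table metrics (AC, BA, F, R, P, ET) on the held-out
# test split using each run's final selected mask.

OPTIMIZERS <- c("aoahg", "aoa", "hgs")

fs_driver <- function(label) {
  switch(label, aoahg = run_aoahg, aoa = run_aoa, hgs = run_hgs)
}

#' Evaluate a feature mask on the held-out test split
#'
#' Trains the classifier on the selected columns of the full training
#' partition (fit + validation rows, standardized on that partition) and
#' computes the metric set on the test partition.
#'
#' @param data An `embedding_dataset`.
#' @param mask 0/1 feature mask; must select at least one feature.
#' @param classifier_spec Classifier label.
#' @param seed Integer seed for the classifier fit.
#' @return A `metrics_report`.
#' @export
evaluate_mask_on_test <- function(data, mask, classifier_spec = "svm",
                                  seed = data$meta$seed) {
  cols <- which(mask != 0)
  if (length(cols) == 0) stop("mask must select at least one feature")
  std <- standardize_train_apply(
    data$X[data$train_idx, cols, drop = FALSE],
    data$X[data$test_idx, cols, drop = FALSE])
  pred <- train_and_predict(classifier_spec, std$fit, data$y[data$train_idx],
                            std$apply, seed = seed)
  compute_metrics(data$y[data$test_idx], pred)
}

#' Cross optimizers and classifiers over seeds
#'
#' Runs every (optimizer, classifier, seed) combination: the optimizer
#' searches with that classifier's validation loss as its fitness, and the
#' final mask is then scored on the held-out test split. Execution time
#' (`ET`) is measured around the optimizer call only.
#'
#' @param data An `embedding_dataset`.
#' @param optimizers Subset of `c("aoahg", "aoa", "hgs")`.
#' @param classifiers Subset of `c("svm", "knn", "rf", "xgb")`.
#' @param params An [optimizer_params()]; its `seed` field is overridden by
#'   each element of `seeds`.
#' @param seeds Integer vector of run seeds (one repeat per seed).
#' @return A data frame with one row per combination and columns
#'   `optimizer`, `classifier`, `seed`, `AC`, `BA`, `F`, `R`, `P`, `ET`,
#'   `selected`, `fitness`, and `mask` (the selected mask as a bit string,
#'   so every row's metrics can be re-derived from its `(seed, mask)` pair).
#' @examples
#' d <- generate_embedding_dataset(n = 80, dim = 10, k_informative = 3,
#'                                 n_classes = 2, class_sep = 4, seed = 1)
#' run_benchmark(d, optimizers = "aoahg", classifiers = c("svm", "knn"),
#'               params = optimizer_params(pop_size = 8, max_iter = 2),
#'               seeds = 1L)
#' @export
run_benchmark <- function(data, optimizers = OPTIMIZERS,
                          classifiers = CLASSIFIERS,
                          params = optimizer_params(), seeds = 1L) {
  bad <- setdiff(optimizers, OPTIMIZERS)
  if (length(bad)) stop("unknown optimizer(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(classifiers, CLASSIFIERS)
  if (length(bad)) stop("unknown classifier(s): ", paste(bad, collapse = ", "))
  if (length(seeds) < 1) stop("at least one seed is required")

  grid <- expand.grid(seed = as.integer(seeds), classifier = classifiers,
                      optimizer = optimizers, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    p <- params
    p$seed <- g$seed
    res <- fs_driver(g$optimizer)(data, p, g$classifier)
    met <- evaluate_mask_on_test(data, res$best_mask, g$classifier,
                                 seed = g$seed)
    data.frame(optimizer = g$optimizer, classifier = g$classifier,
               seed = g$seed,
               AC = met$accuracy, BA = met$balanced_accuracy, F = met$f1,
               R = met$recall, P = met$precision, ET = res$elapsed,
               selected = res$selected_count, fitness = res$best_fitness,
               mask = paste(res$best_mask, collapse = ""),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Aggregate benchmark rows over seeds
#'
#' Mean of every metric per (optimizer, classifier) cell, the single-number
#' analogue of a stochastic method's repeated runs.
#'
#' @param results A data frame from [run_benchmark()].
#' @return A data frame with one row per (optimizer, classifier) and the
#'   averaged metric columns.
#' @export
benchmark_summary <- function(results) {
  num <- c("AC", "BA", "F", "R", "P", "ET", "selected", "fitness")
  agg <- stats::aggregate(results[num],
                          by = results[c("optimizer", "classifier")],
                          FUN = mean)
  agg[order(agg$optimizer, agg$classifier), , drop = FALSE]
}
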