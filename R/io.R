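# Plain-text I/O: datasets travel as CSV (header, numeric feature columns,
# one integer label column) with an optional JSON sidecar carrying the
# generation metadata, ground-truth mask and split indices; selected masks
# as two-column CSV; results as JSON.

#' Write an embedding dataset to CSV (+ JSON sidecar)
#'
#' The CSV holds one row per sample: the feature columns followed by a
#' `label` column. A sidecar `<path>.json` records the split indices, the
#' ground-truth informative mask (synthetic data only) and the generation
#' parameters, so a round trip preserves the full object.
#'
#' @param data An `embedding_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_embedding_csv <- function(data, path) {
  df <- as.data.frame(data$X)
  df$label <- data$y
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(meta = data$meta,
               informative_mask = data$informative_mask,
               train_idx = data$train_idx, test_idx = data$test_idx,
               fit_idx = data$fit_idx, val_idx = data$val_idx)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an embedding dataset from CSV
#'
#' Reads a delimited feature table with one label column. If the JSON
#' sidecar written by [write_embedding_csv()] is present its splits and
#' ground truth are restored; otherwise fresh stratified train/test and
#' fit/validation splits are created from `seed`.
#'
#' @param path CSV path.
#' @param label_col Name of the label column (default `"label"`).
#' @param train_frac Training fraction used when no sidecar exists.
#' @param seed Seed for split creation when no sidecar exists.
#' @return An `embedding_dataset`.
#' @export
read_embedding_csv <- function(path, label_col = "label", train_frac = 0.8,
                               seed = 1L) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!label_col %in% names(df))
    stop(sprintf("label column '%s' not found", label_col))
  y <- as.integer(df[[label_col]])
  X <- as.matrix(df[setdiff(names(df), label_col)])
  storage.mode(X) <- "double"
  if (anyNA(X) || anyNA(y)) stop("dataset contains missing values")

  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    obj <- list(X = X, y = y,
                informative_mask = as.integer(side$informative_mask),
                train_idx = as.integer(side$train_idx),
                test_idx = as.integer(side$test_idx),
                fit_idx = as.integer(side$fit_idx),
                val_idx = as.integer(side$val_idx),
                meta = side$meta)
  } else {
    old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
    train_idx <- stratified_indices(y, train_frac)
    fit_idx <- train_idx[stratified_indices(y[train_idx], 0.8)]
    obj <- list(X = X, y = y, informative_mask = NULL,
                train_idx = train_idx,
                test_idx = setdiff(seq_along(y), train_idx),
                fit_idx = fit_idx,
                val_idx = setdiff(train_idx, fit_idx),
                meta = list(n = nrow(X), dim = ncol(X),
                            n_classes = length(unique(y)),
                            train_frac = train_frac,
                            seed = as.integer(seed)))
  }
  structure(obj, class = "embedding_dataset")
}

#' Write a selected-feature mask to CSV
#'
#' @param mask Named (or unnamed) 0/1 vector of feature selections.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_mask_csv <- function(mask, path) {
  nm <- names(mask)
  if (is.null(nm)) nm <- sprintf("f%03d", seq_along(mask))
  utils::write.csv(
    data.frame(feature_name = nm, selected = as.integer(mask)),
    path, row.names = FALSE)
  invisible(path)
}

#' Write a feature-selection result to JSON
#'
#' Serializes an `fs_result` (best fitness, selected count, seed, optimizer
#' and classifier labels, elapsed time, convergence series, mask).
#'
#' @param res An `fs_result`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fsresult_json <- function(res, path) {
  out <- list(optimizer = res$optimizer, classifier = res$classifier,
              seed = res$seed, best_fitness = res$best_fitness,
              selected_count = res$selected_count, elapsed = res$elapsed,
              convergence = res$convergence,
              mask = as.integer(res$best_mask))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
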