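# Classifier back-end contract and the metric set reported by the benchmark
# tables: accuracy, balanced accuracy, precision, recall, F1.

CLASSIFIERS <- c("svm", "knn", "rf", "xgb")

#' Train a classifier and predict evaluation labels
#'
#' A uniform contract over the four back-ends used by the wrapper fitness
#' and the benchmark harness: RBF-kernel SVM (`cost = 1`), k-nearest
#' neighbours (`k = 5`), random forest (100 trees) and gradient-boosted
#' trees. Features are expected already standardized by the caller. All
#' stochastic back-ends are seeded so predictions are deterministic.
#'
#' @param classifier_spec One of `"svm"`, `"knn"`, `"rf"`, `"xgb"`.
#' @param X_fit Numeric training matrix (rows = samples).
#' @param y_fit Integer class labels (>= 2 distinct values).
#' @param X_eval Numeric matrix to predict, same column count as `X_fit`.
#' @param seed Integer seed.
#' @return Integer vector of predicted labels, one per row of `X_eval`.
#' @examples
#' d <- generate_embedding_dataset(n = 60, dim = 6, k_informative = 2,
#'                                 n_classes = 2, class_sep = 6, seed = 1)
#' p <- train_and_predict("svm", d$X[d$fit_idx, ], d$y[d$fit_idx],
#'                        d$X[d$val_idx, ], seed = 1)
#' mean(p == d$y[d$val_idx])
#' @export
train_and_predict <- function(classifier_spec, X_fit, y_fit, X_eval,
                              seed = 1L) {
  classifier_spec <- match.arg(classifier_spec, CLASSIFIERS)
  X_fit <- as.matrix(X_fit); X_eval <- as.matrix(X_eval)
  if (nrow(X_fit) == 0) stop("X_fit must be non-empty")
  if (ncol(X_fit) != ncol(X_eval))
    stop("X_fit and X_eval must have the same number of columns")
  if (length(unique(y_fit)) < 2)
    stop("y_fit must contain at least 2 classes")

  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))

  yf <- factor(y_fit)
  pred <- switch(classifier_spec,
    svm = {
      fit <- e1071::svm(x = X_fit, y = yf, kernel = "radial", cost = 1,
                        scale = FALSE)
      stats::predict(fit, X_eval)
    },
    knn = class::knn(train = X_fit, test = X_eval, cl = yf,
                     k = min(5L, nrow(X_fit))),
    rf = {
      fit <- randomForest::randomForest(x = X_fit, y = yf, ntree = 100)
      stats::predict(fit, X_eval)
    },
    xgb = {
      fit <- xgboost::xgboost(X_fit, yf, nrounds = 50, max_depth = 6,
                              learning_rate = 0.3, nthreads = 1,
                              verbosity = 0)
      stats::predict(fit, X_eval, type = "class")
    })
  as.integer(as.character(pred))
}

#' Classification metrics report
#'
#' Accuracy, balanced accuracy (mean of per-class recalls over classes
#' present in `y_true`), and precision / recall / F1 averaged across
#' classes. Averaging is support-weighted by default (one number per table
#' cell even for multiclass problems); macro averaging is available. A
#' class with no predicted positives contributes precision 0.
#'
#' @param y_true True labels.
#' @param y_pred Predicted labels, same length.
#' @param average `"weighted"` (by class support) or `"macro"`.
#' @return An object of class `metrics_report`: list with `accuracy`,
#'   `balanced_accuracy`, `precision`, `recall`, `f1`, all in `[0, 1]`.
#' @examples
#' compute_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0))
#' @export
compute_metrics <- function(y_true, y_pred,
                            average = c("weighted", "macro")) {
  average <- match.arg(average)
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have the same length")
  if (length(y_true) == 0) stop("labels must be non-empty")

  lev <- sort(unique(c(y_true, y_pred)))
  yt <- factor(y_true, levels = lev)
  yp <- factor(y_pred, levels = lev)
  cm <- table(yt, yp)

  support <- rowSums(cm)
  tp <- diag(cm)
  pred_pos <- colSums(cm)

  present <- support > 0
  rec <- ifelse(present, tp / pmax(support, 1), NA_real_)
  prec <- ifelse(pred_pos > 0, tp / pmax(pred_pos, 1), 0)

  f1 <- ifelse(present & (prec + rec > 0),
               2 * prec * rec / (prec + rec), 0)

  w <- if (average == "weighted") support[present] / sum(support)
       else rep(1 / sum(present), sum(present))

  structure(list(
    accuracy = mean(y_true == y_pred),
    balanced_accuracy = mean(rec[present]),
    precision = sum(w * prec[present]),
    recall = sum(w * rec[present]),
    f1 = sum(w * f1[present])
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "accuracy %.4f | balanced accuracy %.4f | precision %.4f | recall %.4f | F1 %.4f\n",
    x$accuracy, x$balanced_accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}

# Standardize columns using means/sds estimated on the fit rows only.
# Zero-variance columns are left centred (scale divisor 1).
standardize_train_apply <- function(X_fit, X_apply) {
  mu <- colMeans(X_fit)
  sd <- apply(X_fit, 2, stats::sd)
  sd[sd == 0 | is.na(sd)] <- 1
  list(
    fit = sweep(sweep(X_fit, 2, mu, `-`), 2, sd, `/`),
    apply = sweep(sweep(X_apply, 2, mu, `-`), 2, sd, `/`)
  )
}
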