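# Wrapper feature-selection layer: binarization of continuous positions,
# classifier-based fitness, the AOAHG hybrid driver, plain AOA and HGS
# baseline drivers, and an exhaustive enumeration oracle for small
# dimensions.

#' Binarize a continuous position into a feature mask
#'
#' Bit `j` is 1 iff the coordinate is strictly greater than the threshold
#' (a coordinate exactly at the threshold is not selected).
#'
#' @param x Numeric position vector (or matrix, binarized element-wise).
#' @param threshold Cut point, default 0.5.
#' @return Integer 0/1 vector (or matrix) of the same shape.
#' @examples
#' binarize(c(0.7, 0.2, 0.5))
#' @export
binarize <- function(x, threshold = 0.5) {
  out <- x
  out[] <- as.integer(x > threshold)
  storage.mode(out) <- "integer"
  out
}

#' Combined wrapper-FS fitness
#'
#' `lam * gamma + (1 - lam) * count / dim`: a convex combination of the
#' classifier validation loss and the selected-feature ratio, minimized.
#'
#' @param gamma Classifier validation loss in `[0, 1]`.
#' @param mask 0/1 feature mask (or its selected count as a scalar).
#' @param dim Total number of candidate features (> 0).
#' @param lam Weight `lambda` in `(0, 1]`.
#' @return The fitness value.
#' @examples
#' fs_fitness(0.1, rep(c(1, 0), each = 64), 128, lam = 0.99) # 0.104
#' @export
fs_fitness <- function(gamma, mask, dim, lam = 0.99) {
  if (dim <= 0) stop("dim must be positive")
  stopifnot(gamma >= 0, gamma <= 1, lam > 0, lam <= 1)
  count <- if (length(mask) == 1) mask else sum(mask != 0)
  lam * gamma + (1 - lam) * count / dim
}

# Precompute the standardized fit/validation matrices and labels once per
# run; every gamma evaluation then only subsets columns. Standardization
# parameters come from the fit partition only.
make_eval_ctx <- function(data, classifier_spec, seed = data$meta$seed) {
  stopifnot(inherits(data, "embedding_dataset"))
  classifier_spec <- match.arg(classifier_spec, CLASSIFIERS)
  if (length(unique(data$y[data$fit_idx])) < 2 ||
      length(unique(data$y[data$val_idx])) < 2)
    stop("both fit and validation partitions must contain >= 2 classes")
  std <- standardize_train_apply(data$X[data$fit_idx, , drop = FALSE],
                                 data$X[data$val_idx, , drop = FALSE])
  list(X_fit = std$fit, y_fit = data$y[data$fit_idx],
       X_val = std$apply, y_val = data$y[data$val_idx],
       classifier = classifier_spec, seed = as.integer(seed))
}

gamma_from_ctx <- function(ctx, mask) {
  cols <- which(mask != 0)
  if (length(cols) == 0) stop("mask must select at least one feature")
  pred <- train_and_predict(ctx$classifier,
                            ctx$X_fit[, cols, drop = FALSE], ctx$y_fit,
                            ctx$X_val[, cols, drop = FALSE], seed = ctx$seed)
  1 - mean(pred == ctx$y_val)
}

#' Classifier validation loss for a feature mask
#'
#' Trains the given classifier on the selected columns of the fit partition
#' (a stratified 80/20 sub-split of the training partition recorded on the
#' dataset) and returns `1 - accuracy` on the validation partition.
#' Deterministic given the dataset and seed, so the wrapper fitness is a
#' pure function of the mask within one run.
#'
#' @param mask 0/1 feature mask; must select at least one feature.
#' @param data An `embedding_dataset`.
#' @param classifier_spec One of `"svm"`, `"knn"`, `"rf"`, `"xgb"`.
#' @param seed Integer seed for the classifier fit (defaults to the
#'   dataset's generation seed so every caller sees the same loss).
#' @return The validation loss in `[0, 1]`.
#' @export
evaluate_gamma <- function(mask, data, classifier_spec = "svm",
                           seed = data$meta$seed) {
  ctx <- make_eval_ctx(data, classifier_spec, seed)
  gamma_from_ctx(ctx, mask)
}

# Evaluate the fitness of every row of a position matrix, caching by mask
# so repeated subsets (frequent once the population concentrates) cost one
# classifier fit. The empty mask never trains a model: its fitness is the
# sentinel 1.0, the maximum of the fitness range, so empty solutions
# survive but can never become best.
evaluate_population <- function(X, ctx, lam, cache) {
  masks <- binarize(X)
  vapply(seq_len(nrow(X)), function(i) {
    m <- masks[i, ]
    if (sum(m) == 0) return(1.0)
    key <- paste(m, collapse = "")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit$fitness)
    g <- gamma_from_ctx(ctx, m)
    f <- fs_fitness(g, m, length(m), lam)
    cache[[key]] <- list(gamma = g, fitness = f)
    f
  }, numeric(1))
}

fs_result <- function(best_x, best_fit, conv, elapsed, params, optimizer,
                      classifier, data) {
  mask <- as.integer(binarize(best_x))
  names(mask) <- colnames(data$X)
  structure(list(
    best_mask = mask,
    best_position = best_x,
    best_fitness = best_fit,
    selected_count = sum(mask),
    convergence = conv,
    elapsed = elapsed,
    seed = params$seed,
    optimizer = optimizer,
    classifier = classifier
  ), class = "fs_result")
}

#' @export
print.fs_result <- function(x, ...) {
  cat(sprintf("%s feature selection (classifier: %s, seed %d)\n",
              toupper(x$optimizer), x$classifier, x$seed))
  cat(sprintf("  best fitness : %.6f\n", x$best_fitness))
  cat(sprintf("  selected     : %d / %d features\n",
              x$selected_count, length(x$best_mask)))
  cat(sprintf("  iterations   : %d   elapsed: %.2f s\n",
              length(x$convergence) - 1L, x$elapsed))
  invisible(x)
}

# Shared population-based driver. `method` picks the position-update rule;
# everything else (initialization, evaluation, elitist best tracking,
# hunger bookkeeping for the HGS-bearing methods) is common.
fs_engine <- function(data, params, classifier_spec, method) {
  validate_optimizer_params(params)
  classifier_spec <- match.arg(classifier_spec, CLASSIFIERS)
  t0 <- proc.time()[["elapsed"]]

  ctx <- make_eval_ctx(data, classifier_spec)
  cache <- new.env(parent = emptyenv())
  rng <- rng_stream(params$seed)

  N <- params$pop_size
  Tm <- params$max_iter
  d <- ncol(data$X)
  box <- search_bounds(rep(0, d), rep(1, d))

  X <- init_population(N, d, box, rng)
  fits <- evaluate_population(X, ctx, params$lam, cache)
  b <- which.min(fits)
  best_x <- X[b, ]
  best_fit <- fits[b]
  H <- numeric(N)
  conv <- numeric(Tm + 1)
  conv[1] <- best_fit

  for (t in seq_len(Tm)) {
    moa_t <- moa(t, Tm, params)
    mop_t <- mop(t, Tm, params$alpha)

    if (method %in% c("aoahg", "hgs")) {
      # Per-solution draws, in a fixed order: weights (r3, r4, r5), hunger
      # (r6, r inside update_hunger), then the variation draw for R.
      r3 <- rng$unif(N); r4 <- rng$unif(N); r5 <- rng$unif(N)
      W1 <- weight_w1(H, sum(H), N, params, r3, r4)
      W2 <- weight_w2(H, sum(H), r5)
      hs <- update_hunger(fits, min(fits), max(fits), H, box, params, rng)
      H <- hs$H
      Rv <- variation_R(t, Tm, rng$unif(N))
    }

    if (method == "aoahg") {
      dyn <- update_bounds(X)
      Pi <- matrix(rng$unif(N * d), N, d, byrow = TRUE)
      PA <- matrix(rng$unif(N * d), N, d, byrow = TRUE)
      PH <- matrix(rng$unif(N * d), N, d, byrow = TRUE)
      for (i in seq_len(N)) {
        x_aoa <- aoa_explore_rule(best_x, mop_t, dyn$lower, dyn$upper,
                                  params, PA[i, ])
        x_hgs <- aoahg_hgs_rule(X[i, ], best_x, W1[i], W2[i], Rv[i], PH[i, ])
        X[i, ] <- ifelse(Pi[i, ] > moa_t, x_aoa, x_hgs)
      }
    } else if (method == "aoa") {
      r1 <- matrix(rng$unif(N * d), N, d, byrow = TRUE)
      r2 <- matrix(rng$unif(N * d), N, d, byrow = TRUE)
      r3a <- matrix(rng$unif(N * d), N, d, byrow = TRUE)
      for (i in seq_len(N)) {
        x_exp <- aoa_explore_rule(best_x, mop_t, box$lower, box$upper,
                                  params, r2[i, ])
        x_xpl <- aoa_exploit_rule(best_x, mop_t, box$lower, box$upper,
                                  params, r3a[i, ])
        X[i, ] <- ifelse(r1[i, ] > moa_t, x_exp, x_xpl)
      }
    } else { # hgs
      for (i in seq_len(N)) {
        E_i <- energy_E(fits[i], best_fit)
        X[i, ] <- hgs_position_update(X[i, ], best_x, W1[i], W2[i], Rv[i],
                                      E_i, params, rng)
      }
    }

    fits <- evaluate_population(X, ctx, params$lam, cache)
    if (min(fits) < best_fit) { # strict: first-found best kept on ties
      b <- which.min(fits)
      best_fit <- fits[b]
      best_x <- X[b, ]
    }
    conv[t + 1] <- best_fit
  }

  elapsed <- proc.time()[["elapsed"]] - t0
  fs_result(best_x, best_fit, conv, elapsed, params, method,
            classifier_spec, data)
}

#' Run the AOAHG hybrid feature selector
#'
#' Each iteration evaluates the wrapper fitness of every solution, updates
#' the elitist best, refreshes the MOA/MOP schedules and the hunger system,
#' then updates every coordinate: with the per-coordinate gate `Pi > MOA`
#' an AOA exploration move (divide when `PA > 0.5`, multiply otherwise,
#' with dynamic per-dimension bounds recomputed from the population at the
#' start of the iteration), otherwise an HGS-style attraction move (sign
#' chosen by `PH`).
#'
#' @param data An `embedding_dataset` (see
#'   [generate_embedding_dataset()] or [read_embedding_csv()]).
#' @param params An [optimizer_params()].
#' @param classifier_spec Fitness classifier: `"svm"` (default), `"knn"`,
#'   `"rf"` or `"xgb"`.
#' @return An `fs_result`: best mask, best fitness, selected count, the
#'   per-iteration best-fitness series (length `max_iter + 1`, always
#'   non-increasing), elapsed seconds, seed and labels.
#' @examples
#' d <- generate_embedding_dataset(n = 80, dim = 8, k_informative = 3,
#'                                 n_classes = 2, class_sep = 4, seed = 1)
#' run_aoahg(d, optimizer_params(pop_size = 10, max_iter = 3, seed = 1))
#' @export
run_aoahg <- function(data, params = optimizer_params(),
                      classifier_spec = "svm") {
  fs_engine(data, params, classifier_spec, "aoahg")
}

#' Run the plain AOA feature selector
#'
#' Baseline driver using only the arithmetic operators: per coordinate,
#' exploration (divide/multiply) when `r1 > MOA`, exploitation
#' (subtract/add) otherwise, always around the best solution.
#'
#' @inheritParams run_aoahg
#' @return An `fs_result`.
#' @export
run_aoa <- function(data, params = optimizer_params(),
                    classifier_spec = "svm") {
  fs_engine(data, params, classifier_spec, "aoa")
}

#' Run the plain HGS feature selector
#'
#' Baseline driver using the three-branch hunger games move per solution:
#' self-perturbation with probability `l`, otherwise attraction toward the
#' best with sign gated by the energy term.
#'
#' @inheritParams run_aoahg
#' @return An `fs_result`.
#' @export
run_hgs <- function(data, params = optimizer_params(),
                    classifier_spec = "svm") {
  fs_engine(data, params, classifier_spec, "hgs")
}

#' Exhaustive feature-subset oracle
#'
#' Enumerates every non-empty mask over `dim <= 16` features, evaluates the
#' identical fitness used by the drivers, and returns the global minimizer.
#' Ties are broken toward fewer selected features, then toward the
#' lexicographically smallest bit vector. Intended as an independent ground
#' truth for validating the stochastic drivers on small problems.
#'
#' @param data An `embedding_dataset` with at most 16 features.
#' @param classifier_spec Fitness classifier label.
#' @param lam Fitness weight `lambda`.
#' @return A list with the optimal `mask` (0/1 integer vector), its
#'   `fitness`, its validation loss `gamma`, and `n_evaluated`.
#' @export
exhaustive_fs_oracle <- function(data, classifier_spec = "svm", lam = 0.99) {
  d <- ncol(data$X)
  if (d > 16) stop("exhaustive enumeration is limited to dim <= 16")
  ctx <- make_eval_ctx(data, classifier_spec)

  best <- NULL
  n_masks <- 2^d - 1
  for (code in seq_len(n_masks)) {
    m <- as.integer(bitwAnd(bitwShiftR(code, d - seq_len(d)), 1L))
    g <- gamma_from_ctx(ctx, m)
    f <- fs_fitness(g, m, d, lam)
    cand <- list(mask = m, fitness = f, gamma = g)
    if (is.null(best) || oracle_better(cand, best)) best <- cand
  }
  best$n_evaluated <- n_masks
  names(best$mask) <- colnames(data$X)
  best
}

# Strictly better under the oracle's total order: lower fitness, then
# fewer features, then lexicographically smaller bit vector.
oracle_better <- function(a, b) {
  if (a$fitness != b$fitness) return(a$fitness < b$fitness)
  ca <- sum(a$mask); cb <- sum(b$mask)
  if (ca != cb) return(ca < cb)
  diff <- which(a$mask != b$mask)
  length(diff) > 0 && a$mask[diff[1]] < b$mask[diff[1]]
}
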