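#' Optimizer parameter set
#'
#' Bundles every tunable constant shared by the AOA, HGS and AOAHG drivers.
#' Defaults follow the conventions of the originating AOA/HGS literature and
#' the wrapper-FS protocol used throughout this package: the math optimizer
#' accelerated (MOA) schedule runs linearly from `min_acc` to `max_acc`, the
#' math optimizer probability (MOP) decays with sensitivity `alpha`, and the
#' fitness is the convex combination `lam * loss + (1 - lam) * subset_ratio`.
#'
#' @param min_acc Lower endpoint of the MOA schedule, in `[0, max_acc)`.
#' @param max_acc Upper endpoint of the MOA schedule, in `(min_acc, 1]`.
#' @param alpha Sensitivity exponent of the MOP schedule (> 0).
#' @param mu Search-control constant multiplying the dynamic-range term of
#'   the AOA arithmetic rules, in `[0, 1]`.
#' @param epsilon Small positive stabilizer added to the divide-rule
#'   denominator (and to aggregate-hunger denominators).
#' @param lam Fitness weight `lambda` in `(0, 1]`; the classifier loss is
#'   weighted `lam`, the selected-feature ratio `1 - lam`.
#' @param l_hgs HGS branch threshold `l` in `(0, 1)`.
#' @param LH Hunger lower bound (> 0).
#' @param pop_size Population size `N` (>= 2).
#' @param max_iter Iteration budget `T` (>= 1).
#' @param seed Integer seed driving every random draw of a run.
#'
#' @return An object of class `optimizer_params` (a validated list).
#' @examples
#' p <- optimizer_params(pop_size = 30, max_iter = 10, seed = 42)
#' p$lam
#' @export
optimizer_params <- function(min_acc = 0.2, max_acc = 1.0, alpha = 5,
                             mu = 0.5, epsilon = 1e-12, lam = 0.99,
                             l_hgs = 0.08, LH = 100,
                             pop_size = 50L, max_iter = 20L, seed = 1L) {
  p <- list(min_acc = min_acc, max_acc = max_acc, alpha = alpha, mu = mu,
            epsilon = epsilon, lam = lam, l_hgs = l_hgs, LH = LH,
            pop_size = as.integer(pop_size), max_iter = as.integer(max_iter),
            seed = as.integer(seed))
  validate_optimizer_params(p)
  structure(p, class = "optimizer_params")
}

validate_optimizer_params <- function(p) {
  stopifnot(
    p$min_acc >= 0, p$min_acc < p$max_acc, p$max_acc <= 1,
    p$alpha > 0,
    p$mu >= 0, p$mu <= 1,
    p$epsilon > 0,
    p$lam > 0, p$lam <= 1,
    p$l_hgs > 0, p$l_hgs < 1,
    p$LH > 0,
    p$pop_size >= 2L,
    p$max_iter >= 0L
  )
  invisible(p)
}

#' @export
print.optimizer_params <- function(x, ...) {
  cat("Optimizer parameters\n")
  cat(sprintf("  MOA range  : [%.3g, %.3g]   alpha: %.3g   mu: %.3g\n",
              x$min_acc, x$max_acc, x$alpha, x$mu))
  cat(sprintf("  lambda     : %.3g   l: %.3g   LH: %.3g   epsilon: %.2g\n",
              x$lam, x$l_hgs, x$LH, x$epsilon))
  cat(sprintf("  population : %d   iterations: %d   seed: %d\n",
              x$pop_size, x$max_iter, x$seed))
  invisible(x)
}

#' Per-dimension search bounds
#'
#' @param lower Numeric vector of per-dimension lower bounds `L`.
#' @param upper Numeric vector of per-dimension upper bounds `U`; must
#'   satisfy `lower[j] <= upper[j]` element-wise.
#' @return An object of class `search_bounds`.
#' @examples
#' search_bounds(rep(0, 4), rep(1, 4))
#' @export
search_bounds <- function(lower, upper) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (length(lower) != length(upper))
    stop("lower and upper must have the same length")
  if (any(lower > upper))
    stop("every lower bound must be <= its upper bound")
  structure(list(lower = lower, upper = upper), class = "search_bounds")
}
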