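# Pure numeric primitives of AOA and HGS: schedules, per-coordinate update
# rules and hunger bookkeeping. No classifiers, no files. All position
# updates are clipped to the fixed global box [0, 1] so the downstream 0.5
# binarization threshold stays meaningful.

#' Clip coordinates to the global unit box
#' @param x Numeric vector or matrix.
#' @return `x` with every element forced into `[0, 1]`.
#' @keywords internal
clip_unit <- function(x) pmin(1, pmax(0, x))

#' Math optimizer accelerated (MOA) schedule
#'
#' Linear ramp `Min + t * (Max - Min) / T` gating exploration versus
#' exploitation: branches conditioned on a draw exceeding MOA fire less
#' often as iterations progress.
#'
#' @param t Current iteration, `0 <= t <= T`.
#' @param T_max Iteration budget `T >= 1`.
#' @param params An [optimizer_params()] object supplying `min_acc`, `max_acc`.
#' @return The accelerator value, non-decreasing in `t`, in
#'   `[min_acc, max_acc]`.
#' @examples
#' moa(10, 20, optimizer_params())
#' @export
moa <- function(t, T_max, params = optimizer_params()) {
  if (T_max < 1) stop("T_max must be >= 1")
  stopifnot(t >= 0, t <= T_max)
  params$min_acc + t * (params$max_acc - params$min_acc) / T_max
}

#' Math optimizer probability (MOP) schedule
#'
#' Decaying step scale `1 - t^(1/alpha) / T^(1/alpha)` used inside the AOA
#' arithmetic update rules.
#'
#' @inheritParams moa
#' @param alpha Sensitivity exponent (> 0).
#' @return A value in `[0, 1]`, non-increasing in `t`; 1 at `t = 0`, 0 at
#'   `t = T`.
#' @examples
#' mop(1, 32, alpha = 5) # exactly 0.5
#' @export
mop <- function(t, T_max, alpha = 5) {
  if (T_max < 1) stop("T_max must be >= 1")
  stopifnot(t >= 0, t <= T_max, alpha > 0)
  1 - t^(1 / alpha) / T_max^(1 / alpha)
}

#' AOA exploration rule (divide / multiply)
#'
#' The two exploration operators applied to the best coordinate: division by
#' `MOP + epsilon` when the gate draw exceeds 0.5, multiplication by `MOP`
#' otherwise, each scaled by `(U - L) * mu + L`. Vectorized over dimensions.
#'
#' @param best_j Best-solution coordinate(s) `Xb_j`.
#' @param mop_val MOP value at the current iteration.
#' @param lower_j,upper_j Per-dimension bounds feeding the range term.
#' @param params An [optimizer_params()] (uses `mu`, `epsilon`).
#' @param r2 Uniform gate draw(s).
#' @return Updated coordinate(s), clipped to `[0, 1]`.
#' @export
aoa_explore_rule <- function(best_j, mop_val, lower_j, upper_j,
                             params = optimizer_params(), r2) {
  stopifnot(mop_val >= 0)
  term <- (upper_j - lower_j) * params$mu + lower_j
  out <- ifelse(r2 > 0.5,
                best_j / (mop_val + params$epsilon) * term,
                best_j * mop_val * term)
  clip_unit(out)
}

#' AOA exploitation rule (subtract / add)
#'
#' The two exploitation operators: subtraction of `MOP * ((U - L) * mu + L)`
#' from the best coordinate when the gate draw exceeds 0.5, addition
#' otherwise. Vectorized over dimensions.
#'
#' @inheritParams aoa_explore_rule
#' @param r3 Uniform gate draw(s).
#' @return Updated coordinate(s), clipped to `[0, 1]`.
#' @export
aoa_exploit_rule <- function(best_j, mop_val, lower_j, upper_j,
                             params = optimizer_params(), r3) {
  stopifnot(mop_val >= 0)
  term <- (upper_j - lower_j) * params$mu + lower_j
  out <- ifelse(r3 > 0.5,
                best_j - mop_val * term,
                best_j + mop_val * term)
  clip_unit(out)
}

#' Hyperbolic secant
#'
#' `sech(x) = 2 / (exp(x) + exp(-x))`, an even function with range `(0, 1]`.
#'
#' @param x Numeric vector.
#' @return `sech(x)`.
#' @examples
#' sech(0) # 1
#' @export
sech <- function(x) 2 / (exp(x) + exp(-x))

#' Variation-control value R
#'
#' `R = 2 * s * rand - s` with shrink factor `s = 2 * (1 - t / T)`, so the
#' search radius contracts linearly to zero over the run and `|R| <= s`.
#'
#' @inheritParams moa
#' @param rand Uniform draw(s) on `[0, 1]`.
#' @return `R`, vectorized over `rand`.
#' @export
variation_R <- function(t, T_max, rand) {
  if (T_max < 1) stop("T_max must be >= 1")
  stopifnot(t >= 0, t <= T_max)
  s <- 2 * (1 - t / T_max)
  2 * s * rand - s
}

#' Energy term E
#'
#' `E = sech(|Fit_i - Fit_b|)`: close-to-best solutions have energy near 1,
#' far ones near 0. Gates the sign of the HGS attraction step.
#'
#' @param fit_i Fitness of the solution under update.
#' @param fit_b Best fitness.
#' @return Value in `(0, 1]`, equal to 1 iff `fit_i == fit_b`.
#' @export
energy_E <- function(fit_i, fit_b) sech(abs(fit_i - fit_b))

#' Update per-solution hunger
#'
#' The HGS hunger bookkeeping. The solution attaining the best fitness has
#' its hunger reset to 0; every other solution accumulates a new hunger
#' `Hn`, where `TH = 2 * (Fit_i - Fit_b) / (Fit_w - Fit_b) * r6 * (UB - LB)`
#' and `Hn = LH * (1 + r)` whenever `TH < LH` (otherwise `Hn = TH`). When
#' all fitnesses are equal (`Fit_w == Fit_b`) `TH` is defined as 0.
#'
#' @param fits Numeric vector of current fitness values.
#' @param fit_b Best fitness (`<= min(fits)` is not required; the reset
#'   applies to solutions with `fits == fit_b`).
#' @param fit_w Worst fitness of the current iteration.
#' @param hunger Numeric vector of current hunger values `H`.
#' @param bounds A [search_bounds()]; the scalar range `UB - LB` is taken as
#'   the mean per-dimension width.
#' @param params An [optimizer_params()] (uses `LH`).
#' @param rng An [rng_stream()]; consumes `r6` then `r`, one each per
#'   solution.
#' @return A list with updated `H` and aggregate `SH = sum(H)`.
#' @export
update_hunger <- function(fits, fit_b, fit_w, hunger, bounds,
                          params = optimizer_params(), rng) {
  n <- length(fits)
  stopifnot(length(hunger) == n)
  r6 <- rng$unif(n)
  r <- rng$unif(n)
  width <- mean(bounds$upper - bounds$lower)
  if (fit_w == fit_b) {
    TH <- rep(0, n)
  } else {
    TH <- 2 * (fits - fit_b) / (fit_w - fit_b) * r6 * width
  }
  Hn <- ifelse(TH < params$LH, params$LH * (1 + r), TH)
  H <- ifelse(fits == fit_b, 0, hunger + Hn)
  list(H = H, SH = sum(H))
}

#' Hunger weight W1
#'
#' `W1 = H_i * N / SH * r4` when `r3 < l`, otherwise 1. The aggregate-hunger
#' denominator is stabilized with `epsilon` so an all-zero hunger state
#' yields 0 on the first branch.
#'
#' @param H_i Hunger value(s).
#' @param SH Aggregate hunger.
#' @param n Population size `N`.
#' @param params An [optimizer_params()] (uses `l_hgs`, `epsilon`).
#' @param r3,r4 Uniform draws (vectorized with `H_i`).
#' @return The weight(s).
#' @export
weight_w1 <- function(H_i, SH, n, params = optimizer_params(), r3, r4) {
  stopifnot(SH >= 0)
  ifelse(r3 < params$l_hgs, H_i * n / (SH + params$epsilon) * r4, 1)
}

#' Hunger weight W2
#'
#' `W2 = 2 * (1 - exp(-|H_i - SH|)) * r5`, lying in `[0, 2)` for uniform
#' `r5`.
#'
#' @inheritParams weight_w1
#' @param r5 Uniform draw(s).
#' @return The weight(s).
#' @export
weight_w2 <- function(H_i, SH, r5) {
  stopifnot(all(H_i >= 0), SH >= 0)
  2 * (1 - exp(-abs(H_i - SH))) * r5
}

#' Plain HGS position update (whole solution)
#'
#' The three-branch HGS move: with probability `l` a self-perturbation
#' `X * (1 + rand)`; otherwise an attraction step toward the best solution,
#' `W1 * Xb +/- R * W2 * (Xb - X)`, the sign chosen by comparing a draw with
#' the energy `E`. Consumes `r1`, `r2`, `rand` from `rng` in that order.
#'
#' @param x Current position vector.
#' @param best Best position vector `Xb`.
#' @param W1,W2 Hunger weights for this solution.
#' @param R Variation-control value for this solution.
#' @param E Energy term for this solution.
#' @param params An [optimizer_params()] (uses `l_hgs`).
#' @param rng An [rng_stream()].
#' @return Updated position, clipped to `[0, 1]`.
#' @export
hgs_position_update <- function(x, best, W1, W2, R, E,
                                params = optimizer_params(), rng) {
  r1 <- rng$unif(1)
  r2 <- rng$unif(1)
  rand <- rng$unif(1)
  out <- if (r1 < params$l_hgs) {
    x * (1 + rand)
  } else if (r2 > E) {
    W1 * best + R * W2 * (best - x)
  } else {
    W1 * best - R * W2 * (best - x)
  }
  clip_unit(out)
}

#' HGS-style coordinate rule used inside AOAHG
#'
#' The per-coordinate hybrid move `W1 * x_j -/+ R * W2 * |x_j - Xb_j|`, the
#' sign chosen by the gate draw `pH` (minus when `pH > 0.5`). Vectorized
#' over dimensions.
#'
#' @param x_j Current coordinate(s).
#' @param best_j Best-solution coordinate(s).
#' @param W1,W2 Hunger weights of the solution under update.
#' @param R Variation-control value of the solution under update.
#' @param pH Uniform gate draw(s).
#' @return Updated coordinate(s), clipped to `[0, 1]`.
#' @export
aoahg_hgs_rule <- function(x_j, best_j, W1, W2, R, pH) {
  step <- R * W2 * abs(x_j - best_j)
  out <- ifelse(pH > 0.5, W1 * x_j - step, W1 * x_j + step)
  clip_unit(out)
}

#' Initialize a population inside given bounds
#'
#' Each coordinate is drawn as `rand * (U_j - L_j) + L_j`.
#'
#' @param n Population size (>= 2).
#' @param dim Number of dimensions (>= 1).
#' @param bounds A [search_bounds()] of length `dim`.
#' @param rng An [rng_stream()]; consumes `n * dim` draws row by row.
#' @return An `n x dim` numeric matrix of positions.
#' @export
init_population <- function(n, dim, bounds, rng) {
  if (n < 1 || dim < 1) stop("n and dim must be positive")
  if (length(bounds$lower) != dim) stop("bounds length must equal dim")
  u <- matrix(rng$unif(n * dim), nrow = n, ncol = dim, byrow = TRUE)
  sweep(sweep(u, 2, bounds$upper - bounds$lower, `*`), 2, bounds$lower, `+`)
}

#' Dynamic bounds from the current population
#'
#' Per-dimension `L_j = min_i X_ij`, `U_j = max_i X_ij`; these shrink the
#' range term of the AOA arithmetic rules as the population concentrates.
#'
#' @param pop An `n x dim` position matrix.
#' @return A [search_bounds()] object.
#' @export
update_bounds <- function(pop) {
  if (!is.matrix(pop) || nrow(pop) < 1) stop("pop must be a non-empty matrix")
  search_bounds(apply(pop, 2, min), apply(pop, 2, max))
}
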