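---
title: "Methods: hybrid AOA–HGS wrapper feature selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid AOA-HGS wrapper feature selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aoahg)
```

## The problem

Deep networks turn a medical image into a fixed-length embedding — here
treated as a vector of `Dim` continuous features (128 is a typical width).
Many coordinates are redundant or noisy; classifying on all of them costs
time and can cost accuracy. Wrapper feature selection searches the space of
feature subsets using a classifier's validation performance as the
objective. With `Dim` binary choices, the search space has `2^Dim - 1`
non-empty subsets, so exhaustive enumeration stops being possible beyond a
handful of features and a stochastic search takes over.

This package implements a hybrid population-based search, AOAHG, that gates
the arithmetic operators of the arithmetic optimization algorithm (AOA)
with the hunger-driven operators of hunger games search (HGS), together
with both parents as baselines and an exhaustive oracle for small `Dim`.

## Solution encoding and fitness

Each of `N` solutions is a position `X_i` in the unit box `[0,1]^Dim`.
A position binarizes to a mask by a strict threshold:

    BX_ij = 1  if  X_ij > 0.5,   else 0.

The minimized fitness of a mask is

    Fit_i = lambda * gamma_i + (1 - lambda) * |BX_i| / Dim,

where `gamma_i` is the validation loss (1 − accuracy) of a classifier
trained on the selected columns, and `|BX_i|/Dim` the selected-feature
ratio. The default `lambda = 0.99` is the common wrapper-FS convention:
classification quality dominates, with a small pressure toward small
subsets. With `lambda = 1` the ratio is ignored; the weight is
configurable in `optimizer_params()`.

`gamma` is computed on a stratified 80/20 fit/validation sub-split of the
training partition, fixed once per dataset, so fitness is a deterministic
function of the mask within a run and the test partition is never touched
during the search. Features are standardized with means and standard
deviations estimated on the fit rows only (the RBF-kernel SVM is scale
sensitive). An empty mask never trains a classifier: its fitness is the
sentinel `1.0`, the maximum of the fitness range, so empty solutions
survive in the population but can never become the best.

## Search dynamics

Every iteration `t = 1 … T` updates two schedules:

* `MOA(t) = Min + t (Max − Min) / T`, a linear ramp (defaults
  `Min = 0.2`, `Max = 1`) gating which operator family fires;
* `MOP(t) = 1 − t^(1/alpha) / T^(1/alpha)` (default `alpha = 5`), a
  decaying step scale inside the arithmetic rules.

**AOAHG update.** For each solution `i` and coordinate `j`, three uniform
gates `Pi, PA, PH` are drawn. If `Pi > MOA(t)` an AOA exploration move is
applied to the best coordinate `Xb_j`:

    divide   (PA > 0.5):  Xb_j / (MOP + eps) * ((U_j − L_j) mu + L_j)
    multiply (otherwise): Xb_j * MOP * ((U_j − L_j) mu + L_j)

with `mu = 0.5` and `eps = 1e-12` stabilizing the quotient. `L_j, U_j` are
*dynamic* bounds — the per-dimension envelope of the current population,
recomputed once at the start of each iteration — so the arithmetic range
term shrinks as the population concentrates. Otherwise an HGS-style
attraction move is applied:

    PH > 0.5:  W1 * X_ij − R * W2 * |X_ij − Xb_j|
    else    :  W1 * X_ij + R * W2 * |X_ij − Xb_j|

`W1, W2` are the hunger weights, computed per solution; `R` shrinks
linearly (`|R| <= 2(1 − t/T)`). Every updated coordinate is clipped to the
fixed global box `[0,1]` — without this the 0.5 binarization threshold
would drift out of reach of the moves.

**Hunger system.** Each solution carries a hunger value `H_i`: the current
best solution's hunger is reset to 0 each iteration, all others accumulate
`Hn`, where `TH = 2 (Fit_i − Fit_b)/(Fit_w − Fit_b) * r6 * (UB − LB)` and
`Hn = LH (1 + r)` when `TH < LH` (default `LH = 100`). On the unit box
`UB − LB = 1`, so the `LH` branch essentially always fires — hunger then
grows by `LH`-scale increments for non-best solutions, which is exactly
the regime the weights are built for: `W1` is 1 with probability `1 − l`
(default `l = 0.08`) and otherwise rescales by relative hunger;
`W2 = 2 (1 − e^{−|H_i − SH|}) r5` saturates near `2 r5`. When all
fitnesses are equal, `TH` is defined as 0 (avoiding 0/0); when total
hunger is zero, `W1`'s hungry branch returns 0 via an `eps`-stabilized
denominator.

**Baselines.** Plain AOA uses the arithmetic rules only: per coordinate,
exploration (divide/multiply) when `r1 > MOA`, exploitation
(`Xb_j ∓ MOP * ((U−L) mu + L)`) otherwise, on the fixed global box. Plain
HGS updates whole solutions with the three-branch move: self-inflation
`X (1 + rand)` with probability `l`, otherwise attraction
`W1 Xb ± R W2 (Xb − X)` with the sign gated by the energy
`E = sech(|Fit_i − Fit_b|)`.

Both drivers and the hybrid are elitist: the best-so-far mask and fitness
are tracked outside the population, so the reported convergence series is
non-increasing by construction.

## Choices where the formulation was open

* **Hyperbolic secant.** `sech(x) = 2/(e^x + e^{−x})`. (The csch-like
  variant with a minus sign is singular at 0 and would break the
  requirement `E ∈ (0, 1]`.)
* **The attraction target in the hybrid's HGS rule** is the best
  solution's coordinate `Xb_j`, by analogy with the plain HGS attraction
  toward `Xb`; the alternative reading (the solution's own previous
  coordinate) would make the `|X_ij − X|` term vanish identically.
* **Hunger weights per solution, not per coordinate.** The hunger state is
  a per-solution quantity; recomputing `W1/W2` per coordinate would add
  `Dim` draws per solution without a defensible interpretation.
* **Draw order** (fixed for reproducibility): per iteration — weight draws
  `r3, r4, r5` (per solution), hunger draws `r6, r` (per solution), the
  variation draw for `R` (per solution), then the gates `Pi`, `PA`, `PH`
  (per solution × dimension, row by row). All randomness flows through a
  seeded stream that is insulated from the global RNG, so classifier fits
  (which seed the global RNG) cannot perturb a trajectory.
* **`rand` in the HGS inflation branch is uniform on [0, 1]**, keeping the
  perturbation bounded (`X` grows by at most a factor 2 before clipping);
  a heavy-tailed draw would mostly saturate the clip.
* **Hunger reference fitness** is the *current iteration's* minimum, so
  the invariant "the best solution's hunger is 0" holds every iteration
  even when the elitist best-so-far no longer sits in the population.
* **Ties** for the best solution keep the first one found; the exhaustive
  oracle breaks fitness ties toward fewer features, then the
  lexicographically smallest bit vector, making its output unique and
  reproducible.

## The synthetic generator

`generate_embedding_dataset()` emulates the embedding-classification
setting without any images: `k` informative columns carry class-conditional
Gaussian means placed at the vertices of a regular simplex (every pairwise
class separation equals `class_sep`), with the simplex coordinates spread
over blocks of columns (scaled by `1/sqrt(block size)`, which preserves
the pairwise distances) so that *every* planted column carries genuine
class signal; the remaining `Dim − k` columns are independent standard
Gaussian noise. Defaults — `n = 400`, `Dim = 128`, `k = 10`, two classes,
`class_sep = 3`, `noise_sd = 1`, `train_frac = 0.8` — mirror a typical
two-class embedding problem at a size where a full study (tens of seeded
runs) completes on one CPU in minutes.

What the generator does **not** emulate: correlated noise dimensions,
heavy-tailed or rectified activation distributions, label noise, and
class imbalance. Passing tests on this generator therefore show that the
optimizer machinery and the wrapper protocol behave as specified — not
that any particular accuracy will transfer to real embeddings.

## Validation-resolution limits, honestly

Two properties of the desk-scale study conditions matter when reading
results:

1. **The validation split is small.** With `n = 400` and the 80/20/80/20
   protocol, `gamma` is measured on 64 samples — a resolution of 1/64 ≈
   1.6%. Among 118 noise columns, several will correlate with those 64
   labels by chance as strongly as a genuinely (but weakly) informative
   column. The *global optimum* of the wrapper fitness then contains
   chance-correlated noise columns in place of weak informative ones, so
   recovery of the full planted subset is capped well below 100% for any
   search algorithm — a property of wrapper selection with a small fixed
   hold-out, not of a particular optimizer. Larger `n` or cross-validated
   fitness (out of scope here) are the standard remedies.
2. **Intense exploitation pays on such surfaces.** Plain AOA regenerates
   every coordinate around the elitist best — effectively a randomized
   hill-climb — and can reach lower fitness on this coarse surface than
   the more exploratory hybrid. On large real datasets, where the
   validation surface is much finer, the hybrid's balance is the point;
   the benchmark harness (`run_benchmark()`) reports both so the
   comparison is always explicit.

## Problem sizes used by the test suite and acceptance script

Chosen as the package's own study conditions: oracle agreement on
`Dim = 8` (`n = 300`, 3 informative, `class_sep = 3`; all 255 subsets
enumerated, 20 hybrid runs at population 30, 20 iterations); recovery and
ordering on `Dim = 128` (`n = 400`, 10 informative, `class_sep = 3`;
population 50, 20 iterations, SVM fitness, 10–20 seeds); harness
integrity on a 3 optimizer × 4 classifier grid with reduced population.
The evaluation protocol (population 50, 20 iterations; metrics AC/BA/F/R/P
plus execution time; SVM, KNN, random forest and gradient-boosted
back-ends) matches the benchmark convention the package follows.

```{r example, eval = FALSE}
d <- generate_embedding_dataset(n = 300, dim = 8, k_informative = 3,
                                n_classes = 2, class_sep = 3, seed = 11)
res <- run_aoahg(d, optimizer_params(pop_size = 30, max_iter = 20, seed = 1))
ora <- exhaustive_fs_oracle(d)
c(res$best_fitness, ora$fitness) # hybrid vs exhaustive optimum
```

## Known limitations

* Hold-out (not cross-validated) fitness; see the resolution discussion
  above.
* The exhaustive oracle is limited to `Dim <= 16`.
* Gradient-boosted trees use histogram binning and may misplace a few
  points even on widely separated classes at small sample sizes; the SVM
  back-end is the default for fitness.
* Binary masks only — no feature weighting or multi-objective front.
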