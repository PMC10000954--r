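# Unit and property tests for the AOA/HGS numeric primitives.

test_that("MOA schedule hits its endpoints and midpoint and is non-decreasing", {
  p <- optimizer_params(min_acc = 0.2, max_acc = 1.0)
  expect_identical(moa(0, 10, p), 0.2)
  expect_identical(moa(10, 10, p), 1.0)
  expect_equal(moa(5, 10, p), 0.6)
  vals <- vapply(0:20, moa, numeric(1), T_max = 20, params = p)
  expect_true(all(diff(vals) >= 0))
  expect_true(all(vals >= p$min_acc & vals <= p$max_acc))
  expect_error(moa(1, 0, p))
})

test_that("MOP schedule decays from 1 to 0 and 32 = 2^5 forces 0.5", {
  expect_identical(mop(0, 10, 5), 1)
  expect_identical(mop(10, 10, 5), 0)
  expect_equal(mop(1, 32, 5), 0.5)
  vals <- vapply(0:20, mop, numeric(1), T_max = 20, alpha = 5)
  expect_true(all(diff(vals) <= 0))
  expect_true(all(vals >= 0 & vals <= 1))
  expect_error(mop(1, 0, 5))
})

test_that("AOA exploration rule: divide and multiply branch arithmetic, clipping", {
  p <- optimizer_params(mu = 0.5, epsilon = 1e-12)
  # divide branch: 0.5 / 0.5 * 0.5
  expect_equal(aoa_explore_rule(0.5, 0.5, 0, 1, p, r2 = 0.9), 0.5)
  # multiply branch: 0.5 * 0.5 * 0.5
  expect_equal(aoa_explore_rule(0.5, 0.5, 0, 1, p, r2 = 0.1), 0.125)
  # mop = 0 blows up the quotient, clipped to the box
  expect_identical(aoa_explore_rule(0.5, 0, 0, 1, p, r2 = 0.9), 1)
})

test_that("AOA exploitation rule: subtract and add branch arithmetic", {
  p <- optimizer_params(mu = 0.5)
  expect_equal(aoa_exploit_rule(0.5, 0.5, 0, 1, p, r3 = 0.9), 0.25)
  expect_equal(aoa_exploit_rule(0.5, 0.5, 0, 1, p, r3 = 0.1), 0.75)
  expect_equal(aoa_exploit_rule(0.5, 0, 0, 1, p, r3 = 0.9), 0.5)
  expect_equal(aoa_exploit_rule(0.5, 0, 0, 1, p, r3 = 0.1), 0.5)
})

test_that("sech is the even hyperbolic secant with range (0, 1]", {
  expect_identical(sech(0), 1)
  expect_equal(sech(1), 2 / (exp(1) + exp(-1)))
  x <- seq(-5, 5, by = 0.37)
  expect_equal(sech(x), sech(-x))
  expect_true(all(sech(x) > 0 & sech(x) <= 1))
})

test_that("variation R obeys its envelope |R| <= s", {
  expect_identical(variation_R(10, 10, 0.83), 0)
  expect_identical(variation_R(3, 10, 0.5), 0)
  expect_identical(variation_R(0, 10, 1), 2)
  for (t in 0:10) {
    s <- 2 * (1 - t / 10)
    r <- variation_R(t, 10, runif(50))
    expect_true(all(abs(r) <= s + 1e-12))
  }
})

test_that("energy term is 1 exactly at equal fitness and decays with distance", {
  expect_identical(energy_E(0.3, 0.3), 1)
  expect_equal(energy_E(1.2, 0.2), 2 / (exp(1) + exp(-1)))
  d <- seq(0, 4, by = 0.25)
  e <- energy_E(0.1 + d, 0.1)
  expect_true(all(diff(e) < 0))
  expect_true(all(e > 0 & e <= 1))
})

test_that("hunger update resets the best, accumulates others, sums to SH", {
  p <- optimizer_params(LH = 100)
  box <- search_bounds(rep(0, 4), rep(1, 4))
  fits <- c(0.1, 0.4, 0.9)
  hs <- update_hunger(fits, 0.1, 0.9, c(5, 5, 5), box, p, rng_stream(1))
  expect_identical(hs$H[1], 0)
  expect_true(all(hs$H[2:3] > 5)) # accumulated on top of previous hunger
  expect_identical(hs$SH, sum(hs$H))

  # unit-width box: TH <= 2 < LH, so new hunger is always LH * (1 + r)
  expect_true(all(hs$H[2:3] >= 5 + 100))
  expect_true(all(hs$H[2:3] <= 5 + 200))

  # degenerate all-equal fitness: only finite hunger, best rule still applies
  hs2 <- update_hunger(c(0.2, 0.2), 0.2, 0.2, c(1, 1), box, p, rng_stream(2))
  expect_identical(hs2$H, c(0, 0))
})

test_that("hunger thresholds follow the TH / LH branch arithmetic", {
  p <- optimizer_params(LH = 100)
  # wide bounds make TH = 2 * frac * r6 * 100; replay the stream's own
  # draws (r6 then r, two each) as an independent recomputation
  box <- search_bounds(rep(0, 2), rep(100, 2))
  for (s in 1:25) {
    draws <- rng_stream(s)$unif(4)
    r6 <- draws[1:2]; r <- draws[3:4]
    TH2 <- 2 * 1 * r6[2] * 100
    expected2 <- if (TH2 < 100) 100 * (1 + r[2]) else TH2
    hs <- update_hunger(c(0, 1), 0, 1, c(0, 0), box, p, rng_stream(s))
    expect_identical(hs$H[1], 0)
    expect_equal(hs$H[2], expected2)
    expect_identical(hs$SH, sum(hs$H))
  }
})

test_that("hunger weight W1 branches and stabilized denominator", {
  p <- optimizer_params(l_hgs = 0.08)
  expect_identical(weight_w1(7, 10, 50, p, r3 = 0.5, r4 = 0.3), 1)
  expect_identical(weight_w1(0, 10, 50, p, r3 = 0.01, r4 = 0.3), 0)
  expect_equal(weight_w1(10, 10, 50, p, r3 = 0.01, r4 = 0.02), 1,
               tolerance = 1e-9)
  # all-zero hunger: epsilon guard gives 0, not NaN
  expect_identical(weight_w1(0, 0, 50, p, r3 = 0.01, r4 = 0.9), 0)
})

test_that("hunger weight W2 range and special values", {
  expect_identical(weight_w2(5, 5, r5 = 0.7), 0)
  expect_equal(weight_w2(log(2), 2 * log(2), r5 = 1), 1)
  h <- runif(100, 0, 1000); sh <- runif(100, 0, 1000); r5 <- runif(100)
  w <- weight_w2(h, sh, r5)
  expect_true(all(w >= 0 & w < 2))
})

test_that("HGS position update branches: collapse to best, identity, clipping", {
  p <- optimizer_params(l_hgs = 0.08)
  x <- c(0.2, 0.8, 0.4); b <- c(0.6, 0.6, 0.6)
  # find seeds driving each branch
  for (s in 1:200) {
    r <- rng_stream(s)
    probe <- rng_stream(s)$unif(2)
    out <- hgs_position_update(x, b, W1 = 1, W2 = 0, R = 0.5, E = 0.5, p, r)
    if (probe[1] >= p$l_hgs) {
      # attraction with W2 = 0: X := Xb exactly (both signs)
      expect_identical(out, b)
    } else {
      # inflation branch: X * (1 + rand), clipped
      expect_true(all(out >= x - 1e-12))
    }
  }
  # explicit clipped arithmetic: 0.8 + 1 * 1 * (0.8 - 0.4) = 1.2 -> 1
  for (s in 1:200) {
    probe <- rng_stream(s)$unif(2)
    if (probe[1] > p$l_hgs && probe[2] > 0.1) {
      out <- hgs_position_update(0.4, 0.8, 1, 1, 1, E = 0.1, p, rng_stream(s))
      expect_identical(out, 1)
      break
    }
  }
})

test_that("AOAHG coordinate rule arithmetic and zero-step identity", {
  expect_identical(aoahg_hgs_rule(0.3, 0.9, W1 = 1, W2 = 1, R = 0, pH = 0.9), 0.3)
  expect_identical(aoahg_hgs_rule(0.3, 0.9, W1 = 1, W2 = 1, R = 0, pH = 0.1), 0.3)
  expect_equal(aoahg_hgs_rule(0.4, 0.8, 1, 1, 1, pH = 0.9), 0)
  expect_equal(aoahg_hgs_rule(0.4, 0.8, 1, 1, 1, pH = 0.1), 0.8)
})

test_that("population init respects bounds, degenerate intervals, determinism", {
  b <- search_bounds(rep(0, 2), rep(1, 2))
  X <- init_population(3, 2, b, rng_stream(1))
  expect_identical(dim(X), c(3L, 2L))
  expect_true(all(X >= 0 & X <= 1))

  bd <- search_bounds(rep(0.5, 3), rep(0.5, 3))
  Xd <- init_population(4, 3, bd, rng_stream(9))
  expect_true(all(Xd == 0.5))

  expect_identical(init_population(5, 4, search_bounds(rep(0, 4), rep(1, 4)),
                                   rng_stream(7)),
                   init_population(5, 4, search_bounds(rep(0, 4), rep(1, 4)),
                                   rng_stream(7)))
  expect_error(init_population(0, 2, b, rng_stream(1)))
})

test_that("dynamic bounds are the per-dimension population envelope", {
  X <- rbind(c(0.2, 0.5), c(0.7, 0.1), c(0.4, 0.9))
  b <- update_bounds(X)
  expect_identical(b$lower, c(0.2, 0.1))
  expect_identical(b$upper, c(0.7, 0.9))
  one <- update_bounds(matrix(c(0.3, 0.6), 1))
  expect_identical(one$lower, one$upper)
  expect_true(all(X >= matrix(b$lower, 3, 2, byrow = TRUE) &
                  X <= matrix(b$upper, 3, 2, byrow = TRUE)))
  expect_error(update_bounds(matrix(numeric(0), 0, 2)))
})

test_that("every update rule keeps coordinates inside the unit box", {
  p <- optimizer_params()
  r <- rng_stream(2024)
  for (i in 1:50) {
    x <- r$unif(6); b <- r$unif(6)
    mopv <- r$unif(1); lo <- r$unif(6) * 0.5; hi <- lo + r$unif(6) * 0.5
    out1 <- aoa_explore_rule(b, mopv, lo, hi, p, r$unif(6))
    out2 <- aoa_exploit_rule(b, mopv, lo, hi, p, r$unif(6))
    out3 <- aoahg_hgs_rule(x, b, W1 = 3 * r$unif(1), W2 = 2 * r$unif(1),
                           R = variation_R(i %% 10, 10, r$unif(1)),
                           pH = r$unif(6))
    out4 <- hgs_position_update(x, b, W1 = 3 * r$unif(1), W2 = 2 * r$unif(1),
                                R = 2, E = r$unif(1), p, r)
    for (out in list(out1, out2, out3, out4))
      expect_true(all(out >= 0 & out <= 1))
  }
})

test_that("rng streams are reproducible and isolated from the global RNG", {
  a <- rng_stream(5); b <- rng_stream(5)
  expect_identical(a$unif(10), b$unif(10))
  set.seed(999) # must not disturb the stream
  expect_identical(a$unif(10), b$unif(10))
  # stream draws must not advance the global sequence either
  set.seed(123); g_ref <- runif(5)
  set.seed(123); rng_stream(5)$unif(7); g_new <- runif(5)
  expect_identical(g_ref, g_new)
})

test_that("parameter invariants are enforced", {
  expect_error(optimizer_params(min_acc = 0.9, max_acc = 0.5))
  expect_error(optimizer_params(lam = 0))
  expect_error(optimizer_params(l_hgs = 1))
  expect_error(optimizer_params(pop_size = 1))
  expect_error(search_bounds(c(0, 1), c(1, 0.5)))
})
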