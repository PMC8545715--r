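test_that("dyadic partitioning normalizes and nests correctly", {
  uni <- dyadic_measures(rep(3, 16), 1)
  expect_equal(uni$mu, c(0.5, 0.5))
  expect_equal(uni$epsilon, 0.5)
  # cascade self-consistency: re-binning a deep cascade at a coarser level
  # reproduces the cascade at that level
  w5 <- generate_binomial_cascade(0.7, 5)
  for (k in 1:4) {
    expect_equal(dyadic_measures(w5, k)$mu, generate_binomial_cascade(0.7, k))
  }
  set.seed(3)
  counts <- rpois(64, 40)
  for (k in 1:6) expect_lt(abs(sum(dyadic_measures(counts, k)$mu) - 1), 1e-12)
  expect_error(dyadic_measures(rep(0, 8), 2), "all-zero")
  expect_error(dyadic_measures(rep(1, 8), 4), "exceeds")
  expect_error(dyadic_measures(rep(1, 12), 3), "divisible")
})

test_that("partition sums follow the cascade product structure", {
  p <- dyadic_measures(rep(2, 32), 3)
  expect_equal(partition_sum(p, 1), 1)
  expect_equal(partition_sum(p, 0), 8)   # all bins occupied at level 3
  w <- generate_binomial_cascade(0.7, 6)
  part <- dyadic_measures(w, 6)
  for (q in c(-2, 2)) {
    expect_equal(partition_sum(part, q), (0.7^q + 0.3^q)^6, tolerance = 1e-12)
  }
})

test_that("Chhabra weights normalize and specialize at q = 0, 1", {
  w <- generate_binomial_cascade(0.7, 4)
  part <- dyadic_measures(w, 4)
  expect_equal(chhabra_weights(part, 1), part$mu)
  expect_equal(chhabra_weights(part, 0), rep(1 / 16, 16))
  part1 <- dyadic_measures(generate_binomial_cascade(0.7, 1), 1)
  expect_equal(chhabra_weights(part1, 2), c(0.49, 0.09) / 0.58)
  for (q in c(-3, 0.5, 4)) {
    expect_lt(abs(sum(chhabra_weights(part, q)) - 1), 1e-12)
  }
})

test_that("uniform curves give a degenerate spectrum with perfect fits", {
  sp <- run_multifractal(rep(600000, 1024))
  expect_equal(nrow(sp$table), 19)
  expect_true(all(sp$table$accepted))
  expect_equal(sp$table$alpha, rep(1, 19), tolerance = 1e-10)
  expect_equal(sp$table$f, rep(1, 19), tolerance = 1e-10)
  expect_equal(sp$table$D, rep(1, 19), tolerance = 1e-10)
  expect_true(all(sp$table$r2_alpha >= 1 - 1e-12))
  expect_true(all(sp$table$r2_D >= 1 - 1e-12))
  expect_lt(sp$descriptors$delta_alpha, 1e-9)
  expect_true(is.nan(sp$descriptors$A))   # point spectrum: A undefined
})

test_that("estimators recover the cascade closed forms", {
  w <- generate_binomial_cascade(0.7, 10)
  af0 <- estimate_alpha_f(w, 0)
  expect_equal(af0$alpha, 1.1258, tolerance = 0.02)
  expect_true(af0$accepted)
  d2 <- estimate_Dq(w, 2)
  expect_equal(d2$D, -log2(0.58), tolerance = 0.02)
  u <- estimate_alpha_f(generate_binomial_cascade(0.5, 8), 3)
  expect_equal(u$alpha, 1, tolerance = 1e-10)
  expect_equal(u$f, 1, tolerance = 1e-10)
  # full grid against the closed form, the acceptance-grade comparison
  sp <- run_multifractal(w, q_grid = -5:5)
  tru <- cascade_true_spectrum(0.7, -5:5)
  expect_lt(max(abs(sp$table$D - tru$D)), 0.03)
  expect_lt(max(abs(sp$table$alpha - tru$alpha)), 0.03)
  expect_lt(max(abs(sp$table$f - tru$f)), 0.03)
})

test_that("D0 is exactly 1 for strictly positive curves", {
  set.seed(11)
  for (L in c(64, 1024)) {
    curve <- runif(L, min = 1, max = 100)
    d0 <- estimate_Dq(curve, 0)
    expect_equal(d0$D, 1, tolerance = 1e-12)
    expect_equal(d0$r2_D, 1)
  }
})

test_that("tangent identities hold for estimated spectra", {
  w <- generate_binomial_cascade(0.65, 10)
  sp <- run_multifractal(w)
  tb <- sp$table
  # exact geometric scaling: regression recovers identities to float precision
  expect_equal(tb$f[tb$q == 0], tb$D[tb$q == 0], tolerance = 1e-6)
  expect_equal(tb$alpha[tb$q == 1], tb$D[tb$q == 1], tolerance = 1e-6)
  expect_equal(tb$f[tb$q == 1], tb$D[tb$q == 1], tolerance = 1e-6)
  # monotonicity of D_q on exact cascade input
  expect_true(all(diff(tb$D) <= 1e-6))
})

test_that("alpha_min recovery on exact cascades; shuffling destroys scaling", {
  # unshuffled: the extreme accepted q recovers -log2(max(p, 1-p))
  for (p in c(0.6, 0.65, 0.7, 0.75, 0.8)) {
    w <- generate_binomial_cascade(p, 10)
    sp <- run_multifractal(w)
    expect_lt(abs(sp$descriptors$alpha_min - (-log2(max(p, 1 - p)))), 0.05)
  }
  # shuffled bins: same weight multiset, but the spatial nesting that the
  # dyadic regression measures is gone, so the estimate moves toward the
  # homogeneous value 1 (this is what shuffling is meant to demonstrate)
  target <- -log2(0.7)
  shuffled <- vapply(1:5, function(s) {
    w <- generate_binomial_cascade(0.7, 10, shuffle_seed = s)
    run_multifractal(w)$descriptors$alpha_min
  }, numeric(1))
  expect_true(all(abs(shuffled - target) > 0.05))
  expect_true(all(abs(shuffled - 1) < abs(target - 1)))
})

test_that("empty bins drop whole levels for negative q only", {
  counts <- c(rep(4, 8), 0, rep(4, 7))  # one empty slice at level 4
  pos <- estimate_Dq(counts, 2, k_range = 1:4)
  expect_equal(pos$n_levels, 4)
  neg <- estimate_Dq(counts, -2, k_range = 1:4)
  expect_equal(neg$n_levels, 3)         # level 4 has an empty bin: dropped
  expect_error(estimate_Dq(counts, -2, k_range = 2:4), "fewer than 3")
})

test_that("non-power-of-two curves are truncated centered, with warning", {
  counts <- c(1000, rep(10, 16), 1000)  # length 18 -> centered 16
  expect_warning(sp <- run_multifractal(counts, k_range = 1:4),
                 "not a power of 2")
  expect_equal(sp$L, 16)
  # the extreme first/last slices fell outside the centered window
  expect_equal(sp$table$D[sp$table$q == 0], 1, tolerance = 1e-10)
  expect_error(run_multifractal(rep(1, 4)), "at least 3")
})

test_that("spectrum descriptors summarize shape and asymmetry", {
  spc <- run_multifractal(generate_binomial_cascade(0.7, 10))
  d <- spc$descriptors
  expect_equal(d$A, 1, tolerance = 0.05)  # alpha0 is the exact midpoint
  expect_equal(d$D0, 1, tolerance = 1e-10)
  expect_gt(d$delta_alpha, 0.5)           # strongly multifractal input
  expect_gt(d$Dqmin_Dqmax, 0)
  sp5 <- run_multifractal(generate_binomial_cascade(0.5, 10))
  expect_equal(sp5$descriptors$D0_D2, 0, tolerance = 1e-10)
})
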