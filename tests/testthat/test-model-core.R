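test_that("interpolation weights hit the decentralized, dictatorial and intermediate cases", {
  expect_equal(interpolation_weights(4, 0)$w, rep(0.25, 4))
  expect_equal(interpolation_weights(4, 1)$w, c(1, 0, 0, 0))
  expect_equal(interpolation_weights(5, 0.5)$w, c(0.6, 0.1, 0.1, 0.1, 0.1))
})

test_that("interpolation weights satisfy their invariants on a grid", {
  for (n in c(2L, 3L, 7L, 50L)) {
    for (omega in seq(0, 1, by = 0.1)) {
      iw <- interpolation_weights(n, omega)
      expect_equal(sum(iw$w), 1, tolerance = 1e-12)
      expect_true(all(diff(iw$w) <= 0))
      expect_true(all(iw$w >= 0))
    }
  }
})

test_that("interpolation weights reject invalid sizes and omega", {
  expect_error(interpolation_weights(1, 0.5), "n")
  expect_error(interpolation_weights(4, -0.1), "omega")
  expect_error(interpolation_weights(4, 1.2), "omega")
})

test_that("Freeman centralization matches hand values and inverts the weight map", {
  expect_equal(freeman_centralization(rep(1/3, 3)), 0)
  expect_equal(freeman_centralization(c(1, 0, 0)), 1)
  expect_equal(freeman_centralization(c(0.5, 0.25, 0.25)), 0.25)
  for (n in c(2L, 5L, 50L)) {
    for (omega in seq(0, 1, by = 0.25)) {
      expect_equal(freeman_centralization(interpolation_weights(n, omega)$w),
                   omega, tolerance = 1e-12)
    }
  }
  expect_error(freeman_centralization(c(0.5, 0.2)), "sum")
})

test_that("collective estimate is the omega-weighted convex combination", {
  expect_equal(collective_estimate(c(4, 2, 6), 0), 4)
  expect_equal(collective_estimate(c(4, 2, 6), 1), 4)
  expect_equal(collective_estimate(c(1, 2, 6), 0.5), 2)
  expect_error(collective_estimate(numeric(0), 0.5))
  set.seed(5)
  for (i in 1:50) {
    a <- rlnorm(sample(1:20, 1), 1, 2)
    omega <- runif(1)
    est <- collective_estimate(a, omega)
    expect_gte(est, min(a))
    expect_lte(est, max(a))
  }
})

test_that("initial-estimate sampling is reproducible and respects each family", {
  ctx <- estimation_context("lognormal", 2, 1, 1)
  set.seed(99); a1 <- sample_initial_estimates(ctx, 20)
  set.seed(99); a2 <- sample_initial_estimates(ctx, 20)
  expect_identical(a1, a2)

  # median of theta * exp(mu + sigma Z) is theta * exp(mu)
  set.seed(7)
  x <- sample_initial_estimates(ctx, 1e5)
  expect_equal(median(x), 2 * exp(1), tolerance = 0.02)

  # degenerate dispersion collapses to the atom theta * exp(mu)
  set.seed(7)
  x0 <- sample_initial_estimates(estimation_context("lognormal", 2, 0, 1e-12), 10)
  expect_equal(x0, rep(2, 10), tolerance = 1e-10)

  # normal family: positive support enforced, resamples recorded
  set.seed(8)
  xn <- sample_initial_estimates(estimation_context("normal", 2, 0, 3), 5000)
  expect_true(all(xn > 0))
  expect_gt(attr(xn, "n_resampled"), 0)

  # pareto draws sit above the scale theta * exp(mu)
  set.seed(9)
  xp <- sample_initial_estimates(estimation_context("pareto", 2, 0.5, 1), 1000)
  expect_true(all(xp >= 2 * exp(0.5)))

  bad <- structure(list(family = "weibull", theta = 2, mu = 0, sigma = 1),
                   class = "estimation_context")
  expect_error(sample_initial_estimates(bad, 5), "unsupported family")
})

test_that("multiplicative families are scale-equivariant in theta", {
  for (fam in c("lognormal", "pareto", "loglaplace")) {
    set.seed(31); a1 <- sample_initial_estimates(estimation_context(fam, 2, 0.3, 1.2), 500)
    set.seed(31); a3 <- sample_initial_estimates(estimation_context(fam, 6, 0.3, 1.2), 500)
    expect_equal(a3, 3 * a1, tolerance = 1e-12)
    expect_equal(collective_estimate(a3, 0.4), 3 * collective_estimate(a1, 0.4),
                 tolerance = 1e-12)
  }
})

test_that("context constructor validates its parameters", {
  expect_error(estimation_context("lognormal", theta = -1), "theta")
  expect_error(estimation_context("lognormal", sigma = 0), "sigma")
  expect_error(estimation_context("cauchy"))
})
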