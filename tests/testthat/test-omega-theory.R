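test_that("omega = 0 is a self-comparison and returns probability zero with a warning", {
  ctx <- estimation_context("lognormal", 2, 0, 1)
  expect_warning(est <- estimate_omega(ctx, 10, 0, reps = 100), "omega = 0")
  expect_equal(est$p_hat, 0)
})

test_that("a point-mass context produces exact ties, which count against centralization", {
  # sigma -> 0 with mu = 0 puts all mass at theta = 2 (exactly representable),
  # so both aggregates coincide and the strict comparison never holds
  ctx <- estimation_context("lognormal", 2, 0, 1e-300)
  set.seed(1)
  est <- estimate_omega(ctx, 10, 0.5, reps = 500)
  expect_equal(est$p_hat, 0)
})

test_that("Monte-Carlo estimate matches an independent large-rep oracle", {
  # Oracle: 1e6-rep simulation of the same probability in numpy gave
  # 0.68269 (se 0.00047) for lognormal(theta 2, mu 1, sigma 1), n 50, omega 1/3
  ctx <- estimation_context("lognormal", 2, 1, 1)
  set.seed(42)
  est <- estimate_omega(ctx, 50, 1/3, reps = 2e4)
  expect_equal(est$se, sqrt(est$p_hat * (1 - est$p_hat) / est$reps))
  expect_lt(abs(est$p_hat - 0.68269), 4 * est$se)
  expect_gt(est$p_hat, 0.5)
})

test_that("estimate and bound are invariant to theta for multiplicative families", {
  for (fam in c("lognormal", "pareto")) {
    set.seed(13); e1 <- estimate_omega(estimation_context(fam, 2, 0.5, 1), 20, 1/3, 5000)
    set.seed(13); e2 <- estimate_omega(estimation_context(fam, 200, 0.5, 1), 20, 1/3, 5000)
    expect_identical(e1$p_hat, e2$p_hat)
    b1 <- omega_lower_bound(estimation_context(fam, 2, 0.5, 1), 20, 1/3)
    b2 <- omega_lower_bound(estimation_context(fam, 200, 0.5, 1), 20, 1/3)
    expect_equal(b1$value, b2$value, tolerance = 1e-9)
  }
})

test_that("estimates tighten with replicates", {
  ctx <- estimation_context("lognormal", 2, 0, 1.5)
  set.seed(21); e_small <- estimate_omega(ctx, 50, 1/3, reps = 4e3)
  set.seed(22); e_big <- estimate_omega(ctx, 50, 1/3, reps = 4e4)
  expect_lt(e_big$se, e_small$se)
  expect_lt(abs(e_big$p_hat - e_small$p_hat),
            3 * sqrt(e_small$se^2 + e_big$se^2))
})

test_that("lower bound maximizer matches a brute-force grid oracle", {
  # independent objective: plain pareto CDF and naive power on a dense grid
  theta <- 2; mu <- 0; sigma <- 2; n <- 50; omega <- 1/3
  scale <- theta * exp(mu)
  F <- function(x) ifelse(x >= scale, 1 - (x / scale)^(-1 / sigma), 0)
  edge <- theta / (1 - omega)
  beta <- edge + exp(seq(-20, 40, length.out = 1e6))
  g <- F(beta) * (1 - F(n * beta)^(n - 1))
  bnd <- omega_lower_bound(estimation_context("pareto", theta, mu, sigma), n, omega)
  expect_equal(bnd$value, max(g), tolerance = 1e-6)
  expect_gt(bnd$beta_star, edge)
  expect_true(bnd$converged)
  expect_gte(bnd$value, 0); expect_lte(bnd$value, 1)
})

test_that("bound degenerates to zero when all mass sits below the domain edge", {
  # atom at theta * exp(mu) = 2 < edge = 3, so F(n beta) = 1 on the domain
  bnd <- omega_lower_bound(estimation_context("lognormal", 2, 0, 1e-6), 50, 1/3)
  expect_equal(bnd$value, 0, tolerance = 1e-12)
  expect_error(omega_lower_bound(estimation_context("lognormal", 2, 0, 1), 50, 1),
               "omega")
})

test_that("large-n bound profile separates heavy from thin tails", {
  heavy <- bound_limit_profile(estimation_context("pareto", 2, 0, 2), 1/3)
  expect_false(heavy$verdict == "to_zero")
  expect_equal(length(heavy$bound_values), length(heavy$n_list))
  thin <- bound_limit_profile(estimation_context("normal", 2, 0, 0.5), 1/3)
  expect_identical(thin$verdict, "to_zero")
  expect_error(bound_limit_profile(estimation_context("pareto", 2, 0, 2), 1/3,
                                   n_list = c(100, 100)), "increasing")
})

test_that("heatmap cells reproduce direct estimates through derived substreams", {
  grid <- omega_heatmap("lognormal", mu_grid = 0.5, sigma_grid = 1, n = 20,
                        omega = 1/3, reps = 2000, seed = 5)
  set.seed(crowdcontext:::cell_seed(5, 1, 1))
  direct <- estimate_omega(estimation_context("lognormal", 2, 0.5, 1), 20, 1/3, 2000)
  expect_identical(grid$cells$p_hat, direct$p_hat)

  grid2 <- omega_heatmap("lognormal", mu_grid = 0.5, sigma_grid = 1, n = 20,
                         omega = 1/3, reps = 2000, seed = 5)
  expect_identical(grid$values, grid2$values)
  expect_error(omega_heatmap("lognormal", 0, c(0.5, -1), reps = 10, seed = 1),
               "sigma")
})

test_that("omega grids export one CSV row per cell with the bound attached", {
  grid <- omega_heatmap("lognormal", mu_grid = c(0, 1), sigma_grid = c(0.5, 1, 2),
                        n = 10, omega = 1/3, reps = 500, seed = 3)
  expect_identical(dim(grid$values), c(2L, 3L))
  path <- tempfile(fileext = ".csv")
  write_omega_grid(grid, path)
  csv <- read.csv(path)
  expect_identical(nrow(csv), 6L)
  expect_identical(names(csv), c("mu", "sigma", "p_hat", "se", "bound"))
  expect_true(all(csv$bound <= 1 & csv$bound >= 0))
})
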