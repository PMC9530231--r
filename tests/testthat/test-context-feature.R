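test_that("normal MLE matches closed forms", {
  f <- fit_normal_mle(c(1, 3))
  expect_equal(f$param1, 2)
  expect_equal(f$param2, 1)
  expect_equal(f$loglik, -(2 / 2) * (log(2 * pi) + 2 * log(1) + 1))
  set.seed(4)
  x <- rnorm(1e4, 100, 5)
  g <- fit_normal_mle(x)
  expect_equal(g$param1, 100, tolerance = 0.15 / 100)
  expect_equal(g$param2, 5, tolerance = 0.15 / 5)
  n <- length(x)
  expect_equal(g$loglik, -(n / 2) * (log(2 * pi) + 2 * log(g$param2) + 1))
  expect_error(fit_normal_mle(rep(2, 10)), "constant")
})

test_that("log-normal MLE is the normal MLE on logs plus the Jacobian", {
  f <- fit_lognormal_mle(c(exp(1), exp(3)))
  expect_equal(f$param1, 2)
  expect_equal(f$param2, 1)
  set.seed(11)
  x <- exp(rnorm(500))
  fl <- fit_lognormal_mle(x)
  fn <- fit_normal_mle(log(x))
  expect_equal(fl$loglik, fn$loglik - sum(log(x)), tolerance = 1e-12)
  expect_error(fit_lognormal_mle(c(1, 0, 2)), "positive")
  expect_error(fit_lognormal_mle(c(1, -1)), "positive")
})

test_that("R discriminates heavy-tailed from thin-tailed samples", {
  set.seed(2)
  heavy <- compute_R(rlnorm(1000))
  expect_gt(heavy$R, 0.99)
  thin <- compute_R(abs(rnorm(1000, 100, 20)))
  expect_lt(thin$R, 0.01)
  # the normalized-likelihood invariant, overflow-safe anchor at 0.5
  for (tf in list(heavy, thin)) {
    expect_equal(tf$R,
                 1 / (1 + exp(tf$loglik_normal - tf$loglik_lognormal)),
                 tolerance = 1e-12)
    expect_gte(tf$R, 0); expect_lte(tf$R, 1)
  }
})

test_that("R is permutation invariant and nearly scale invariant", {
  set.seed(6)
  x <- rlnorm(200, 1, 0.8)
  r0 <- compute_R(x)$R
  expect_identical(compute_R(sample(x))$R, r0)
  for (c_ in c(0.1, 10)) {
    expect_lt(abs(compute_R(c_ * x)$R - r0), 0.05)
  }
})

test_that("R ranks generating families correctly at every sample size", {
  for (n in c(10, 50, 200)) {
    r_ln <- r_n <- numeric(50)
    for (s in 1:50) {
      set.seed(1000 + s)
      r_ln[s] <- compute_R(rlnorm(n, 0, 1))$R
      r_n[s] <- compute_R(abs(rnorm(n, 100, 20)))$R
    }
    expect_gt(median(r_ln), median(r_n))
  }
})

test_that("per-task features pool initial estimates and apply the small-sample floor", {
  set.seed(3)
  trials <- make_trials(list(
    list(study = "s1", task = "t_heavy", group = "g1",
         initial = exp(rnorm(20, 1, 1.5)), revised = rep(1, 20), truth = 5),
    list(study = "s1", task = "t_heavy", group = "g2",
         initial = exp(rnorm(20, 1, 1.5)), revised = rep(1, 20), truth = 5),
    list(study = "s1", task = "t_tiny", group = "g3",
         initial = c(1, 2, 3), revised = c(1, 2, 3), truth = 2)))
  expect_message(ft <- task_features(trials), "undefined")
  expect_identical(nrow(ft), 2L)
  expect_true(is.na(ft$R[ft$task_id == "t_tiny"]))
  heavy_row <- ft[ft$task_id == "t_heavy", ]
  expect_identical(heavy_row$n_obs, 40L)  # pooled across both groups
  expect_false(is.na(heavy_row$R))
})
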