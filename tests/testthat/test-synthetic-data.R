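test_that("generation is deterministic under a fixed seed", {
  s1 <- generate_study(small_config(), seed = 41)
  s2 <- generate_study(small_config(), seed = 41)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$meta$tasks, s2$meta$tasks)
  s3 <- generate_study(small_config(), seed = 42)
  expect_false(identical(s1$trials$estimate, s3$trials$estimate))
})

test_that("task catalogs alternate thin and heavy regimes with positive truths", {
  set.seed(1)
  cat2 <- generate_task_catalog(synth_config(n_studies = 1L, tasks_per_study = 2L))
  expect_identical(sort(cat2$family), c("lognormal", "normal"))
  expect_true(all(cat2$theta > 0))
  set.seed(2)
  catalog <- generate_task_catalog(synth_config())
  expect_identical(nrow(catalog), 52L)
  expect_true(all(catalog$sigma > 0))
  # 13 tasks per study alternate thin/heavy starting thin: 7 + 6 per study
  expect_identical(as.vector(table(catalog$regime)), c(24L, 28L))
})

test_that("generated corpora pass the loader and positivity filter unchanged", {
  sim <- generate_study(small_config(), seed = 43)
  path <- tempfile(fileext = ".csv")
  write_trials(sim$trials, path)
  loaded <- load_trials(path)
  filtered <- filter_positive_tasks(loaded)  # no message expected: all positive
  expect_identical(nrow(filtered), nrow(sim$trials))
})

test_that("control groups keep their initial estimates exactly", {
  sim <- generate_study(small_config(), seed = 44)
  tr <- sim$trials
  ctl <- tr[tr$condition == "control", ]
  init <- ctl[ctl$stage == "initial", ]
  rev <- ctl[ctl$stage == "revised", ]
  key <- function(d) paste(d$task_id, d$group_id, d$subject_id)
  expect_identical(rev$estimate[order(key(rev))], init$estimate[order(key(init))])
  oc <- summarize_trials(tr)
  expect_true(all(oc$improved[oc$interactive == 0L] == 0L))
})

test_that("full influence with no noise reproduces the weighted-average operator", {
  cfg <- small_config(susceptibility = 1, noise_sd = 0)
  sim <- generate_study(cfg, seed = 45)
  oc <- summarize_trials(sim$trials)
  meta <- sim$meta$groups
  init <- sim$trials[sim$trials$stage == "initial", ]
  inter <- meta[meta$condition == "interactive", ]
  for (k in sample(nrow(inter), 20)) {
    row <- inter[k, ]
    a <- init$estimate[init$task_id == row$task_id &
                         init$group_id == row$group_id]
    central <- init$subject_id[init$task_id == row$task_id &
                                 init$group_id == row$group_id]
    a_star <- row$omega_g * a[central == row$central_subject] +
      (1 - row$omega_g) * mean(a)
    got <- oc$collective_revised[oc$task_id == row$task_id &
                                   oc$group_id == row$group_id]
    expect_equal(got, a_star, tolerance = 1e-12)
  }
})

test_that("catalog regimes map onto the intended R regimes", {
  sim <- generate_study(synth_config(), seed = 46)
  ft <- suppressMessages(task_features(sim$trials))
  ft <- merge(ft, sim$meta$tasks[, c("study_id", "task_id", "regime")])
  heavy_ok <- mean(ft$R[ft$regime == "heavy"] > 0.5)
  thin_ok <- mean(ft$R[ft$regime == "thin"] < 0.5)
  expect_gte(heavy_ok, 0.9)
  expect_gte(thin_ok, 0.9)
})

test_that("outcome records are invariant to relabeling subjects within groups", {
  sim <- generate_study(small_config(), seed = 47)
  tr <- sim$trials
  oc1 <- summarize_trials(tr)
  # reverse which subject holds which (initial, revised) pair within each trial
  key <- paste(tr$study_id, tr$task_id, tr$group_id, tr$stage)
  perm <- tr
  for (k in unique(key)) {
    idx <- which(key == k)
    perm$estimate[idx] <- perm$estimate[rev(idx)]
  }
  oc2 <- summarize_trials(perm)
  expect_equal(oc1$collective_initial, oc2$collective_initial)
  expect_equal(oc1$collective_revised, oc2$collective_revised)
  expect_identical(oc1$improved, oc2$improved)
})

test_that("configuration invariants are enforced", {
  expect_error(synth_config(control_fraction = 0), "control_fraction")
  expect_error(synth_config(group_size = c(0L, 5L)))
  expect_error(synth_config(groups_per_study = 2L, control_fraction = 0.9),
               "interactive")
  expect_error(synth_config(omega_range = c(0.5, 1.5)))
})
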