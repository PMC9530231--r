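#' Configuration for the synthetic multi-study estimation corpus
#'
#' Defines the statistical structure of a synthetic trial corpus emulating
#' multi-study group estimation experiments: several studies, each with its
#' own tasks and groups; tasks alternate between thin-tailed (normal) and
#' heavy-tailed (log-normal) estimation contexts so that the per-task
#' heavy-tailedness feature `R` spans its range; interactive groups revise
#' their estimates under weighted-average social influence with a group-level
#' centralization `omega_g`, while control groups keep their initial
#' estimates (the fully decentralized baseline, centralization exactly zero).
#'
#' Defaults mirror the scale of the reanalyzed experimental corpus: 4
#' studies, 52 tasks, 100 groups of 15-30 subjects (the corpus averages about
#' 29 participants per group), 1,300 trials, about 15% control groups.
#'
#' @param n_studies Number of studies.
#' @param tasks_per_study Tasks per study.
#' @param groups_per_study Groups per study; each group answers all of its
#'   study's tasks.
#' @param group_size Integer range `c(min, max)` of subjects per group.
#' @param control_fraction Fraction of groups without social interaction;
#'   must leave at least one group in each condition.
#' @param theta_range Range of task truths, sampled log-uniformly.
#' @param lognormal_mu,lognormal_sigma Ranges of bias and shape for
#'   heavy-tailed (log-normal) tasks. Defaults `mu` in `[0, 1]` (the
#'   overestimation regime typical of numerical estimation) and `sigma` in
#'   `[0.5, 2]`.
#' @param normal_cv,normal_bias For thin-tailed (normal) tasks: coefficient
#'   of variation range (`sigma = cv * theta`) and relative bias range
#'   (`mu = bias * theta`).
#' @param omega_range Range of the group-level centralization `omega_g`
#'   drawn for interactive groups. Setting both ends to 0 plants a null
#'   (no centralization) effect.
#' @param susceptibility Scalar `s` in `[0, 1]`: how far each subject moves
#'   from their initial estimate toward the influence-weighted group target.
#' @param noise_sd Relative revision noise: each revised estimate gets
#'   additive Normal(0, `noise_sd` * target) noise.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_studies = 4L, tasks_per_study = 13L,
                         groups_per_study = 25L, group_size = c(15L, 30L),
                         control_fraction = 0.15,
                         theta_range = c(10, 1000),
                         lognormal_mu = c(0, 1), lognormal_sigma = c(0.5, 2),
                         normal_cv = c(0.1, 0.3), normal_bias = c(-0.1, 0.1),
                         omega_range = c(0.2, 0.8), susceptibility = 0.8,
                         noise_sd = 0.05) {
  stopifnot(n_studies >= 1, tasks_per_study >= 1, groups_per_study >= 2,
            length(group_size) == 2L, group_size[1L] >= 1,
            group_size[2L] >= group_size[1L],
            control_fraction > 0, control_fraction < 1,
            theta_range[1L] > 0, theta_range[2L] >= theta_range[1L],
            lognormal_sigma[1L] > 0, normal_cv[1L] > 0,
            omega_range[1L] >= 0, omega_range[2L] <= 1,
            omega_range[2L] >= omega_range[1L],
            susceptibility >= 0, susceptibility <= 1, noise_sd >= 0)
  n_control <- max(1L, round(control_fraction * groups_per_study))
  if (n_control >= groups_per_study)
    stop("control_fraction leaves no interactive group")
  structure(list(n_studies = as.integer(n_studies),
                 tasks_per_study = as.integer(tasks_per_study),
                 groups_per_study = as.integer(groups_per_study),
                 group_size = as.integer(group_size),
                 control_fraction = control_fraction,
                 theta_range = theta_range,
                 lognormal_mu = lognormal_mu,
                 lognormal_sigma = lognormal_sigma,
                 normal_cv = normal_cv, normal_bias = normal_bias,
                 omega_range = omega_range,
                 susceptibility = susceptibility, noise_sd = noise_sd),
            class = "synth_config")
}

runif_range <- function(n, r) stats::runif(n, r[1L], r[2L])

#' Generate a catalog of estimation tasks with alternating tail regimes
#'
#' Creates the per-task estimation contexts for every study in the
#' configuration. Tasks alternate between a thin-tailed normal context
#' (small coefficient of variation, small relative bias; expected task-level
#' `R < 0.5`) and a heavy-tailed log-normal context (shape in the configured
#' range; expected `R > 0.5`), with a log-uniform positive truth. Uses the
#' session RNG.
#'
#' @param cfg A [synth_config()].
#' @return Data frame with one row per (study_id, task_id): `family`,
#'   `theta`, `mu`, `sigma`, and the intended `regime`
#'   (`"thin"`/`"heavy"`).
#' @export
generate_task_catalog <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  rows <- list()
  for (s in seq_len(cfg$n_studies)) {
    for (t in seq_len(cfg$tasks_per_study)) {
      theta <- exp(stats::runif(1, log(cfg$theta_range[1L]),
                                log(cfg$theta_range[2L])))
      heavy <- (t %% 2L) == 0L
      if (heavy) {
        mu <- runif_range(1, cfg$lognormal_mu)
        sigma <- runif_range(1, cfg$lognormal_sigma)
        family <- "lognormal"
      } else {
        mu <- runif_range(1, cfg$normal_bias) * theta
        sigma <- runif_range(1, cfg$normal_cv) * theta
        family <- "normal"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        study_id = sprintf("study_%02d", s),
        task_id = sprintf("task_%02d_%02d", s, t),
        family = family, theta = theta, mu = mu, sigma = sigma,
        regime = if (heavy) "heavy" else "thin")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic multi-study trial table with planted moderation
#'
#' Simulates the full corpus defined by `cfg`: for each study, a task catalog
#' (see [generate_task_catalog()]) and a set of groups (interactive or
#' control); every group answers every task of its study. Per interactive
#' trial:
#'
#' 1. each subject draws an i.i.d. initial estimate from the task's
#'    estimation context;
#' 2. one subject is chosen uniformly at random as the central individual;
#' 3. the influence target is the centralized collective estimate
#'    `a* = omega_g * a_central + (1 - omega_g) * mean(a)`;
#' 4. each subject's revised estimate is
#'    `(1 - s) * own_initial + s * a* + Normal(0, noise_sd * a*)`.
#'
#' With `s = 1` and zero noise the revised collective estimate equals `a*`
#' exactly, reproducing the weighted-average aggregation operator. Control
#' groups keep revised = initial, so their collective estimate is the
#' decentralized mean exactly. The planted moderation is thus structural:
#' interactive groups benefit on heavy-tailed tasks (where centralization
#' tends to beat the mean) and are hurt on thin-tailed ones.
#'
#' @param cfg A [synth_config()].
#' @param seed Integer seed; the same seed reproduces the corpus exactly.
#' @return List with `trials` (a validated `trial_table`) and `meta` (ground
#'   truth: the task catalog and per-group `condition`, `omega_g`, and
#'   central subject).
#' @export
generate_study <- function(cfg = synth_config(), seed = 1L) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(seed)
  catalog <- generate_task_catalog(cfg)
  t_study <- t_task <- t_group <- t_subject <- t_stage <- t_cond <- list()
  t_est <- t_truth <- list()
  g_study <- g_task <- g_group <- g_cond <- g_central <- character(0)
  g_omega <- numeric(0)
  k <- 0L
  for (s in seq_len(cfg$n_studies)) {
    study <- sprintf("study_%02d", s)
    n_groups <- cfg$groups_per_study
    n_control <- max(1L, round(cfg$control_fraction * n_groups))
    conditions <- sample(rep(c("control", "interactive"),
                             c(n_control, n_groups - n_control)))
    sizes <- sample(seq(cfg$group_size[1L], cfg$group_size[2L]),
                    n_groups, replace = TRUE)
    tasks <- catalog[catalog$study_id == study, , drop = FALSE]
    for (g in seq_len(n_groups)) {
      group <- sprintf("%s_grp_%03d", study, g)
      cond <- conditions[g]
      m <- sizes[g]
      omega_g <- if (cond == "interactive")
        runif_range(1, cfg$omega_range) else 0
      subjects <- sprintf("%s_subj_%02d", group, seq_len(m))
      for (t in seq_len(nrow(tasks))) {
        ctx <- estimation_context(tasks$family[t], theta = tasks$theta[t],
                                  mu = tasks$mu[t], sigma = tasks$sigma[t])
        a <- as.numeric(sample_initial_estimates(ctx, m))
        central <- sample.int(m, 1L)
        if (cond == "interactive") {
          target <- omega_g * a[central] + (1 - omega_g) * mean(a)
          revised <- (1 - cfg$susceptibility) * a +
            cfg$susceptibility * target +
            stats::rnorm(m, 0, cfg$noise_sd * target)
        } else {
          revised <- a
        }
        k <- k + 1L
        t_study[[k]] <- rep(study, 2L * m)
        t_task[[k]] <- rep(tasks$task_id[t], 2L * m)
        t_group[[k]] <- rep(group, 2L * m)
        t_subject[[k]] <- rep(subjects, 2L)
        t_stage[[k]] <- rep(c("initial", "revised"), each = m)
        t_est[[k]] <- c(a, revised)
        t_truth[[k]] <- rep(tasks$theta[t], 2L * m)
        t_cond[[k]] <- rep(cond, 2L * m)
        g_study[k] <- study; g_task[k] <- tasks$task_id[t]
        g_group[k] <- group; g_cond[k] <- cond
        g_omega[k] <- omega_g; g_central[k] <- subjects[central]
      }
    }
  }
  trials <- data.frame(study_id = unlist(t_study), task_id = unlist(t_task),
                       group_id = unlist(t_group),
                       subject_id = unlist(t_subject),
                       stage = unlist(t_stage), estimate = unlist(t_est),
                       truth = unlist(t_truth), condition = unlist(t_cond))
  groups <- data.frame(study_id = g_study, task_id = g_task,
                       group_id = g_group, condition = g_cond,
                       omega_g = g_omega, central_subject = g_central)
  list(trials = validate_trials(trials),
       meta = list(tasks = catalog, groups = groups, config = cfg,
                   seed = seed))
}
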