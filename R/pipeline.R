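TRIAL_COLUMNS <- c("study_id", "task_id", "group_id", "subject_id",
                   "stage", "estimate", "truth", "condition")

# Validates the canonical long-format trial schema: one initial and one
# revised record per (study, task, group, subject), truth constant within
# (study, task). Returns the table with class "trial_table" prepended.
validate_trials <- function(trials) {
  if (!is.data.frame(trials)) stop("'trials' must be a data frame")
  missing_cols <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(missing_cols) > 0)
    stop(sprintf("trial table is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  if (!is.numeric(trials$estimate))
    stop("column 'estimate' must be numeric")
  if (anyNA(trials$estimate)) {
    bad <- which(is.na(trials$estimate))
    stop(sprintf("non-numeric/missing estimate at row(s): %s",
                 paste(utils::head(bad, 5L), collapse = ", ")))
  }
  if (!is.numeric(trials$truth) || anyNA(trials$truth) || any(trials$truth <= 0))
    stop("column 'truth' must be positive numeric without NAs")
  if (!all(trials$stage %in% c("initial", "revised")))
    stop("column 'stage' must be 'initial' or 'revised'")
  if (!all(trials$condition %in% c("interactive", "control")))
    stop("column 'condition' must be 'interactive' or 'control'")
  subj_key <- paste(trials$study_id, trials$task_id, trials$group_id,
                    trials$subject_id, sep = "\r")
  key <- paste(subj_key, trials$stage, sep = "\r")
  dup <- duplicated(key)
  if (any(dup))
    stop(sprintf("duplicate stage records at row(s): %s",
                 paste(utils::head(which(dup), 5L), collapse = ", ")))
  n_stages <- table(subj_key)
  if (any(n_stages != 2L)) {
    bad_key <- names(n_stages)[n_stages != 2L][1L]
    stop(sprintf("subject-trial '%s' lacks a matching initial/revised pair",
                 gsub("\r", "/", bad_key)))
  }
  tk <- paste(trials$study_id, trials$task_id, sep = "\r")
  rng_by_task <- vapply(split(trials$truth, tk),
                        function(v) v[1L] != v[length(v)] || any(v != v[1L]),
                        logical(1))
  if (any(rng_by_task))
    stop("'truth' must be constant within each (study, task)")
  class(trials) <- unique(c("trial_table", class(trials)))
  trials
}

#' Load a trial table from CSV
#'
#' Reads a long-format table of individual initial and revised estimates, one
#' row per (study, task, group, subject, stage). The canonical columns are
#' `study_id, task_id, group_id, subject_id, stage, estimate, truth,
#' condition`; deposits using different headers are handled through `mapping`,
#' a named character vector from canonical names to the file's column names
#' (e.g. `c(estimate = "guess", truth = "correct_answer")`).
#'
#' Validation requires exactly one `initial` and one `revised` record per
#' subject-trial, a positive task-constant `truth`, and a `condition` of
#' `"interactive"` or `"control"`; violations are reported with row numbers.
#'
#' @param path CSV file path.
#' @param mapping Optional named character vector renaming file columns to
#'   the canonical schema.
#' @return A validated `trial_table` data frame.
#' @export
load_trials <- function(path, mapping = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(mapping)) {
    for (canon in names(mapping)) {
      src <- mapping[[canon]]
      if (!src %in% names(df))
        stop(sprintf("mapped column '%s' (for '%s') not in file", src, canon))
      names(df)[names(df) == src] <- canon
    }
  }
  validate_trials(df)
}

#' Write a trial table to CSV
#'
#' @param trials A `trial_table` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(as.data.frame(trials)[, TRIAL_COLUMNS], path,
                   row.names = FALSE)
  invisible(path)
}

#' Drop tasks containing any negative estimate
#'
#' The analysis applies to positive numerical estimation tasks; any task in
#' which any estimate (initial or revised, any group) is negative is removed
#' entirely, at the task level. Zero estimates are retained here but excluded
#' later from the positive pool used by [task_features()].
#'
#' @param trials A `trial_table`.
#' @return The filtered `trial_table`; the number of removed tasks is
#'   reported via [message()].
#' @export
filter_positive_tasks <- function(trials) {
  trials <- validate_trials(trials)
  tk <- paste(trials$study_id, trials$task_id, sep = "\r")
  has_neg <- tapply(trials$estimate, tk, function(v) any(v < 0))
  bad <- names(has_neg)[has_neg]
  if (length(bad) > 0) {
    message(sprintf("removed %d task(s) containing negative estimates", length(bad)))
    trials <- trials[!(tk %in% bad), , drop = FALSE]
  }
  if (nrow(trials) == 0) warning("no tasks remain after positivity filter")
  validate_trials(trials)
}

#' Collapse a trial table to group-level outcome records
#'
#' One trial is one group answering one task. The collective initial
#' (revised) estimate is the mean of the group's individual initial (revised)
#' estimates -- the pre-interaction mean corresponds to the fully
#' decentralized influence structure. The binary outcome `improved` is 1
#' exactly when the revised collective estimate is *strictly* closer to the
#' truth than the initial one (ties are not improvements), and `interactive`
#' records the social-interaction condition.
#'
#' @param trials A `trial_table`.
#' @return Data frame with one row per (study_id, task_id, group_id):
#'   `collective_initial`, `collective_revised`, `abs_err_initial`,
#'   `abs_err_revised`, `improved`, `interactive`, `truth`, `n_subjects`.
#' @export
summarize_trials <- function(trials) {
  trials <- validate_trials(trials)
  key <- paste(trials$study_id, trials$task_id, trials$group_id, sep = "\r")
  is_init <- trials$stage == "initial"
  ci <- tapply(trials$estimate[is_init], key[is_init], mean)
  cr <- tapply(trials$estimate[!is_init], key[!is_init], mean)
  n_subj <- tapply(trials$estimate[is_init], key[is_init], length)
  if (!setequal(names(ci), names(cr)))
    stop("incomplete trial: no revised records")
  init <- trials[is_init, , drop = FALSE]
  first <- init[!duplicated(key[is_init]), , drop = FALSE]
  fk <- paste(first$study_id, first$task_id, first$group_id, sep = "\r")
  out <- data.frame(study_id = first$study_id, task_id = first$task_id,
                    group_id = first$group_id, truth = first$truth,
                    n_subjects = as.integer(n_subj[fk]),
                    collective_initial = as.numeric(ci[fk]),
                    collective_revised = as.numeric(cr[fk]))
  out$abs_err_initial <- abs(out$collective_initial - out$truth)
  out$abs_err_revised <- abs(out$collective_revised - out$truth)
  out$improved <- as.integer(out$abs_err_revised < out$abs_err_initial)
  out$interactive <- as.integer(first$condition == "interactive")
  out <- out[order(out$study_id, out$task_id, out$group_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Attach per-task heavy-tailedness features to outcome records
#'
#' Merges the `R` column of [task_features()] onto the outcome table by
#' (study_id, task_id); every trial of a task carries that task's `R`.
#' Records of tasks whose `R` is undefined are excluded and their count
#' reported.
#'
#' @param outcomes Output of [summarize_trials()].
#' @param features Output of [task_features()].
#' @return `outcomes` with an `R` column, rows with undefined `R` removed.
#' @export
attach_task_features <- function(outcomes, features) {
  merged <- merge(outcomes, features[, c("study_id", "task_id", "R")],
                  by = c("study_id", "task_id"), all.x = TRUE, sort = FALSE)
  n_drop <- sum(is.na(merged$R))
  if (n_drop > 0) {
    message(sprintf("excluded %d outcome record(s) on tasks with undefined R", n_drop))
    merged <- merged[!is.na(merged$R), , drop = FALSE]
  }
  merged <- merged[order(merged$study_id, merged$task_id, merged$group_id), ,
                   drop = FALSE]
  rownames(merged) <- NULL
  merged
}

#' Standardize revised-estimate errors within task
#'
#' Adds `z_err`, the z-scored absolute error of the revised collective
#' estimate, standardized within each (study, task) across all trials of
#' that task (both conditions pooled), using the sample standard deviation
#' (divisor `n - 1`). Standardization makes errors comparable across tasks
#' whose correct answers differ by orders of magnitude. Tasks with a single
#' trial or zero error variance cannot be standardized; their records are
#' excluded and counted.
#'
#' @param outcomes Outcome records (any output of [summarize_trials()] or
#'   later stages).
#' @return `outcomes` with a `z_err` column; non-standardizable rows removed.
#' @export
standardize_errors <- function(outcomes) {
  tk <- interaction(outcomes$study_id, outcomes$task_id, drop = TRUE)
  mu <- tapply(outcomes$abs_err_revised, tk, mean)
  sd_ <- tapply(outcomes$abs_err_revised, tk, stats::sd)
  n_ <- tapply(outcomes$abs_err_revised, tk, length)
  keep_task <- names(mu)[n_ >= 2 & !is.na(sd_) & sd_ > 0]
  dropped <- sum(!(tk %in% keep_task))
  if (dropped > 0)
    message(sprintf("excluded %d record(s) on tasks with <2 trials or zero error variance",
                    dropped))
  out <- outcomes[tk %in% keep_task, , drop = FALSE]
  tk2 <- interaction(out$study_id, out$task_id, drop = TRUE)
  out$z_err <- as.numeric((out$abs_err_revised - mu[as.character(tk2)]) /
                            sd_[as.character(tk2)])
  rownames(out) <- NULL
  out
}

# Extracts a compact summary from a merMod fit.
summarize_mixed_fit <- function(fit, model_type) {
  sm <- summary(fit)
  ct <- as.data.frame(sm$coefficients)
  stat_col <- if (model_type == "logistic") "z value" else "t value"
  p_col <- grep("^Pr", names(ct), value = TRUE)
  coefs <- data.frame(term = rownames(ct),
                      estimate = ct[, "Estimate"],
                      se = ct[, "Std. Error"],
                      statistic = ct[, stat_col],
                      p_value = if (length(p_col) > 0) ct[, p_col[1L]]
                                else 2 * stats::pnorm(-abs(ct[, stat_col])),
                      row.names = NULL)
  vc <- as.data.frame(lme4::VarCorr(fit))
  ranef_var <- stats::setNames(vc$vcov, vc$grp)
  list(coefficients = coefs, ranef_var = ranef_var,
       n_obs = stats::nobs(fit))
}

#' Mixed-effects logistic model: does improvement depend on R?
#'
#' Fits, on trials with social interaction only, a mixed-effects logistic
#' regression of the improvement indicator on the heavy-tailedness feature
#' `R`, with random intercepts by group and by study:
#' `improved ~ R + (1 | group) + (1 | study)` (Laplace approximation via
#' [lme4::glmer()]). A positive coefficient on `R` means heavier-tailed
#' estimation contexts have a higher probability of improving after
#' (centralizing) social interaction.
#'
#' @param outcomes Outcome records carrying `R` (see
#'   [attach_task_features()]); control trials are dropped internally.
#' @return A `crowd_mm` object: coefficient table (estimate, SE, z, p),
#'   random-effect variances, `n_obs`, a `separation_flag`, and the
#'   underlying `merMod` fit.
#' @export
fit_improvement_model <- function(outcomes) {
  d <- outcomes[outcomes$interactive == 1L, , drop = FALSE]
  if (nrow(d) == 0) stop("no interactive trials to fit")
  if (length(unique(d$study_id)) < 2)
    stop("need trials from at least 2 studies")
  if (stats::var(d$improved) == 0)
    stop("outcome 'improved' is constant; nothing to fit")
  if (stats::sd(d$R) < 1e-12)
    stop("singular design: R is constant across tasks")
  d$group_id <- factor(d$group_id); d$study_id <- factor(d$study_id)
  fit <- suppressMessages(lme4::glmer(
    improved ~ R + (1 | group_id) + (1 | study_id),
    data = d, family = stats::binomial(),
    control = lme4::glmerControl(optimizer = "bobyqa",
                                 check.conv.singular = "ignore")))
  eta <- stats::qlogis(pmin(pmax(stats::fitted(fit), 1e-12), 1 - 1e-12))
  res <- summarize_mixed_fit(fit, "logistic")
  structure(list(model_type = "logistic",
                 formula = "improved ~ R + (1 | group) + (1 | study)",
                 coefficients = res$coefficients,
                 ranef_var = res$ranef_var, resid_var = NA_real_,
                 n_obs = res$n_obs,
                 separation_flag = any(abs(eta) > 15),
                 fit = fit),
            class = "crowd_mm")
}

#' Mixed-effects linear model: error moderation by R and interaction
#'
#' Fits, on all trials (both conditions), a linear mixed model of the
#' z-scored absolute error of the revised collective estimate on the
#' heavy-tailedness feature `R`, the social-interaction indicator `I`, and
#' their interaction, with random intercepts by group and by study:
#' `z_err ~ R * I + (1 | group) + (1 | study)` (REML via [lmerTest::lmer()],
#' Satterthwaite p-values). A negative interaction coefficient means that as
#' `R` grows, social interaction (centralized influence) increasingly
#' *reduces* the revised error relative to no interaction.
#'
#' @param outcomes Outcome records carrying `R` and `z_err` (see
#'   [standardize_errors()]).
#' @return A `crowd_mm` object: coefficient table (estimate, SE, t, p),
#'   random-effect and residual variances, `n_obs`, and the `merMod` fit.
#' @export
fit_error_model <- function(outcomes) {
  d <- outcomes
  if (!all(c("z_err", "R") %in% names(d)))
    stop("outcomes must carry 'z_err' and 'R'")
  if (length(unique(d$interactive)) < 2)
    stop("both interactive and control trials are required")
  if (stats::sd(d$R) < 1e-12)
    stop("singular design: R is constant across tasks")
  d$group_id <- factor(d$group_id); d$study_id <- factor(d$study_id)
  d$I <- d$interactive
  fit <- suppressMessages(lmerTest::lmer(
    z_err ~ R * I + (1 | group_id) + (1 | study_id),
    data = d, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore")))
  res <- summarize_mixed_fit(fit, "linear")
  structure(list(model_type = "linear",
                 formula = "z_err ~ R * I + (1 | group) + (1 | study)",
                 coefficients = res$coefficients,
                 ranef_var = res$ranef_var,
                 resid_var = stats::sigma(fit)^2,
                 n_obs = res$n_obs,
                 separation_flag = FALSE,
                 fit = fit),
            class = "crowd_mm")
}

#' @export
print.crowd_mm <- function(x, digits = 4, ...) {
  cat(sprintf("Mixed-effects %s model: %s  (n = %d)\n",
              x$model_type, x$formula, x$n_obs))
  ct <- x$coefficients
  ct[, -1] <- lapply(ct[, -1], signif, digits)
  print(ct, row.names = FALSE)
  cat("Random-effect variances:",
      paste(sprintf("%s = %.4g", names(x$ranef_var), x$ranef_var),
            collapse = ", "), "\n")
  if (isTRUE(x$separation_flag))
    cat("warning: fitted probabilities near 0/1 suggest quasi-separation\n")
  invisible(x)
}

#' @export
coef.crowd_mm <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' Marginal predictions of the error model over an R grid
#'
#' Fixed-effects predictions of the standardized revised error over a grid of
#' `R` values for each condition, with pointwise 95% confidence bands from
#' the fixed-effect covariance matrix.
#'
#' @param model A linear `crowd_mm` from [fit_error_model()].
#' @param r_grid Grid of R values in `[0, 1]`.
#' @return Data frame: `R`, `interactive`, `fit`, `se`, `lower`, `upper`.
#' @export
marginal_effects <- function(model, r_grid = seq(0, 1, by = 0.05)) {
  stopifnot(inherits(model, "crowd_mm"), model$model_type == "linear")
  beta <- coef(model)
  V <- as.matrix(stats::vcov(model$fit))
  grid <- expand.grid(R = r_grid, interactive = c(0L, 1L))
  X <- cbind(1, grid$R, grid$interactive, grid$R * grid$interactive)
  colnames(X) <- names(beta)
  est <- drop(X %*% beta)
  se <- sqrt(rowSums((X %*% V) * X))
  data.frame(R = grid$R, interactive = grid$interactive, fit = est, se = se,
             lower = est - 1.96 * se, upper = est + 1.96 * se)
}
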