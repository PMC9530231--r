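#' Maximum-likelihood normal fit
#'
#' Fits a normal distribution by maximum likelihood: mean is the sample mean,
#' standard deviation the MLE with divisor `n`. The total log-likelihood at
#' the MLE has the closed form `-(n/2) * (log(2*pi) + 2*log(sd_hat) + 1)`.
#'
#' @param x Numeric vector, length `>= 2`, non-constant.
#' @return A `dist_fit` object: `family`, `param1` (mean), `param2` (sd),
#'   `loglik`, `n_obs`.
#' @export
fit_normal_mle <- function(x) {
  if (!is.numeric(x) || length(x) < 2L || anyNA(x))
    stop("'x' must be a numeric vector of length >= 2 without NAs")
  n <- length(x)
  m <- mean(x)
  s <- sqrt(sum((x - m)^2) / n)
  if (s <= 0) stop("degenerate fit: 'x' is constant")
  ll <- -(n / 2) * (log(2 * pi) + 2 * log(s) + 1)
  structure(list(family = "normal", param1 = m, param2 = s, loglik = ll,
                 n_obs = n), class = "dist_fit")
}

#' Maximum-likelihood log-normal fit
#'
#' Fits a log-normal distribution by maximum likelihood: a normal MLE on
#' `log(x)`, with the change-of-variables Jacobian `-sum(log(x))` included in
#' the log-likelihood so it is comparable with [fit_normal_mle()] on the same
#' data.
#'
#' @param x Numeric vector of strictly positive values, length `>= 2`,
#'   non-constant.
#' @return A `dist_fit` object: `family`, `param1` (meanlog), `param2`
#'   (sdlog), `loglik`, `n_obs`.
#' @export
fit_lognormal_mle <- function(x) {
  if (!is.numeric(x) || length(x) < 2L || anyNA(x))
    stop("'x' must be a numeric vector of length >= 2 without NAs")
  if (any(x <= 0)) stop("log-normal fit requires strictly positive data")
  lx <- log(x)
  f <- fit_normal_mle(lx)
  structure(list(family = "lognormal", param1 = f$param1, param2 = f$param2,
                 loglik = f$loglik - sum(lx), n_obs = f$n_obs),
            class = "dist_fit")
}

#' @export
print.dist_fit <- function(x, ...) {
  cat(sprintf("%s MLE (n = %d): %s = %.6g, %s = %.6g, loglik = %.4f\n",
              x$family, x$n_obs,
              if (x$family == "lognormal") "meanlog" else "mean", x$param1,
              if (x$family == "lognormal") "sdlog" else "sd", x$param2,
              x$loglik))
  invisible(x)
}

#' Heavy-tailedness feature R of an estimation context
#'
#' The feature `R` measures whether a task's initial estimates are better
#' described by a heavy-tailed (log-normal) or thin-tailed (normal)
#' distribution: the normalized relative likelihood
#' `R = exp(L_LN) / (exp(L_LN) + exp(L_N))`, where `L_LN` and `L_N` are the
#' total log-likelihoods of the maximum-likelihood log-normal and normal fits.
#' Both families have two free parameters, so no complexity penalty is
#' applied. `R = 0` indicates a decisively normal (thin-tailed) sample,
#' `R = 1` a decisively log-normal (heavy-tailed) one, and `R = 0.5` that the
#' two describe the data equally well. Computed as
#' `plogis(L_LN - L_N)`, which is overflow-safe for large samples.
#'
#' @param x Numeric vector of strictly positive, non-constant estimates,
#'   length `>= 2`.
#' @return A `task_feature` object: `R` in `(0, 1)`, `loglik_lognormal`,
#'   `loglik_normal`, `n_obs`, and the two `dist_fit` objects.
#' @examples
#' set.seed(1)
#' compute_R(rlnorm(500))$R      # near 1
#' compute_R(rnorm(500, 100, 5))$R  # near 0
#' @export
compute_R <- function(x) {
  fit_ln <- fit_lognormal_mle(x)
  fit_n <- fit_normal_mle(x)
  R <- stats::plogis(fit_ln$loglik - fit_n$loglik)
  structure(list(R = R, loglik_lognormal = fit_ln$loglik,
                 loglik_normal = fit_n$loglik, n_obs = fit_n$n_obs,
                 fit_lognormal = fit_ln, fit_normal = fit_n),
            class = "task_feature")
}

#' @export
print.task_feature <- function(x, ...) {
  cat(sprintf("R = %.4f (n = %d; loglik lognormal %.2f vs normal %.2f)\n",
              x$R, x$n_obs, x$loglik_lognormal, x$loglik_normal))
  invisible(x)
}

#' Per-task heavy-tailedness features of a trial table
#'
#' Pools the initial estimates of all individuals across all groups answering
#' each task within each study and computes [compute_R()] per (study, task).
#' Tasks with fewer than `min_estimates` strictly positive initial estimates
#' get `R = NA` and are excluded by downstream model fits; zero estimates are
#' dropped from the pool (the log-normal fit requires positive support).
#'
#' @param trials A trial table (see [load_trials()]).
#' @param min_estimates Minimum number of positive initial estimates required
#'   to compute `R`. Default 5.
#' @return Data frame with one row per (study_id, task_id): `n_obs`, fitted
#'   parameters of both families, both total log-likelihoods, and `R`.
#' @export
task_features <- function(trials, min_estimates = 5L) {
  trials <- validate_trials(trials)
  init <- trials[trials$stage == "initial", , drop = FALSE]
  keys <- unique(init[, c("study_id", "task_id")])
  keys <- keys[order(keys$study_id, keys$task_id), , drop = FALSE]
  rows <- lapply(seq_len(nrow(keys)), function(k) {
    x <- init$estimate[init$study_id == keys$study_id[k] &
                         init$task_id == keys$task_id[k]]
    x <- x[x > 0]
    out <- data.frame(study_id = keys$study_id[k], task_id = keys$task_id[k],
                      n_obs = length(x), mean = NA_real_, sd = NA_real_,
                      meanlog = NA_real_, sdlog = NA_real_,
                      loglik_normal = NA_real_, loglik_lognormal = NA_real_,
                      R = NA_real_)
    if (length(x) >= min_estimates && stats::sd(x) > 0) {
      tf <- compute_R(x)
      out$mean <- tf$fit_normal$param1; out$sd <- tf$fit_normal$param2
      out$meanlog <- tf$fit_lognormal$param1; out$sdlog <- tf$fit_lognormal$param2
      out$loglik_normal <- tf$loglik_normal
      out$loglik_lognormal <- tf$loglik_lognormal
      out$R <- tf$R
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  n_na <- sum(is.na(res$R))
  if (n_na > 0)
    message(sprintf("R undefined for %d task(s) (fewer than %d positive estimates or constant); excluded downstream",
                    n_na, min_estimates))
  res
}
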