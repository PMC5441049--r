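#' Analytical confidence interval for the expected survival probability
#'
#' Normal-approximation interval on the cumulative-risk scale:
#' bounds are `exp(-H_i(t) +/- z * sqrt(var(H_i(t))))`, clamped to `[0, 1]`.
#' The variance of `H_i(t) = H0(t) exp(pi_i)` combines the baseline-hazard
#' variation and the coefficient covariance by the delta method:
#'
#' `var(H_i(t)) = exp(2 pi_i) * [ sum_{t_k <= t} d_k / S0(t_k)^2  +  Q' V Q ]`
#'
#' with `Q = sum_{t_k <= t} (d_k / S0(t_k)) (z_i - zbar(t_k))`, `S0` and
#' `zbar` the risk-set sums of the training data over the active columns, and
#' `V` the inverse Hessian of the partial log-likelihood evaluated at the
#' estimates. For a penalized fit the Hessian is computed over the active set
#' (unpenalized columns plus nonzero penalized coefficients); the L1 penalty
#' contributes no curvature there.
#'
#' @inheritParams scores
#' @param tau Horizon (years).
#' @param level Confidence level (default 0.95).
#' @return Tibble with `surv`, `se_cum_hazard`, `lower`, `upper`.
#' @export
analytic_ci <- function(fit, new_biomarkers, treatment, clinical = NULL,
                        tau = 5, level = 0.95) {
  if (is.null(fit$train)) stop("fit carries no training internals; refit with with_baseline = TRUE",
                               call. = FALSE)
  tr <- fit$train
  sc <- scores(fit, new_biomarkers, treatment, clinical)
  X <- standardize_new(fit, new_biomarkers)
  if (length(treatment) == 1) treatment <- rep(treatment, nrow(X))

  # new patients' values on the active columns, in training-column order
  z_new <- matrix(0, nrow(X), length(tr$active_names),
                  dimnames = list(NULL, tr$active_names))
  for (j in seq_along(tr$active_names)) {
    role <- tr$active_role[j]
    z_new[, j] <- switch(role,
      treatment = treatment,
      clinical = as.matrix(clinical)[, tr$active_names[j]],
      main = X[, tr$active_marker[j]],
      interaction = X[, tr$active_marker[j]] * treatment
    )
  }

  ord <- order(tr$time)
  tt <- tr$time[ord]; ev <- tr$event[ord]
  elp <- exp(tr$lp[ord])
  za <- tr$x_active[ord, , drop = FALSE]
  d_times <- unique(tt[ev == 1 & tt <= tau])
  base_var <- 0
  qmat <- matrix(0, nrow(X), ncol(za))       # per-patient Q vectors
  zbar_sum <- matrix(0, length(d_times), ncol(za))
  w_k <- numeric(length(d_times))
  for (k in seq_along(d_times)) {
    at_risk <- tt >= d_times[k]
    s0 <- sum(elp[at_risk])
    d <- sum(ev == 1 & tt == d_times[k])
    base_var <- base_var + d / s0^2
    w_k[k] <- d / s0
    if (ncol(za)) zbar_sum[k, ] <- colSums(za[at_risk, , drop = FALSE] * elp[at_risk]) / s0
  }
  H0 <- sum(w_k)
  if (ncol(za)) {
    info <- cox_information(tr$time, tr$event, tr$x_active, tr$lp)
    cond <- tryCatch(kappa(info, exact = FALSE), error = function(e) Inf)
    V <- tryCatch(solve(info), error = function(e)
      stop("singular Hessian over the active set (condition number ",
           format(cond, digits = 3), ")", call. = FALSE))
    q_common <- colSums(zbar_sum * w_k)      # sum_k w_k zbar_k
    # Q_i = H0 * z_i - sum_k w_k zbar_k
    qmat <- sweep(z_new * H0, 2, q_common, "-")
    coef_var <- rowSums((qmat %*% V) * qmat)
  } else {
    coef_var <- rep(0, nrow(X))
  }
  r <- exp(sc$lin_pred)
  Hi <- H0 * r
  var_Hi <- r^2 * (base_var + coef_var)
  z <- stats::qnorm(1 - (1 - level) / 2)
  lower <- exp(-(Hi + z * sqrt(var_Hi)))
  upper <- exp(-(Hi - z * sqrt(var_Hi)))
  tibble::tibble(surv = exp(-Hi), se_cum_hazard = sqrt(var_Hi),
                 lower = pmax(0, pmin(1, lower)),
                 upper = pmax(0, pmin(1, upper)))
}

#' Non-parametric bootstrap confidence intervals for survival probabilities
#'
#' Draws `B` with-replacement resamples of the training patients and re-runs
#' the entire development pipeline on each: standardization, adaptive-weight
#' computation, lambda-grid construction, single cross-validation, final fit
#' and Breslow baseline. The interval for each new patient is the empirical
#' percentile interval (linear-interpolation quantiles) of the B survival
#' probabilities. Resamples with no events are redrawn and counted.
#'
#' @param data Training `surv_dataset` (raw scale).
#' @param new_biomarkers,treatment,clinical New patients to predict (raw
#'   scale biomarkers).
#' @param tau Horizon (years).
#' @param B Number of bootstrap resamples (default 200).
#' @param level Confidence level.
#' @param seed Seed; the same seed yields identical intervals.
#' @param penalty,nfolds,nlambda,lambda_min_ratio,ridge_nlambda Pipeline
#'   options forwarded to [fit_coxint()].
#' @param max_fail_frac Abort if more than this fraction of resamples fails
#'   to fit.
#' @return Tibble with `lower` and `upper` per new patient; the B x n
#'   replicate matrix is attached as attribute `"replicates"`, and the number
#'   of redrawn / failed resamples as `"n_redrawn"` / `"n_failed"`.
#' @export
bootstrap_ci <- function(data, new_biomarkers, treatment, clinical = NULL,
                         tau = 5, B = 200, level = 0.95, seed = NULL,
                         penalty = "adaptive_lasso", nfolds = 5, nlambda = 100,
                         lambda_min_ratio = 0.01, ridge_nlambda = 25,
                         max_fail_frac = 0.1) {
  check_fittable(data)
  if (!is.null(seed)) set.seed(seed)
  n <- length(data$time)
  n_new <- nrow(as.matrix(new_biomarkers))
  reps <- matrix(NA_real_, B, n_new)
  n_redrawn <- 0L; n_failed <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (sum(data$event[idx]) > 0) break
      n_redrawn <- n_redrawn + 1L
    }
    boot <- subset_patients(data, idx)
    boot$standardization <- NULL
    fit <- tryCatch(
      fit_coxint(boot, penalty = penalty, nfolds = nfolds, nlambda = nlambda,
                 lambda_min_ratio = lambda_min_ratio,
                 ridge_nlambda = ridge_nlambda),
      error = function(e) NULL
    )
    if (is.null(fit)) { n_failed <- n_failed + 1L; next }
    reps[b, ] <- drop(predict_survival(fit, new_biomarkers, treatment,
                                       clinical, times = tau))
  }
  if (n_failed > max_fail_frac * B) {
    stop(n_failed, " of ", B, " bootstrap resamples failed to fit", call. = FALSE)
  }
  if (n_redrawn > 0) message(n_redrawn, " event-free resample(s) redrawn")
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  qs <- apply(reps, 2, stats::quantile, probs = probs, na.rm = TRUE, type = 7)
  out <- tibble::tibble(lower = unname(qs[1, ]), upper = unname(qs[2, ]))
  attr(out, "replicates") <- reps
  attr(out, "n_redrawn") <- n_redrawn
  attr(out, "n_failed") <- n_failed
  out
}
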