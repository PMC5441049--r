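#' Mean bias of estimated survival probabilities
#'
#' `(1/n) sum_i (Shat_i(tau) - S_i(tau))` against the theoretical survival
#' probabilities of the data-generating model.
#'
#' @param estimates,truths Aligned numeric vectors.
#' @return Scalar mean bias.
#' @export
mean_bias <- function(estimates, truths) {
  stopifnot(length(estimates) == length(truths))
  mean(estimates - truths)
}

#' Standard error of the survival-probability estimator
#'
#' `sqrt( (1/(n-1)) sum_i (Shat_i - E[Shat_i])^2 )`, where the patient-level
#' expectation `E[Shat_i]` is estimated as the patient's mean estimate across
#' replications sharing the same truth (`expectation = "patient"`, the
#' default, which requires a matrix of estimates with replications in
#' columns), or as the within-replication cohort mean
#' (`expectation = "cohort"`). With a matrix input the per-replication SEs
#' are averaged.
#'
#' @param estimates Numeric matrix (patients x replications) or vector.
#' @param expectation `"patient"` or `"cohort"`.
#' @return Scalar standard error.
#' @export
survival_se <- function(estimates, expectation = c("patient", "cohort")) {
  expectation <- match.arg(expectation)
  est <- as.matrix(estimates)
  n <- nrow(est)
  if (n < 2) stop("need at least 2 patients", call. = FALSE)
  if (expectation == "patient") {
    if (ncol(est) < 2) stop("patient-level expectation needs >= 2 replications", call. = FALSE)
    ebar <- rowMeans(est)
  } else {
    ebar <- matrix(colMeans(est), n, ncol(est), byrow = TRUE)
  }
  mean(sqrt(colSums((est - ebar)^2) / (n - 1)))
}

#' Empirical coverage probability of survival confidence intervals
#'
#' Fraction of patients whose interval contains the theoretical survival
#' probability.
#'
#' @param lower,upper,truths Aligned vectors.
#' @return Scalar in [0, 1].
#' @export
coverage <- function(lower, upper, truths) {
  stopifnot(length(lower) == length(truths), length(upper) == length(truths))
  if (any(upper < lower, na.rm = TRUE)) stop("malformed intervals (upper < lower)", call. = FALSE)
  mean(lower <= truths & truths <= upper)
}

rep_seeds <- function(seed, reps) {
  if (!is.null(seed)) set.seed(seed)
  sample.int(.Machine$integer.max - 1L, reps)
}

#' Predictive-accuracy experiment across simulation replications
#'
#' For each replication: generate a training/validation twin pair, fit the
#' requested strategy with single cross-validation on the training set, and
#' compute the requested evaluation modes -- metrics on the training set
#' itself (`"train_1cv"`), double-cross-validated metrics on the training set
#' (`"train_2cv"`), the selected model applied to the validation set
#' (`"validation"`), and the unpenalized oracle model on the truth variables
#' applied to the validation set (`"oracle"`).
#'
#' @param scenario Scenario id 1-6.
#' @param penalty Fitting strategy (see [fit_coxint()]); ignored when only
#'   `"oracle"` is requested.
#' @param reps Number of replications.
#' @param seed Master seed; every replicate is reproducible from it.
#' @param n,p Dataset dimensions.
#' @param modes Subset of `c("train_1cv", "train_2cv", "validation", "oracle",
#'   "truth")`. `"oracle"` is the unpenalized Cox model fitted to the truth
#'   variables on the training set; `"truth"` evaluates the validation data
#'   with the data-generating model's own scores and survival curves (the
#'   noise-free upper reference, which the fitted oracle approaches with a
#'   small estimation-noise attenuation, most visible in delta-C).
#' @param k1,k2 Inner / outer fold counts.
#' @param tau Horizon.
#' @param nlambda,lambda_min_ratio,ridge_nlambda Grid controls forwarded to
#'   [fit_coxint()].
#' @param max_fail_frac Abort when more than this fraction of replicates
#'   fails.
#' @return List of class `sim_experiment`: `replicates` (one metric row per
#'   rep x mode), `summary` (means by mode), `config`.
#' @export
run_experiment <- function(scenario, penalty = "adaptive_lasso", reps = 25,
                           seed = 1, n = 1500, p = 500,
                           modes = c("train_1cv", "validation", "oracle"),
                           k1 = 5, k2 = 5, tau = 5, nlambda = 100,
                           lambda_min_ratio = 0.01, ridge_nlambda = 25,
                           max_fail_frac = 0.1) {
  modes <- match.arg(modes, c("train_1cv", "train_2cv", "validation", "oracle",
                              "truth"),
                     several.ok = TRUE)
  spec <- scenario_spec(scenario, n = n, p = p)
  seeds <- rep_seeds(seed, reps)
  rows <- vector("list", reps)
  failures <- 0L
  for (r in seq_len(reps)) {
    res <- tryCatch(run_one_replicate(spec, penalty, seeds[r], modes, k1, k2,
                                      tau, nlambda, lambda_min_ratio,
                                      ridge_nlambda),
                    error = function(e) {
                      message("replicate ", r, " failed: ", conditionMessage(e))
                      NULL
                    })
    if (is.null(res)) failures <- failures + 1L else rows[[r]] <- dplyr::mutate(res, rep = r)
  }
  if (failures > max_fail_frac * reps) {
    stop(failures, " of ", reps, " replicates failed", call. = FALSE)
  }
  replicates <- dplyr::bind_rows(rows)
  summary <- dplyr::summarise(dplyr::group_by(replicates, .data$mode),
                              dplyr::across(c("ibrier", "uno_c", "delta_c"), mean),
                              n_reps = dplyr::n(), .groups = "drop")
  structure(list(replicates = replicates, summary = summary,
                 config = list(scenario = scenario, penalty = penalty,
                               reps = reps, seed = seed, n = n, p = p,
                               modes = modes, k1 = k1, k2 = k2, tau = tau,
                               failures = failures)),
            class = "sim_experiment")
}

run_one_replicate <- function(spec, penalty, seed, modes, k1, k2, tau,
                              nlambda, lambda_min_ratio, ridge_nlambda) {
  need_valid <- any(c("validation", "oracle", "truth") %in% modes)
  sim <- simulate_trial(spec, seed = seed, validation = need_valid)
  out <- list()
  if ("oracle" %in% modes) {
    ofit <- oracle_model(sim$train, sim$effects)
    out$oracle <- metric_report(sim$validation, ofit, tau, mode = "oracle")
  }
  if ("truth" %in% modes) {
    va <- sim$validation
    eta <- drop(va$biomarkers %*% sim$effects$gamma)
    lp <- sim$effects$alpha * va$treatment +
      drop(va$biomarkers %*% sim$effects$beta) + eta * va$treatment
    times <- ibrier_times(va$time, va$event, tau)
    sm <- exp(-outer(exp(lp), spec$lambda0 * times))
    out$truth <- metric_report(va, tau = tau, surv_matrix = sm,
                               lin_pred = lp, mod_score = eta, mode = "truth")
  }
  if (any(c("train_1cv", "validation") %in% modes)) {
    fit <- fit_coxint(sim$train, penalty = penalty, nfolds = k1,
                      nlambda = nlambda, lambda_min_ratio = lambda_min_ratio,
                      ridge_nlambda = ridge_nlambda)
    if ("train_1cv" %in% modes) {
      out$train_1cv <- metric_report(sim$train, fit, tau, mode = "train_1cv")
    }
    if ("validation" %in% modes) {
      out$validation <- metric_report(sim$validation, fit, tau, mode = "validation")
    }
  }
  if ("train_2cv" %in% modes) {
    dcv <- double_cv_scores(sim$train, penalty = penalty, k2 = k2, k1 = k1,
                            nlambda = nlambda,
                            lambda_min_ratio = lambda_min_ratio,
                            ridge_nlambda = ridge_nlambda)
    times <- ibrier_times(sim$train$time, sim$train$event, tau)
    sm <- double_cv_survival(dcv, sim$train, times)
    out$train_2cv <- metric_report(sim$train, tau = tau, surv_matrix = sm,
                                   lin_pred = dcv$scores$lin_pred,
                                   mod_score = dcv$scores$mod_score,
                                   mode = "train_2cv")
  }
  dplyr::bind_rows(out)
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat("<sim_experiment> scenario", x$config$scenario, "| penalty", x$config$penalty,
      "|", x$config$reps, "reps ( n =", x$config$n, ", p =", x$config$p, ")\n")
  print(x$summary)
  invisible(x)
}

#' Accuracy, precision and coverage of expected survival probabilities
#'
#' Holds one effect realization and one validation cohort fixed (the twin
#' design: replications share the truth), regenerates the training data each
#' replication, fits the strategy by single cross-validation, and estimates
#' the 5-year survival probability of every validation patient under their
#' observed arm, with analytical and (optionally) bootstrap confidence
#' intervals, pointwise and spline-smoothed. Summaries are the mean bias,
#' the standard error of the estimator (patient-level expectation across
#' replications), and the empirical coverage probability of the 95%
#' intervals against the theoretical survival probabilities.
#'
#' @inheritParams run_experiment
#' @param n_valid Size of the fixed validation cohort.
#' @param B Bootstrap resamples per replication (0 disables the bootstrap).
#' @param level Confidence level.
#' @param spline Also compute the spline-smoothed strategy.
#' @return List of class `accuracy_experiment`: `summary` tibble (mean_bias,
#'   se, coverage by strategy x interval method), `estimates` (patients x
#'   reps), `config`.
#' @export
run_accuracy_experiment <- function(scenario, penalty = "adaptive_lasso",
                                    reps = 10, seed = 1, n = 500, p = 100,
                                    n_valid = 100, B = 100, level = 0.95,
                                    tau = 5, k1 = 5, nlambda = 50,
                                    lambda_min_ratio = 0.01,
                                    ridge_nlambda = 15, spline = TRUE,
                                    max_fail_frac = 0.1) {
  spec <- scenario_spec(scenario, n = n, p = p)
  set.seed(seed)
  effects <- draw_effects(spec)
  X_val <- generate_biomarkers(n_valid, p, spec$block_size, spec$rho)
  T_val <- sample(c(-0.5, 0.5), n_valid, replace = TRUE)
  truth <- theoretical_survival(X_val, T_val, effects, spec, t = tau)
  seeds <- sample.int(.Machine$integer.max - 1L, reps)

  est <- matrix(NA_real_, n_valid, reps)
  est_spline <- matrix(NA_real_, n_valid, reps)
  cov_rows <- vector("list", reps)
  failures <- 0L
  for (r in seq_len(reps)) {
    res <- tryCatch({
      set.seed(seeds[r])
      train <- generate_survival(
        generate_biomarkers(n, p, spec$block_size, spec$rho),
        effects = effects, spec = spec)
      fit <- fit_coxint(train, penalty = penalty, nfolds = k1,
                        nlambda = nlambda,
                        lambda_min_ratio = lambda_min_ratio,
                        ridge_nlambda = ridge_nlambda)
      s_hat <- drop(predict_survival(fit, X_val, T_val, times = tau))
      iv_an <- analytic_ci(fit, X_val, T_val, tau = tau, level = level)
      iv_bt <- if (B > 0) {
        bootstrap_ci(train, X_val, T_val, tau = tau, B = B, level = level,
                     penalty = penalty, nfolds = k1, nlambda = nlambda,
                     lambda_min_ratio = lambda_min_ratio,
                     ridge_nlambda = ridge_nlambda)
      }
      eta <- scores(fit, X_val, T_val)$mod_score
      phi <- scores(fit, X_val, T_val)$prog_score
      sp <- if (spline) {
        smooth_by_group(eta, phi, T_val,
                        estimate = s_hat,
                        an_lower = iv_an$lower, an_upper = iv_an$upper,
                        bt_lower = if (!is.null(iv_bt)) iv_bt$lower,
                        bt_upper = if (!is.null(iv_bt)) iv_bt$upper)
      }
      list(s_hat = s_hat, iv_an = iv_an, iv_bt = iv_bt, sp = sp)
    }, error = function(e) {
      message("replicate ", r, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) { failures <- failures + 1L; next }
    est[, r] <- res$s_hat
    cv <- tibble::tibble(
      rep = r,
      mb_pointwise = mean_bias(res$s_hat, truth),
      cp_analytic_pointwise = coverage(res$iv_an$lower, res$iv_an$upper, truth),
      cp_bootstrap_pointwise = if (!is.null(res$iv_bt))
        coverage(res$iv_bt$lower, res$iv_bt$upper, truth) else NA_real_
    )
    if (!is.null(res$sp)) {
      est_spline[, r] <- res$sp$estimate
      cv$mb_spline <- mean_bias(res$sp$estimate, truth)
      cv$cp_analytic_spline <- coverage(res$sp$an_lower, res$sp$an_upper, truth)
      cv$cp_bootstrap_spline <- if (!is.null(res$iv_bt))
        coverage(res$sp$bt_lower, res$sp$bt_upper, truth) else NA_real_
    }
    cov_rows[[r]] <- cv
  }
  if (failures > max_fail_frac * reps) {
    stop(failures, " of ", reps, " replicates failed", call. = FALSE)
  }
  per_rep <- dplyr::bind_rows(cov_rows)
  ok <- colSums(!is.na(est)) > 0
  summary <- tibble::tibble(
    strategy = c("pointwise", if (spline) "spline"),
    mean_bias = c(mean(per_rep$mb_pointwise),
                  if (spline) mean(per_rep$mb_spline)),
    se = c(survival_se(est[, ok, drop = FALSE]),
           if (spline) survival_se(est_spline[, ok, drop = FALSE])),
    cp_analytic = c(mean(per_rep$cp_analytic_pointwise),
                    if (spline) mean(per_rep$cp_analytic_spline)),
    cp_bootstrap = c(mean(per_rep$cp_bootstrap_pointwise),
                     if (spline) mean(per_rep$cp_bootstrap_spline))
  )
  structure(list(summary = summary, per_rep = per_rep, estimates = est,
                 truth = truth,
                 config = list(scenario = scenario, penalty = penalty,
                               reps = reps, seed = seed, n = n, p = p,
                               n_valid = n_valid, B = B, tau = tau,
                               failures = failures)),
            class = "accuracy_experiment")
}

# Spline-smooth per-patient quantities against the modifying score within
# arm x prognostic-group panels. Degenerate panels (constant score, too few
# points) fall back to the panel mean, the natural limit of a smoother.
smooth_by_group <- function(eta, phi, treatment, ...) {
  ys <- list(...)
  ys <- ys[!vapply(ys, is.null, logical(1))]
  grp <- if (length(unique(phi)) >= 4) prognostic_groups(phi) else rep(1L, length(phi))
  out <- lapply(ys, function(y) rep(NA_real_, length(eta)))
  for (a in unique(treatment)) {
    for (g in unique(grp)) {
      sel <- which(treatment == a & grp == g)
      if (!length(sel)) next
      x <- eta[sel]
      for (nm in names(ys)) {
        y <- pmin(pmax(ys[[nm]][sel], 0), 1)
        out[[nm]][sel] <- if (length(unique(x)) < 5 || diff(range(x)) < 1e-10) {
          mean(y)
        } else {
          sp <- fit_constrained_spline(x, y)
          predict(sp, x)
        }
      }
    }
  }
  tibble::as_tibble(out)
}

#' @export
print.accuracy_experiment <- function(x, ...) {
  cat("<accuracy_experiment> scenario", x$config$scenario, "|", x$config$reps,
      "reps | n =", x$config$n, ", p =", x$config$p,
      ", B =", x$config$B, "\n")
  print(x$summary)
  invisible(x)
}

#' Empirical censoring rates of a scenario, overall and by arm
#'
#' @param scenario Scenario id.
#' @param reps Replications to average over.
#' @param n,p Dataset dimensions (`p` may be small: censoring depends on the
#'   active effects only).
#' @param seed Seed.
#' @return Tibble: overall, control (`T = -0.5`) and experimental
#'   (`T = +0.5`) censoring proportions.
#' @export
censoring_rates <- function(scenario, reps = 20, n = 1500, p = 500, seed = 1) {
  spec <- scenario_spec(scenario, n = n, p = p)
  seeds <- rep_seeds(seed, reps)
  rows <- purrr::map_dfr(seeds, function(s) {
    sim <- simulate_trial(spec, seed = s, validation = FALSE)
    d <- sim$train
    tibble::tibble(
      overall = mean(d$event == 0),
      control = mean(d$event[d$treatment < 0] == 0),
      experimental = mean(d$event[d$treatment > 0] == 0)
    )
  })
  dplyr::summarise(rows, dplyr::across(dplyr::everything(), mean))
}
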