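#' Breslow estimator of the cumulative baseline hazard
#'
#' `H0(t) = sum_{event times t_k <= t} d_k / sum_{j at risk at t_k} exp(pi_j)`,
#' a right-continuous step function equal to zero before the first event
#' time. Tied events share one risk-set denominator with their count in the
#' numerator, consistently with the Breslow partial likelihood.
#'
#' @param fit A `coxint_fit` (its coefficients define the linear predictor).
#' @param data The training `surv_dataset` (standardized as used for the fit).
#' @return Tibble with `time` (sorted distinct event times), `n_event`, and
#'   `cum_hazard`.
#' @export
breslow_baseline <- function(fit, data) {
  dm <- design_matrix(data)
  lp <- drop(dm$x %*% coef_vector(fit, dm))
  breslow_from_lp(data$time, data$event, lp)
}

breslow_from_lp <- function(time, event, lp) {
  ord <- order(time)
  tt <- time[ord]; ev <- event[ord]; elp <- exp(lp[ord])
  s0 <- rev(cumsum(rev(elp)))
  d_times <- unique(tt[ev == 1])
  d <- vapply(d_times, function(t0) sum(ev == 1 & tt == t0), numeric(1))
  s0_at <- s0[match(d_times, tt)]
  if (any(s0_at <= 0)) stop("empty risk set at an event time", call. = FALSE)
  tibble::tibble(time = d_times, n_event = d, cum_hazard = cumsum(d / s0_at))
}

# Evaluate a right-continuous cumulative-hazard step function; beyond the last
# observed step the last value is carried forward with a warning.
eval_cum_hazard <- function(baseline, t, warn_beyond = TRUE) {
  idx <- findInterval(t, baseline$time)
  out <- c(0, baseline$cum_hazard)[idx + 1]
  if (warn_beyond && any(t > max(baseline$time))) {
    warning("prediction time beyond the last event time; last step carried forward",
            call. = FALSE)
  }
  out
}

attach_baseline <- function(fit, data) {
  dm <- design_matrix(data)
  lp <- drop(dm$x %*% coef_vector(fit, dm))
  fit$baseline <- breslow_from_lp(data$time, data$event, lp)
  active <- !dm$penalized
  active[dm$role == "main"] <- fit$beta_hat != 0
  active[dm$role == "interaction"] <- fit$gamma_hat != 0
  fit$train <- list(time = data$time, event = data$event, lp = lp,
                    x_active = dm$x[, active, drop = FALSE],
                    active_names = colnames(dm$x)[active],
                    active_role = dm$role[active],
                    active_marker = dm$marker[active])
  fit
}

standardize_new <- function(fit, new_biomarkers) {
  if (is.null(fit$standardization)) return(as.matrix(new_biomarkers))
  apply_standardization(new_biomarkers, fit$standardization)
}

#' Prognostic, treatment-effect modifying, and full linear scores
#'
#' For patient i: prognostic score `phi_i = sum_j beta_j X_ij`, modifying
#' score `eta_i = sum_j gamma_j X_ij` (treatment-free), and linear predictor
#' `pi_i = alpha T_i + phi_i + eta_i T_i` plus any clinical terms. New
#' biomarkers are supplied on the raw scale and are placed on the training
#' scale internally using the stored standardization.
#'
#' @param fit A `coxint_fit`.
#' @param new_biomarkers Matrix/data frame of biomarker values (raw scale).
#' @param treatment Treatment codes (+/-0.5) per patient.
#' @param clinical Optional clinical covariate matrix.
#' @return Tibble with `prog_score`, `mod_score`, `lin_pred`.
#' @export
scores <- function(fit, new_biomarkers, treatment, clinical = NULL) {
  X <- standardize_new(fit, new_biomarkers)
  if (length(treatment) == 1) treatment <- rep(treatment, nrow(X))
  stopifnot(nrow(X) == length(treatment))
  phi <- drop(X %*% unname(fit$beta_hat))
  eta <- drop(X %*% unname(fit$gamma_hat))
  lp <- fit$alpha_hat * treatment + phi + eta * treatment
  if (!is.null(fit$clinical_hat)) {
    if (is.null(clinical)) stop("model includes clinical covariates; supply them",
                                call. = FALSE)
    lp <- lp + drop(as.matrix(clinical) %*% unname(fit$clinical_hat))
  }
  tibble::tibble(prog_score = phi, mod_score = eta, lin_pred = lp)
}

#' Expected survival probabilities for new patients
#'
#' `S_i(t) = exp(-H0(t) * exp(pi_i))` with `H0` the Breslow baseline of the
#' fitted model and `pi_i` the patient's linear predictor.
#'
#' @inheritParams scores
#' @param times Evaluation times (years); default the 5-year horizon.
#' @return Matrix of survival probabilities (patients x times); with a single
#'   time, still a 1-column matrix.
#' @export
predict_survival <- function(fit, new_biomarkers, treatment, clinical = NULL,
                             times = 5) {
  if (is.null(fit$baseline)) stop("fit carries no baseline hazard", call. = FALSE)
  sc <- scores(fit, new_biomarkers, treatment, clinical)
  H0 <- eval_cum_hazard(fit$baseline, times, warn_beyond = FALSE)
  if (any(times > max(fit$baseline$time))) {
    warning("prediction time beyond the last event time; last step carried forward",
            call. = FALSE)
  }
  outer(exp(sc$lin_pred), H0, function(r, h) exp(-h * r))
}

#' Tidy per-patient prediction table at a single horizon
#'
#' The broom-style interface to [predict_survival()], [scores()] and the
#' interval constructors: one row per patient with the expected survival
#' probability, the three scores, and (optionally) confidence bounds.
#'
#' @inheritParams scores
#' @param tau Horizon (years).
#' @param ci `"none"`, `"analytic"`, or `"bootstrap"`.
#' @param level Confidence level.
#' @param id Optional patient identifiers.
#' @param ... For `ci = "bootstrap"`: passed to [bootstrap_ci()] (`data`, `B`,
#'   `seed`, pipeline options are required there).
#' @return Tibble: id, tau, surv, prog_score, mod_score, lin_pred, ci_lower,
#'   ci_upper, ci_method.
#' @export
predict_expected_survival <- function(fit, new_biomarkers, treatment,
                                      clinical = NULL, tau = 5,
                                      ci = c("none", "analytic", "bootstrap"),
                                      level = 0.95, id = NULL, ...) {
  ci <- match.arg(ci)
  sc <- scores(fit, new_biomarkers, treatment, clinical)
  s <- drop(predict_survival(fit, new_biomarkers, treatment, clinical, times = tau))
  n <- length(s)
  out <- tibble::tibble(
    id = id %||% as.character(seq_len(n)), tau = tau, surv = s,
    prog_score = sc$prog_score, mod_score = sc$mod_score,
    lin_pred = sc$lin_pred,
    ci_lower = NA_real_, ci_upper = NA_real_, ci_method = ci
  )
  if (ci == "analytic") {
    iv <- analytic_ci(fit, new_biomarkers, treatment, clinical, tau, level)
    out$ci_lower <- iv$lower; out$ci_upper <- iv$upper
  } else if (ci == "bootstrap") {
    iv <- bootstrap_ci(new_biomarkers = new_biomarkers, treatment = treatment,
                       clinical = clinical, tau = tau, level = level, ...)
    out$ci_lower <- iv$lower; out$ci_upper <- iv$upper
  }
  out
}
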