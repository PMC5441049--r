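#' Kaplan-Meier estimate of the censoring distribution
#'
#' Fits the Kaplan-Meier estimator with the event indicator reversed, giving
#' `S_C(t) = P(C > t)`, the weight source of all IPCW metrics here.
#'
#' @param time Follow-up times.
#' @param event Event indicators (0/1).
#' @return A function `S_C(t)` (right-continuous step function) with the
#'   underlying step table attached as attribute `"steps"`.
#' @export
censoring_km <- function(time, event) {
  km <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  steps <- tibble::tibble(time = km$time, surv = km$surv)
  f <- function(t) {
    idx <- findInterval(t, steps$time)
    c(1, steps$surv)[idx + 1]
  }
  attr(f, "steps") <- steps
  f
}

# Marginal KM of the event-time distribution (weight function of the
# integrated Brier score).
event_km <- function(time, event) {
  km <- survival::survfit(survival::Surv(time, event) ~ 1)
  steps <- tibble::tibble(time = km$time, surv = km$surv)
  f <- function(t) {
    idx <- findInterval(t, steps$time)
    c(1, steps$surv)[idx + 1]
  }
  attr(f, "steps") <- steps
  f
}

#' Time-dependent Brier score under censoring (IPCW / Graf estimator)
#'
#' `(1/n) * sum_i [ S_i(t)^2 I(t_i <= t, d_i = 1) / S_C(t_i)
#'                 + (1 - S_i(t))^2 I(t_i > t) / S_C(t) ]`:
#' patients with an observed event before `t` contribute their squared
#' predicted survival (they did not survive), patients still at risk at `t`
#' contribute the squared complement, and both are inverse-weighted by the
#' censoring survival.
#'
#' @param time,event Observed follow-up and event indicator of the evaluation
#'   data.
#' @param pred Predicted survival probabilities `S_i(t)` at time `t`.
#' @param t Evaluation time.
#' @param cens Censoring survival function (default recomputed from the
#'   data via [censoring_km()]).
#' @return Scalar Brier score.
#' @export
brier_score <- function(time, event, pred, t, cens = censoring_km(time, event)) {
  stopifnot(length(pred) == length(time))
  if (any(pred < -1e-12 | pred > 1 + 1e-12)) stop("predictions outside [0,1]", call. = FALSE)
  n <- length(time)
  early_event <- time <= t & event == 1
  still_at_risk <- time > t
  g_ti <- cens(pmin(time, t))
  g_t <- cens(t)
  if (any(early_event & g_ti <= 0) || (any(still_at_risk) && g_t <= 0)) {
    stop("censoring survival is zero for a contributing patient", call. = FALSE)
  }
  sum(pred[early_event]^2 / g_ti[early_event]) / n +
    sum((1 - pred[still_at_risk])^2) / g_t / n
}

#' Integrated Brier score over [0, tau]
#'
#' Integrates the time-dependent Brier score with respect to the weight
#' `W(t) = (1 - S(t)) / (1 - S(tau))`, `S` the marginal Kaplan-Meier of the
#' event distribution on the evaluation data, so that `W(0) = 0` and
#' `W(tau) = 1`. `W` is a step function, so the integral is the exact
#' Stieltjes sum of `Brier(t_k) * dW(t_k)` over event times in `(0, tau]`.
#'
#' @param time,event Evaluation data.
#' @param surv_matrix Matrix of predicted survival probabilities, patients in
#'   rows, columns matching `eval_times`.
#' @param eval_times Times at which `surv_matrix` is evaluated; must cover
#'   the event times up to `tau` (the integral is taken over `eval_times`).
#'   Default: the distinct event times up to `tau`.
#' @param tau Horizon.
#' @param cens Optional censoring survival function.
#' @return Scalar integrated Brier score.
#' @export
integrated_brier <- function(time, event, surv_matrix, eval_times = NULL,
                             tau = 5, cens = censoring_km(time, event)) {
  if (is.null(eval_times)) eval_times <- ibrier_times(time, event, tau)
  surv_matrix <- as.matrix(surv_matrix)
  stopifnot(ncol(surv_matrix) == length(eval_times))
  skm <- event_km(time, event)
  s_tau <- skm(tau)
  if (s_tau >= 1) stop("no events before tau: weight function degenerate", call. = FALSE)
  w <- (1 - skm(eval_times)) / (1 - s_tau)
  dw <- diff(c(0, w))
  keep <- dw > 0
  if (!any(keep)) stop("no weight increments before tau", call. = FALSE)
  br <- vapply(which(keep), function(j)
    brier_score(time, event, surv_matrix[, j], eval_times[j], cens), numeric(1))
  sum(br * dw[keep])
}

#' @rdname integrated_brier
#' @export
ibrier_times <- function(time, event, tau = 5) {
  sort(unique(time[event == 1 & time <= tau]))
}

#' Uno's C-statistic (IPCW concordance) at a horizon
#'
#' `sum_{i,i'} S_C(t_i)^{-2} I(t_i < t_i', t_i < tau) I(score_i > score_i') d_i`
#' over `sum_{i,i'} S_C(t_i)^{-2} I(t_i < t_i', t_i < tau) d_i`.
#' Tied scores contribute 1/2 to the numerator, so a constant score yields
#' 0.5; tied times are excluded (strict `t_i < t_i'`). Higher scores are
#' taken to mean higher risk (shorter survival).
#'
#' @param time,event Evaluation data.
#' @param score Risk scores (e.g. the linear predictor).
#' @param tau Horizon.
#' @param cens Optional censoring survival function (recomputed from the
#'   supplied data by default; for arm-specific use, pass the arm's own).
#' @return C statistic in [0, 1].
#' @export
uno_c <- function(time, event, score, tau = 5,
                  cens = censoring_km(time, event)) {
  stopifnot(length(score) == length(time))
  usable_i <- which(event == 1 & time < tau)
  if (!length(usable_i)) stop("no usable pairs: no events before tau", call. = FALSE)
  g <- cens(time[usable_i])
  if (any(g <= 0)) stop("censoring survival zero at an event time", call. = FALSE)
  w <- g^-2
  num <- 0; den <- 0
  for (k in seq_along(usable_i)) {
    i <- usable_i[k]
    later <- time > time[i]
    n_pairs <- sum(later)
    if (!n_pairs) next
    conc <- sum(score[i] > score[later]) + 0.5 * sum(score[i] == score[later])
    num <- num + w[k] * conc
    den <- den + w[k] * n_pairs
  }
  if (den == 0) stop("no usable pairs for Uno's C", call. = FALSE)
  num / den
}

#' Arm-specific concordance difference of the modifying score
#'
#' `|UnoC(eta, tau; T = +0.5) - UnoC(eta, tau; T = -0.5)|`, each C computed
#' within one arm only (including that arm's own censoring distribution).
#' Measures the strength of the biomarker-by-treatment interaction: a
#' modifying score discriminates survival differently across arms exactly
#' when it modifies the treatment effect.
#'
#' @param time,event,treatment Evaluation data (treatment coded +/-0.5).
#' @param eta Treatment-effect modifying scores.
#' @param tau Horizon.
#' @return Nonnegative scalar.
#' @export
delta_c <- function(time, event, treatment, eta, tau = 5) {
  arms <- c(0.5, -0.5)
  cs <- vapply(arms, function(a) {
    sel <- treatment == a
    if (!any(sel)) stop("arm ", a, " is empty", call. = FALSE)
    uno_c(time[sel], event[sel], eta[sel], tau)
  }, numeric(1))
  abs(cs[1] - cs[2])
}

#' One-row predictive-accuracy report for a model on an evaluation dataset
#'
#' Computes the integrated Brier score (model-based survival predictions over
#' the event-time grid), Uno's C of the linear predictor, and the
#' arm-specific concordance difference of the modifying score.
#'
#' @param data Evaluation `surv_dataset` (raw scale).
#' @param fit A `coxint_fit`; ignored if `surv_matrix`, `lin_pred` and
#'   `mod_score` are all supplied (e.g. double-cross-validated scores).
#' @param tau Horizon.
#' @param surv_matrix Optional precomputed survival matrix over
#'   `ibrier_times(data$time, data$event, tau)`.
#' @param lin_pred,mod_score Optional precomputed scores.
#' @param mode Label stored in the output (`"train_1cv"`, `"train_2cv"`,
#'   `"validation"`, ...).
#' @return One-row tibble: mode, tau, ibrier, uno_c, delta_c.
#' @export
metric_report <- function(data, fit = NULL, tau = 5, surv_matrix = NULL,
                          lin_pred = NULL, mod_score = NULL, mode = "validation") {
  times <- ibrier_times(data$time, data$event, tau)
  if (is.null(lin_pred) || is.null(mod_score)) {
    sc <- scores(fit, data$biomarkers, data$treatment, data$clinical)
    lin_pred <- lin_pred %||% sc$lin_pred
    mod_score <- mod_score %||% sc$mod_score
  }
  if (is.null(surv_matrix)) {
    surv_matrix <- predict_survival(fit, data$biomarkers, data$treatment,
                                    data$clinical, times = times)
  }
  tibble::tibble(
    mode = mode, tau = tau,
    ibrier = integrated_brier(data$time, data$event, surv_matrix, times, tau),
    uno_c = uno_c(data$time, data$event, lin_pred, tau),
    delta_c = delta_c(data$time, data$event, data$treatment, mod_score, tau)
  )
}
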