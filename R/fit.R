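#' Penalty specification for the interaction Cox model
#'
#' The penalized partial log-likelihood is
#' `l(alpha, beta, gamma) - lambda * (sum_j theta_j |beta_j| + sum_j vartheta_j |gamma_j|)`,
#' so the treatment coefficient (and any clinical covariates) are unpenalized
#' by construction. The lasso corresponds to all weights equal to 1; the
#' adaptive lasso uses reciprocals of preliminary ridge estimates
#' (see [adaptive_weights()]). For the ridge penalty the absolute values are
#' replaced by squares with the same weights.
#'
#' @param penalty One of `"none"`, `"ridge"`, `"lasso"`, `"adaptive_lasso"`.
#' @param theta Nonnegative weights for the p biomarker main effects.
#' @param vartheta Nonnegative weights for the p interactions.
#' @param weight_cap Weights at or above this cap mark a coefficient as
#'   excluded from the model (the reciprocal of an exactly-zero ridge
#'   estimate).
#' @param sd_scale If `TRUE`, penalty weights are additionally scaled by the
#'   empirical standard deviation of each design column (squared for the
#'   ridge), which is equivalent to solving on solver-standardized columns.
#'   The biomarker main effects are unit-variance already, so in practice
#'   this halves the effective penalty per unit interaction coefficient
#'   (`sd(X_j T) = 0.5` under the +/-0.5 treatment coding).
#' @return A `penalty_spec` list.
#' @export
penalty_spec <- function(penalty = c("lasso", "adaptive_lasso", "ridge", "none"),
                         theta = NULL, vartheta = NULL, weight_cap = 1e6,
                         sd_scale = FALSE) {
  penalty <- match.arg(penalty)
  if (!is.null(theta) && any(theta < 0)) stop("negative theta weights", call. = FALSE)
  if (!is.null(vartheta) && any(vartheta < 0)) stop("negative vartheta weights", call. = FALSE)
  structure(list(penalty = penalty, theta = theta, vartheta = vartheta,
                 weight_cap = weight_cap, sd_scale = isTRUE(sd_scale)),
            class = "penalty_spec")
}

penalty_factors <- function(penalty, dm, quadratic = FALSE) {
  p <- sum(dm$role == "main")
  theta <- penalty$theta %||% rep(1, p)
  vartheta <- penalty$vartheta %||% rep(1, p)
  stopifnot(length(theta) == p, length(vartheta) == p)
  pf <- numeric(length(dm$role))
  pf[dm$role == "main"] <- theta
  pf[dm$role == "interaction"] <- vartheta
  if (isTRUE(penalty$sd_scale)) {
    s <- dm$col_sd
    pf <- pf * if (quadratic) s^2 else s
  }
  pf
}

# lambda on the penalized-partial-log-likelihood scale -> glmnet scale.
# glmnet rescales penalty factors to sum to nvars and divides the
# log-likelihood by n, hence the conversion below (verified against the
# weighted KKT entry point in the test suite).
lambda_to_glmnet <- function(lambda, pf, n) {
  lambda * sum(pf) / (n * length(pf))
}

#' Smallest lambda at which all penalized coefficients are zero
#'
#' Computed from the KKT conditions of the weighted L1 problem: with the
#' unpenalized columns fitted alone (treatment and clinical covariates), the
#' boundary is `max_j |U_j| / w_j` over penalized columns, `U` the partial
#' log-likelihood score at that point.
#'
#' @param data A standardized `surv_dataset`.
#' @param penalty A [penalty_spec()].
#' @return Scalar lambda on the partial-log-likelihood scale.
#' @export
lambda_max <- function(data, penalty = penalty_spec("lasso")) {
  dm <- design_matrix(data)
  pf <- penalty_factors(penalty, dm)
  unpen <- !dm$penalized
  fit0 <- survival::coxph(survival::Surv(data$time, data$event) ~ dm$x[, unpen, drop = FALSE])
  lp0 <- drop(dm$x[, unpen, drop = FALSE] %*% stats::coef(fit0))
  u <- cox_score(data$time, data$event, dm$x[, dm$penalized, drop = FALSE], lp0)
  w <- pf[dm$penalized]
  ok <- !capped_weights(penalty, dm)[dm$penalized] & w > 0
  if (!any(ok)) stop("all penalized coefficients excluded by the weight cap", call. = FALSE)
  max(abs(u[ok]) / w[ok])
}

# which design columns carry a weight at or beyond the exclusion cap
# (judged on the raw adaptive weights, before any sd scaling)
capped_weights <- function(penalty, dm) {
  p <- sum(dm$role == "main")
  theta <- penalty$theta %||% rep(1, p)
  vartheta <- penalty$vartheta %||% rep(1, p)
  out <- rep(FALSE, length(dm$role))
  out[dm$role == "main"] <- theta >= penalty$weight_cap
  out[dm$role == "interaction"] <- vartheta >= penalty$weight_cap
  out
}

#' Log-spaced lambda grid from the weighted KKT boundary
#'
#' @inheritParams lambda_max
#' @param nlambda Grid length (default 100).
#' @param lambda_min_ratio Smallest grid value as a fraction of `lambda_max`.
#' @return Strictly decreasing numeric vector.
#' @export
lambda_grid <- function(data, penalty = penalty_spec("lasso"), nlambda = 100,
                        lambda_min_ratio = 0.01) {
  lmax <- lambda_max(data, penalty) * 1.0001   # margin over the exact boundary
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = nlambda))
}

new_coxint_fit <- function(alpha_hat, beta_hat, gamma_hat, marker_names,
                           lambda, penalty, baseline = NULL,
                           standardization = NULL, clinical_hat = NULL,
                           clinical_names = NULL, cv = NULL, train = NULL,
                           method = penalty$penalty) {
  structure(list(alpha_hat = alpha_hat, clinical_hat = clinical_hat,
                 beta_hat = stats::setNames(beta_hat, marker_names),
                 gamma_hat = stats::setNames(gamma_hat, marker_names),
                 marker_names = marker_names, clinical_names = clinical_names,
                 lambda = lambda, penalty = penalty, baseline = baseline,
                 standardization = standardization, cv = cv, train = train,
                 method = method),
            class = "coxint_fit")
}

#' @export
print.coxint_fit <- function(x, ...) {
  cat("<coxint_fit> penalty:", x$method,
      " lambda:", format(x$lambda, digits = 4), "\n",
      " alpha_hat (treatment):", format(x$alpha_hat, digits = 4), "\n",
      " selected main effects:", sum(x$beta_hat != 0), "/", length(x$beta_hat),
      "  interactions:", sum(x$gamma_hat != 0), "/", length(x$gamma_hat), "\n")
  invisible(x)
}

#' Fit the penalized interaction Cox model at a fixed lambda
#'
#' Maximizes the weighted-L1 (or squared, for ridge) penalized partial
#' log-likelihood over `(alpha, clinical, beta, gamma)` with treatment and
#' clinical covariates unpenalized. Coefficient solutions come from cyclic
#' coordinate descent (glmnet) on the exact objective; ties use the Breslow
#' approximation throughout.
#'
#' @param data A standardized `surv_dataset` (see [standardize_biomarkers()]).
#' @param lambda Penalty strength on the partial-log-likelihood scale.
#' @param penalty A [penalty_spec()].
#' @param with_baseline Attach the Breslow baseline and training internals
#'   needed for prediction and analytic intervals.
#' @param thresh Coordinate-descent convergence threshold.
#' @return A `coxint_fit`.
#' @export
fit_penalized <- function(data, lambda, penalty = penalty_spec("lasso"),
                          with_baseline = TRUE, thresh = 1e-9) {
  check_fittable(data)
  dm <- design_matrix(data)
  pf <- penalty_factors(penalty, dm, quadratic = penalty$penalty == "ridge")
  n <- length(data$time)
  p <- sum(dm$role == "main")
  y <- survival::Surv(data$time, data$event)

  if (penalty$penalty == "none" || all(pf[dm$penalized] == 0)) {
    cf <- fit_unpenalized_columns(data, dm, active = rep(TRUE, ncol(dm$x)))
    coefs <- cf
  } else {
    excl <- which(capped_weights(penalty, dm))
    pf_use <- pf
    pf_use[excl] <- 1  # excluded explicitly below; keep conversion stable
    alpha_en <- if (penalty$penalty == "ridge") 0 else 1
    # ridge: objective uses lambda * sum(w_j * coef_j^2); glmnet's ridge term is
    # lambda/2 * sum(vf * coef^2), absorbed by the same conversion with factor 2
    lam_g <- lambda_to_glmnet(lambda, pf_use, n) * if (alpha_en == 0) 2 else 1
    # descending mini-path ending at the requested lambda improves warm starts
    lam_seq <- unique(c(lam_g * c(8, 4, 2), lam_g))
    fit <- glmnet::glmnet(dm$x, y, family = "cox", standardize = FALSE,
                          penalty.factor = pf_use, lambda = lam_seq,
                          exclude = if (length(excl)) excl else NULL,
                          alpha = alpha_en, thresh = thresh, maxit = 1e5)
    coefs <- as.numeric(glmnet::coef.glmnet(fit, s = lam_g, exact = FALSE))
    if (anyNA(coefs)) stop("penalized fit failed to converge", call. = FALSE)
  }

  main_idx <- which(dm$role == "main")
  int_idx <- which(dm$role == "interaction")
  cl_idx <- which(dm$role == "clinical")
  fit_obj <- new_coxint_fit(
    alpha_hat = coefs[1],
    clinical_hat = if (length(cl_idx)) stats::setNames(coefs[cl_idx], colnames(dm$x)[cl_idx]) else NULL,
    beta_hat = coefs[main_idx],
    gamma_hat = coefs[int_idx],
    marker_names = colnames(data$biomarkers),
    clinical_names = colnames(dm$x)[cl_idx],
    lambda = lambda, penalty = penalty,
    standardization = data$standardization
  )
  if (with_baseline) fit_obj <- attach_baseline(fit_obj, data)
  fit_obj
}

check_fittable <- function(data) {
  stopifnot(inherits(data, "surv_dataset"))
  if (length(data$time) < 2) stop("need at least 2 patients", call. = FALSE)
  if (sum(data$event) < 1) stop("need at least one event", call. = FALSE)
  invisible(data)
}

fit_null_model <- function(data, penalty) {
  dm <- design_matrix(data)
  coefs <- fit_unpenalized_columns(data, dm, active = !dm$penalized)
  out <- new_coxint_fit(
    alpha_hat = coefs[1],
    clinical_hat = if (any(dm$role == "clinical"))
      stats::setNames(coefs[dm$role == "clinical"], colnames(dm$x)[dm$role == "clinical"]) else NULL,
    beta_hat = coefs[dm$role == "main"],
    gamma_hat = coefs[dm$role == "interaction"],
    marker_names = colnames(data$biomarkers),
    clinical_names = colnames(dm$x)[dm$role == "clinical"],
    lambda = Inf, penalty = penalty,
    standardization = data$standardization,
    method = penalty$penalty
  )
  attach_baseline(out, data)
}

fit_unpenalized_columns <- function(data, dm, active) {
  coefs <- numeric(ncol(dm$x))
  xx <- dm$x[, active, drop = FALSE]
  fit <- survival::coxph(survival::Surv(data$time, data$event) ~ xx,
                         ties = "breslow")
  if (anyNA(stats::coef(fit))) stop("unpenalized Cox fit is singular", call. = FALSE)
  coefs[active] <- stats::coef(fit)
  coefs
}

#' Adaptive-lasso weights from a preliminary ridge fit
#'
#' Fits the interaction model under the ridge penalty (treatment and clinical
#' covariates unpenalized), tunes the ridge lambda by the same cross-validated
#' partial log-likelihood criterion used for the lasso, and returns weights
#' `theta_j = 1/|beta_j^ridge|`, `vartheta_j = 1/|gamma_j^ridge|`. Weights are
#' capped at `weight_cap`; a capped coefficient is reported as excluded.
#'
#' @param data A standardized `surv_dataset`.
#' @param nfolds Folds for the ridge cvl tuning (default 5).
#' @param nlambda Ridge grid length.
#' @param seed Seed for the fold assignment.
#' @param foldid Optional explicit fold assignment (overrides `seed`).
#' @param weight_cap Cap for reciprocal weights.
#' @param sd_scale Scale penalties by design-column standard deviations (see
#'   [penalty_spec()]); propagated to the returned spec.
#' @return A `penalty_spec` with `penalty = "adaptive_lasso"` and populated
#'   weights; the tuned ridge coefficients are attached as attributes.
#' @export
adaptive_weights <- function(data, nfolds = 5, nlambda = 25, seed = NULL,
                             foldid = NULL, weight_cap = 1e6,
                             sd_scale = FALSE) {
  check_fittable(data)
  dm <- design_matrix(data)
  pf <- penalty_factors(penalty_spec("ridge", sd_scale = sd_scale), dm,
                        quadratic = TRUE)
  n <- length(data$time)
  y <- survival::Surv(data$time, data$event)
  if (is.null(foldid)) foldid <- make_folds(data, k = nfolds, seed = seed)

  # bounded ridge grid anchored at the lasso KKT boundary: 100 x lambda_max
  # down to 0.01 x lambda_max (log-spaced); the cvl criterion picks within it
  lmax <- lambda_max(data, penalty_spec("lasso"))
  grid_spec <- exp(seq(log(100 * lmax), log(0.01 * lmax), length.out = nlambda))
  grid_g <- lambda_to_glmnet(grid_spec, pf, n) * 2
  # looser threshold than the final fit: only reciprocal magnitudes are
  # needed, and near-zero coefficients map to the cap either way
  # looser threshold and iteration cap than the final fit: only reciprocal
  # magnitudes are needed, near-zero coefficients map to the cap either way,
  # and a truncated path just shortens the grid the cvl criterion scans
  base <- suppressWarnings(
    glmnet::glmnet(dm$x, y, family = "cox", alpha = 0, standardize = FALSE,
                   penalty.factor = pf, lambda = grid_g, thresh = 1e-6,
                   maxit = 5e3))
  grid_g <- base$lambda   # the path may stop early on numerical trouble
  cvl_vals <- cvl_glmnet_grid(data, dm, pf, grid_g, foldid, alpha = 0,
                              thresh = 1e-6, maxit = 5e3)
  best <- pick_lambda(grid_g, cvl_vals)
  coefs <- as.numeric(glmnet::coef.glmnet(base, s = best))

  main_idx <- which(dm$role == "main")
  int_idx <- which(dm$role == "interaction")
  theta <- pmin(1 / abs(coefs[main_idx]), weight_cap)
  vartheta <- pmin(1 / abs(coefs[int_idx]), weight_cap)
  theta[!is.finite(theta)] <- weight_cap
  vartheta[!is.finite(vartheta)] <- weight_cap
  spec <- penalty_spec("adaptive_lasso", theta = theta, vartheta = vartheta,
                       weight_cap = weight_cap, sd_scale = sd_scale)
  attr(spec, "ridge_lambda_glmnet") <- best
  attr(spec, "ridge_coefs") <- coefs
  spec
}

#' Refit selected coefficients in an unpenalized Cox model
#'
#' Restricts the model to treatment, clinical covariates, and the biomarker
#' terms with nonzero penalized estimates, and re-estimates them by ordinary
#' partial-likelihood maximization; all other coefficients are exactly zero.
#'
#' @param fit A fitted `coxint_fit`.
#' @param data The training `surv_dataset` (standardized, as used for `fit`).
#' @return A `coxint_fit` with refitted coefficients and its own baseline.
#' @export
refit_unpenalized <- function(fit, data) {
  stopifnot(inherits(fit, "coxint_fit"))
  dm <- design_matrix(data)
  active <- !dm$penalized
  active[dm$role == "main"] <- fit$beta_hat != 0
  active[dm$role == "interaction"] <- fit$gamma_hat != 0
  if (sum(active) > length(data$time) / 2) {
    warning("selected set exceeds n/2; refit attempted anyway", call. = FALSE)
  }
  coefs <- fit_unpenalized_columns(data, dm, active)
  out <- new_coxint_fit(
    alpha_hat = coefs[1],
    clinical_hat = if (any(dm$role == "clinical"))
      stats::setNames(coefs[dm$role == "clinical"], colnames(dm$x)[dm$role == "clinical"]) else NULL,
    beta_hat = coefs[dm$role == "main"],
    gamma_hat = coefs[dm$role == "interaction"],
    marker_names = colnames(data$biomarkers),
    clinical_names = colnames(dm$x)[dm$role == "clinical"],
    lambda = fit$lambda, penalty = fit$penalty,
    standardization = data$standardization,
    method = paste0("refit_", fit$method)
  )
  attach_baseline(out, data)
}

#' Develop a prediction model end to end
#'
#' The high-level fitting entry point: standardizes the biomarkers (storing
#' the training scale), computes adaptive weights from a cvl-tuned ridge fit
#' when requested, builds the lambda grid from the weighted KKT boundary,
#' selects lambda by k1-fold cross-validated partial log-likelihood, fits the
#' final model and attaches the Breslow baseline.
#'
#' @param data A `surv_dataset`; standardized internally if not already.
#' @param penalty `"lasso"`, `"adaptive_lasso"`, or their `refit_` variants
#'   (`"refit_lasso"`, `"refit_adaptive_lasso"`).
#' @param nfolds k1, folds of the single cross-validation (default 5).
#' @param nlambda,lambda_min_ratio Lambda-grid controls.
#' @param ridge_nlambda Grid length for the adaptive ridge pre-step.
#' @param seed Seed controlling the (event-stratified) fold assignments.
#' @param sd_scale Scale penalties by design-column standard deviations,
#'   i.e. solve on solver-standardized columns (see [penalty_spec()]).
#' @return A `coxint_fit` with a `cv` report (lambda grid, cvl values,
#'   selected lambda).
#' @export
fit_coxint <- function(data,
                       penalty = c("adaptive_lasso", "lasso",
                                   "refit_adaptive_lasso", "refit_lasso"),
                       nfolds = 5, nlambda = 100, lambda_min_ratio = 0.01,
                       ridge_nlambda = 25, seed = NULL, sd_scale = FALSE) {
  penalty <- match.arg(penalty)
  refit <- startsWith(penalty, "refit_")
  base_pen <- sub("^refit_", "", penalty)
  if (is.null(data$standardization)) data <- standardize_biomarkers(data)
  foldid <- make_folds(data, k = nfolds, seed = seed)
  spec <- if (base_pen == "adaptive_lasso") {
    adaptive_weights(data, nfolds = nfolds, nlambda = ridge_nlambda,
                     foldid = foldid, sd_scale = sd_scale)
  } else {
    penalty_spec("lasso", sd_scale = sd_scale)
  }
  if (base_pen == "adaptive_lasso" &&
      all(spec$theta >= spec$weight_cap) && all(spec$vartheta >= spec$weight_cap)) {
    # every biomarker excluded by the ridge pre-step: the adaptive-lasso limit
    # is the unpenalized treatment(+clinical)-only model
    fit <- fit_null_model(data, spec)
  } else {
    grid <- lambda_grid(data, spec, nlambda = nlambda,
                        lambda_min_ratio = lambda_min_ratio)
    sel <- select_lambda(data, spec, grid, foldid = foldid)
    fit <- fit_penalized(data, sel$lambda, spec)
    fit$cv <- sel$report
  }
  if (refit) {
    penalized <- fit
    fit <- refit_unpenalized(fit, data)
    fit$cv <- penalized$cv
  }
  fit
}

#' Broom-style tidy method for fitted interaction Cox models
#'
#' @param x A `coxint_fit`.
#' @param nonzero_only Drop zero coefficients.
#' @param ... Unused.
#' @return Tibble with `term`, `role` (treatment / clinical / main /
#'   interaction), `marker` and `estimate`.
#' @export
tidy.coxint_fit <- function(x, nonzero_only = FALSE, ...) {
  out <- dplyr::bind_rows(
    tibble::tibble(term = "treatment", role = "treatment", marker = NA_character_,
                   estimate = x$alpha_hat),
    if (!is.null(x$clinical_hat))
      tibble::tibble(term = names(x$clinical_hat), role = "clinical",
                     marker = NA_character_, estimate = unname(x$clinical_hat)),
    tibble::tibble(term = x$marker_names, role = "main", marker = x$marker_names,
                   estimate = unname(x$beta_hat)),
    tibble::tibble(term = paste0(x$marker_names, ":trt"), role = "interaction",
                   marker = x$marker_names, estimate = unname(x$gamma_hat))
  )
  if (nonzero_only) out <- dplyr::filter(out, .data$estimate != 0 | .data$role %in% c("treatment", "clinical"))
  out
}

#' @rdname tidy.coxint_fit
#' @export
glance.coxint_fit <- function(x, ...) {
  tibble::tibble(
    penalty = x$method,
    lambda = x$lambda,
    n_main = sum(x$beta_hat != 0),
    n_interaction = sum(x$gamma_hat != 0),
    alpha_hat = x$alpha_hat,
    cvl_max = if (!is.null(x$cv)) max(x$cv$cvl) else NA_real_
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Export the coefficient path along a lambda grid as a tibble
#'
#' @param data Standardized `surv_dataset`.
#' @param penalty A [penalty_spec()].
#' @param grid Lambda grid (partial-log-likelihood scale); default from
#'   [lambda_grid()].
#' @return Tibble with one row per (lambda, term) with nonzero estimate plus
#'   per-lambda nonzero counts.
#' @export
coef_path <- function(data, penalty = penalty_spec("lasso"), grid = NULL) {
  if (is.null(data$standardization)) data <- standardize_biomarkers(data)
  if (is.null(grid)) grid <- lambda_grid(data, penalty)
  dm <- design_matrix(data)
  pf <- penalty_factors(penalty, dm)
  n <- length(data$time)
  lam_g <- lambda_to_glmnet(grid, pf, n)
  fit <- glmnet::glmnet(dm$x, survival::Surv(data$time, data$event),
                        family = "cox", standardize = FALSE,
                        penalty.factor = pf, lambda = lam_g)
  cb <- as.matrix(glmnet::coef.glmnet(fit))
  purrr::map_dfr(seq_along(grid), function(i) {
    nz <- which(cb[, i] != 0)
    tibble::tibble(lambda = grid[i], term = rownames(cb)[nz],
                   estimate = cb[nz, i], n_nonzero = sum(dm$penalized & cb[, i] != 0))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
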