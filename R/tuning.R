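#' Event-stratified cross-validation folds
#'
#' Random, seeded fold assignment stratified on event status so that every
#' fold receives a proportional share of events; this prevents event-free
#' training complements under the heavy censoring (60--80%) typical of the
#' trials this package targets.
#'
#' @param data A `surv_dataset`.
#' @param k Number of folds.
#' @param seed Optional seed (assignment drawn from the current RNG stream
#'   when `NULL`).
#' @return Integer vector of fold indices (length n).
#' @export
make_folds <- function(data, k = 5, seed = NULL) {
  n <- length(data$time)
  if (k < 2 || k > n) stop("k must be between 2 and n", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  foldid <- integer(n)
  for (grp in list(which(data$event == 1), which(data$event == 0))) {
    foldid[grp] <- sample(rep_len(seq_len(k), length(grp)))
  }
  foldid
}

subset_patients <- function(data, idx) {
  data$id <- data$id[idx]
  data$time <- data$time[idx]
  data$event <- data$event[idx]
  data$treatment <- data$treatment[idx]
  data$biomarkers <- data$biomarkers[idx, , drop = FALSE]
  if (!is.null(data$clinical)) data$clinical <- data$clinical[idx, , drop = FALSE]
  data
}

#' Cross-validated partial log-likelihood (cvl) at one lambda
#'
#' The Verweij--van Houwelingen criterion: for each fold k, fit the penalized
#' model without fold k, then add `l(coef_{-k}; all data) - l(coef_{-k}; data
#' without fold k)`. The penalty term cancels in the difference, so plain
#' partial log-likelihoods are used. An empty fold contributes zero.
#'
#' @param data Standardized `surv_dataset`.
#' @param penalty A [penalty_spec()].
#' @param lambda Penalty strength (partial-log-likelihood scale).
#' @param foldid Integer fold assignment (see [make_folds()]).
#' @return Scalar cvl value (larger is better).
#' @export
cvl <- function(data, penalty, lambda, foldid) {
  dm <- design_matrix(data)
  total <- 0
  for (k in sort(unique(foldid))) {
    in_fold <- foldid == k
    if (!any(in_fold)) next
    sub <- subset_patients(data, which(!in_fold))
    fit <- tryCatch(
      fit_penalized(sub, lambda, penalty, with_baseline = FALSE),
      error = function(e) stop("fold ", k, " fit failed: ", conditionMessage(e),
                               call. = FALSE)
    )
    coefs <- coef_vector(fit, dm)
    total <- total +
      cox_loglik(data$time, data$event, dm$x, coefs) -
      cox_loglik(sub$time, sub$event, dm$x[!in_fold, , drop = FALSE], coefs)
  }
  total
}

coef_vector <- function(fit, dm) {
  c(fit$alpha_hat,
    if (any(dm$role == "clinical")) unname(fit$clinical_hat),
    unname(fit$beta_hat), unname(fit$gamma_hat))
}

# cvl over a whole glmnet-scale lambda grid, one glmnet path per fold.
# A fold fit with n_k rows reproduces the same penalized-plik objective when
# its glmnet lambdas are scaled by n/n_k.
cvl_glmnet_grid <- function(data, dm, pf, grid_g, foldid, alpha = 1,
                            exclude = NULL, thresh = 1e-7, maxit = 1e5) {
  n <- length(data$time)
  out <- numeric(length(grid_g))
  for (k in sort(unique(foldid))) {
    keep <- foldid != k
    if (all(keep)) next
    n_k <- sum(keep)
    fit <- tryCatch(
      glmnet::glmnet(dm$x[keep, , drop = FALSE],
                     survival::Surv(data$time[keep], data$event[keep]),
                     family = "cox", standardize = FALSE, penalty.factor = pf,
                     lambda = grid_g * n / n_k, alpha = alpha,
                     exclude = exclude, maxit = maxit, thresh = thresh),
      error = function(e) stop("fold ", k, " fit failed: ", conditionMessage(e),
                               call. = FALSE)
    )
    cb <- as.matrix(glmnet::coef.glmnet(fit))
    m <- ncol(cb)   # the path may stop early on numerical trouble at tiny lambda
    if (m < 1) stop("fold ", k, " returned an empty path", call. = FALSE)
    lp_full <- dm$x %*% cb
    for (i in seq_along(grid_g)) {
      if (i > m) { out[i] <- NA_real_; next }
      out[i] <- out[i] +
        cox_loglik_lp(data$time, data$event, lp_full[, i]) -
        cox_loglik_lp(data$time[keep], data$event[keep], lp_full[keep, i])
    }
  }
  out
}

pick_lambda <- function(grid, cvl_values) {
  if (all(is.na(cvl_values))) stop("cvl is NaN over the whole grid", call. = FALSE)
  best <- max(cvl_values, na.rm = TRUE)
  # grids are decreasing; among maximizers prefer the largest lambda (sparser)
  idx <- which(cvl_values == best)[1]
  grid[idx]
}

#' Select lambda by maximizing the cross-validated partial log-likelihood
#'
#' @inheritParams cvl
#' @param grid Decreasing lambda grid; default from [lambda_grid()].
#' @param nfolds k1 (default 5), used when `foldid` is not given.
#' @param seed Seed for the fold assignment.
#' @param foldid Optional explicit fold assignment.
#' @return List with `lambda` (the maximizer; ties broken toward the larger,
#'   sparser value), `report` (tibble of lambda and cvl) and `foldid`.
#' @export
select_lambda <- function(data, penalty, grid = NULL, nfolds = 5, seed = NULL,
                          foldid = NULL) {
  if (is.null(data$standardization)) data <- standardize_biomarkers(data)
  if (is.null(foldid)) foldid <- make_folds(data, k = nfolds, seed = seed)
  if (is.null(grid)) grid <- lambda_grid(data, penalty)
  dm <- design_matrix(data)
  pf <- penalty_factors(penalty, dm)
  excl <- which(capped_weights(penalty, dm))
  pf_use <- pf
  pf_use[excl] <- 1
  grid_g <- lambda_to_glmnet(grid, pf_use, length(data$time))
  vals <- cvl_glmnet_grid(data, dm, pf_use, grid_g, foldid, alpha = 1,
                          exclude = if (length(excl)) excl else NULL)
  lam <- pick_lambda(grid, vals)
  list(lambda = lam,
       report = tibble::tibble(lambda = grid, cvl = vals, selected = grid == lam),
       foldid = foldid)
}

#' Double cross-validation: out-of-sample scores without external data
#'
#' Splits patients into k2 outer folds; for each fold, the entire development
#' pipeline -- biomarker standardization, adaptive-weight computation, lambda
#' grid, inner k1-fold cvl tuning, final fit -- is re-run on the outer
#' training set only, and the held-out patients are scored with that model.
#' Every patient thus receives exactly one prognostic score, modifying score
#' and linear predictor from a model that never saw them, mimicking an
#' external validation. The scores are intended only for computing predictive
#' accuracy metrics.
#'
#' @param data A `surv_dataset` (raw scale; standardization happens inside
#'   each outer training set).
#' @param penalty Penalty name as in [fit_coxint()].
#' @param k2 Outer folds (default 5).
#' @param k1 Inner folds for lambda tuning (default 5).
#' @param seed Seed controlling all fold assignments.
#' @param ... Passed to [fit_coxint()] (grid sizes etc.).
#' @return A `double_cv` object: `scores` tibble (id, fold, prog_score,
#'   mod_score, lin_pred, time, event, treatment), `models` (per-fold
#'   `coxint_fit`s) and `foldid`.
#' @export
double_cv_scores <- function(data, penalty = "adaptive_lasso", k2 = 5, k1 = 5,
                             seed = NULL, ...) {
  check_fittable(data)
  if (!is.null(seed)) set.seed(seed)
  foldid <- make_folds(data, k = k2)
  models <- vector("list", k2)
  rows <- vector("list", k2)
  for (k in seq_len(k2)) {
    hold <- foldid == k
    train <- subset_patients(data, which(!hold))
    train$standardization <- NULL            # re-standardize inside the loop
    if (sum(train$event) == 0) stop("outer fold ", k, " training set has no events",
                                    call. = FALSE)
    fit <- fit_coxint(train, penalty = penalty, nfolds = k1, ...)
    models[[k]] <- fit
    sc <- scores(fit, new_biomarkers = data$biomarkers[hold, , drop = FALSE],
                 treatment = data$treatment[hold],
                 clinical = if (!is.null(data$clinical)) data$clinical[hold, , drop = FALSE])
    rows[[k]] <- dplyr::mutate(sc, id = data$id[hold], fold = k,
                               time = data$time[hold], event = data$event[hold],
                               treatment = data$treatment[hold])
  }
  scores_tbl <- dplyr::bind_rows(rows)
  scores_tbl <- scores_tbl[order(match(scores_tbl$id, data$id)), ]
  out <- list(scores = scores_tbl, models = models, foldid = foldid,
              penalty = penalty)
  class(out) <- "double_cv"
  out
}

#' Survival predictions from the per-fold models of a double cross-validation
#'
#' Each patient's predicted survival curve comes from the outer-fold model
#' that excluded them.
#'
#' @param dcv A `double_cv` object.
#' @param data The dataset passed to [double_cv_scores()].
#' @param times Evaluation times.
#' @return Matrix (n x length(times)) of predicted survival probabilities.
#' @export
double_cv_survival <- function(dcv, data, times) {
  n <- length(data$time)
  out <- matrix(NA_real_, n, length(times))
  for (k in seq_along(dcv$models)) {
    hold <- which(dcv$foldid == k)
    pr <- predict_survival(dcv$models[[k]],
                           new_biomarkers = data$biomarkers[hold, , drop = FALSE],
                           treatment = data$treatment[hold],
                           clinical = if (!is.null(data$clinical)) data$clinical[hold, , drop = FALSE],
                           times = times)
    out[hold, ] <- pr
  }
  out
}
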