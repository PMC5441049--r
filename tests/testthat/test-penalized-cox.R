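test_that("partial log-likelihood matches closed forms and brute force", {
  # 2 patients, times (1, 2), both events, all coefficients zero
  d <- make_fixture(time = c(1, 2), event = c(1, 1))
  expect_equal(cox_loglik_lp(d$time, d$event), log(1 / 2) + log(1 / 1))

  # shift invariance of the partial likelihood
  d6 <- make_toy_data(n = 20, p = 2)
  lp <- rnorm(20)
  expect_equal(cox_loglik_lp(d6$time, d6$event, lp),
               cox_loglik_lp(d6$time, d6$event, lp + 7.3))

  # tied event times: matches an independent Breslow-tie summation
  dt <- make_fixture(time = c(1, 2, 2, 3, 4, 5), event = c(1, 1, 1, 0, 1, 0))
  lp <- c(0.3, -0.2, 0.5, 0.1, -0.4, 0.2)
  expect_equal(cox_loglik_lp(dt$time, dt$event, lp),
               brute_loglik(dt$time, dt$event, lp))

  expect_error(cox_loglik_lp(c(1, 2), c(0, 0)), "no events")
})

test_that("score and information agree with numerical derivatives", {
  d <- make_toy_data(n = 40, p = 3)
  dm <- design_matrix(standardize_biomarkers(d))
  b <- c(0.2, -0.1, 0.3, 0, 0.15, -0.2, 0.1)
  f <- function(bb) cox_loglik(d$time, d$event, dm$x, bb)
  g_num <- vapply(seq_along(b), function(j) {
    h <- 1e-6; e <- replace(numeric(7), j, h)
    (f(b + e) - f(b - e)) / (2 * h)
  }, numeric(1))
  lp <- drop(dm$x %*% b)
  expect_equal(cox_score(d$time, d$event, dm$x, lp), g_num, tolerance = 1e-5,
               ignore_attr = TRUE)
  h_num <- matrix(0, 7, 7)
  for (j in 1:7) {
    h <- 1e-5; e <- replace(numeric(7), j, h)
    h_num[, j] <- (cox_score(d$time, d$event, dm$x, drop(dm$x %*% (b + e))) -
                   cox_score(d$time, d$event, dm$x, drop(dm$x %*% (b - e)))) / (2 * h)
  }
  expect_equal(cox_information(d$time, d$event, dm$x, lp), -h_num,
               tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("lambda at or above the KKT boundary yields the treatment-only model", {
  d <- standardize_biomarkers(make_toy_data(n = 80, p = 4))
  lmax <- lambda_max(d)
  fit <- fit_penalized(d, lmax * 1.001, penalty_spec("lasso"))
  expect_true(all(fit$beta_hat == 0))
  expect_true(all(fit$gamma_hat == 0))
  trt_only <- survival::coxph(survival::Surv(d$time, d$event) ~ d$treatment,
                              ties = "breslow")
  expect_equal(fit$alpha_hat, unname(coef(trt_only)), tolerance = 1e-4)
  # just below the boundary at least one penalized coefficient activates
  fit2 <- fit_penalized(d, lmax * 0.9, penalty_spec("lasso"))
  expect_gt(sum(fit2$beta_hat != 0) + sum(fit2$gamma_hat != 0), 0)
})

test_that("the returned optimum maximizes the penalized objective", {
  d <- standardize_biomarkers(make_toy_data(n = 70, p = 3))
  dm <- design_matrix(d)
  lam <- lambda_max(d) * 0.3
  fit <- fit_penalized(d, lam, penalty_spec("lasso"), thresh = 1e-12)
  b_hat <- c(fit$alpha_hat, unname(fit$beta_hat), unname(fit$gamma_hat))
  obj <- function(b) cox_loglik(d$time, d$event, dm$x, b) - lam * sum(abs(b[-1]))
  # objective at the optimum beats the zero-penalized-coefficient point ...
  b0 <- replace(rep(0, 7), 1, fit$alpha_hat)
  expect_gte(obj(b_hat), obj(b0))
  # ... and an independent BFGS polish cannot improve it
  pol <- optim(b_hat, function(b) -obj(b), method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  expect_lte(-pol$value - obj(b_hat), 1e-6)
})

test_that("adaptive lasso with unit weights reproduces the plain lasso", {
  d <- standardize_biomarkers(make_toy_data(n = 60, p = 3))
  lam <- lambda_max(d) * 0.4
  f_lasso <- fit_penalized(d, lam, penalty_spec("lasso"), thresh = 1e-11)
  f_unit <- fit_penalized(d, lam,
                          penalty_spec("adaptive_lasso", theta = rep(1, 3),
                                       vartheta = rep(1, 3)), thresh = 1e-11)
  expect_equal(f_unit$beta_hat, f_lasso$beta_hat, tolerance = 1e-6)
  expect_equal(f_unit$gamma_hat, f_lasso$gamma_hat, tolerance = 1e-6)
  expect_equal(f_unit$alpha_hat, f_lasso$alpha_hat, tolerance = 1e-6)
})

test_that("adaptive weights are reciprocal ridge magnitudes with a cap", {
  d <- standardize_biomarkers(make_toy_data(n = 80, p = 4))
  w <- adaptive_weights(d, seed = 7)
  rc <- attr(w, "ridge_coefs")
  dm <- design_matrix(d)
  theta_exp <- pmin(1 / abs(rc[dm$role == "main"]), w$weight_cap)
  expect_equal(w$theta, theta_exp)
  expect_true(all(w$theta > 0), all(w$vartheta > 0))
  # reciprocal rule on a known value and the cap rule at zero
  expect_equal(penalty_spec("adaptive_lasso", theta = 1 / abs(0.5),
                            vartheta = 1)$theta, 2)
  expect_equal(pmin(1 / abs(0), 1e6), 1e6)
})

test_that("solution path shrinks monotonically in sparsity at the endpoints", {
  d <- standardize_biomarkers(make_toy_data(n = 90, p = 4))
  grid <- lambda_grid(d, nlambda = 12)
  path <- coef_path(d, grid = grid)
  nz <- dplyr::distinct(path, lambda, n_nonzero)
  expect_equal(nz$n_nonzero[which.max(nz$lambda)], 0)
  expect_gte(nz$n_nonzero[which.min(nz$lambda)],
             nz$n_nonzero[which.max(nz$lambda)])
  # penalized estimates at the top of the grid never exceed the unpenalized fit
  f_top <- fit_penalized(d, max(grid), penalty_spec("lasso"))
  f_zero <- fit_penalized(d, 0, penalty_spec("none"))
  expect_true(all(abs(f_top$beta_hat) <= abs(f_zero$beta_hat) + 1e-6))
  expect_true(all(abs(f_top$gamma_hat) <= abs(f_zero$gamma_hat) + 1e-6))
})

test_that("a dominant true interaction is recovered with the largest |gamma|", {
  set.seed(88)
  d <- make_toy_data(n = 300, p = 10, seed = 777,
                     beta = rep(0, 10),
                     gamma = c(-1, rep(0, 9)), alpha = -0.3)
  d <- standardize_biomarkers(d)
  fit <- fit_penalized(d, lambda_max(d) * 0.1, penalty_spec("lasso"))
  expect_equal(which.max(abs(fit$gamma_hat)), 1L, ignore_attr = TRUE)
})

test_that("refit re-estimates the selected set unpenalized and zeroes the rest", {
  d <- standardize_biomarkers(make_toy_data(n = 80, p = 4))
  fit <- fit_penalized(d, lambda_max(d) * 0.35, penalty_spec("lasso"))
  rf <- refit_unpenalized(fit, d)
  expect_equal(rf$beta_hat != 0, fit$beta_hat != 0)
  expect_equal(rf$gamma_hat != 0, fit$gamma_hat != 0)
  # matches a direct unpenalized fit on the selected columns
  dm <- design_matrix(d)
  act <- c(TRUE, unname(fit$beta_hat != 0), unname(fit$gamma_hat != 0))
  direct <- survival::coxph(survival::Surv(d$time, d$event) ~
                              dm$x[, act, drop = FALSE], ties = "breslow")
  expect_equal(coef_vector(rf, dm)[act], unname(coef(direct)), tolerance = 1e-6)

  # empty selection collapses to the treatment-only model
  f0 <- fit_penalized(d, lambda_max(d) * 1.01, penalty_spec("lasso"))
  rf0 <- refit_unpenalized(f0, d)
  trt_only <- survival::coxph(survival::Surv(d$time, d$event) ~ d$treatment,
                              ties = "breslow")
  expect_equal(rf0$alpha_hat, unname(coef(trt_only)), tolerance = 1e-6)
})
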