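test_that("Breslow baseline reduces to Nelson-Aalen under the null model", {
  d <- make_fixture(time = c(1, 2, 3, 4, 5), event = c(1, 1, 0, 1, 0))
  fit <- new_coxint_fit(alpha_hat = 0, beta_hat = 0, gamma_hat = 0,
                        marker_names = "x1", lambda = 0,
                        penalty = penalty_spec("none"))
  bl <- breslow_baseline(fit, d)
  expect_equal(bl$time, c(1, 2, 4))
  expect_equal(bl$cum_hazard, cumsum(c(1 / 5, 1 / 4, 1 / 2)))
  # single event among n at risk
  d1 <- make_fixture(time = c(2, 3, 4), event = c(1, 0, 0))
  bl1 <- breslow_baseline(fit, d1)
  expect_equal(bl1$cum_hazard, 1 / 3)
})

test_that("Breslow baseline with covariates matches hand-enumerated risk sums", {
  time <- c(1, 2, 2, 3, 4, 5, 6, 7)
  event <- c(1, 1, 1, 0, 1, 0, 1, 0)
  x <- matrix(c(0.5, -0.2, 0.1, 0.8, -0.5, 0.3, 0.2, -0.1), ncol = 1,
              dimnames = list(NULL, "x1"))
  d <- make_fixture(time, event, trt = rep(c(-0.5, 0.5), 4), x = x)
  fit <- new_coxint_fit(alpha_hat = 0.4, beta_hat = -0.6, gamma_hat = 0.2,
                        marker_names = "x1", lambda = 0,
                        penalty = penalty_spec("none"))
  dm <- design_matrix(d)
  lp <- drop(dm$x %*% c(0.4, -0.6, 0.2))
  bl <- breslow_baseline(fit, d)
  # brute force: loop over event times, tied pair at t=2 shares one risk set
  expected <- c()
  H <- 0
  for (t0 in c(1, 2, 4, 6)) {
    dsum <- sum(event == 1 & time == t0)
    H <- H + dsum / sum(exp(lp[time >= t0]))
    expected <- c(expected, H)
  }
  expect_equal(bl$cum_hazard, expected)
})

test_that("survival predictions follow exp(-H0 exp(lp)) and its edge cases", {
  d <- standardize_biomarkers(make_toy_data(n = 50, p = 2))
  fit <- fit_penalized(d, lambda_max(d) * 1.05, penalty_spec("lasso"))
  # H0 = 0 before the first event: S = 1 for any patient
  t_first <- min(fit$baseline$time)
  s <- predict_survival(fit, d$biomarkers[1:3, ], c(0.5, -0.5, 0.5),
                        times = t_first / 2)
  expect_equal(drop(s), rep(1, 3))
  # fixed arithmetic: all coefficients zero, H0(t) = 0.2614
  fit0 <- new_coxint_fit(alpha_hat = 0, beta_hat = c(0, 0), gamma_hat = c(0, 0),
                         marker_names = colnames(d$biomarkers), lambda = 0,
                         penalty = penalty_spec("none"),
                         baseline = tibble::tibble(time = 1, cum_hazard = 0.2614),
                         standardization = d$standardization)
  s0 <- predict_survival(fit0, d$biomarkers[1, , drop = FALSE], 0.5, times = 1)
  expect_equal(drop(s0), exp(-0.2614), tolerance = 1e-12)
  # beyond the last event time: last step carried forward, with a warning
  expect_warning(
    s_far <- predict_survival(fit, d$biomarkers[1, , drop = FALSE], 0.5,
                              times = max(fit$baseline$time) + 100),
    "beyond"
  )
  s_last <- predict_survival(fit, d$biomarkers[1, , drop = FALSE], 0.5,
                             times = max(fit$baseline$time))
  expect_equal(drop(s_far), drop(s_last))
})

test_that("survival curves are nonincreasing, start at 1, and order by risk", {
  d <- standardize_biomarkers(make_toy_data(n = 60, p = 3))
  fit <- fit_penalized(d, lambda_max(d) * 0.2, penalty_spec("lasso"))
  times <- c(0, sort(unique(d$time)))
  sm <- suppressWarnings(predict_survival(fit, d$biomarkers, d$treatment,
                                          times = times))
  expect_true(all(sm[, 1] == 1))
  expect_true(all(diff(t(sm)) <= 1e-12))
  # two same-arm patients differing only in a main-effect marker
  fitb <- new_coxint_fit(alpha_hat = 0, beta_hat = c(-0.5, 0, 0),
                         gamma_hat = c(0, 0, 0),
                         marker_names = colnames(d$biomarkers), lambda = 0,
                         penalty = penalty_spec("none"),
                         standardization = d$standardization)
  fitb <- survtailor:::attach_baseline(fitb, d)
  x_pair <- rbind(d$biomarkers[1, ], d$biomarkers[1, ])
  # undo standardization for input (raw scale expected)
  x_raw <- sweep(sweep(x_pair, 2, d$standardization$scale, "*"), 2,
                 d$standardization$center, "+")
  x_raw[2, 1] <- x_raw[2, 1] + 2 * d$standardization$scale[1]
  s_pair <- predict_survival(fitb, x_raw, c(0.5, 0.5), times = 5)
  expect_gt(s_pair[2, 1], s_pair[1, 1])  # larger X with beta < 0: higher survival
})

test_that("scores decompose the linear predictor used in prediction", {
  d <- standardize_biomarkers(make_toy_data(n = 40, p = 3))
  fit <- fit_penalized(d, lambda_max(d) * 0.15, penalty_spec("lasso"))
  x_raw <- sweep(sweep(d$biomarkers, 2, d$standardization$scale, "*"), 2,
                 d$standardization$center, "+")
  sc_plus <- scores(fit, x_raw, 0.5)
  sc_minus <- scores(fit, x_raw, -0.5)
  # eta is treatment-free
  expect_equal(sc_plus$mod_score, sc_minus$mod_score)
  expect_equal(sc_plus$prog_score, sc_minus$prog_score)
  # pi = alpha T + phi + eta T, bit-identical with the predictor in surv
  expect_equal(sc_plus$lin_pred,
               fit$alpha_hat * 0.5 + sc_plus$prog_score + sc_plus$mod_score * 0.5)
  s <- predict_survival(fit, x_raw, 0.5, times = 5)
  H0 <- survtailor:::eval_cum_hazard(fit$baseline, 5, warn_beyond = FALSE)
  expect_equal(drop(s), exp(-H0 * exp(sc_plus$lin_pred)))
  # all-zero coefficients give zero scores
  fit0 <- new_coxint_fit(alpha_hat = 0, beta_hat = numeric(3), gamma_hat = numeric(3),
                         marker_names = colnames(d$biomarkers), lambda = 0,
                         penalty = penalty_spec("none"),
                         standardization = d$standardization)
  sc0 <- scores(fit0, x_raw, 0.5)
  expect_true(all(sc0$prog_score == 0 & sc0$mod_score == 0 & sc0$lin_pred == 0))
})

test_that("training predictions are invariant to when standardization happens", {
  d_raw <- make_toy_data(n = 50, p = 3, seed = 66)
  d_std <- standardize_biomarkers(d_raw)
  fit <- fit_penalized(d_std, lambda_max(d_std) * 0.3, penalty_spec("lasso"))
  # raw inputs standardized at predict time reproduce the training lp
  s1 <- predict_survival(fit, d_raw$biomarkers, d_raw$treatment, times = 5)
  dm <- design_matrix(d_std)
  lp_train <- drop(dm$x %*% coef_vector(fit, dm))
  H0 <- survtailor:::eval_cum_hazard(fit$baseline, 5, warn_beyond = FALSE)
  expect_equal(drop(s1), exp(-H0 * exp(lp_train)), tolerance = 1e-12)
})
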