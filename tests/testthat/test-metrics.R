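test_that("censoring KM reverses the event indicator correctly", {
  # no censored patients: S_C identically 1
  g1 <- censoring_km(c(1, 2, 3), c(1, 1, 1))
  expect_equal(g1(c(0.5, 2.5, 10)), c(1, 1, 1))
  # one censoring at t=2 among 4 at risk: step to 3/4
  g2 <- censoring_km(c(2, 3, 4, 5), c(0, 1, 1, 1))
  expect_equal(g2(c(1.5, 2, 3.5)), c(1, 3 / 4, 3 / 4))
  # matches survival::survfit on a 10-patient fixture
  set.seed(2)
  tt <- rexp(10); ev <- rbinom(10, 1, 0.5)
  g <- censoring_km(tt, ev)
  km <- survival::survfit(survival::Surv(tt, 1 - ev) ~ 1)
  expect_equal(g(km$time), km$surv)
})

test_that("Brier score matches closed forms and a hand-computed IPCW sum", {
  # uncensored, perfect predictions -> 0
  tt <- c(1, 2, 6, 7); ev <- rep(1, 4)
  pred_perf <- c(0, 0, 1, 1)
  expect_equal(brier_score(tt, ev, pred_perf, t = 5), 0)
  # uncensored, all predictions 0.5 -> 0.25
  expect_equal(brier_score(tt, ev, rep(0.5, 4), t = 5), 0.25)
  # censored 8-patient fixture vs brute force
  time <- c(1, 2, 3, 4, 5, 6, 7, 8)
  event <- c(1, 0, 1, 1, 0, 1, 0, 1)
  pred <- c(0.2, 0.4, 0.3, 0.5, 0.6, 0.7, 0.8, 0.9)
  tau <- 5.5
  g <- censoring_km(time, event)
  manual <- 0
  for (i in 1:8) {
    if (time[i] <= tau && event[i] == 1) {
      manual <- manual + pred[i]^2 / g(time[i])
    } else if (time[i] > tau) {
      manual <- manual + (1 - pred[i])^2 / g(tau)
    }
  }
  expect_equal(brier_score(time, event, pred, tau), manual / 8)
  # no censoring: equals the plain mean squared error of survival indicators
  surv_ind <- as.numeric(tt > 3)
  pred <- c(0.1, 0.3, 0.8, 0.6)
  expect_equal(brier_score(tt, ev, pred, t = 3),
               mean((surv_ind - pred)^2))
})

test_that("integrated Brier normalizes the weight and is zero for perfection", {
  d <- make_toy_data(n = 40, p = 2, seed = 77)
  times <- ibrier_times(d$time, d$event, tau = 5)
  # perfect predictions at every time
  sm_perf <- outer(d$time, times, ">")
  storage.mode(sm_perf) <- "double"
  expect_equal(integrated_brier(d$time, d$event, sm_perf, times, tau = 5), 0)
  # weight construction: W(0) = 0 and W(tau) = 1 by construction
  skm <- survtailor:::event_km(d$time, d$event)
  w <- (1 - skm(times)) / (1 - skm(5))
  expect_equal(w[length(w)], 1)
  expect_gte(w[1], 0)
  # integral equals the explicit Stieltjes sum
  sm <- matrix(0.7, 40, length(times))
  dw <- diff(c(0, w))
  manual <- sum(vapply(seq_along(times), function(j)
    brier_score(d$time, d$event, sm[, j], times[j]) * dw[j], numeric(1)))
  expect_equal(integrated_brier(d$time, d$event, sm, times, tau = 5), manual)
})

test_that("Uno's C matches closed forms, brute force, and survival::concordance", {
  # uncensored, scores perfectly anti-ordered with survival time -> 1
  tt <- 1:6; ev <- rep(1, 6); sc <- 6:1
  expect_equal(uno_c(tt, ev, sc, tau = 10), 1)
  # constant scores -> 0.5 under the tie rule
  expect_equal(uno_c(tt, ev, rep(2, 6), tau = 10), 0.5)
  # complement property on tie-free data
  set.seed(11)
  tt <- rexp(20); ev <- rbinom(20, 1, 0.7); sc <- rnorm(20)
  expect_equal(uno_c(tt, ev, sc, 2) + uno_c(tt, ev, -sc, 2), 1)
  # censored 10-patient fixture vs the O(n^2) double-sum oracle
  time <- c(0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4, 4.5, 5)
  event <- c(1, 0, 1, 1, 0, 1, 1, 0, 1, 0)
  score <- c(2.5, 1, 3, 0.5, 2, 1.5, 3, 0, 1, 2)  # includes ties
  g <- censoring_km(time, event)
  expect_equal(uno_c(time, event, score, tau = 4.2),
               brute_uno_c(time, event, score, tau = 4.2, g))
  # agrees with the survival package's Uno weighting on tie-free scores
  set.seed(4)
  tt <- rexp(80, 0.3); ev <- rbinom(80, 1, 0.6); sc <- rnorm(80)
  cf <- survival::concordance(survival::Surv(tt, ev) ~ sc, reverse = TRUE,
                              timewt = "n/G2", ymax = 3)
  expect_equal(uno_c(tt, ev, sc, tau = 3), unname(cf$concordance),
               tolerance = 1e-10)
  # reordering patients leaves the statistic unchanged
  perm <- sample(80)
  expect_equal(uno_c(tt[perm], ev[perm], sc[perm], tau = 3),
               uno_c(tt, ev, sc, tau = 3))
})

test_that("delta-C is zero under symmetry and positive for a true modifier", {
  d <- make_toy_data(n = 80, p = 2, seed = 15)
  # constant eta: both arm C equal 0.5
  expect_equal(delta_c(d$time, d$event, d$treatment, rep(1, 80), tau = 5), 0)
  # identical data and scores in both arms -> 0
  tt <- rep(c(1, 2, 3, 4), 2); ev <- rep(c(1, 1, 0, 1), 2)
  trt <- rep(c(0.5, -0.5), each = 4); sc <- rep(c(3, 1, 2, 4), 2)
  expect_equal(delta_c(tt, ev, trt, sc, tau = 5), 0)
  # a strong true modifier separates the arms
  d2 <- make_toy_data(n = 400, p = 2, seed = 52, beta = c(0, 0),
                      gamma = c(-1.5, 0), alpha = 0)
  eta <- d2$biomarkers[, 1] * -1.5
  expect_gt(delta_c(d2$time, d2$event, d2$treatment, eta, tau = 5), 0.2)
})

test_that("metric_report is invariant to patient reordering", {
  d <- make_toy_data(n = 60, p = 3, seed = 23)
  fit <- fit_coxint(d, penalty = "lasso", seed = 2, nlambda = 15)
  m1 <- metric_report(d, fit)
  d2 <- subset_patients(d, sample(60))
  m2 <- metric_report(d2, fit)
  expect_equal(m1$ibrier, m2$ibrier, tolerance = 1e-10)
  expect_equal(m1$uno_c, m2$uno_c, tolerance = 1e-10)
  expect_equal(m1$delta_c, m2$delta_c, tolerance = 1e-10)
})
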