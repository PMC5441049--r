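test_that("biomarker generator reproduces the block AR(1) correlation", {
  set.seed(5)
  X <- generate_biomarkers(2000, 50, block_size = 25, rho = 0.8)
  # adjacent columns in a block
  expect_equal(cor(X[, 1], X[, 2]), 0.8, tolerance = 0.05)
  # lag-5 within block: 0.8^5 = 0.328
  expect_equal(cor(X[, 1], X[, 6]), 0.8^5, tolerance = 0.05)
  # across blocks independent
  expect_lt(abs(cor(X[, 25], X[, 26])), 0.1)
  # rho = 0 removes within-block correlation
  X0 <- generate_biomarkers(2000, 10, block_size = 5, rho = 0)
  expect_lt(max(abs(cor(X0)[upper.tri(diag(10))])), 0.1)
  # unit marginal variance
  expect_equal(unname(apply(X, 2, var)), rep(1, 50), tolerance = 0.15)
})

test_that("effect draws follow the scenario table and placement rules", {
  spec1 <- scenario_spec(1, n = 100, p = 500)
  set.seed(1); e1 <- draw_effects(spec1)
  expect_equal(e1$alpha, 0)
  expect_true(all(e1$beta == 0) && all(e1$gamma == 0))
  spec2 <- scenario_spec(2, n = 100, p = 500)
  set.seed(1); e2 <- draw_effects(spec2)
  expect_equal(e2$alpha, -0.8)
  expect_true(all(e2$beta == 0) && all(e2$gamma == 0))
  spec4 <- scenario_spec(4, n = 100, p = 500)
  set.seed(1); e4 <- draw_effects(spec4)
  expect_equal(sum(e4$gamma != 0), 15)
  expect_true(all(e4$gamma[e4$mod_set] >= -0.40 & e4$gamma[e4$mod_set] <= -0.10))
  # modifiers spread across distinct blocks when blocks are free
  expect_equal(unique(diff(e4$mod_set)), 25)
  spec6 <- scenario_spec(6, n = 100, p = 500)
  set.seed(1); e6 <- draw_effects(spec6)
  expect_equal(sum(e6$beta != 0), 20)
  expect_equal(sum(e6$gamma != 0), 15)
  # truth sets disjoint
  expect_length(intersect(e6$prog_set, e6$mod_set), 0)
  expect_true(all(e6$beta[e6$prog_set] >= -0.20 & e6$beta[e6$prog_set] <= -0.05))
})

test_that("survival generation matches the constant-hazard closed forms", {
  spec <- scenario_spec(1, n = 4000, p = 4, censor_target = 0)
  set.seed(33)
  eff <- draw_effects(spec)
  X <- generate_biomarkers(4000, 4, 2, 0)
  d <- generate_survival(X, effects = eff, spec = spec)
  # baseline patient survival at tau: P(t > 5) = 0.77
  expect_equal(mean(d$time > 5), 0.77, tolerance = 0.02)
  # KM at tau matches exp(-lambda0 tau)
  km <- survival::survfit(survival::Surv(d$time, d$event) ~ 1)
  s5 <- summary(km, times = 5)$surv
  expect_equal(s5, exp(-spec$lambda0 * 5), tolerance = 0.02)
  # doubling all hazards halves median survival (exponential scaling)
  spec_half <- scenario_spec(1, n = 4000, p = 4,
                             s0_tau = exp(2 * log(0.77)), censor_target = 0)
  set.seed(33)
  d2 <- generate_survival(X, treatment = d$treatment, effects = eff,
                          spec = spec_half)
  expect_equal(median(d2$time), median(d$time) / 2, tolerance = 0.15)
})

test_that("theoretical survival matches its closed form and the empirical KM", {
  spec <- scenario_spec(2, n = 100, p = 4)
  eff <- structure(list(alpha = -0.8, beta = rep(0, 4), gamma = rep(0, 4),
                        prog_set = integer(0), mod_set = integer(0)),
                   class = "effect_realization")
  x0 <- matrix(0, 1, 4, dimnames = list(NULL, paste0("bm", 1:4)))
  expect_equal(theoretical_survival(x0, 0, eff, spec, t = 5), 0.77)
  expect_equal(theoretical_survival(x0, 0.5, eff, spec, t = 5),
               0.77^exp(-0.4), tolerance = 1e-12)
  # Monte-Carlo check against a large cohort
  spec_nc <- scenario_spec(2, n = 100, p = 4, censor_target = 0)
  set.seed(77)
  Xb <- generate_biomarkers(50000, 4, 2, 0)
  trt <- rep(0.5, 50000)
  db <- generate_survival(Xb, treatment = trt, effects = eff, spec = spec_nc)
  expect_equal(mean(db$time > 5), 0.77^exp(-0.4), tolerance = 0.01)
})

test_that("censoring calibration hits the null target and replays across scenarios", {
  spec <- scenario_spec(1, n = 100, p = 4)
  # closed form under the null: P(C < T) = (1 - exp(-lambda0 u)) / (lambda0 u)
  x <- spec$lambda0 * spec$censor_max
  expect_equal((1 - exp(-x)) / x, 0.72, tolerance = 1e-4)
  # target 0 disables censoring
  expect_equal(scenario_spec(1, n = 10, p = 2, censor_target = 0)$censor_max, Inf)
  # the same censoring window is reused by every scenario
  expect_equal(scenario_spec(6, n = 10, p = 4)$censor_max, spec$censor_max)
  # ... which reproduces the arm-specific rates under a pure treatment effect
  m_ctrl <- spec$lambda0 * exp(0.4) * spec$censor_max
  m_exp <- spec$lambda0 * exp(-0.4) * spec$censor_max
  expect_equal((1 - exp(-m_ctrl)) / m_ctrl, 0.62, tolerance = 0.005)
  expect_equal((1 - exp(-m_exp)) / m_exp, 0.80, tolerance = 0.005)
})

test_that("the same seed yields byte-identical datasets and truths", {
  spec <- scenario_spec(6, n = 40, p = 50)
  s1 <- simulate_trial(spec, seed = 12)
  s2 <- simulate_trial(spec, seed = 12)
  expect_identical(s1$train$time, s2$train$time)
  expect_identical(s1$train$biomarkers, s2$train$biomarkers)
  expect_identical(s1$effects, s2$effects)
  expect_identical(s1$validation$time, s2$validation$time)
  # twin design: training and validation share the effect realization
  expect_identical(attr(s1$train, "truth_surv") |> length(), 40L)
})

test_that("oracle model covers the truth parameters at the nominal rate", {
  spec <- scenario_spec(3, n = 400, p = 50)
  covered <- total <- 0
  for (r in 1:10) {
    sim <- simulate_trial(spec, seed = 400 + r, validation = FALSE)
    ofit <- oracle_model(sim$train, sim$effects)
    # structural count: treatment + 2 active main effects at p = 50 (2 blocks)
    expect_equal(sum(ofit$beta_hat != 0), length(sim$effects$prog_set))
    # Wald coverage of the drawn beta via the refit information matrix
    dm_x <- cbind(sim$train$treatment,
                  sim$train$biomarkers[, sim$effects$prog_set, drop = FALSE])
    cph <- survival::coxph(survival::Surv(sim$train$time, sim$train$event) ~ dm_x,
                           ties = "breslow")
    est <- coef(cph)[-1]; se <- sqrt(diag(vcov(cph)))[-1]
    truth <- sim$effects$beta[sim$effects$prog_set]
    covered <- covered + sum(abs(est - truth) <= 1.96 * se)
    total <- total + length(truth)
  }
  expect_gt(covered / total, 0.80)  # ~95% nominal, small-sample slack
  # scenario 1: empty truth sets give the treatment-only oracle
  spec1 <- scenario_spec(1, n = 200, p = 10)
  sim1 <- simulate_trial(spec1, seed = 3, validation = FALSE)
  o1 <- oracle_model(sim1$train, sim1$effects)
  expect_true(all(o1$beta_hat == 0) && all(o1$gamma_hat == 0))
})

test_that("simulation export writes train/validation/truth/manifest", {
  dir <- withr::local_tempdir()
  spec <- scenario_spec(4, n = 30, p = 50)
  sim <- simulate_trial(spec, seed = 2)
  write_simulation(sim, dir)
  expect_true(all(file.exists(file.path(dir, c("train.csv", "validation.csv",
                                               "truth.json", "manifest.json")))))
  tr <- read_surv_data(file.path(dir, "train.csv"), biomarkers = "bm", id = "id")
  expect_equal(tr$time, sim$train$time)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_equal(truth$gamma, sim$effects$gamma)
})
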