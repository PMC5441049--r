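#' Scenario definition for the randomized-trial simulation engine
#'
#' Six built-in scenarios span the null and alternative configurations used
#' for the operating-characteristics study:
#' 1. complete null; 2. treatment effect only (alpha = -0.8);
#' 3. 20 prognostic markers (beta_j ~ U(-0.20, -0.05));
#' 4. 15 treatment-effect modifiers (gamma_j ~ U(-0.40, -0.10));
#' 5. treatment effect + scenario 4; 6. 20 prognostic markers + scenario 5.
#' Biomarkers are Gaussian with unit variance and an AR(1) correlation
#' `0.8^|j-j'|` inside 25-marker blocks; event times are exponential with
#' baseline survival `S0(tau) = 0.77` at `tau = 5` years; censoring is
#' uniform (administrative, as under constant accrual), calibrated once
#' under the complete null to a 72% censoring rate and reused unchanged
#' across scenarios so that arm-specific rates under treatment effects
#' emerge endogenously (roughly 62%/80% under the scenario-2 treatment
#' effect).
#'
#' @param scenario Integer 1-6.
#' @param n Patients per dataset (default 1500).
#' @param p Biomarkers (default 500).
#' @param block_size AR(1) correlation block size (default 25).
#' @param rho Within-block base correlation (default 0.8).
#' @param s0_tau Baseline survival at the horizon (default 0.77).
#' @param tau Horizon in years (default 5).
#' @param censor_target Censoring proportion under the complete null
#'   (default 0.72; 0 disables censoring).
#' @return A `scenario_spec` list (includes the baseline hazard `lambda0`
#'   and the calibrated censoring-window upper bound `censor_max`).
#' @export
scenario_spec <- function(scenario = 1, n = 1500, p = 500, block_size = 25,
                          rho = 0.8, s0_tau = 0.77, tau = 5,
                          censor_target = 0.72) {
  stopifnot(scenario %in% 1:6, n >= 2, p >= 1)
  cfg <- list(
    list(alpha = 0,    n_prog = 0,  n_mod = 0),
    list(alpha = -0.8, n_prog = 0,  n_mod = 0),
    list(alpha = 0,    n_prog = 20, n_mod = 0),
    list(alpha = 0,    n_prog = 0,  n_mod = 15),
    list(alpha = -0.8, n_prog = 0,  n_mod = 15),
    list(alpha = -0.8, n_prog = 20, n_mod = 15)
  )[[scenario]]
  spec <- list(scenario = scenario, n = n, p = p, block_size = block_size,
               rho = rho, alpha = cfg$alpha,
               n_prog = cfg$n_prog, prog_range = c(-0.20, -0.05),
               n_mod = cfg$n_mod, mod_range = c(-0.40, -0.10),
               s0_tau = s0_tau, tau = tau, censor_target = censor_target)
  spec$lambda0 <- -log(s0_tau) / tau
  spec$censor_max <- calibrate_censoring(spec)
  structure(spec, class = "scenario_spec")
}

#' Calibrate the uniform censoring window to the complete-null target
#'
#' Censoring times are uniform on `(0, u)` — administrative censoring under
#' constant accrual. `u` is solved so that, under the complete null (every
#' patient's event hazard equals the baseline `lambda0`), the expected
#' censoring proportion `P(C < T) = (1 - exp(-lambda0 u)) / (lambda0 u)`
#' equals the target. The same window is reused for every scenario, so the
#' arm-specific rates under treatment effects emerge endogenously.
#'
#' @param spec A `scenario_spec` (or list with `lambda0` and
#'   `censor_target`).
#' @param tol Root-finding tolerance on the rate.
#' @return Upper bound of the censoring window (`Inf` when the target is 0,
#'   i.e. censoring disabled).
#' @export
calibrate_censoring <- function(spec, tol = 1e-4) {
  target <- spec$censor_target
  if (target == 0) return(Inf)
  if (target <= 0 || target >= 1) stop("censoring target must be in [0, 1)", call. = FALSE)
  f <- function(u) {
    x <- spec$lambda0 * u
    (1 - exp(-x)) / x - target
  }
  stats::uniroot(f, c(1e-8, 1e8), tol = tol / spec$lambda0)$root
}

#' Draw block-correlated Gaussian biomarkers
#'
#' Rows are i.i.d. multivariate normal; within each consecutive block of
#' `block_size` markers the correlation is `rho^|j - j'|` (AR(1)); markers in
#' different blocks are independent; every marker has unit variance.
#'
#' @param n,p Dimensions.
#' @param block_size Block length (last block may be shorter).
#' @param rho AR(1) base correlation.
#' @return n x p matrix with columns `bm0001`, `bm0002`, ...
#' @export
generate_biomarkers <- function(n, p, block_size = 25, rho = 0.8) {
  X <- matrix(stats::rnorm(n * p), n, p)
  if (rho != 0) {
    starts <- seq(1, p, by = block_size)
    for (s in starts) {
      cols <- s:min(s + block_size - 1, p)
      m <- length(cols)
      if (m == 1) next
      S <- rho^abs(outer(seq_len(m), seq_len(m), "-"))
      X[, cols] <- X[, cols] %*% chol(S)
    }
  }
  colnames(X) <- sprintf("bm%04d", seq_len(p))
  X
}

#' Draw one realization of the true regression effects
#'
#' Active prognostic markers occupy the first marker of each of the first
#' `n_prog` blocks; modifiers occupy the first marker of the next `n_mod`
#' blocks. When the prognostic markers already span all blocks, modifiers
#' fall back to the middle marker of the first `n_mod` blocks, which keeps
#' the two truth sets disjoint and nearly uncorrelated (lag-12 AR(1)
#' correlation `0.8^12` is negligible). Coefficients are drawn uniformly
#' from the scenario ranges.
#'
#' @param spec A `scenario_spec`.
#' @return An `effect_realization`: `alpha`, `beta` (p-vector), `gamma`
#'   (p-vector), and the index sets `prog_set`, `mod_set`.
#' @export
draw_effects <- function(spec) {
  p <- spec$p; bs <- spec$block_size
  n_blocks <- ceiling(p / bs)
  if (spec$n_prog + spec$n_mod > p) stop("active sets exceed p", call. = FALSE)
  # deterministic spread: first markers of consecutive blocks, then middle
  # markers, then the remaining offsets; prognostic markers take the first
  # n_prog positions of the cycle and modifiers the next n_mod (disjoint)
  mid <- min(ceiling(bs / 2) + 1, bs)
  offsets <- unique(c(1, mid, setdiff(seq_len(bs), c(1, mid))))
  candidates <- as.vector(outer((seq_len(n_blocks) - 1) * bs, offsets, "+"))
  candidates <- candidates[candidates <= p]
  prog_set <- sort(candidates[seq_len(spec$n_prog)])
  mod_set <- sort(candidates[spec$n_prog + seq_len(spec$n_mod)])
  beta <- numeric(p); gamma <- numeric(p)
  if (length(prog_set)) {
    beta[prog_set] <- stats::runif(length(prog_set), min(spec$prog_range),
                                   max(spec$prog_range))
  }
  if (length(mod_set)) {
    gamma[mod_set] <- stats::runif(length(mod_set), min(spec$mod_range),
                                   max(spec$mod_range))
  }
  structure(list(alpha = spec$alpha, beta = beta, gamma = gamma,
                 prog_set = prog_set, mod_set = mod_set),
            class = "effect_realization")
}

#' Generate randomized-trial survival data from drawn effects
#'
#' Treatment is assigned +/-0.5 with probability 0.5; event times are
#' exponential with hazard `lambda0 * exp(alpha T + beta'X + gamma'X T)`
#' (inverse-transform sampling); censoring times are independent uniform
#' draws on the calibrated window; the observed time is the minimum and
#' the event indicator flags whether the event came first.
#'
#' @param X Biomarker matrix (from [generate_biomarkers()]).
#' @param treatment Treatment codes; drawn at random if `NULL`.
#' @param effects An `effect_realization`.
#' @param spec The `scenario_spec`.
#' @return A `surv_dataset`; the per-patient theoretical survival at the
#'   horizon is attached as attribute `"truth_surv"`.
#' @export
generate_survival <- function(X, treatment = NULL, effects, spec) {
  n <- nrow(X)
  if (is.null(treatment)) treatment <- sample(c(-0.5, 0.5), n, replace = TRUE)
  lp <- effects$alpha * treatment + drop(X %*% effects$beta) +
    drop(X %*% effects$gamma) * treatment
  haz <- spec$lambda0 * exp(lp)
  t_event <- stats::rexp(n, haz)
  t_cens <- if (is.finite(spec$censor_max)) stats::runif(n, 0, spec$censor_max) else rep(Inf, n)
  obs <- pmin(t_event, t_cens)
  delta <- as.integer(t_event <= t_cens)
  df <- data.frame(id = as.character(seq_len(n)), time = obs, event = delta,
                   treatment = treatment, X, check.names = FALSE)
  out <- surv_dataset(df, biomarkers = colnames(X), id = "id")
  attr(out, "truth_surv") <- theoretical_survival(X, treatment, effects, spec)
  out
}

#' Theoretical survival probability under the simulation model
#'
#' `S_i(t) = exp(-lambda0 * t * exp(alpha T_i + beta'x_i + gamma'x_i T_i))`.
#'
#' @inheritParams generate_survival
#' @param t Horizon (default the scenario's `tau`).
#' @return Numeric vector of survival probabilities.
#' @export
theoretical_survival <- function(X, treatment, effects, spec, t = spec$tau) {
  lp <- effects$alpha * treatment + drop(as.matrix(X) %*% effects$beta) +
    drop(as.matrix(X) %*% effects$gamma) * treatment
  exp(-spec$lambda0 * t * exp(lp))
}

#' Simulate a training / validation twin pair for one replication
#'
#' Draws one effect realization and two independent datasets sharing it,
#' matching the paired design of the operating-characteristics study.
#'
#' @param spec A `scenario_spec`.
#' @param seed Seed (byte-identical output for equal seeds).
#' @param validation Generate the validation twin too.
#' @return List: `train`, `validation` (or NULL), `effects`, `spec`.
#' @export
simulate_trial <- function(spec, seed = NULL, validation = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  effects <- draw_effects(spec)
  train <- generate_survival(generate_biomarkers(spec$n, spec$p, spec$block_size, spec$rho),
                             effects = effects, spec = spec)
  valid <- NULL
  if (validation) {
    valid <- generate_survival(generate_biomarkers(spec$n, spec$p, spec$block_size, spec$rho),
                               effects = effects, spec = spec)
  }
  list(train = train, validation = valid, effects = effects, spec = spec)
}

#' Oracle model: unpenalized Cox fit on the truly active variables
#'
#' Fits an ordinary Cox model on the treatment, the main effects of every
#' truly active marker (prognostic or modifying), and the interactions of
#' the true modifiers. Serves as the performance upper reference.
#'
#' @param train Training `surv_dataset`.
#' @param effects The `effect_realization` that generated it.
#' @return A `coxint_fit` (penalty `"none"`, method `"oracle"`).
#' @export
oracle_model <- function(train, effects) {
  p <- ncol(train$biomarkers)
  main_set <- sort(union(which(effects$beta != 0), which(effects$gamma != 0)))
  int_set <- sort(which(effects$gamma != 0))
  X <- train$biomarkers
  cols <- cbind(treatment = train$treatment,
                X[, main_set, drop = FALSE],
                if (length(int_set)) X[, int_set, drop = FALSE] * train$treatment)
  fit <- survival::coxph(survival::Surv(train$time, train$event) ~ cols,
                         ties = "breslow")
  cf <- stats::coef(fit)
  if (anyNA(cf)) stop("oracle Cox fit is singular", call. = FALSE)
  beta <- numeric(p); gamma <- numeric(p)
  beta[main_set] <- cf[1 + seq_along(main_set)]
  if (length(int_set)) gamma[int_set] <- cf[1 + length(main_set) + seq_along(int_set)]
  out <- new_coxint_fit(alpha_hat = cf[[1]], beta_hat = beta, gamma_hat = gamma,
                        marker_names = colnames(X), lambda = 0,
                        penalty = penalty_spec("none"), method = "oracle")
  attach_baseline(out, train)
}

#' Write one simulated replication to disk as plain text
#'
#' Writes `train.csv`, `validation.csv`, `truth.json` (effects) and
#' `manifest.json` (all resolved parameters) under `dir`.
#'
#' @param sim Output of [simulate_trial()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_surv_data(sim$train, file.path(dir, "train.csv"))
  if (!is.null(sim$validation)) {
    write_surv_data(sim$validation, file.path(dir, "validation.csv"))
  }
  jsonlite::write_json(
    list(alpha = sim$effects$alpha, beta = sim$effects$beta,
         gamma = sim$effects$gamma, prog_set = sim$effects$prog_set,
         mod_set = sim$effects$mod_set),
    file.path(dir, "truth.json"), digits = NA)
  jsonlite::write_json(unclass(sim$spec), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
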