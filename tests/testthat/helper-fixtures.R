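# Small in-code fixtures shared across the suite.

# Deterministic toy trial: n patients, p biomarkers, moderate effects.
make_toy_data <- function(n = 60, p = 4, seed = 421, censor = TRUE,
                          beta = c(0.6, -0.5), gamma = c(0, 0, -0.8),
                          alpha = -0.4) {
  beta <- rep_len(c(beta, numeric(p)), p)
  gamma <- rep_len(c(gamma, numeric(p)), p)
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", seq_len(p))))
  trt <- sample(c(-0.5, 0.5), n, replace = TRUE)
  lp <- alpha * trt + drop(X %*% beta) + drop(X %*% gamma) * trt
  t_event <- rexp(n, 0.1 * exp(lp))
  t_cens <- if (censor) rexp(n, 0.06) else rep(Inf, n)
  df <- data.frame(id = as.character(seq_len(n)), time = pmin(t_event, t_cens),
                   event = as.integer(t_event <= t_cens), treatment = trt, X,
                   check.names = FALSE)
  surv_dataset(df, biomarkers = colnames(X), id = "id")
}

# Hand-sized fixture with known times/events for closed-form checks.
make_fixture <- function(time, event, trt = NULL, x = NULL) {
  n <- length(time)
  if (is.null(trt)) trt <- rep(c(-0.5, 0.5), length.out = n)
  if (is.null(x)) x <- matrix(seq_len(n) / n, n, 1, dimnames = list(NULL, "x1"))
  df <- data.frame(time = time, event = event, treatment = trt, x,
                   check.names = FALSE)
  surv_dataset(df, biomarkers = colnames(x))
}

# Independent brute-force Breslow partial log-likelihood: explicit loop over
# event times, no shared code with the package internals.
brute_loglik <- function(time, event, lp) {
  ll <- 0
  for (t0 in unique(time[event == 1])) {
    d_idx <- which(event == 1 & time == t0)
    risk <- which(time >= t0)
    ll <- ll + sum(lp[d_idx]) - length(d_idx) * log(sum(exp(lp[risk])))
  }
  ll
}

# Independent O(n^2) double-sum Uno's C with explicit loops.
brute_uno_c <- function(time, event, score, tau, g) {
  num <- den <- 0
  n <- length(time)
  for (i in seq_len(n)) {
    if (event[i] != 1 || time[i] >= tau) next
    w <- g(time[i])^-2
    for (j in seq_len(n)) {
      if (time[i] >= time[j]) next
      den <- den + w
      if (score[i] > score[j]) num <- num + w
      else if (score[i] == score[j]) num <- num + w / 2
    }
  }
  num / den
}
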