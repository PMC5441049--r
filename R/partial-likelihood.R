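#' Cox partial log-likelihood with Breslow handling of ties
#'
#' Evaluates the partial log-likelihood of a Cox model at a given linear
#' predictor. Tied event times are handled with the Breslow approximation
#' (all tied events share one risk-set denominator), consistently with the
#' Breslow baseline-hazard estimator used for prediction.
#'
#' @param time Follow-up times.
#' @param event Event indicators (0/1); at least one event is required.
#' @param lp Linear predictor per patient (default all zero).
#' @return The partial log-likelihood (scalar).
#' @export
cox_loglik_lp <- function(time, event, lp = rep(0, length(time))) {
  stopifnot(length(time) == length(event), length(lp) == length(time))
  if (sum(event) == 0) stop("no events: partial likelihood undefined", call. = FALSE)
  lp <- lp - max(lp)                       # guard exp overflow; plik is shift-invariant
  ord <- order(time)
  tt <- time[ord]; ev <- event[ord]; elp <- exp(lp[ord])
  # risk-set sums S0(t) = sum_{t_j >= t} exp(lp_j), via reverse cumulative sum
  s0 <- rev(cumsum(rev(elp)))
  ev_idx <- which(ev == 1)
  d_times <- tt[ev_idx]
  first_at_risk <- match(d_times, tt)      # first index with this time (ties share S0)
  sum(log(elp[ev_idx])) - sum(log(s0[first_at_risk]))
}

#' @describeIn cox_loglik_lp Partial log-likelihood at a coefficient vector
#'   for a design matrix `x` (`lp = x %*% coefs`).
#' @param x Design matrix.
#' @param coefs Coefficient vector conformable with `x`.
#' @export
cox_loglik <- function(time, event, x, coefs) {
  cox_loglik_lp(time, event, drop(as.matrix(x) %*% coefs))
}

# Score vector and observed information of the Breslow partial log-likelihood.
# Used for the weighted KKT lambda_max, the analytic variance of the
# cumulative hazard, and as an independent check of the optimizer in tests.
cox_score <- function(time, event, x, lp) {
  x <- as.matrix(x)
  ord <- order(time)
  tt <- time[ord]; ev <- event[ord]; xx <- x[ord, , drop = FALSE]
  elp <- exp(lp[ord] - max(lp))
  s0 <- rev(cumsum(rev(elp)))
  s1 <- apply(xx * elp, 2, function(col) rev(cumsum(rev(col))))
  s1 <- matrix(s1, nrow = length(tt))
  u <- rep(0, ncol(x))
  for (i in which(ev == 1)) {
    k <- match(tt[i], tt)
    u <- u + xx[i, ] - s1[k, ] / s0[k]
  }
  u
}

cox_information <- function(time, event, x, lp) {
  x <- as.matrix(x)
  m <- ncol(x)
  ord <- order(time)
  tt <- time[ord]; ev <- event[ord]; xx <- x[ord, , drop = FALSE]
  elp <- exp(lp[ord] - max(lp))
  info <- matrix(0, m, m)
  ut <- unique(tt[ev == 1])
  for (t0 in ut) {
    at_risk <- which(tt >= t0)
    w <- elp[at_risk]
    s0 <- sum(w)
    xr <- xx[at_risk, , drop = FALSE]
    s1 <- colSums(xr * w)
    s2 <- crossprod(xr, xr * w)
    d <- sum(ev == 1 & tt == t0)
    xbar <- s1 / s0
    info <- info + d * (s2 / s0 - tcrossprod(xbar))
  }
  info
}
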