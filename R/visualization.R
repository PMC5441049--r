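#' Scale modifying scores to the training 2.5%/97.5% quantile range
#'
#' `eta' = (eta - q_{0.025}(eta_train)) / (q_{0.975}(eta_train) - q_{0.025}(eta_train))`.
#' New patients are scaled with the TRAINING quantiles, so values outside the
#' training range map outside [0, 1] and are deliberately not clipped.
#' Quantiles use the linear-interpolation empirical definition (type 7), the
#' convention shared by every quantile in this package.
#'
#' @param eta Scores to scale.
#' @param eta_train Training scores defining the quantiles (default `eta`).
#' @return Scaled scores.
#' @export
scale_eta <- function(eta, eta_train = eta) {
  qs <- stats::quantile(eta_train, c(0.025, 0.975), type = 7, names = FALSE)
  if (diff(qs) == 0) {
    stop("modifying score is constant: the model has no treatment-effect modifying component",
         call. = FALSE)
  }
  (eta - qs[1]) / (qs[2] - qs[1])
}

#' Prognostic risk groups by the Cox 16.4 / 33.6 / 33.6 / 16.4 split
#'
#' Cuts the prognostic score at its 16.4th, 50th and 83.6th percentiles into
#' four ordered risk groups (1 = best prognosis under negative-is-better
#' coefficients depends on sign; groups are simply ordered by score).
#' Boundary ties go to the lower group.
#'
#' @param phi Prognostic scores (n >= 4).
#' @return Integer group labels 1..4. A constant score yields a single group
#'   with a warning.
#' @export
prognostic_groups <- function(phi) {
  if (length(phi) < 4) stop("need at least 4 patients to form groups", call. = FALSE)
  if (length(unique(phi)) == 1) {
    warning("constant prognostic score: a single group is returned", call. = FALSE)
    return(rep(1L, length(phi)))
  }
  qs <- stats::quantile(phi, c(0.164, 0.5, 0.836), type = 7, names = FALSE)
  findInterval(phi, qs, left.open = TRUE) + 1L
}

#' Least-squares B-spline with values constrained to [0, 1]
#'
#' Fits a cubic B-spline by least squares with the number of interior nodes
#' chosen by the Gaussian AIC `n log(RSS/n) + 2 k` over `node_candidates`.
#' The basis includes the intercept column, so it is a partition of unity;
#' constraining the basis coefficients to [0, 1] (bounded least squares)
#' therefore guarantees the fitted curve stays inside [0, 1] everywhere by
#' the convex-hull property.
#'
#' @param x,y Data (y in [0, 1]); at least 5 points.
#' @param node_candidates Candidate interior node counts (default 1:5).
#' @return A `constrained_spline`: list with `knots`, `coef`, `boundary`,
#'   `aic` table, callable through [predict()].
#' @export
fit_constrained_spline <- function(x, y, node_candidates = 1:5) {
  stopifnot(length(x) == length(y))
  if (length(x) < 5) stop("need at least 5 points for spline smoothing", call. = FALSE)
  if (any(y < -1e-9 | y > 1 + 1e-9)) stop("y must lie in [0, 1]", call. = FALSE)
  y <- pmin(pmax(y, 0), 1)
  n <- length(x)
  bnd <- range(x)
  fits <- lapply(node_candidates, function(nn) {
    knots <- stats::quantile(x, seq_len(nn) / (nn + 1), type = 7, names = FALSE)
    basis <- splines::bs(x, knots = knots, degree = 3, intercept = TRUE,
                         Boundary.knots = bnd)
    k <- ncol(basis)
    rss_fun <- function(cf) sum((y - drop(basis %*% cf))^2)
    grad_fun <- function(cf) -2 * drop(crossprod(basis, y - drop(basis %*% cf)))
    start <- pmin(pmax(stats::coef(stats::lm.fit(basis, y)), 0), 1)
    start[is.na(start)] <- mean(y)
    opt <- stats::optim(start, rss_fun, grad_fun, method = "L-BFGS-B",
                        lower = 0, upper = 1,
                        control = list(maxit = 500, factr = 1e4))
    list(knots = knots, coef = opt$par, k = k,
         aic = n * log(max(opt$value, 1e-12) / n) + 2 * k)
  })
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  best <- fits[[which.min(aics)]]
  structure(list(knots = best$knots, coef = best$coef, boundary = bnd,
                 n_nodes = length(best$knots),
                 aic = tibble::tibble(n_nodes = node_candidates, aic = aics)),
            class = "constrained_spline")
}

#' @export
predict.constrained_spline <- function(object, newdata, ...) {
  x <- pmin(pmax(newdata, object$boundary[1]), object$boundary[2])
  basis <- splines::bs(x, knots = object$knots, degree = 3, intercept = TRUE,
                       Boundary.knots = object$boundary)
  drop(basis %*% object$coef)
}

#' Plot data for the treatment-benefit visualization
#'
#' Evaluates every patient under BOTH arms (counterfactual prediction at
#' T = +0.5 and T = -0.5), scales the modifying score by the training
#' quantiles, forms prognostic risk groups, and attaches confidence bounds.
#' The returned table alone suffices to re-render the figure.
#'
#' @param fit A `coxint_fit`.
#' @param data `surv_dataset` of patients to display (raw-scale biomarkers).
#' @param tau Horizon (years).
#' @param ci `"analytic"`, `"bootstrap"`, or `"none"`.
#' @param train_data Training dataset; required for `ci = "bootstrap"`.
#' @param groups Stratify into prognostic risk groups (forced to a single
#'   group when the model selects no prognostic marker).
#' @param ... Passed to [bootstrap_ci()] (e.g. `B`, `seed`).
#' @return Tibble: id, arm, eta_scaled, prog_group, surv, lower, upper.
#' @export
treatment_benefit_data <- function(fit, data, tau = 5,
                                   ci = c("analytic", "bootstrap", "none"),
                                   train_data = NULL, groups = TRUE, ...) {
  ci <- match.arg(ci)
  sc <- scores(fit, data$biomarkers, data$treatment, data$clinical)
  eta_scaled <- scale_eta(sc$mod_score)
  grp <- if (groups && any(fit$beta_hat != 0)) prognostic_groups(sc$prog_score)
         else rep(1L, length(sc$prog_score))
  arms <- c(`-0.5` = -0.5, `0.5` = 0.5)
  out <- purrr::map_dfr(arms, function(a) {
    trt <- rep(a, length(data$time))
    s <- drop(predict_survival(fit, data$biomarkers, trt, data$clinical, times = tau))
    lo <- up <- rep(NA_real_, length(s))
    if (ci == "analytic") {
      iv <- analytic_ci(fit, data$biomarkers, trt, data$clinical, tau)
      lo <- iv$lower; up <- iv$upper
    } else if (ci == "bootstrap") {
      if (is.null(train_data)) stop("bootstrap CIs need `train_data`", call. = FALSE)
      iv <- bootstrap_ci(train_data, data$biomarkers, trt, data$clinical,
                         tau = tau, ...)
      lo <- iv$lower; up <- iv$upper
    }
    tibble::tibble(id = data$id, arm = a, eta_scaled = eta_scaled,
                   prog_group = grp, surv = s, lower = lo, upper = up)
  })
  attr(out, "tau") <- tau
  attr(out, "ci") <- ci
  out
}

#' Spline-smoothed curves for a treatment-benefit table
#'
#' For each arm x prognostic-group panel, fits three constrained B-splines
#' (point estimate, lower bound, upper bound) against the scaled modifying
#' score and evaluates them on a grid.
#'
#' @param plot_data Output of [treatment_benefit_data()].
#' @param node_candidates Interior-node candidates for AIC selection.
#' @param grid_length Evaluation grid size per panel.
#' @return Tibble: arm, prog_group, eta_scaled, curve (estimate/lower/upper),
#'   value.
#' @export
treatment_benefit_splines <- function(plot_data, node_candidates = 1:5,
                                      grid_length = 101) {
  panels <- dplyr::group_split(dplyr::group_by(plot_data, .data$arm, .data$prog_group))
  purrr::map_dfr(panels, function(pd) {
    grid <- seq(min(pd$eta_scaled), max(pd$eta_scaled), length.out = grid_length)
    curves <- list(estimate = pd$surv, lower = pd$lower, upper = pd$upper)
    purrr::imap_dfr(curves, function(yy, nm) {
      if (all(is.na(yy))) return(NULL)
      sp <- fit_constrained_spline(pd$eta_scaled, yy, node_candidates)
      tibble::tibble(arm = pd$arm[1], prog_group = pd$prog_group[1],
                     eta_scaled = grid, curve = nm,
                     value = predict(sp, grid))
    })
  })
}

#' Treatment-benefit plot
#'
#' Expected survival probability at the horizon against the scaled
#' treatment-effect modifying score, both arms per patient, pointwise
#' (points + vertical CI segments) or spline-smoothed within prognostic risk
#' groups (three curves per arm per panel).
#'
#' @param plot_data Output of [treatment_benefit_data()].
#' @param strategy `"pointwise"` or `"spline"`.
#' @param node_candidates Passed to [treatment_benefit_splines()].
#' @return A ggplot object.
#' @export
plot_treatment_benefit <- function(plot_data, strategy = c("pointwise", "spline"),
                                   node_candidates = 1:5) {
  strategy <- match.arg(strategy)
  pd <- dplyr::mutate(plot_data,
                      arm_label = factor(ifelse(.data$arm > 0, "experimental", "control"),
                                         levels = c("control", "experimental")))
  gg <- ggplot2::ggplot(pd, ggplot2::aes(x = .data$eta_scaled, colour = .data$arm_label)) +
    ggplot2::labs(x = "treatment-effect modifying score (scaled)",
                  y = paste0("expected survival at ", attr(plot_data, "tau") %||% 5, " years"),
                  colour = "arm") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
  if (strategy == "pointwise") {
    gg <- gg + ggplot2::geom_point(ggplot2::aes(y = .data$surv), size = 0.8)
    if (!all(is.na(pd$lower))) {
      gg <- gg + ggplot2::geom_linerange(
        ggplot2::aes(ymin = .data$lower, ymax = .data$upper), alpha = 0.4)
    }
    if (length(unique(pd$prog_group)) > 1) {
      gg <- gg + ggplot2::facet_wrap(~prog_group, labeller = ggplot2::label_both)
    }
  } else {
    sp <- treatment_benefit_splines(plot_data, node_candidates)
    sp <- dplyr::mutate(sp,
                        arm_label = factor(ifelse(.data$arm > 0, "experimental", "control"),
                                           levels = c("control", "experimental")))
    gg <- gg +
      ggplot2::geom_point(ggplot2::aes(y = .data$surv), size = 0.5, alpha = 0.3) +
      ggplot2::geom_line(data = sp,
                         ggplot2::aes(y = .data$value, linetype = .data$curve)) +
      ggplot2::scale_linetype_manual(values = c(estimate = "solid",
                                                lower = "dashed", upper = "dashed"))
    if (length(unique(pd$prog_group)) > 1) {
      gg <- gg + ggplot2::facet_wrap(~prog_group, labeller = ggplot2::label_both)
    }
  }
  gg
}

#' Treatment-benefit plot for a fitted model
#'
#' @param object A `coxint_fit`.
#' @param data Patients to display.
#' @param tau Horizon.
#' @param ci,strategy See [treatment_benefit_data()] / [plot_treatment_benefit()].
#' @param ... Passed to [treatment_benefit_data()].
#' @importFrom ggplot2 autoplot
#' @export
autoplot.coxint_fit <- function(object, data, tau = 5, ci = "none",
                                strategy = "pointwise", ...) {
  pd <- treatment_benefit_data(object, data, tau = tau, ci = ci, ...)
  plot_treatment_benefit(pd, strategy = strategy)
}

#' @export
ggplot2::autoplot
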