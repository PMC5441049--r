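#' Construct a validated survival dataset for interaction modelling
#'
#' Bundles right-censored survival outcomes from a randomized trial with a
#' biomarker matrix and optional unpenalized clinical covariates. The
#' treatment arm is coded numerically as +0.5 (experimental) and -0.5
#' (control) so that main biomarker effects represent the average prognostic
#' component across arms and biomarker-by-treatment products represent the
#' treatment-effect modifying component.
#'
#' @param data A data frame with one row per patient.
#' @param time Name of the follow-up time column (years, nonnegative).
#' @param event Name of the event indicator column (1 = event, 0 = censored).
#' @param treatment Name of the treatment column. Any two-level coding is
#'   accepted and recoded to +/-0.5; see `treatment_map`.
#' @param biomarkers Character vector of biomarker column names.
#' @param clinical Optional character vector of clinical covariate columns
#'   (never standardized, never penalized).
#' @param id Optional name of a patient identifier column; defaults to row
#'   order.
#' @param treatment_map Optional length-2 character/numeric vector naming the
#'   level mapped to the experimental arm (+0.5) first and the control arm
#'   (-0.5) second. By default the larger of `{0,1}`-type codings (or the
#'   level sorting last) is taken as experimental.
#'
#' @return An object of class `surv_dataset`: a list with elements
#'   `id`, `time`, `event`, `treatment`, `biomarkers` (n x p matrix),
#'   `clinical` (n x q matrix or NULL) and `standardization` (NULL until
#'   [standardize_biomarkers()] is applied).
#' @export
surv_dataset <- function(data, time = "time", event = "event",
                         treatment = "treatment", biomarkers,
                         clinical = NULL, id = NULL, treatment_map = NULL) {
  stopifnot(is.data.frame(data))
  need <- c(time, event, treatment, biomarkers, clinical, id)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tm <- as.numeric(data[[time]])
  ev <- data[[event]]
  if (anyNA(tm)) stop("NA or non-numeric values in column '", time, "'", call. = FALSE)
  if (any(tm < 0)) stop("negative times in column '", time, "'", call. = FALSE)
  if (anyNA(ev) || !all(ev %in% c(0, 1))) {
    stop("column '", event, "' must be binary 0/1", call. = FALSE)
  }
  trt_raw <- data[[treatment]]
  if (anyNA(trt_raw)) stop("NA values in column '", treatment, "'", call. = FALSE)
  trt <- recode_treatment(trt_raw, treatment_map, treatment)

  X <- as.matrix(data[biomarkers])
  storage.mode(X) <- "double"
  if (anyNA(X)) {
    bad <- biomarkers[colSums(is.na(data[biomarkers])) > 0][1]
    stop("NA values in biomarker column '", bad, "'", call. = FALSE)
  }
  colnames(X) <- biomarkers

  Z <- NULL
  if (!is.null(clinical)) {
    Z <- as.matrix(data[clinical])
    storage.mode(Z) <- "double"
    if (anyNA(Z)) stop("NA values in clinical covariates", call. = FALSE)
    colnames(Z) <- clinical
  }
  ids <- if (is.null(id)) as.character(seq_len(nrow(data))) else as.character(data[[id]])

  structure(
    list(id = ids, time = tm, event = as.integer(ev), treatment = trt,
         biomarkers = X, clinical = Z, standardization = NULL),
    class = "surv_dataset"
  )
}

recode_treatment <- function(x, treatment_map, colname) {
  if (is.numeric(x) && all(x %in% c(-0.5, 0.5))) return(as.numeric(x))
  lev <- sort(unique(as.character(x)))
  if (length(lev) != 2) {
    stop("column '", colname, "' must have exactly 2 levels, found ",
         length(lev), call. = FALSE)
  }
  if (is.null(treatment_map)) {
    # the level sorting last ({0,1} -> 1, {control, experimental} alphabetical)
    treatment_map <- c(lev[2], lev[1])
  }
  treatment_map <- as.character(treatment_map)
  if (!setequal(treatment_map, lev)) {
    stop("treatment_map does not match the observed levels of '", colname, "'",
         call. = FALSE)
  }
  ifelse(as.character(x) == treatment_map[1], 0.5, -0.5)
}

#' @export
print.surv_dataset <- function(x, ...) {
  cat("<surv_dataset> n =", length(x$time),
      " p =", ncol(x$biomarkers),
      " events =", sum(x$event),
      " arms (+0.5/-0.5) =", sum(x$treatment > 0), "/", sum(x$treatment < 0), "\n")
  if (!is.null(x$standardization)) cat("  biomarkers standardized (training scale stored)\n")
  invisible(x)
}

#' Number of patients / biomarkers in a survival dataset
#' @param data A `surv_dataset`.
#' @return Integer.
#' @export
n_patients <- function(data) length(data$time)

#' @rdname n_patients
#' @export
n_biomarkers <- function(data) ncol(data$biomarkers)

#' Read a delimited survival dataset
#'
#' Reads a header-ed delimited text file and validates it into a
#' [surv_dataset()]. Column roles are given by name; biomarker columns may be
#' named explicitly or through a common prefix.
#'
#' @inheritParams surv_dataset
#' @param path Path to a delimited text file with a header row.
#' @param biomarkers Character vector of biomarker column names, or a single
#'   string interpreted as a prefix when `prefix = TRUE`.
#' @param prefix If `TRUE`, `biomarkers` is a column-name prefix.
#' @param delim Field delimiter, default comma.
#' @return A `surv_dataset`.
#' @export
read_surv_data <- function(path, time = "time", event = "event",
                           treatment = "treatment", biomarkers = "x",
                           prefix = length(biomarkers) == 1L,
                           clinical = NULL, id = NULL,
                           treatment_map = NULL, delim = ",") {
  df <- utils::read.delim(path, sep = delim, header = TRUE, check.names = FALSE)
  if (prefix) {
    biomarkers <- grep(paste0("^", biomarkers), names(df), value = TRUE)
    biomarkers <- setdiff(biomarkers, c(time, event, treatment, clinical, id))
    if (!length(biomarkers)) stop("no biomarker columns matched the prefix", call. = FALSE)
  }
  surv_dataset(df, time = time, event = event, treatment = treatment,
               biomarkers = biomarkers, clinical = clinical, id = id,
               treatment_map = treatment_map)
}

#' Write a survival dataset back to delimited text
#'
#' @param data A `surv_dataset`.
#' @param path Output file path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_surv_data <- function(data, path, delim = ",") {
  df <- as_tibble(data)
  utils::write.table(df, path, sep = delim, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
as_tibble.surv_dataset <- function(x, ...) {
  df <- tibble::tibble(id = x$id, time = x$time, event = x$event,
                       treatment = x$treatment)
  df <- dplyr::bind_cols(df, tibble::as_tibble(x$biomarkers))
  if (!is.null(x$clinical)) df <- dplyr::bind_cols(df, tibble::as_tibble(x$clinical))
  df
}

#' Standardize biomarker columns to mean zero and unit variance
#'
#' Centers and scales each biomarker column and stores the per-column
#' `(center, scale)` so that future patients can be placed on the training
#' scale with [apply_standardization()]. Treatment and clinical covariates are
#' never touched. Idempotent: re-standardizing leaves values unchanged.
#'
#' @param data A `surv_dataset` with at least 2 patients.
#' @return The dataset with standardized biomarkers and a populated
#'   `standardization` element (tibble: column, center, scale).
#' @export
standardize_biomarkers <- function(data) {
  stopifnot(inherits(data, "surv_dataset"))
  if (length(data$time) < 2) stop("need at least 2 patients to standardize", call. = FALSE)
  X <- data$biomarkers
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  if (any(scl == 0)) {
    stop("constant biomarker column '", colnames(X)[scl == 0][1],
         "' cannot be standardized", call. = FALSE)
  }
  data$biomarkers <- sweep(sweep(X, 2, ctr, "-"), 2, scl, "/")
  data$standardization <- tibble::tibble(column = colnames(X), center = ctr, scale = scl)
  data
}

#' Apply a stored training standardization to new biomarker values
#'
#' @param x A numeric matrix (or data frame) of biomarker values with the
#'   training columns, or a `surv_dataset`.
#' @param standardization A standardization tibble as stored by
#'   [standardize_biomarkers()].
#' @return Matrix (or `surv_dataset`) on the training scale.
#' @export
apply_standardization <- function(x, standardization) {
  if (inherits(x, "surv_dataset")) {
    x$biomarkers <- apply_standardization(x$biomarkers, standardization)
    x$standardization <- standardization
    return(x)
  }
  x <- as.matrix(x)
  idx <- match(standardization$column, colnames(x))
  if (anyNA(idx)) stop("new data lacks biomarker column(s): ",
                       paste(standardization$column[is.na(idx)], collapse = ", "),
                       call. = FALSE)
  x <- x[, idx, drop = FALSE]
  sweep(sweep(x, 2, standardization$center, "-"), 2, standardization$scale, "/")
}

#' Build the interaction design matrix
#'
#' Columns are ordered `[treatment, clinical, X_1..X_p, X_1:T..X_p:T]`;
#' interaction columns are products of the (already standardized) biomarkers
#' and the +/-0.5 treatment code. The penalized mask is `FALSE` exactly on the
#' treatment and clinical columns.
#'
#' @param data A `surv_dataset` (biomarkers should already be standardized for
#'   fitting).
#' @return List with `x` (design matrix), `penalized` (logical mask),
#'   `role` (one of treatment/clinical/main/interaction per column) and
#'   `marker` (biomarker name or NA per column).
#' @export
design_matrix <- function(data) {
  X <- data$biomarkers
  p <- ncol(X)
  XT <- X * data$treatment
  colnames(XT) <- paste0(colnames(X), ":trt")
  cl <- data$clinical
  x <- cbind(treatment = data$treatment, cl, X, XT)
  q <- if (is.null(cl)) 0L else ncol(cl)
  role <- c("treatment", rep("clinical", q), rep("main", p), rep("interaction", p))
  marker <- c(NA, rep(NA, q), colnames(X), colnames(X))
  col_sd <- rep(1, ncol(x))
  pen <- role %in% c("main", "interaction")
  col_sd[pen] <- apply(x[, pen, drop = FALSE], 2, stats::sd)
  list(x = x, penalized = pen, role = role, marker = marker, col_sd = col_sd)
}

#' Export / import a fitted model as versioned JSON
#'
#' Serializes coefficients, the selected penalty and its weights, the Breslow
#' baseline table and the training standardization, so that predictions for
#' new patients can be reproduced without the training data.
#'
#' @param fit A `coxint_fit`.
#' @param path JSON file path.
#' @return `path` invisibly; `read_coxint_model()` returns a `coxint_fit`
#'   (without the training-data internals needed for analytic intervals).
#' @export
write_coxint_model <- function(fit, path) {
  stopifnot(inherits(fit, "coxint_fit"))
  obj <- list(
    format = "survtailor-model",
    version = 1L,
    penalty = fit$penalty$penalty,
    lambda = fit$lambda,
    alpha_hat = fit$alpha_hat,
    clinical_hat = fit$clinical_hat,
    beta_hat = as.list(stats::setNames(fit$beta_hat, fit$marker_names)),
    gamma_hat = as.list(stats::setNames(fit$gamma_hat, fit$marker_names)),
    theta = fit$penalty$theta,
    vartheta = fit$penalty$vartheta,
    baseline = list(time = fit$baseline$time, cum_hazard = fit$baseline$cum_hazard),
    standardization = list(column = fit$standardization$column,
                           center = fit$standardization$center,
                           scale = fit$standardization$scale)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_coxint_model
#' @export
read_coxint_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "survtailor-model")) {
    stop("not a survtailor model file", call. = FALSE)
  }
  new_coxint_fit(
    alpha_hat = obj$alpha_hat,
    clinical_hat = if (length(obj$clinical_hat)) unlist(obj$clinical_hat) else NULL,
    beta_hat = unlist(obj$beta_hat),
    gamma_hat = unlist(obj$gamma_hat),
    marker_names = names(obj$beta_hat),
    lambda = obj$lambda,
    penalty = penalty_spec(obj$penalty, theta = obj$theta, vartheta = obj$vartheta),
    baseline = tibble::tibble(time = obj$baseline$time,
                              cum_hazard = obj$baseline$cum_hazard),
    standardization = tibble::tibble(column = obj$standardization$column,
                                     center = obj$standardization$center,
                                     scale = obj$standardization$scale)
  )
}
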