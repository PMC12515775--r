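#' Construct a biomarker progression equation
#'
#' One-step annual regression for the time-path of a biomarker under no
#' intervention: next-year value as a linear function of the previous
#' value and covariates, either on the natural scale (`linear`) or on a
#' logit-rescaled bounded range (`logistic_transform`, where the linear
#' model acts on `qlogis((y - lo)/(hi - lo))`). Predictions are clamped
#' to the physiological bounds.
#'
#' @param biomarker One of [biomarker_names()].
#' @param model_type `"linear"` or `"logistic_transform"`.
#' @param coefficients Named numeric; recognised names: `intercept`,
#'   `prev` (previous value, transformed scale for logistic_transform),
#'   `age`, `male`, `duration`, `year`.
#' @param residual_sd Residual standard deviation (same units as the
#'   biomarker for `linear`; logit units for `logistic_transform`).
#' @param bounds Length-2 physiological clamp `[lo, hi]`; defaults to the
#'   package's per-biomarker bounds.
#' @return Object of class `biomarker_equation`.
#' @export
biomarker_equation <- function(biomarker, model_type = c("linear",
                                                         "logistic_transform"),
                               coefficients, residual_sd = 0,
                               bounds = NULL) {
  biomarker <- match.arg(biomarker, biomarker_names())
  model_type <- match.arg(model_type)
  if (is.null(names(coefficients)))
    stop2("coefficients must be named")
  if (residual_sd < 0) stop2("residual_sd must be >= 0")
  bounds <- bounds %||% .biomarker_bounds[[biomarker]]
  if (bounds[1] >= bounds[2]) stop2("bounds must satisfy lo < hi")
  eq <- list(biomarker = biomarker, model_type = model_type,
             coefficients = coefficients, residual_sd = residual_sd,
             bounds = bounds)
  class(eq) <- "biomarker_equation"
  eq
}

bm_lp <- function(coefs, prev, covariates) {
  lp <- unname(coefs["intercept"] %0% 0)
  if ("prev" %in% names(coefs)) lp <- lp + coefs[["prev"]] * prev
  for (v in setdiff(names(coefs), c("intercept", "prev"))) {
    if (is.null(covariates[[v]]))
      stop2("biomarker model needs covariate `", v, "`")
    lp <- lp + coefs[[v]] * as.numeric(covariates[[v]])
  }
  lp
}

#' Predict next-year biomarker value
#'
#' Deterministic conditional mean when `rng = FALSE`; mean plus a
#' Gaussian residual when `rng = TRUE`. Vectorised over persons.
#'
#' @param eq A [biomarker_equation()].
#' @param prev Previous-year value(s), natural scale.
#' @param covariates Named list / data frame of covariates (`age`,
#'   `male`, `duration`, `year`, as required by the equation).
#' @param rng Logical: add the residual draw? (Uses the current RNG
#'   stream.)
#' @return Next-year value(s), clamped to the equation bounds.
#' @export
predict_biomarker <- function(eq, prev, covariates = list(), rng = FALSE) {
  lo <- eq$bounds[1]; hi <- eq$bounds[2]
  if (eq$model_type == "linear") {
    mu <- bm_lp(eq$coefficients, prev, covariates)
    y <- if (rng) mu + rnorm(length(mu), 0, eq$residual_sd) else mu
  } else {
    pv <- clamp(prev, lo + 1e-9, hi - 1e-9)
    z <- qlogis((pv - lo) / (hi - lo))
    mu <- bm_lp(eq$coefficients, z, covariates)
    zz <- if (rng) mu + rnorm(length(mu), 0, eq$residual_sd) else mu
    y <- lo + (hi - lo) * plogis(zz)
  }
  clamp(y, lo, hi)
}

#' Fit a biomarker progression model
#'
#' Least squares (linear) or logit-scale least squares
#' (`logistic_transform`) on consecutive-year value pairs; the residual
#' standard deviation comes from the fit residuals.
#'
#' @param panel Data frame with columns `value` (next-year value), `prev`
#'   (previous-year value), `year` (integer year index) and any covariate
#'   columns named in `covariate_spec`.
#' @param biomarker Which biomarker the panel describes.
#' @param model_type As in [biomarker_equation()].
#' @param covariate_spec Covariate columns to include besides `prev`.
#' @param bounds Clamp bounds (needed for the logit rescaling).
#' @return A fitted [biomarker_equation()] with attributes `se` and
#'   `n_observations`.
#' @export
fit_biomarker_model <- function(panel, biomarker,
                                model_type = c("linear",
                                               "logistic_transform"),
                                covariate_spec = character(0),
                                bounds = NULL) {
  model_type <- match.arg(model_type)
  biomarker <- match.arg(biomarker, biomarker_names())
  bounds <- bounds %||% .biomarker_bounds[[biomarker]]
  if (length(unique(panel$year)) < 2L)
    stop2("need observations from at least 2 distinct years")
  lo <- bounds[1]; hi <- bounds[2]
  y <- panel$value; pv <- panel$prev
  if (model_type == "logistic_transform") {
    y <- qlogis((clamp(y, lo + 1e-9, hi - 1e-9) - lo) / (hi - lo))
    pv <- qlogis((clamp(pv, lo + 1e-9, hi - 1e-9) - lo) / (hi - lo))
  }
  X <- cbind(intercept = 1, prev = pv)
  for (v in covariate_spec) X <- cbind(X, as.numeric(panel[[v]]))
  colnames(X) <- c("intercept", "prev", covariate_spec)
  fit <- lm.fit(X, y)
  res <- fit$residuals
  df_res <- length(y) - ncol(X)
  sigma <- if (df_res > 0) sqrt(sum(res^2) / df_res) else 0
  eq <- biomarker_equation(biomarker, model_type,
                           coefficients = fit$coefficients,
                           residual_sd = sigma, bounds = bounds)
  XtXinv <- tryCatch(chol2inv(chol(crossprod(X))),
                     error = function(e) NULL)
  attr(eq, "se") <- if (!is.null(XtXinv)) setNames(
    sigma * sqrt(diag(XtXinv)), colnames(X)) else NULL
  attr(eq, "n_observations") <- length(y)
  eq
}

#' Advance all four biomarkers by one annual cycle
#'
#' Each biomarker is updated from the *previous* cycle's values, so the
#' update is order-independent. Diastolic BP has no progression model and
#' is carried unchanged.
#'
#' @param state Named list / data frame with current `bmi`, `hba1c`,
#'   `sbp`, `dbp`, `ldl` and the covariates the equations need.
#' @param catalog Named list of [biomarker_equation()]s covering all of
#'   [biomarker_names()].
#' @param rng `FALSE` (conditional-mean paths, the default policy) or
#'   `TRUE` (stochastic residuals).
#' @return Named list of updated biomarker vectors (incl. unchanged
#'   `dbp`).
#' @export
progress_biomarkers <- function(state, catalog, rng = FALSE) {
  missing_bm <- setdiff(biomarker_names(), names(catalog))
  if (length(missing_bm))
    stop2("biomarker catalog lacks: ", paste(missing_bm, collapse = ", "))
  out <- list()
  for (b in biomarker_names())
    out[[b]] <- predict_biomarker(catalog[[b]], state[[b]], state, rng)
  out$dbp <- state$dbp
  out
}

#' Default biomarker progression catalog (synthetic)
#'
#' Gentle mean-reverting upward drifts chosen as a plausible stated
#' world for an elderly East Asian type 2 diabetes population: slow
#' worsening of glycaemia and blood pressure with age, near-stationary
#' BMI and LDL. These are synthetic placeholder coefficients, not fitted
#' values from any restricted dataset; replace via
#' [read_biomarker_catalog()] for fidelity runs.
#'
#' @return Named list of [biomarker_equation()]s.
#' @export
default_biomarker_catalog <- function() {
  list(
    bmi = biomarker_equation("bmi", "linear",
      c(intercept = 0.10, prev = 0.996), residual_sd = 0.5),
    hba1c = biomarker_equation("hba1c", "linear",
      c(intercept = 0.28, prev = 0.97, duration = 0.001),
      residual_sd = 0.35),
    sbp = biomarker_equation("sbp", "linear",
      c(intercept = 3.0, prev = 0.97, age = 0.015), residual_sd = 6),
    ldl = biomarker_equation("ldl", "linear",
      c(intercept = 0.08, prev = 0.97), residual_sd = 0.25))
}
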