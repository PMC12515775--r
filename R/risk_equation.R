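#' Construct a risk equation for one outcome
#'
#' A risk equation couples a linear predictor \eqn{\beta'x} with a
#' parametric time-to-event family (or an annual logistic model for
#' mortality). Parameterisations, with \eqn{lp = \beta'x}:
#' \describe{
#'   \item{exponential}{proportional hazards, \eqn{H(t) = e^{lp} t}}
#'   \item{weibull}{proportional hazards, \eqn{H(t) = e^{lp} t^{k}},
#'     shape \eqn{k > 0}}
#'   \item{gompertz}{proportional hazards,
#'     \eqn{H(t) = e^{lp}(e^{\gamma t}-1)/\gamma}; \eqn{\gamma \to 0}
#'     recovers the exponential}
#'   \item{loglogistic}{accelerated failure time,
#'     \eqn{S(t) = 1/(1 + (t e^{-lp})^{1/\sigma})}, shape stores
#'     \eqn{\sigma > 0}}
#'   \item{lognormal}{accelerated failure time,
#'     \eqn{S(t) = 1 - \Phi((\log t - lp)/\sigma)}, shape stores
#'     \eqn{\sigma > 0}}
#'   \item{flexible_parametric}{Royston-Parmar style:
#'     \eqn{\log H(t) = s(\log t) + lp} with \eqn{s} a restricted
#'     (natural) cubic spline; requires monotone \eqn{s}}
#'   \item{logistic}{annual event probability
#'     \eqn{p = 1/(1+e^{-lp})}; used for mortality}
#' }
#'
#' @param outcome One of [outcome_names()].
#' @param family One of the seven families above.
#' @param coefficients Named numeric vector including `intercept`; the
#'   remaining names form the covariate specification, in order. For
#'   `flexible_parametric` the intercept lives in the spline, so
#'   `coefficients` holds covariate effects only.
#' @param shape Family shape parameter (Weibull `k`, Gompertz `gamma`,
#'   log-logistic / log-normal `sigma`). Ignored otherwise.
#' @param gamma Spline coefficients (flexible_parametric only); length
#'   `2 + number of internal knots`.
#' @param knots All spline knots on the log-time scale, boundary knots
#'   first and last (flexible_parametric only).
#' @return An object of class `risk_equation`.
#' @export
risk_equation <- function(outcome, family, coefficients,
                          shape = NULL, gamma = NULL, knots = NULL) {
  outcome <- match.arg(outcome, outcome_names())
  family <- match.arg(family, .all_families)
  if (is.null(names(coefficients)) && length(coefficients))
    stop2("coefficients must be named")
  if (family != "flexible_parametric" &&
      !"intercept" %in% names(coefficients))
    stop2("coefficients must include an `intercept` term")
  if (family %in% c("weibull", "loglogistic", "lognormal")) {
    if (is.null(shape) || shape <= 0)
      stop2(family, " family requires shape > 0")
  }
  if (family == "gompertz" && is.null(shape))
    stop2("gompertz family requires a shape (gamma) parameter")
  if (family == "flexible_parametric") {
    if (is.null(gamma) || is.null(knots))
      stop2("flexible_parametric requires `gamma` and `knots`")
    if (length(knots) < 2L || is.unsorted(knots, strictly = TRUE))
      stop2("knots must be strictly increasing with >= 2 entries")
    if (length(gamma) != length(knots))
      stop2("need length(gamma) == length(knots) ",
            "(intercept + linear + one per internal knot)")
    if (!spline_is_monotone(gamma, knots))
      stop2("fitted log cumulative-hazard spline is non-monotone; ",
            "equation rejected")
  }
  eq <- list(outcome = outcome, family = family,
             coefficients = coefficients, shape = shape,
             gamma = gamma, knots = knots,
             covariate_spec = setdiff(names(coefficients), "intercept"))
  class(eq) <- "risk_equation"
  eq
}

#' @export
print.risk_equation <- function(x, ...) {
  cat("<risk_equation>", x$outcome, "~", x$family, "\n")
  cat("  covariates:", if (length(x$covariate_spec))
    paste(x$covariate_spec, collapse = ", ") else "(intercept only)", "\n")
  if (!is.null(x$shape)) cat("  shape:", signif(x$shape, 5), "\n")
  invisible(x)
}

#' Linear predictor of a risk equation
#'
#' Computes `intercept + sum(beta_i * x_i)` over the equation's covariate
#' specification. Every covariate named in the equation must be present
#' (a missing one is an error, never silently zero); extra covariates in
#' `covariates` are ignored.
#'
#' @param eq A [risk_equation()].
#' @param covariates Named list / named numeric vector, or a data frame
#'   (one value per row).
#' @return Numeric vector of linear predictor values.
#' @export
linear_predictor <- function(eq, covariates) {
  need <- eq$covariate_spec
  if (is.data.frame(covariates)) {
    missing_cv <- setdiff(need, names(covariates))
    if (length(missing_cv))
      stop2("missing covariate(s) for ", eq$outcome, ": ",
            paste(missing_cv, collapse = ", "))
    lp <- rep(unname(eq$coefficients["intercept"] %0% 0),
              nrow(covariates))
    for (v in need) lp <- lp + eq$coefficients[[v]] *
        as.numeric(covariates[[v]])
    return(lp)
  }
  covariates <- as.list(covariates)
  missing_cv <- setdiff(need, names(covariates))
  if (length(missing_cv))
    stop2("missing covariate(s) for ", eq$outcome, ": ",
          paste(missing_cv, collapse = ", "))
  lp <- unname(eq$coefficients["intercept"] %0% 0)
  for (v in need) lp <- lp + eq$coefficients[[v]] *
      as.numeric(covariates[[v]])
  lp
}

# intercept may be absent (flexible_parametric): treat as 0
`%0%` <- function(a, b) if (length(a) == 0L || is.na(a)) b else a

# --- restricted cubic spline on log time (Royston-Parmar style) ---------

rcs_basis <- function(x, knots) {
  kmin <- knots[1]; kmax <- knots[length(knots)]
  internal <- knots[-c(1, length(knots))]
  out <- cbind(1, x)
  for (kj in internal) {
    lam <- (kmax - kj) / (kmax - kmin)
    vj <- pmax(x - kj, 0)^3 - lam * pmax(x - kmin, 0)^3 -
      (1 - lam) * pmax(x - kmax, 0)^3
    out <- cbind(out, vj)
  }
  out
}

rcs_deriv <- function(x, knots) {
  kmin <- knots[1]; kmax <- knots[length(knots)]
  internal <- knots[-c(1, length(knots))]
  out <- cbind(0, 1)[rep(1, length(x)), , drop = FALSE]
  for (kj in internal) {
    lam <- (kmax - kj) / (kmax - kmin)
    dj <- 3 * pmax(x - kj, 0)^2 - 3 * lam * pmax(x - kmin, 0)^2 -
      3 * (1 - lam) * pmax(x - kmax, 0)^2
    out <- cbind(out, dj)
  }
  out
}

spline_eval <- function(gamma, knots, x) drop(rcs_basis(x, knots) %*% gamma)
spline_slope <- function(gamma, knots, x) drop(rcs_deriv(x, knots) %*% gamma)

spline_is_monotone <- function(gamma, knots) {
  grid <- seq(knots[1] - 2, knots[length(knots)] + 2, length.out = 401)
  all(spline_slope(gamma, knots, grid) > 0)
}

# --- cumulative hazard / survival / hazard per family -------------------

cumulative_hazard <- function(eq, lp, t) {
  fam <- eq$family
  if (fam == "logistic")
    stop2("logistic is an annual-probability family, not a survival family")
  if (any(t < 0)) stop2("t must be >= 0")
  m <- max(length(t), length(lp))
  t <- rep_len(t, m); lp <- rep_len(lp, m)
  switch(fam,
    exponential = exp(lp) * t,
    weibull = exp(lp) * t^eq$shape,
    gompertz = {
      g <- eq$shape
      if (abs(g) < 1e-8) exp(lp) * t * (1 + g * t / 2)
      else exp(lp) * (exp(g * t) - 1) / g
    },
    loglogistic = {
      H <- -log(plogis((lp - suppressWarnings(log(t))) / eq$shape))
      ifelse(t == 0, 0, H)
    },
    lognormal = {
      H <- -pnorm((suppressWarnings(log(t)) - lp) / eq$shape,
                  lower.tail = FALSE, log.p = TRUE)
      ifelse(t == 0, 0, H)
    },
    flexible_parametric = {
      H <- exp(spline_eval(eq$gamma, eq$knots,
                           suppressWarnings(log(t))) + lp)
      ifelse(t == 0, 0, H)
    })
}

hazard_rate <- function(eq, lp, t) {
  fam <- eq$family
  m <- max(length(t), length(lp))
  t <- rep_len(t, m); lp <- rep_len(lp, m)
  switch(fam,
    exponential = exp(lp) + 0 * t,
    weibull = exp(lp) * eq$shape * t^(eq$shape - 1),
    gompertz = exp(lp) * exp(eq$shape * t),
    loglogistic = {
      z <- (log(t) - lp) / eq$shape
      plogis(z) / (eq$shape * t)
    },
    lognormal = {
      z <- (log(t) - lp) / eq$shape
      dnorm(z) / (eq$shape * t *
                    pnorm(z, lower.tail = FALSE))
    },
    flexible_parametric = {
      x <- log(t)
      H <- exp(spline_eval(eq$gamma, eq$knots, x) + lp)
      H * spline_slope(eq$gamma, eq$knots, x) / t
    },
    stop2("no hazard for family ", fam))
}

#' Survival function of a risk equation
#'
#' @param eq A [risk_equation()] with a survival family.
#' @param lp Linear predictor value(s), from [linear_predictor()].
#' @param t Time(s) in years, `t >= 0`. `S(0) = 1` for every family.
#' @return Survival probabilities in `[0, 1]`, non-increasing in `t`.
#' @export
survival_prob <- function(eq, lp, t) {
  H <- cumulative_hazard(eq, lp, t)
  clamp(exp(-H), 0, 1)
}

#' Flexible parametric (spline-on-log-time) survival
#'
#' Convenience wrapper asserting the flexible-parametric family; the log
#' cumulative hazard is a restricted cubic spline in `log t` shifted by
#' the linear predictor, and `S(0) = 1` by convention.
#'
#' @inheritParams survival_prob
#' @return Survival probabilities.
#' @export
retinopathy_survival <- function(eq, lp, t) {
  if (eq$family != "flexible_parametric")
    stop2("equation must use the flexible_parametric family")
  survival_prob(eq, lp, t)
}

#' Annual mortality probability (logistic equation)
#'
#' @param eq A [risk_equation()] with `family = "logistic"`.
#' @param covariates Named covariate values (vector, list or data frame).
#' @return Probability `1/(1 + exp(-lp))`.
#' @export
mortality_probability <- function(eq, covariates) {
  if (eq$family != "logistic")
    stop2("mortality_probability requires a logistic-family equation, got ",
          eq$family)
  plogis(linear_predictor(eq, covariates))
}

#' Annual event probability from conditional survival
#'
#' The discrete annual-cycle probability of an event in `[t, t+1)` given
#' event-free survival to `t`: `p = 1 - S(t+1)/S(t)`, clamped to
#' `[0, 1]`. For a logistic (mortality) equation this delegates to
#' [mortality_probability()] (the annual probability is then
#' time-constant by construction). If `S(t) = 0` the probability is 1,
#' with a warning.
#'
#' @param eq A [risk_equation()].
#' @param covariates Named covariate values (vector, list or data frame).
#' @param t Cycle start time (years since model entry), `t >= 0`.
#' @return Probability vector.
#' @export
annual_event_probability <- function(eq, covariates, t) {
  if (eq$family == "logistic")
    return(mortality_probability(eq, covariates))
  if (any(t < 0)) stop2("t must be >= 0")
  lp <- linear_predictor(eq, covariates)
  s0 <- survival_prob(eq, lp, t)
  s1 <- survival_prob(eq, lp, t + 1)
  p <- ifelse(s0 == 0, 1, 1 - s1 / s0)
  if (any(s0 == 0))
    warning("S(t) = 0 for some persons; annual probability set to 1")
  clamp(p, 0, 1)
}

# inverse-CDF event-time sampling: solve S(T) = u
sample_event_time <- function(eq, lp, u) {
  fam <- eq$family
  switch(fam,
    exponential = -log(u) / exp(lp),
    weibull = (-log(u) / exp(lp))^(1 / eq$shape),
    gompertz = {
      g <- eq$shape
      if (abs(g) < 1e-8) -log(u) / exp(lp)
      else {
        arg <- 1 + g * (-log(u)) / exp(lp)
        ifelse(arg <= 0, Inf, log(pmax(arg, 1e-300)) / g)
      }
    },
    loglogistic = exp(lp) * (1 / u - 1)^eq$shape,
    lognormal = exp(lp + eq$shape * qnorm(1 - u)),
    flexible_parametric = {
      target <- log(-log(u))  # solve s(log t) + lp = log(-log u)
      vapply(seq_along(u), function(i) {
        rhs <- target[i] - (if (length(lp) > 1L) lp[i] else lp)
        f <- function(x) spline_eval(eq$gamma, eq$knots, x) - rhs
        lo <- eq$knots[1] - 20; hi <- eq$knots[length(eq$knots)] + 20
        if (f(hi) < 0) return(Inf)
        if (f(lo) > 0) return(exp(lo))
        exp(uniroot(f, c(lo, hi), tol = 1e-10)$root)
      }, numeric(1))
    },
    stop2("cannot sample event times from family ", fam))
}
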