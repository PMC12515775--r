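#' Fit a risk equation by maximum likelihood
#'
#' Fits one parametric family to a right-censored event panel. For
#' survival families the panel holds one row per subject with columns
#' `time` (> 0) and `status` (1 event, 0 censored) plus covariates; the
#' log-likelihood is `sum(d * log h(t) - H(t))`. For the logistic family
#' the panel is person-year rows with a binary `status` per row and the
#' model is ordinary logistic regression. Optimiser: BFGS with fixed
#' tolerances, recorded in the result for reproducibility.
#'
#' @param panel Data frame with `time`, `status` and the covariates named
#'   in `covariate_spec`.
#' @param family One of the supported families.
#' @param covariate_spec Character vector of covariate column names
#'   (possibly empty for an intercept-only model).
#' @param outcome Outcome name attached to the fitted equation.
#' @param n_internal_knots Internal knot count for the flexible
#'   parametric family (knots at quantiles of log event time; boundary
#'   knots at min / max event times).
#' @return A `fit_result`: list with `equation`, `log_likelihood`, `aic`,
#'   `n_events`, `n_observations`, `convergence_flag`, `se`,
#'   `optimizer_control`.
#' @export
fit_risk_equation <- function(panel, family, covariate_spec = character(0),
                              outcome = "mortality",
                              n_internal_knots = 1L) {
  family <- match.arg(family, .all_families)
  if (!all(c("time", "status") %in% names(panel)))
    stop2("panel must have `time` and `status` columns")
  missing_cv <- setdiff(covariate_spec, names(panel))
  if (length(missing_cv))
    stop2("panel lacks covariate(s): ", paste(missing_cv, collapse = ", "))
  d <- as.numeric(panel$status)
  if (sum(d) < 1) stop2("panel contains zero events; cannot fit")
  X <- if (length(covariate_spec))
    as.matrix(panel[, covariate_spec, drop = FALSE]) else
      matrix(numeric(0), nrow(panel), 0)
  storage.mode(X) <- "double"

  if (family == "logistic") return(fit_logistic(panel, X, covariate_spec,
                                                outcome))

  tt <- as.numeric(panel$time)
  if (any(tt <= 0)) stop2("survival panel requires time > 0")
  ctrl <- list(maxit = 1000, reltol = 1e-12)

  if (family == "flexible_parametric") {
    return(fit_fpm(tt, d, X, covariate_spec, outcome, n_internal_knots,
                   ctrl))
  }

  nll <- make_nll(family, tt, d, X)
  rate0 <- log(sum(d) / sum(tt))
  start <- switch(family,
    exponential = c(rate0, rep(0, ncol(X))),
    weibull = c(rate0, rep(0, ncol(X)), 0),           # last: log shape
    gompertz = c(rate0, rep(0, ncol(X)), 0.01),       # last: gamma
    loglogistic = c(-rate0, rep(0, ncol(X)), 0),      # AFT scale-ish
    lognormal = c(-rate0, rep(0, ncol(X)), 0))        # last: log sigma
  opt <- optim(start, nll, method = "BFGS", control = ctrl,
               hessian = TRUE)
  k <- length(start)
  beta <- setNames(opt$par[seq_len(1 + ncol(X))],
                   c("intercept", covariate_spec))
  shape <- switch(family,
    exponential = NULL,
    weibull = exp(opt$par[k]),
    gompertz = opt$par[k],
    loglogistic = exp(opt$par[k]),
    lognormal = exp(opt$par[k]))
  eq <- risk_equation(outcome, family, beta, shape = shape)
  se <- tryCatch(sqrt(diag(solve(opt$hessian))), error = function(e)
    rep(NA_real_, k))
  fit_result(eq, -opt$value, k, sum(d), nrow(panel),
             opt$convergence == 0, se, ctrl)
}

fit_result <- function(eq, loglik, k, n_events, n_obs, converged, se,
                       ctrl) {
  out <- list(equation = eq, log_likelihood = loglik,
              aic = 2 * k - 2 * loglik, n_parameters = k,
              n_events = n_events, n_observations = n_obs,
              convergence_flag = converged, se = se,
              optimizer_control = ctrl)
  class(out) <- "fit_result"
  out
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>", x$equation$outcome, "~", x$equation$family,
      sprintf("| logLik %.2f | AIC %.2f | events %d/%d | %s\n",
              x$log_likelihood, x$aic, x$n_events, x$n_observations,
              if (x$convergence_flag) "converged" else "NOT CONVERGED"))
  invisible(x)
}

# negative log-likelihood factory for the closed-form families;
# parameter layout: (intercept, beta..., [transformed shape])
make_nll <- function(family, tt, d, X) {
  lt <- log(tt)
  function(par) {
    nb <- 1 + ncol(X)
    lp <- par[1] + if (ncol(X)) drop(X %*% par[2:nb]) else 0
    ll <- switch(family,
      exponential = d * lp - exp(lp) * tt,
      weibull = {
        k <- exp(par[nb + 1])
        d * (lp + log(k) + (k - 1) * lt) - exp(lp) * tt^k
      },
      gompertz = {
        g <- par[nb + 1]
        H <- if (abs(g) < 1e-10) exp(lp) * tt else
          exp(lp) * (exp(g * tt) - 1) / g
        d * (lp + g * tt) - H
      },
      loglogistic = {
        s <- exp(par[nb + 1])
        z <- (lt - lp) / s
        logS <- plogis(z, lower.tail = FALSE, log.p = TRUE)
        logf <- z - log(s) - lt + 2 * logS
        d * logf + (1 - d) * logS
      },
      lognormal = {
        s <- exp(par[nb + 1])
        z <- (lt - lp) / s
        logS <- pnorm(z, lower.tail = FALSE, log.p = TRUE)
        logf <- dnorm(z, log = TRUE) - log(s) - lt
        d * logf + (1 - d) * logS
      })
    v <- -sum(ll)
    if (!is.finite(v)) 1e12 else v
  }
}

fit_fpm <- function(tt, d, X, covariate_spec, outcome, n_internal_knots,
                    ctrl) {
  ev <- tt[d == 1]
  bk <- log(range(ev))
  if (diff(bk) <= 0) stop2("degenerate event-time range for spline knots")
  internal <- if (n_internal_knots > 0)
    quantile(log(ev), probs = seq_len(n_internal_knots) /
               (n_internal_knots + 1), names = FALSE) else numeric(0)
  knots <- c(bk[1], internal, bk[2])
  m <- length(knots)
  lt <- log(tt)
  B <- rcs_basis(lt, knots)
  Bd <- rcs_deriv(lt, knots)
  nll <- function(par) {
    g <- par[seq_len(m)]
    beta <- if (ncol(X)) par[(m + 1):(m + ncol(X))] else numeric(0)
    lp <- if (ncol(X)) drop(X %*% beta) else 0
    s <- drop(B %*% g)
    sp <- drop(Bd %*% g)
    if (any(sp[d == 1] <= 0)) return(1e12)
    eta <- s + lp
    ll <- d * (log(pmax(sp, 1e-300)) - lt + eta) - exp(eta)
    v <- -sum(ll)
    if (!is.finite(v)) 1e12 else v
  }
  rate0 <- log(sum(d) / sum(tt))
  start <- c(rate0, 1, rep(0, m - 2), rep(0, ncol(X)))
  opt <- optim(start, nll, method = "BFGS", control = ctrl, hessian = TRUE)
  g <- opt$par[seq_len(m)]
  if (!spline_is_monotone(g, knots))
    stop2("fitted log cumulative-hazard spline is non-monotone; ",
          "fit rejected")
  beta <- setNames(if (ncol(X)) opt$par[(m + 1):(m + ncol(X))] else
    numeric(0), covariate_spec)
  eq <- risk_equation(outcome, "flexible_parametric", beta,
                      gamma = g, knots = knots)
  se <- tryCatch(sqrt(diag(solve(opt$hessian))), error = function(e)
    rep(NA_real_, length(start)))
  fit_result(eq, -opt$value, length(start), sum(d), length(tt),
             opt$convergence == 0, se, ctrl)
}

fit_logistic <- function(panel, X, covariate_spec, outcome) {
  d <- as.numeric(panel$status)
  Xi <- cbind(intercept = 1, X)
  fit <- suppressWarnings(glm.fit(Xi, d, family = binomial()))
  beta <- setNames(fit$coefficients, c("intercept", covariate_spec))
  eq <- risk_equation(outcome, "logistic", beta)
  ll <- sum(d * log(pmax(fit$fitted.values, 1e-300)) +
              (1 - d) * log(pmax(1 - fit$fitted.values, 1e-300)))
  se <- tryCatch({
    w <- fit$fitted.values * (1 - fit$fitted.values)
    sqrt(diag(solve(crossprod(Xi * sqrt(w)))))
  }, error = function(e) rep(NA_real_, ncol(Xi)))
  fit_result(eq, ll, ncol(Xi), sum(d), nrow(panel), fit$converged, se,
             list(method = "glm.fit IRLS"))
}

#' Select the best-fitting family by AIC
#'
#' Fits every candidate family to the same panel and returns the
#' converged fit with the smallest AIC (`2k - 2 logL`). Ties within
#' `1e-9` go to the family listed first by the caller. The full
#' per-family AIC table is attached as attribute `aic_table` for audit.
#'
#' @inheritParams fit_risk_equation
#' @param families Character vector of candidate families, in preference
#'   order.
#' @return The winning `fit_result` with attribute `aic_table`.
#' @export
select_model <- function(panel, families, covariate_spec = character(0),
                         outcome = "mortality", n_internal_knots = 1L) {
  if (!length(families)) stop2("need at least one candidate family")
  fits <- lapply(families, function(f)
    tryCatch(fit_risk_equation(panel, f, covariate_spec, outcome,
                               n_internal_knots),
             error = function(e) e))
  ok <- vapply(fits, function(f) inherits(f, "fit_result") &&
                 f$convergence_flag, logical(1))
  tab <- data.frame(
    family = families,
    aic = vapply(fits, function(f)
      if (inherits(f, "fit_result")) f$aic else NA_real_, numeric(1)),
    log_likelihood = vapply(fits, function(f)
      if (inherits(f, "fit_result")) f$log_likelihood else NA_real_,
      numeric(1)),
    converged = ok)
  if (!any(ok)) stop2("no candidate family converged")
  aics <- tab$aic
  aics[!ok] <- Inf
  best <- which(aics <= min(aics) + 1e-9)[1]  # tie -> first in order
  out <- fits[[best]]
  attr(out, "aic_table") <- tab
  out
}
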