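#' Generate a longitudinal event panel from known risk equations
#'
#' Fixture generator for fitting and recovery tests: draws event times
#' from the stated survival family by inverse-CDF sampling conditional on
#' each person's covariates, with administrative censoring at `horizon`.
#' Survival-family outcomes yield one row per person (`time`, `status`);
#' a logistic (annual mortality) outcome yields person-year rows, one per
#' year at risk, with a binary `status` — the layout
#' [fit_risk_equation()] expects for that family.
#'
#' @param cohort Cohort data frame supplying covariates.
#' @param true_equations Named list of [risk_equation()]s (name = outcome).
#' @param horizon Administrative censoring time in years, `>= 1`.
#' @param seed Integer seed.
#' @return A data frame with columns `person_id`, `outcome`, `time`,
#'   `status` and the union of covariates used by the equations.
#' @export
generate_event_panel <- function(cohort, true_equations, horizon, seed) {
  if (horizon < 1) stop2("horizon must be >= 1")
  if (is.null(names(true_equations)) ||
      !all(vapply(true_equations, inherits, logical(1), "risk_equation")))
    stop2("true_equations must be a named list of risk_equation objects")
  set.seed(seed)
  n <- nrow(cohort)
  covs <- unique(unlist(lapply(true_equations,
                               function(e) e$covariate_spec)))
  out <- vector("list", length(true_equations))
  for (i in seq_along(true_equations)) {
    eq <- true_equations[[i]]
    if (eq$family == "logistic") {
      p <- mortality_probability(eq, cohort)
      rows <- lapply(seq_len(n), function(j) {
        yr <- 0L; dead <- FALSE
        while (yr < horizon && !dead) {
          yr <- yr + 1L
          dead <- runif(1) < p[j]
        }
        k <- yr
        data.frame(person_id = cohort$person_id[j],
                   outcome = eq$outcome,
                   time = seq_len(k),
                   status = c(rep(0L, k - 1L), as.integer(dead)))
      })
      py <- do.call(rbind, rows)
      idx <- match(py$person_id, cohort$person_id)
      for (v in covs) py[[v]] <- as.numeric(cohort[[v]])[idx]
      out[[i]] <- py
    } else {
      lp <- linear_predictor(eq, cohort)
      u <- runif(n)
      T <- sample_event_time(eq, lp, u)
      df <- data.frame(person_id = cohort$person_id,
                       outcome = eq$outcome,
                       time = pmin(T, horizon),
                       status = as.integer(T <= horizon))
      for (v in covs) df[[v]] <- as.numeric(cohort[[v]])
      out[[i]] <- df
    }
  }
  do.call(rbind, out)
}
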