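# shared fixtures: everything is built in code at test time
library(data.table)

small_cohort <- function(n = 200, seed = 99) {
  generate_cohort(cohort_profile(n = n, seed = seed))
}

# covariate frame for fitting tests
sim_covariates <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(person_id = sprintf("S%06d", seq_len(n)),
             x1 = rnorm(n), x2 = rbinom(n, 1, 0.4))
}

# a 13-outcome catalog where nothing ever happens (zero hazards,
# zero mortality): the null model
null_equation_catalog <- function() {
  eqs <- lapply(outcome_names(), function(o) {
    fam <- if (o == "mortality") "logistic" else "exponential"
    risk_equation(o, fam, c(intercept = -Inf))
  })
  setNames(eqs, outcome_names())
}

# catalog with a single active complication at constant annual
# probability p (exponential hazard), everything else off
single_complication_catalog <- function(outcome, p_annual,
                                        p_mortality = 0) {
  eqs <- null_equation_catalog()
  eqs[[outcome]] <- risk_equation(outcome, "exponential",
                                  c(intercept = log(-log(1 - p_annual))))
  if (p_mortality > 0)
    eqs$mortality <- risk_equation("mortality", "logistic",
                                   c(intercept = qlogis(p_mortality)))
  eqs
}

# identity biomarker catalog: next value = previous value
identity_biomarker_catalog <- function() {
  setNames(lapply(biomarker_names(), function(b)
    biomarker_equation(b, "linear", c(intercept = 0, prev = 1))),
    biomarker_names())
}

# drift-only biomarker catalog: next = prev + drift
drift_biomarker_catalog <- function(drift = 0.2) {
  setNames(lapply(biomarker_names(), function(b)
    biomarker_equation(b, "linear", c(intercept = drift, prev = 1))),
    biomarker_names())
}

# hand-built one-person ledger for economics arithmetic tests
toy_ledger <- function(cycles, alive_frac = rep(1, length(cycles)),
                       events = list(), bmi = 24) {
  dt <- data.table::data.table(
    person_id = "T1", sex = factor("female", c("female", "male")),
    cycle = cycles, alive_frac = alive_frac,
    died = c(rep(FALSE, length(cycles) - 1),
             alive_frac[length(cycles)] < 1),
    bmi = bmi, hba1c = 7, sbp = 120, dbp = 70, ldl = 2)
  for (o in complication_names())
    dt[[paste0("ev_", o)]] <- cycles %in% (events[[o]] %||% integer(0))
  dt
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent density/survival oracles built from stats' distributions
# (or first principles), used for quadrature checks
oracle_funs <- function(family, lp, shape) {
  switch(family,
    exponential = list(f = function(t) dexp(t, exp(lp)),
                       S = function(t) pexp(t, exp(lp),
                                            lower.tail = FALSE)),
    weibull = {
      sc <- exp(-lp / shape)
      list(f = function(t) dweibull(t, shape, sc),
           S = function(t) pweibull(t, shape, sc, lower.tail = FALSE))
    },
    lognormal = list(
      f = function(t) dlnorm(t, lp, shape),
      S = function(t) plnorm(t, lp, shape, lower.tail = FALSE)),
    loglogistic = list(
      f = function(t) dlogis((log(t) - lp) / shape) / (shape * t),
      S = function(t) plogis((lp - log(t)) / shape)),
    gompertz = list(
      f = function(t) exp(lp + shape * t) *
        exp(-exp(lp) * (exp(shape * t) - 1) / shape),
      S = function(t) exp(-exp(lp) * (exp(shape * t) - 1) / shape)))
}

# printed baseline target-failure counts (published Table-1-style input)
published_table1_counts <- function() {
  m <- rbind(hba1c = c(250685, 126931, 123754),
             bp = c(359968, 181364, 178604),
             ldl = c(99307, 45838, 53469),
             combined = c(447310, 222991, 224319))
  colnames(m) <- c("all", "male", "female")
  m
}
published_population_n <- 526672
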