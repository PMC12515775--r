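test_that("linear predictor is intercept + beta.x with strict covariates", {
  eq <- risk_equation("neuropathy", "exponential",
                      c(intercept = -1, hba1c = 0.2))
  expect_equal(linear_predictor(eq, c(hba1c = 0)), -1)
  expect_equal(linear_predictor(eq, c(hba1c = 7)), 0.4)
  expect_equal(linear_predictor(eq, c(hba1c = 7, junk = 99)), 0.4)
  expect_error(linear_predictor(eq, c(sbp = 120)), "hba1c")
  df <- data.frame(hba1c = c(0, 7))
  expect_equal(linear_predictor(eq, df), c(-1, 0.4))
})

test_that("survival closed forms and family nesting hold", {
  grid <- c(0.5, 1, 2, 5, 10)
  eqe <- risk_equation("neuropathy", "exponential", c(intercept = 0))
  expect_equal(survival_prob(eqe, log(0.1), 10), exp(-1))
  expect_equal(survival_prob(eqe, log(0.1), 0), 1)
  # Weibull shape 1 == exponential on a grid
  eqw <- risk_equation("neuropathy", "weibull", c(intercept = 0),
                       shape = 1)
  expect_equal(survival_prob(eqw, -1.3, grid),
               survival_prob(eqe, -1.3, grid))
  # Gompertz shape -> 0 == exponential
  eqg <- risk_equation("neuropathy", "gompertz", c(intercept = 0),
                       shape = 1e-12)
  expect_equal(survival_prob(eqg, -1.3, grid),
               survival_prob(eqe, -1.3, grid), tolerance = 1e-8)
  # S(0) = 1 for every survival family
  fams <- list(
    risk_equation("neuropathy", "loglogistic", c(intercept = 0.5),
                  shape = 0.7),
    risk_equation("neuropathy", "lognormal", c(intercept = 0.5),
                  shape = 1.1),
    risk_equation("neuropathy", "gompertz", c(intercept = -2),
                  shape = 0.1))
  for (eq in fams) expect_equal(survival_prob(eq, 0.3, 0), 1)
  expect_error(survival_prob(eqe, 0, -1), ">= 0")
})

test_that("survival axioms hold over random parameterisations", {
  set.seed(42)
  grid <- seq(0, 15, by = 0.25)
  for (rep in 1:20) {
    fam <- sample(c("exponential", "weibull", "gompertz", "loglogistic",
                    "lognormal"), 1)
    shape <- switch(fam, exponential = NULL, gompertz = runif(1, -0.3, 0.5),
                    runif(1, 0.4, 2.5))
    eq <- risk_equation("neuropathy", fam,
                        c(intercept = runif(1, -4, 0)), shape = shape)
    lp <- linear_predictor(eq, list())
    S <- survival_prob(eq, lp, grid)
    expect_true(all(S >= 0 & S <= 1))
    expect_true(all(diff(S) <= 1e-12))
    expect_equal(S[1], 1)
    p <- annual_event_probability(eq, c(x = 0), 0:12)
    expect_true(all(p >= 0 & p <= 1))
    # sum over cycles of S(t) p(t) = total event probability <= 1
    St <- survival_prob(eq, lp, 0:12)
    expect_lte(sum(St[1:12] * p[1:12]), 1 + 1e-12)
  }
})

test_that("mortality probability is the logistic transform and guarded", {
  eq <- risk_equation("mortality", "logistic", c(intercept = 0, x = 1))
  expect_equal(mortality_probability(eq, c(x = 0)), 0.5)
  expect_equal(mortality_probability(eq, c(x = log(3))), 0.75)
  expect_equal(mortality_probability(eq, c(x = -745)), 0)
  expect_equal(mortality_probability(eq, c(x = 745)), 1)
  eqs <- risk_equation("neuropathy", "exponential", c(intercept = 0))
  expect_error(mortality_probability(eqs, c(x = 0)), "logistic")
  expect_error(survival_prob(eq, 0, 1), "not a survival family")
})

test_that("annual probability: memorylessness and monotone hazard", {
  lam <- 0.07
  eqe <- risk_equation("neuropathy", "exponential",
                       c(intercept = log(lam)))
  p <- annual_event_probability(eqe, list(), 0:9)
  expect_equal(p, rep(1 - exp(-lam), 10))
  eqw <- risk_equation("neuropathy", "weibull", c(intercept = -4),
                       shape = 2)
  pw <- annual_event_probability(eqw, list(), 0:9)
  expect_true(all(diff(pw) > 0))  # increasing hazard => increasing p
})

test_that("flexible parametric survival reduces to Weibull and is monotone", {
  # gamma beyond the linear term zero => log H = g0 + g1 log t (Weibull)
  eqf <- risk_equation("retinopathy", "flexible_parametric",
                       setNames(numeric(0), character(0)),
                       gamma = c(-3, 1.4), knots = log(c(0.3, 8)))
  eqw <- risk_equation("retinopathy", "weibull", c(intercept = -3),
                       shape = 1.4)
  grid <- c(0.1, 0.5, 1, 3, 7, 10)
  # the spline intercept g0 = -3 folds into the Weibull linear predictor
  expect_equal(retinopathy_survival(eqf, 0.2, grid),
               survival_prob(eqw, 0.2 - 3, grid), tolerance = 1e-12)
  # default catalog equation: S(0)=1, monotone on (0, 10]
  eq <- default_equation_catalog()$retinopathy
  lp <- linear_predictor(eq, c(hba1c = 8, duration = 5))
  S <- retinopathy_survival(eq, lp, seq(0, 10, by = 0.1))
  expect_equal(S[1], 1)
  expect_true(all(diff(S) <= 0))
  expect_error(retinopathy_survival(eqw, 0, 1), "flexible_parametric")
  # non-monotone spline is rejected at construction
  expect_error(risk_equation("retinopathy", "flexible_parametric",
                             setNames(numeric(0), character(0)),
                             gamma = c(-3, -1), knots = log(c(0.3, 8))),
               "non-monotone")
})

test_that("annual probability equals the quadrature oracle to 1e-8", {
  set.seed(2024)
  fams <- c("exponential", "weibull", "gompertz", "loglogistic",
            "lognormal")
  for (fam in fams) {
    for (i in 1:25) {
      lp <- runif(1, -4, -0.5)
      shape <- switch(fam, exponential = NULL,
                      gompertz = runif(1, -0.2, 0.4),
                      runif(1, 0.5, 2))
      eq <- risk_equation("neuropathy", fam, c(intercept = lp),
                          shape = shape)
      t0 <- runif(1, 0.2, 5)
      p <- annual_event_probability(eq, list(), t0)
      orc <- oracle_funs(fam, lp, shape)
      p_orc <- integrate(orc$f, t0, t0 + 1, rel.tol = 1e-12)$value /
        orc$S(t0)
      expect_lt(abs(p - p_orc), 1e-8)
    }
  }
})

test_that("flexible parametric annual probability matches quadrature", {
  eq <- default_equation_catalog()$retinopathy
  lp <- linear_predictor(eq, c(hba1c = 8.5, duration = 6))
  for (t0 in c(0.5, 2, 4.5)) {
    p <- 1 - survival_prob(eq, lp, t0 + 1) / survival_prob(eq, lp, t0)
    # oracle: integrate -dS/dt by central finite differences
    f <- function(u) {
      h <- 1e-6
      (survival_prob(eq, lp, u - h) - survival_prob(eq, lp, u + h)) /
        (2 * h)
    }
    p_orc <- integrate(f, t0, t0 + 1, rel.tol = 1e-11)$value /
      survival_prob(eq, lp, t0)
    expect_lt(abs(p - p_orc), 1e-8)
  }
})

test_that("exponential MLE has its closed form and AIC its definition", {
  co <- sim_covariates(5000)
  eq <- risk_equation("neuropathy", "exponential",
                      c(intercept = log(0.08)))
  pan <- generate_event_panel(co, list(neuropathy = eq), 10, 3)
  f <- fit_risk_equation(pan, "exponential")
  expect_equal(unname(exp(f$equation$coefficients["intercept"])),
               sum(pan$status) / sum(pan$time), tolerance = 1e-6)
  expect_equal(f$aic, 2 * f$n_parameters - 2 * f$log_likelihood)
  expect_lte(f$n_events, f$n_observations)
  pan0 <- pan; pan0$status <- 0
  expect_error(fit_risk_equation(pan0, "exponential"), "zero events")
})

test_that("fitted models agree with survreg as an external oracle", {
  skip_if_not_installed("survival")
  co <- sim_covariates(8000, seed = 5)
  eq <- risk_equation("cataract", "lognormal",
                      c(intercept = 2, x1 = 0.5), shape = 0.8)
  pan <- generate_event_panel(co, list(cataract = eq), 10, 21)
  f <- fit_risk_equation(pan, "lognormal", "x1", outcome = "cataract")
  sr <- survival::survreg(survival::Surv(time, status) ~ x1, data = pan,
                          dist = "lognormal")
  expect_equal(unname(f$equation$coefficients["intercept"]),
               unname(coef(sr)[1]), tolerance = 1e-4)
  expect_equal(unname(f$equation$coefficients["x1"]),
               unname(coef(sr)[2]), tolerance = 1e-4)
  expect_equal(f$equation$shape, sr$scale, tolerance = 1e-4)
})

test_that("AIC selection returns the generating family and honours ties", {
  co <- sim_covariates(2000, seed = 8)
  eq <- risk_equation("heart_failure", "gompertz",
                      c(intercept = -4, x1 = 0.3), shape = 0.35)
  pan <- generate_event_panel(co, list(heart_failure = eq), 10, 77)
  # single candidate -> that candidate
  one <- select_model(pan, "weibull", "x1", "heart_failure")
  expect_equal(one$equation$family, "weibull")
  # exact tie (same family twice) -> first in caller's order
  tie <- select_model(pan, c("exponential", "exponential"), "x1",
                      "heart_failure")
  expect_equal(attr(tie, "aic_table")$aic[1],
               attr(tie, "aic_table")$aic[2])
  expect_equal(tie$equation$family, "exponential")
})

test_that("Gompertz data select Gompertz in a majority of replicate panels", {
  fams <- c("exponential", "weibull", "gompertz", "loglogistic",
            "lognormal")
  wins <- 0L
  for (r in 1:20) {
    co <- sim_covariates(10000, seed = 100 + r)
    eq <- risk_equation("heart_failure", "gompertz",
                        c(intercept = -4, x1 = 0.3), shape = 0.35)
    pan <- generate_event_panel(co, list(heart_failure = eq), 10,
                                500 + r)
    sm <- select_model(pan, fams, "x1", "heart_failure")
    wins <- wins + (sm$equation$family == "gompertz")
  }
  expect_gt(wins, 10)
})
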