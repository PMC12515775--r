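test_that("annual utility is additive with event/subsequent decrements", {
  ucat <- utility_catalog(baseline_utility = 0.85,
                          excess_weight_decrement = 0)
  expect_equal(annual_utility(character(0), character(0), 24, ucat),
               0.85)
  # stroke event-year 0.15? use catalog values: build an explicit one
  ucat2 <- utility_catalog(
    baseline_utility = 0.85,
    decrements = list(cerebrovascular_disease = c(0.10, 0.06),
                      retinopathy = c(0.05, 0.04)),
    excess_weight_decrement = 0)
  expect_equal(annual_utility("retinopathy", "cerebrovascular_disease",
                              24, ucat2), 0.85 - 0.10 - 0.04)
  # decrements past baseline floor at 0
  ucat3 <- utility_catalog(baseline_utility = 0.3,
                           decrements = list(heart_failure = c(0.9, 0.5)),
                           excess_weight_decrement = 0)
  expect_equal(annual_utility(character(0), "heart_failure", 24, ucat3),
               0)
  expect_error(annual_utility("gout", character(0), 24, ucat), "unknown")
  # excess-weight decrement applies above the BMI threshold
  ucat4 <- utility_catalog(baseline_utility = 0.85,
                           excess_weight_decrement = 0.01,
                           bmi_threshold = 25)
  expect_equal(annual_utility(character(0), character(0), 28, ucat4),
               0.85 - 0.03)
})

test_that("discounting: closed forms and the 10-year annuity factor", {
  expect_equal(discount_factor(1:10, 0), rep(1, 10))
  expect_equal(discount_factor(1, 0.03), 1)
  expect_equal(discount_factor(2, 0.03), 1 / 1.03)
  annuity <- (1 - 1.03^-10) / 0.03 * 1.03   # first-year-undiscounted
  expect_equal(sum(discount_factor(1:10, 0.03)), annuity,
               tolerance = 1e-12)
  expect_error(discount_factor(0, 0.03), "cycle")
})

test_that("person outcomes: LY/QALY/cost accounting on hand-built ledgers", {
  ucat1 <- utility_catalog(baseline_utility = 1,
                           excess_weight_decrement = 0)
  ccat0 <- cost_catalog(management_cost = 0, discount_rate = 0)
  # alive 10 full years, utility 1, rate 0 -> LY = QALY = 10
  led <- toy_ledger(1:10)
  out <- compute_person_outcomes(led, ucat1, ccat0)
  expect_equal(out$ly, 10); expect_equal(out$qaly, 10)
  # death in cycle 1 -> LY 0.5
  led1 <- toy_ledger(1, alive_frac = 0.5)
  expect_equal(compute_person_outcomes(led1, ucat1, ccat0)$ly, 0.5)
  # one MI in cycle 3, horizon 5, rate 0:
  # cost = event + 2 subsequent + 5 management
  ccat <- cost_catalog(
    complication_costs = list(myocardial_infarction = c(12000, 1800)),
    management_cost = 700, discount_rate = 0)
  ucat_mi <- utility_catalog(
    baseline_utility = 0.85,
    decrements = list(myocardial_infarction = c(0.10, 0.04)),
    excess_weight_decrement = 0)
  led5 <- toy_ledger(1:5, events = list(myocardial_infarction = 3))
  out5 <- compute_person_outcomes(led5, ucat_mi, ccat)
  expect_equal(out5$cost, 12000 + 2 * 1800 + 5 * 700)
  expect_equal(out5$qaly, 2 * 0.85 + (0.85 - 0.10) + 2 * (0.85 - 0.04))
  # inflation factor scales costs linearly
  ccat_inf <- cost_catalog(
    complication_costs = list(myocardial_infarction = c(12000, 1800)),
    management_cost = 700, discount_rate = 0, inflation_factor = 1.1)
  expect_equal(compute_person_outcomes(led5, ucat_mi, ccat_inf)$cost,
               out5$cost * 1.1)
})

test_that("QALY <= LY and discounted <= undiscounted on a simulated run", {
  co <- impute_missing(small_cohort(500, seed = 9))
  led <- simulate_cohort(co, default_equation_catalog(),
                         default_biomarker_catalog(), NULL, 10, 3)
  out <- compute_person_outcomes(led, utility_catalog(), cost_catalog())
  expect_true(all(out$qaly <= out$ly + 1e-12))
  expect_true(all(out$qaly_undisc <= out$ly_undisc + 1e-12))
  expect_true(all(out$qaly <= out$qaly_undisc + 1e-12))
  expect_true(all(out$cost <= out$cost_undisc + 1e-12))
  # conservation: ledger alive fractions sum to total undiscounted LY
  expect_equal(sum(out$ly_undisc), sum(led$alive_frac))
})

test_that("identical ledgers give zero deltas; strata sum to the total", {
  co <- impute_missing(small_cohort(600, seed = 10))
  eqs <- default_equation_catalog(); bmc <- default_biomarker_catalog()
  base <- simulate_cohort(co, eqs, bmc, NULL, 10, 8)
  scen <- scenario_presets(10)$hba1c
  ucat <- utility_catalog(); ccat <- cost_catalog()
  z <- aggregate_scenario_delta(base, base, co, scen, ucat, ccat)
  expect_true(all(z$population == 0))
  led <- simulate_cohort(co, eqs, bmc, scen, 10, 8)
  d <- aggregate_scenario_delta(base, led, co, scen, ucat, ccat)
  for (h in c(5, 10)) for (ms in unique(d$measure)) {
    sel <- d$horizon == h & d$measure == ms
    expect_equal(d$population[sel & d$stratum == "all"],
                 d$population[sel & d$stratum == "male"] +
                   d$population[sel & d$stratum == "female"])
  }
  # per-person x denominator recovers the population delta
  expect_equal(d$per_person * d$denominator, d$population)
  # denominator is the count failing the scenario's controlled target
  fl <- target_attainment(co)
  expect_equal(unique(d$denominator[d$stratum == "all"]),
               sum(!fl$hba1c_met))
  expect_error(aggregate_scenario_delta(base, led[person_id !=
    co$person_id[1]], co, scen, ucat, ccat), "different cohorts")
})

test_that("per-complication decomposition is exact and attributes correctly", {
  co <- impute_missing(small_cohort(400, seed = 13))
  ucat <- utility_catalog(excess_weight_decrement = 0)
  ccat <- cost_catalog(discount_rate = 0.03)
  bmc <- default_biomarker_catalog()
  # toy model: only retinopathy active, biomarker-driven
  eqs <- null_equation_catalog()
  eqs$retinopathy <- default_equation_catalog()$retinopathy
  base <- simulate_cohort(co, eqs, bmc, NULL, 10, 6)
  scen <- scenario_presets(10)$hba1c
  led <- simulate_cohort(co, eqs, bmc, scen, 10, 6)
  cmp <- composition_by_complication(base, led, ucat, ccat, 10)
  nonzero <- cmp$component[abs(cmp$cost_saving) > 1e-9]
  expect_equal(nonzero, "retinopathy")  # 100% of complication savings
  # additivity: buckets sum exactly to the aggregate deltas
  d <- aggregate_scenario_delta(base, led, co, scen, ucat, ccat, 10)
  expect_equal(sum(cmp$cost_saving),
               d$population[d$stratum == "all" &
                              d$measure == "cost_saving"])
  expect_equal(sum(cmp$qaly_gain),
               d$population[d$stratum == "all" &
                              d$measure == "qaly_gain"])
  # zero-difference pair -> all-zero decomposition
  z <- composition_by_complication(base, base, ucat, ccat, 10)
  expect_true(all(abs(z$qaly_gain) < 1e-12 &
                    abs(z$cost_saving) < 1e-12))
})

test_that("utility bound variants scale decrements, not baseline", {
  lo <- utility_catalog(bound = "lower")
  hi <- utility_catalog(bound = "upper")
  ce <- utility_catalog()
  expect_equal(lo$decrements$heart_failure,
               ce$decrements$heart_failure * 1.2)
  expect_equal(hi$decrements$heart_failure,
               ce$decrements$heart_failure * 0.8)
  expect_equal(lo$baseline_utility, ce$baseline_utility)
})
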