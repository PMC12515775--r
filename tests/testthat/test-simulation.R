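test_that("null model: everyone survives, no events, LY = horizon", {
  co <- impute_missing(small_cohort(150))
  led <- simulate_cohort(co, null_equation_catalog(),
                         identity_biomarker_catalog(), NULL, 10, 1)
  expect_equal(nrow(led), 150 * 10)
  expect_true(all(led$alive_frac == 1))
  ev_cols <- grep("^ev_", names(led), value = TRUE)
  expect_false(any(as.matrix(led[, ev_cols, with = FALSE])))
  out <- compute_person_outcomes(led, utility_catalog(),
                                 cost_catalog(discount_rate = 0))
  expect_true(all(out$ly_undisc == 10))
})

test_that("constant mortality 0.5 over 2 cycles matches the enumeration oracle", {
  # independent oracle: enumerate the three sample paths under the
  # half-cycle-at-death convention
  paths <- rbind(c(p = 0.5, ly = 0.5),          # die in cycle 1
                 c(p = 0.25, ly = 1.5),         # survive, die in cycle 2
                 c(p = 0.25, ly = 2.0))         # survive both
  e_ly <- sum(paths[, "p"] * paths[, "ly"])     # = 1.125
  co <- impute_missing(generate_cohort(cohort_profile(n = 100000,
                                                      seed = 202)))
  eqs <- single_complication_catalog("neuropathy", 0, p_mortality = 0.5)
  led <- simulate_cohort(co, eqs, identity_biomarker_catalog(), NULL,
                         2, 31)
  out <- compute_person_outcomes(led, utility_catalog(),
                                 cost_catalog(discount_rate = 0))
  se <- sd(out$ly_undisc) / sqrt(nrow(out))
  expect_lt(abs(mean(out$ly_undisc) - e_ly), 4 * se)
})

test_that("constant annual p = 0.2 gives 1 - 0.8^10 cumulative incidence", {
  co <- impute_missing(generate_cohort(cohort_profile(n = 20000,
                                                      seed = 77)))
  eqs <- single_complication_catalog("retinopathy", 0.2)
  led <- simulate_cohort(co, eqs, identity_biomarker_catalog(), NULL,
                         10, 13)
  inc <- led[, list(hit = any(ev_retinopathy)), by = "person_id"]
  # exclude persons with prevalent retinopathy (never at risk)
  at_risk <- !co$hist_retinopathy
  hit <- inc$hit[match(co$person_id[at_risk], inc$person_id)]
  expect_lt(abs(mean(hit) - (1 - 0.8^10)), 0.01)
})

test_that("ledger invariants: rows stop at death, events fire once", {
  co <- impute_missing(small_cohort(800, seed = 3))
  led <- simulate_cohort(co, default_equation_catalog(),
                         default_biomarker_catalog(), NULL, 10, 19)
  per <- led[, list(n_rows = .N, death = if (any(died))
    cycle[died] else NA_integer_, last = max(cycle)), by = "person_id"]
  expect_true(all(is.na(per$death) | per$death == per$last))
  expect_true(all(per$n_rows == per$last))  # contiguous cycles from 1
  # each non-recurrent complication at most once per person
  for (o in complication_names()) {
    cnt <- led[, sum(get(paste0("ev_", o))), by = "person_id"]$V1
    expect_true(all(cnt <= 1), label = o)
  }
  # no event recorded in a death cycle (mortality drawn first)
  ev_cols <- grep("^ev_", names(led), value = TRUE)
  dead_rows <- led[led$died == TRUE]
  expect_false(any(as.matrix(dead_rows[, ev_cols, with = FALSE])))
})

test_that("reproducibility and guard rails", {
  co <- impute_missing(small_cohort(200, seed = 4))
  eqs <- default_equation_catalog()
  bmc <- default_biomarker_catalog()
  a <- simulate_cohort(co, eqs, bmc, NULL, 5, 7)
  b <- simulate_cohort(co, eqs, bmc, NULL, 5, 7)
  expect_equal(as.data.frame(a), as.data.frame(b))
  dup <- rbind(co[1, ], co)
  expect_error(simulate_cohort(dup, eqs, bmc, NULL, 5, 7), "duplicate")
  expect_error(simulate_cohort(co, eqs[-1], bmc, NULL, 5, 7),
               "missing risk equation")
  com <- co; com$hba1c[1] <- NA
  expect_error(simulate_cohort(com, eqs, bmc, NULL, 5, 7), "impute")
})

test_that("common random numbers: null scenario is bit-identical and row order is irrelevant", {
  co <- impute_missing(small_cohort(300, seed = 6))
  eqs <- default_equation_catalog()
  bmc <- default_biomarker_catalog()
  base <- simulate_cohort(co, eqs, bmc, NULL, 10, 99)
  nul <- simulate_cohort(co, eqs, bmc, scenario("null"), 10, 99)
  strip <- function(x) {
    x <- as.data.frame(x)
    attr(x, "scenario") <- NULL
    x
  }
  expect_equal(strip(base), strip(nul))
  # person substreams are keyed by id: shuffling rows permutes the
  # ledger but not any person's trajectory
  perm <- sample(nrow(co))
  shuf <- simulate_cohort(co[perm, ], eqs, bmc, NULL, 10, 99)
  a <- as.data.frame(base[order(person_id, cycle)])
  b <- as.data.frame(shuf[order(person_id, cycle)])
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("protective control cannot increase monotone-equation events under CRN", {
  co <- impute_missing(generate_cohort(cohort_profile(n = 50000,
                                                      seed = 12)))
  eqs <- default_equation_catalog()
  bmc <- default_biomarker_catalog()
  # mortality off so survivor dynamics cannot mask the coupling
  eqs$mortality <- risk_equation("mortality", "logistic",
                                 c(intercept = -Inf))
  base <- simulate_cohort(co, eqs, bmc, NULL, 10, 55)
  scen <- scenario_presets(10)$combined
  led <- simulate_cohort(co, eqs, bmc, scen, 10, 55)
  for (o in complication_names()) {
    n_base <- sum(base[[paste0("ev_", o)]])
    n_scen <- sum(led[[paste0("ev_", o)]])
    expect_lte(n_scen, n_base)
  }
})

test_that("CRN reduces the variance of the QALY delta", {
  co <- impute_missing(small_cohort(400, seed = 21))
  eqs <- default_equation_catalog()
  bmc <- default_biomarker_catalog()
  scen <- scenario_presets(5)$combined
  ucat <- utility_catalog(); ccat <- cost_catalog()
  qaly_total <- function(led) sum(compute_person_outcomes(
    led, ucat, ccat)$qaly)
  d_crn <- d_ind <- numeric(20)
  for (r in 1:20) {
    b <- simulate_cohort(co, eqs, bmc, NULL, 5, r)
    s_crn <- simulate_cohort(co, eqs, bmc, scen, 5, r)
    s_ind <- simulate_cohort(co, eqs, bmc, scen, 5, 10000 + r)
    d_crn[r] <- qaly_total(s_crn) - qaly_total(b)
    d_ind[r] <- qaly_total(s_ind) - qaly_total(b)
  }
  expect_lt(var(d_crn), var(d_ind))
})

test_that("simulate_patient equals the one-row cohort run", {
  co <- impute_missing(small_cohort(5, seed = 2))
  eqs <- default_equation_catalog()
  bmc <- default_biomarker_catalog()
  full <- simulate_cohort(co, eqs, bmc, NULL, 5, 42)
  one <- simulate_patient(co[3, ], eqs, bmc, NULL, 5, 42)
  a <- as.data.frame(full[full$person_id == co$person_id[3]])
  b <- as.data.frame(one)
  rownames(a) <- rownames(b) <- NULL
  for (at in c("scenario", "horizon", "master_seed", "n"))
    attr(a, at) <- attr(b, at) <- NULL
  expect_equal(a, b)
})
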