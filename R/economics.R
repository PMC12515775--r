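#' Utility catalog: baseline utility and complication disutilities
#'
#' QALY weights for type 2 diabetes: a baseline utility for diabetes
#' without complications, an additive decrement per complication
#' (larger in the event year than in subsequent years), and an
#' excess-weight decrement per BMI unit above a threshold. Annual
#' utility is `baseline - sum(decrements)`, floored at 0. The default
#' values are SYNTHETIC placeholders in the style of Asian T2DM utility
#' meta-analyses; supply a transcribed catalog via
#' [read_utility_catalog()] for fidelity runs. `bound` selects the
#' sensitivity variant (+/- 20% on decrements).
#'
#' @param baseline_utility Utility/year without complications, in (0, 1].
#' @param decrements Named list: complication -> `c(event, subsequent)`.
#' @param excess_weight_decrement Utility lost per BMI unit above
#'   `bmi_threshold`.
#' @param bmi_threshold BMI above which the excess-weight decrement
#'   applies.
#' @param bound `"central"`, `"lower"` or `"upper"` decrement variant.
#' @return Object of class `utility_catalog`.
#' @export
utility_catalog <- function(baseline_utility = 0.85,
                            decrements = default_utility_decrements(),
                            excess_weight_decrement = 0.006,
                            bmi_threshold = 25,
                            bound = c("central", "lower", "upper")) {
  bound <- match.arg(bound)
  if (baseline_utility <= 0 || baseline_utility > 1)
    stop2("baseline_utility must be in (0, 1]")
  mult <- switch(bound, central = 1, lower = 1.2, upper = 0.8)
  decrements <- lapply(decrements, function(d) {
    if (any(d < 0)) stop2("utility decrements must be >= 0")
    d * mult
  })
  cat <- list(baseline_utility = baseline_utility,
              decrements = decrements,
              excess_weight_decrement = excess_weight_decrement * mult,
              bmi_threshold = bmi_threshold, bound = bound)
  class(cat) <- "utility_catalog"
  cat
}

default_utility_decrements <- function() {
  # c(event-year, subsequent-year); SYNTHETIC values
  list(myocardial_infarction = c(0.10, 0.04),
       ischaemic_heart_disease = c(0.06, 0.03),
       heart_failure = c(0.11, 0.05),
       cerebrovascular_disease = c(0.15, 0.08),
       peripheral_vascular_disease = c(0.04, 0.02),
       neuropathy = c(0.04, 0.03),
       lower_limb_amputation = c(0.15, 0.10),
       skin_ulcer = c(0.05, 0.02),
       chronic_kidney_disease = c(0.05, 0.03),
       retinopathy = c(0.05, 0.03),
       haemodialysis = c(0.15, 0.10),
       cataract = c(0.03, 0.01))
}

#' Cost catalog: complication and management costs
#'
#' Direct healthcare costs per complication in the event year and in
#' each subsequent year, an annual diabetes-management cost, an
#' inflation factor to the reporting currency year, and the discount
#' rate (default 3%/year for both costs and benefits). Defaults are
#' SYNTHETIC placeholders in 2024 USD magnitudes; supply transcribed
#' unit costs via [read_cost_catalog()] for fidelity runs.
#'
#' @param complication_costs Named list: complication ->
#'   `c(event, subsequent)` cost in currency units.
#' @param management_cost Annual diabetes management cost.
#' @param inflation_factor Multiplier to the reporting currency year.
#' @param discount_rate Annual discount rate, >= 0.
#' @return Object of class `cost_catalog`.
#' @export
cost_catalog <- function(complication_costs = default_complication_costs(),
                         management_cost = 800,
                         inflation_factor = 1,
                         discount_rate = 0.03) {
  if (discount_rate < 0) stop2("discount_rate must be >= 0")
  for (d in complication_costs) if (any(d < 0))
    stop2("costs must be >= 0")
  if (management_cost < 0) stop2("costs must be >= 0")
  cat <- list(complication_costs = complication_costs,
              management_cost = management_cost,
              inflation_factor = inflation_factor,
              discount_rate = discount_rate)
  class(cat) <- "cost_catalog"
  cat
}

default_complication_costs <- function() {
  # c(event-year, subsequent-year) in USD; SYNTHETIC values
  list(myocardial_infarction = c(12000, 1800),
       ischaemic_heart_disease = c(8000, 1200),
       heart_failure = c(10000, 2200),
       cerebrovascular_disease = c(14000, 2500),
       peripheral_vascular_disease = c(4000, 600),
       neuropathy = c(1500, 300),
       lower_limb_amputation = c(18000, 2500),
       skin_ulcer = c(3000, 500),
       chronic_kidney_disease = c(4000, 1200),
       retinopathy = c(2500, 400),
       haemodialysis = c(30000, 30000),
       cataract = c(2000, 100))
}

#' Annual utility for one person-year
#'
#' `baseline - event-year decrements (incident complications)
#' - subsequent-year decrements (prevalent, non-incident complications)
#' - excess-weight decrement`, floored at 0.
#'
#' @param prevalent Character vector of complications with onset before
#'   this cycle.
#' @param incident Character vector of complications with onset in this
#'   cycle.
#' @param bmi BMI this cycle.
#' @param catalog A [utility_catalog()].
#' @return Utility value in `[0, baseline]`.
#' @export
annual_utility <- function(prevalent, incident, bmi, catalog) {
  known <- names(catalog$decrements)
  bad <- setdiff(c(prevalent, incident), known)
  if (length(bad))
    stop2("unknown complication(s): ", paste(bad, collapse = ", "))
  u <- catalog$baseline_utility
  for (o in incident) u <- u - catalog$decrements[[o]][1]
  for (o in setdiff(prevalent, incident))
    u <- u - catalog$decrements[[o]][2]
  u <- u - catalog$excess_weight_decrement *
    max(0, bmi - catalog$bmi_threshold)
  max(u, 0)
}

#' Discount multiplier for an annual cycle
#'
#' End-of-cycle annual discounting with the first year undiscounted:
#' `(1 + rate)^-(cycle - 1)`.
#'
#' @param cycle Year index, >= 1.
#' @param rate Annual discount rate.
#' @return Discount multiplier(s).
#' @export
discount_factor <- function(cycle, rate) {
  if (any(cycle < 1)) stop2("cycle must be >= 1")
  (1 + rate)^(-(cycle - 1))
}

# per-cycle utility and cost columns added to a ledger (data.table),
# restricted to cycles <= horizon. Exact additive structure is reused by
# the per-complication decomposition.
ledger_annual_values <- function(ledger, ucat, ccat, horizon = NULL) {
  dt <- data.table::as.data.table(ledger)
  if (!is.null(horizon)) dt <- dt[dt$cycle <= horizon]
  comps <- complication_names()
  data.table::setorderv(dt, c("person_id", "cycle"))
  u <- rep(ucat$baseline_utility, nrow(dt))
  cost <- rep(ccat$management_cost, nrow(dt))
  for (o in comps) {
    evc <- dt[[paste0("ev_", o)]]
    prev <- as.logical(stats::ave(as.numeric(evc), dt$person_id,
                                  FUN = function(x) cumsum(x) - x))
    dec <- ucat$decrements[[o]] %||% c(0, 0)   # absent entry = no decrement
    cc <- ccat$complication_costs[[o]] %||% c(0, 0)
    du <- evc * dec[1] + prev * dec[2]
    dc <- evc * cc[1] + prev * cc[2]
    u <- u - du
    cost <- cost + dc
    dt[[paste0("du_", o)]] <- du
    dt[[paste0("cost_", o)]] <- dc * dt$alive_frac *
      ccat$inflation_factor
  }
  dt$du_excess_weight <- ucat$excess_weight_decrement *
    pmax(0, dt$bmi - ucat$bmi_threshold)
  u <- pmax(u - dt$du_excess_weight, 0)
  dt$utility <- u
  dt$cost_year <- cost * dt$alive_frac * ccat$inflation_factor
  dt$disc <- discount_factor(dt$cycle, ccat$discount_rate)
  dt
}

#' Per-person life-years, QALYs and costs from a run ledger
#'
#' Life-years are summed alive fractions (half a year in the death
#' cycle); QALYs weight each alive fraction by that cycle's utility;
#' costs sum event-year, subsequent-year and management costs, scaled by
#' the alive fraction and the inflation factor. Discounted versions use
#' the catalog's rate with the first year undiscounted.
#'
#' @param ledger A run ledger from [simulate_cohort()].
#' @param ucat A [utility_catalog()].
#' @param ccat A [cost_catalog()].
#' @param horizon Optional horizon restriction (cycles > horizon are
#'   dropped), for 5-year summaries of a 10-year run.
#' @return `data.table`: `person_id`, `sex`, `ly`, `qaly`, `cost`
#'   (discounted) and `ly_undisc`, `qaly_undisc`, `cost_undisc`.
#' @export
compute_person_outcomes <- function(ledger, ucat, ccat, horizon = NULL) {
  dt <- ledger_annual_values(ledger, ucat, ccat, horizon)
  qy <- dt$alive_frac * dt$utility
  agg <- dt[, list(
    sex = sex[1],
    ly = sum(alive_frac * disc),
    qaly = sum(alive_frac * utility * disc),
    cost = sum(cost_year * disc),
    ly_undisc = sum(alive_frac),
    qaly_undisc = sum(alive_frac * utility),
    cost_undisc = sum(cost_year)), by = "person_id"]
  agg
}

#' Population and per-person deltas between two scenarios
#'
#' Compares a scenario ledger with the natural-path baseline ledger from
#' the same cohort under common random numbers: QALY gain, life-year
#' gain and cost saving (baseline cost minus scenario cost; negative
#' savings mean a cost increase), summed over the population and
#' stratified by sex, at each requested horizon. Per-person values
#' divide the population delta by the number of persons not meeting the
#' scenario's controlled targets at baseline (the Table-1-style
#' denominator).
#'
#' @param base_ledger Natural-path ledger.
#' @param scen_ledger Scenario ledger (same cohort, same master seed).
#' @param cohort The (imputed) cohort both runs used.
#' @param scenario The [scenario()] that produced `scen_ledger`.
#' @param ucat,ccat Utility and cost catalogs.
#' @param horizons Horizons (years) to report.
#' @return Tidy `data.table`: `horizon`, `stratum` (all/male/female),
#'   `measure` (qaly_gain/ly_gain/cost_saving), `population`,
#'   `denominator`, `per_person`.
#' @export
aggregate_scenario_delta <- function(base_ledger, scen_ledger, cohort,
                                     scenario, ucat, ccat,
                                     horizons = c(5, 10)) {
  if (!setequal(unique(base_ledger$person_id),
                unique(scen_ledger$person_id)))
    stop2("ledgers come from different cohorts")
  flags <- target_attainment(cohort)
  fails <- scenario_denominator_flags(flags, scenario)
  denom <- c(all = sum(fails),
             male = sum(fails & cohort$sex == "male"),
             female = sum(fails & cohort$sex == "female"))
  out <- list()
  for (h in horizons) {
    b <- compute_person_outcomes(base_ledger, ucat, ccat, h)
    s <- compute_person_outcomes(scen_ledger, ucat, ccat, h)
    m <- merge(b, s, by = c("person_id", "sex"), suffixes = c("_b", "_s"))
    d <- data.table::data.table(
      sex = m$sex,
      qaly_gain = m$qaly_s - m$qaly_b,
      ly_gain = m$ly_s - m$ly_b,
      cost_saving = m$cost_b - m$cost_s)
    for (st in c("all", "male", "female")) {
      sel <- if (st == "all") rep(TRUE, nrow(d)) else d$sex == st
      for (ms in c("qaly_gain", "ly_gain", "cost_saving")) {
        pop <- sum(d[[ms]][sel])
        out[[length(out) + 1L]] <- data.table::data.table(
          horizon = h, stratum = st, measure = ms, population = pop,
          denominator = unname(denom[st]),
          per_person = if (denom[st] > 0) pop / denom[st] else NA_real_)
      }
    }
  }
  data.table::rbindlist(out)
}

# persons failing at least one of the scenario's controlled targets at
# baseline; for the natural scenario (nothing controlled) fall back to
# the any-of-three denominator.
scenario_denominator_flags <- function(flags, scenario) {
  cf <- scenario$controlled_factors
  if (!length(cf)) return(!flags$all_met)
  fail <- rep(FALSE, nrow(flags))
  if ("hba1c" %in% cf) fail <- fail | !flags$hba1c_met
  if ("bp" %in% cf) fail <- fail | !flags$bp_met
  if ("ldl" %in% cf) fail <- fail | !flags$ldl_met
  fail
}

#' Decompose scenario deltas by complication
#'
#' Additive decomposition of the discounted cost saving and QALY gain
#' into per-complication contributions plus an `excess_weight` utility
#' bucket and a `diabetes_management` residual (baseline utility times
#' life-year change; management-cost change). Buckets sum exactly to
#' the totals provided the utility floor at 0 never binds.
#'
#' @inheritParams aggregate_scenario_delta
#' @param horizon Single horizon (years).
#' @return `data.table`: `component`, `qaly_gain`, `cost_saving`.
#' @export
composition_by_complication <- function(base_ledger, scen_ledger, ucat,
                                        ccat, horizon = NULL) {
  b <- ledger_annual_values(base_ledger, ucat, ccat, horizon)
  s <- ledger_annual_values(scen_ledger, ucat, ccat, horizon)
  comps <- complication_names()
  rows <- list()
  for (o in comps) {
    du_b <- sum(b$alive_frac * b[[paste0("du_", o)]] * b$disc)
    du_s <- sum(s$alive_frac * s[[paste0("du_", o)]] * s$disc)
    c_b <- sum(b[[paste0("cost_", o)]] * b$disc)
    c_s <- sum(s[[paste0("cost_", o)]] * s$disc)
    rows[[o]] <- data.table::data.table(
      component = o,
      qaly_gain = du_b - du_s,   # decrement avoided = utility gained
      cost_saving = c_b - c_s)
  }
  rows$excess_weight <- data.table::data.table(
    component = "excess_weight",
    qaly_gain = sum(b$alive_frac * b$du_excess_weight * b$disc) -
      sum(s$alive_frac * s$du_excess_weight * s$disc),
    cost_saving = 0)
  mgmt_b <- sum(b$alive_frac * ccat$management_cost *
                  ccat$inflation_factor * b$disc)
  mgmt_s <- sum(s$alive_frac * ccat$management_cost *
                  ccat$inflation_factor * s$disc)
  rows$diabetes_management <- data.table::data.table(
    component = "diabetes_management",
    qaly_gain = ucat$baseline_utility *
      (sum(s$alive_frac * s$disc) - sum(b$alive_frac * b$disc)),
    cost_saving = mgmt_b - mgmt_s)
  data.table::rbindlist(rows)
}
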