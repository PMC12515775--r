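#' Simulate a cohort through annual cycles (patient-level Monte Carlo)
#'
#' Composes the 13 risk equations, biomarker progression and an optional
#' control scenario into a per-person per-cycle run ledger. Within each
#' cycle, in fixed order: (1) the scenario-adjusted biomarker values for
#' the cycle are computed (deterministic conditional-mean paths by
#' default); (2) annual mortality is drawn from the logistic equation;
#' (3) survivors draw each not-yet-experienced complication independently
#' from its conditional annual probability `1 - S(t)/S(t-1)`; (4)
#' attained age and duration advance. A death contributes half a year of
#' exposure in its cycle and the person leaves the ledger afterwards.
#'
#' Common random numbers: every person receives a private uniform stream
#' indexed by `(outcome, cycle)`, seeded from a hash of `(person_id,
#' master_seed)`. The same person therefore sees identical draws under
#' different scenarios, and results do not depend on row order.
#'
#' @param cohort Imputed cohort data frame (no missing biomarkers);
#'   duplicate `person_id`s are an error.
#' @param equations Named list of [risk_equation()]s covering all of
#'   [outcome_names()].
#' @param biomarker_catalog Named list of [biomarker_equation()]s
#'   covering all of [biomarker_names()].
#' @param scenario A [scenario()] or `NULL` for the natural path.
#' @param horizon Years to simulate (>= 1).
#' @param master_seed Integer master seed.
#' @param biomarker_rng `FALSE` for conditional-mean biomarker paths
#'   (default analysis policy), `TRUE` for stochastic residuals.
#' @return A `data.table` run ledger: `person_id`, `sex`, `cycle`,
#'   `alive_frac`, `died`, the four biomarkers plus `dbp`, and one
#'   logical `ev_<complication>` column per complication. Rows exist
#'   only up to and including the death cycle. Attributes: `scenario`,
#'   `horizon`, `master_seed`, `n`.
#' @export
simulate_cohort <- function(cohort, equations, biomarker_catalog,
                            scenario = NULL, horizon = 10L,
                            master_seed = 1L, biomarker_rng = FALSE) {
  n <- nrow(cohort)
  if (anyDuplicated(cohort$person_id))
    stop2("duplicate person_id in cohort")
  missing_eq <- setdiff(outcome_names(), names(equations))
  if (length(missing_eq))
    stop2("missing risk equation(s) for: ",
          paste(missing_eq, collapse = ", "))
  for (b in biomarker_names()) if (any(is.na(cohort[[b]])))
    stop2("cohort has missing `", b, "` values: impute first")
  horizon <- as.integer(horizon)
  comps <- complication_names()
  n_out <- length(outcome_names())

  # per-person uniform streams, indexed (outcome, cycle)
  seeds <- person_seeds(cohort$person_id, master_seed)
  U <- matrix(0, n, n_out * horizon)
  for (i in seq_len(n)) {
    set.seed(seeds[i])
    U[i, ] <- runif(n_out * horizon)
  }
  ucol <- function(o_idx, t) (t - 1L) * n_out + o_idx

  covered <- rep(TRUE, n)
  if (!is.null(scenario) && scenario$coverage < 1)
    covered <- coverage_mask(cohort, scenario$coverage,
                             (master_seed + 104729) %% 2147483647)
  if (biomarker_rng) set.seed((master_seed + 7919) %% 2147483647)

  base_bm <- list(bmi = cohort$bmi, hba1c = cohort$hba1c,
                  sbp = cohort$sbp, dbp = cohort$dbp, ldl = cohort$ldl)
  cur <- base_bm
  alive <- rep(TRUE, n)
  H <- as.matrix(cohort[, paste0("hist_", comps), drop = FALSE])
  colnames(H) <- comps
  male <- as.numeric(cohort$sex == "male")
  smoker <- as.numeric(cohort$smoker)
  prior_cvd <- as.logical(cohort$prior_cvd)

  rows <- vector("list", horizon)
  for (t in seq_len(horizon)) {
    # biomarkers effective during cycle t
    state <- c(cur, list(age = cohort$age + (t - 1), male = male,
                         duration = cohort$duration + (t - 1), year = t))
    nat <- progress_biomarkers(state, biomarker_catalog,
                               rng = biomarker_rng)
    if (!is.null(scenario) && length(scenario$controlled_factors)) {
      ctl <- apply_control(nat, base_bm, scenario, t, prior_cvd)
      for (b in names(nat))
        nat[[b]] <- ifelse(covered, ctl[[b]], nat[[b]])
    }
    cur <- nat

    X <- data.frame(age = cohort$age + (t - 1), male = male,
                    duration = cohort$duration + (t - 1),
                    bmi = cur$bmi, hba1c = cur$hba1c, sbp = cur$sbp,
                    dbp = cur$dbp, ldl = cur$ldl, smoker = smoker,
                    prior_cvd = as.numeric(prior_cvd))
    for (o in comps) X[[paste0("hist_", o)]] <- as.numeric(H[, o])

    at_start <- alive
    p_death <- mortality_probability(equations$mortality, X)
    died_now <- at_start & (U[, ucol(1L, t)] < p_death)

    ev <- matrix(FALSE, n, length(comps), dimnames = list(NULL, comps))
    surv <- at_start & !died_now
    for (j in seq_along(comps)) {
      o <- comps[j]
      at_risk <- surv & !H[, o]
      if (!any(at_risk)) next
      p <- annual_event_probability(equations[[o]], X, t - 1)
      ev[, j] <- at_risk & (U[, ucol(j + 1L, t)] < p)
    }
    H <- H | ev

    idx <- which(at_start)
    if (length(idx)) {
      dt <- data.table::data.table(
        person_id = cohort$person_id[idx],
        sex = cohort$sex[idx], cycle = t,
        alive_frac = ifelse(died_now[idx], 0.5, 1),
        died = died_now[idx],
        bmi = cur$bmi[idx], hba1c = cur$hba1c[idx],
        sbp = cur$sbp[idx], dbp = cur$dbp[idx], ldl = cur$ldl[idx])
      for (j in seq_along(comps))
        dt[[paste0("ev_", comps[j])]] <- ev[idx, j]
      rows[[t]] <- dt
    }
    alive <- surv
  }
  ledger <- data.table::rbindlist(rows)
  data.table::setattr(ledger, "scenario", scenario)
  data.table::setattr(ledger, "horizon", horizon)
  data.table::setattr(ledger, "master_seed", master_seed)
  data.table::setattr(ledger, "n", n)
  ledger[]
}

#' Simulate a single patient
#'
#' Convenience wrapper running [simulate_cohort()] on a one-row cohort.
#'
#' @param record One-row cohort data frame.
#' @inheritParams simulate_cohort
#' @return The patient's ledger rows.
#' @export
simulate_patient <- function(record, equations, biomarker_catalog,
                             scenario = NULL, horizon = 10L,
                             master_seed = 1L) {
  stopifnot(nrow(record) == 1L)
  simulate_cohort(record, equations, biomarker_catalog, scenario,
                  horizon, master_seed)
}

# deterministic per-person substream seeds: polynomial hash of the id
# combined with the master seed (all arithmetic exact in doubles).
person_seeds <- function(person_id, master_seed) {
  vapply(as.character(person_id), function(s) {
    h <- 0
    for (c in utf8ToInt(s)) h <- (h * 31 + c) %% 2147483647
    as.integer((h * 48271 + as.numeric(master_seed)) %% 2147483647)
  }, integer(1), USE.NAMES = FALSE)
}

#' Default risk-equation catalog (synthetic)
#'
#' A complete 13-outcome catalog with plausible synthetic coefficients:
#' logistic annual mortality, a flexible parametric (spline) retinopathy
#' equation, and a mix of Weibull / Gompertz / exponential /
#' log-logistic / log-normal equations for the remaining complications.
#' Effect directions follow the epidemiology (glycaemia drives
#' microvascular disease, blood pressure drives stroke and heart
#' failure, LDL drives atherosclerotic events); intercepts are solved in
#' code so each outcome hits a stated 10-year cumulative hazard at the
#' cohort reference point. These are synthetic placeholders, not fitted
#' values from any restricted dataset; replace via
#' [read_equation_catalog()] for fidelity runs.
#'
#' @return Named list of [risk_equation()]s covering [outcome_names()].
#' @export
default_equation_catalog <- function() {
  ref <- c(age = 68, male = 0.5, duration = 6.7, bmi = 25.8,
           hba1c = 7.5, sbp = 136, ldl = 1.95, smoker = 0.15,
           prior_cvd = 0.2)
  ph <- function(outcome, family, betas, H10, shape = NULL) {
    lam0_10 <- switch(family,
      exponential = 10,
      weibull = 10^shape,
      gompertz = (exp(shape * 10) - 1) / shape)
    icpt <- log(H10) - log(lam0_10) - sum(betas * ref[names(betas)])
    risk_equation(outcome, family,
                  c(intercept = unname(icpt), betas), shape = shape)
  }
  aft <- function(outcome, family, betas, S10, shape) {
    lp_ref <- if (family == "loglogistic")
      log(10) + shape * qlogis(S10) else
        log(10) - shape * qnorm(1 - S10)
    icpt <- lp_ref - sum(betas * ref[names(betas)])
    risk_equation(outcome, family,
                  c(intercept = unname(icpt), betas), shape = shape)
  }
  # mortality: annual logistic, ~2.5%/y at the reference point
  mort_betas <- c(age = 0.085, hba1c = 0.05, sbp = 0.006, smoker = 0.3,
                  hist_heart_failure = 0.6, hist_myocardial_infarction = 0.4,
                  hist_cerebrovascular_disease = 0.4,
                  hist_chronic_kidney_disease = 0.4,
                  hist_haemodialysis = 0.8,
                  hist_lower_limb_amputation = 0.5)
  mort_ref <- c(ref, hist_heart_failure = 0.04,
                hist_myocardial_infarction = 0.06,
                hist_cerebrovascular_disease = 0.06,
                hist_chronic_kidney_disease = 0.08,
                hist_haemodialysis = 0.005,
                hist_lower_limb_amputation = 0.005)
  mort_icpt <- qlogis(0.025) -
    sum(mort_betas * mort_ref[names(mort_betas)])
  mortality <- risk_equation("mortality", "logistic",
                             c(intercept = unname(mort_icpt), mort_betas))

  # retinopathy: flexible parametric, strongly glycaemia-driven
  fp_betas <- c(hba1c = 0.25, duration = 0.02)
  fp_knots <- log(c(0.5, 3, 12))
  g0 <- log(0.25) - 1.1 * log(10) -
    sum(fp_betas * ref[names(fp_betas)])
  retinopathy <- risk_equation("retinopathy", "flexible_parametric",
                               fp_betas, gamma = c(g0, 1.1, 0.02),
                               knots = fp_knots)

  list(
    mortality = mortality,
    retinopathy = retinopathy,
    myocardial_infarction = ph("myocardial_infarction", "weibull",
      c(hba1c = 0.08, sbp = 0.010, ldl = 0.35, smoker = 0.35,
        male = 0.25, age = 0.05), H10 = 0.06, shape = 1.15),
    ischaemic_heart_disease = ph("ischaemic_heart_disease", "weibull",
      c(hba1c = 0.06, sbp = 0.008, ldl = 0.30, male = 0.20, age = 0.05),
      H10 = 0.09, shape = 1.10),
    heart_failure = ph("heart_failure", "gompertz",
      c(hba1c = 0.10, sbp = 0.012, bmi = 0.03, age = 0.06),
      H10 = 0.07, shape = 0.05),
    cerebrovascular_disease = ph("cerebrovascular_disease", "gompertz",
      c(sbp = 0.030, hba1c = 0.06, smoker = 0.30, age = 0.05),
      H10 = 0.08, shape = 0.04),
    peripheral_vascular_disease = ph("peripheral_vascular_disease",
      "exponential",
      c(hba1c = 0.10, smoker = 0.40, ldl = 0.20, age = 0.03),
      H10 = 0.04),
    neuropathy = ph("neuropathy", "exponential",
      c(hba1c = 0.15, duration = 0.02, age = 0.02), H10 = 0.10),
    lower_limb_amputation = ph("lower_limb_amputation", "weibull",
      c(hba1c = 0.12, smoker = 0.30), H10 = 0.012, shape = 1.2),
    skin_ulcer = ph("skin_ulcer", "exponential",
      c(hba1c = 0.12, bmi = 0.02), H10 = 0.03),
    chronic_kidney_disease = ph("chronic_kidney_disease", "weibull",
      c(hba1c = 0.12, sbp = 0.012, age = 0.05, duration = 0.02),
      H10 = 0.12, shape = 1.3),
    haemodialysis = aft("haemodialysis", "loglogistic",
      c(hba1c = -0.10, sbp = -0.012, ldl = -0.15, duration = -0.02),
      S10 = 0.985, shape = 0.8),
    cataract = aft("cataract", "lognormal",
      c(age = -0.03, hba1c = -0.05), S10 = 0.88, shape = 1.0))
}
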