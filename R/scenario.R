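#' Define a risk-factor-control scenario
#'
#' A scenario names the controlled factors (any subset of glycaemia,
#' blood pressure, LDL-cholesterol), the years taken to reach target, the
#' fraction of the population achieving control, and the horizon. Targets
#' follow ADA-style guidance: HbA1c < 7.0%, BP < 130/80 mmHg, LDL < 2.6
#' mmol/L (< 1.8 with pre-existing cardiovascular disease); all strict
#' inequalities, so boundary values fail. Because "meeting" a strict
#' target needs a concrete level, each factor has a configurable
#' attainment value sitting just inside its threshold.
#'
#' @param name Scenario label.
#' @param controlled_factors Subset of `c("hba1c", "bp", "ldl")`; empty
#'   means the natural-progression comparator.
#' @param time_to_target Years to reach target (1 = immediate control in
#'   the first year; 3 or 5 for ramped sensitivity scenarios).
#' @param coverage Fraction of the population achieving control,
#'   in (0, 1].
#' @param horizon Simulation horizon in years (must be >=
#'   `time_to_target`).
#' @param attainment Named list of attainment values: `hba1c`, `sbp`,
#'   `dbp`, `ldl`, `ldl_cvd`.
#' @return Object of class `scenario`.
#' @export
scenario <- function(name, controlled_factors = character(0),
                     time_to_target = 1L, coverage = 1, horizon = 10L,
                     attainment = list(hba1c = 6.9, sbp = 125, dbp = 75,
                                       ldl = 2.5, ldl_cvd = 1.7)) {
  bad <- setdiff(controlled_factors, c("hba1c", "bp", "ldl"))
  if (length(bad))
    stop2("unknown controlled factor(s): ", paste(bad, collapse = ", "))
  if (coverage <= 0 || coverage > 1) stop2("coverage must be in (0, 1]")
  if (time_to_target < 1) stop2("time_to_target must be >= 1")
  if (horizon < time_to_target)
    stop2("horizon must be >= time_to_target")
  s <- list(name = name, controlled_factors = controlled_factors,
            time_to_target = as.integer(time_to_target),
            coverage = coverage, horizon = as.integer(horizon),
            targets = list(hba1c = 7.0, sbp = 130, dbp = 80, ldl = 2.6,
                           ldl_cvd = 1.8),
            attainment = attainment)
  class(s) <- "scenario"
  s
}

#' @export
print.scenario <- function(x, ...) {
  cat("<scenario>", x$name, "| control:",
      if (length(x$controlled_factors))
        paste(x$controlled_factors, collapse = "+") else "(none)",
      "| ramp", x$time_to_target, "y | coverage",
      sprintf("%.0f%%", 100 * x$coverage), "| horizon", x$horizon, "y\n")
  invisible(x)
}

#' The four named control scenarios plus the natural comparator
#'
#' Presets mirroring the standard analysis: sole control of HbA1c, BP or
#' LDL-cholesterol, combined control of all three, and the uncontrolled
#' natural-progression comparator.
#'
#' @param horizon Horizon in years.
#' @param time_to_target,coverage Passed through to [scenario()].
#' @return Named list of [scenario()] objects
#'   (`natural`, `hba1c`, `bp`, `ldl`, `combined`).
#' @export
scenario_presets <- function(horizon = 10L, time_to_target = 1L,
                             coverage = 1) {
  mk <- function(nm, cf) scenario(nm, cf, time_to_target, coverage,
                                  horizon)
  list(natural = mk("natural", character(0)),
       hba1c = mk("hba1c", "hba1c"),
       bp = mk("bp", "bp"),
       ldl = mk("ldl", "ldl"),
       combined = mk("combined", c("hba1c", "bp", "ldl")))
}

#' Classify baseline target attainment
#'
#' Strict-inequality targets: HbA1c < 7.0%, BP < 130 *and* < 80 mmHg,
#' LDL < 2.6 mmol/L (< 1.8 with prior CVD). A boundary value (exactly
#' 7.0, 130, 80, 2.6 / 1.8) is NOT met. Requires imputed biomarkers.
#'
#' @param cohort Cohort data frame (or a single-row record) with columns
#'   `hba1c`, `sbp`, `dbp`, `ldl`, `prior_cvd`.
#' @return Data frame of logical flags `hba1c_met`, `bp_met`, `ldl_met`,
#'   `all_met`, one row per person.
#' @export
target_attainment <- function(cohort) {
  need <- c("hba1c", "sbp", "dbp", "ldl")
  for (v in need) if (any(is.na(cohort[[v]])))
    stop2("missing `", v, "` values: impute the cohort first")
  ldl_thr <- ifelse(cohort$prior_cvd, 1.8, 2.6)
  out <- data.frame(hba1c_met = cohort$hba1c < 7.0,
                    bp_met = cohort$sbp < 130 & cohort$dbp < 80,
                    ldl_met = cohort$ldl < ldl_thr)
  out$all_met <- out$hba1c_met & out$bp_met & out$ldl_met
  out
}

# control one component (vectorised): natural-path values that meet the
# strict target keep the natural path; failing values are set to the
# attainment level once the ramp completes (cycle >= k), and during the
# ramp to the linear interpolation from baseline toward attainment --
# never above the natural path.
control_component <- function(natural, baseline, threshold, attain,
                              cycle, k) {
  meets <- natural < threshold
  frac <- min(cycle / k, 1)
  ramp <- baseline + frac * (attain - baseline)
  ctrl <- if (cycle >= k) pmin(natural, attain) else pmin(natural, ramp)
  ifelse(meets, natural, ctrl)
}

#' Impose a control scenario on one cycle's biomarker values
#'
#' For each controlled factor, values on the natural path that fail the
#' target are pulled to the attainment value; with `time_to_target = k >
#' 1` they move linearly from baseline toward the attainment value,
#' reaching it at cycle `k`. Values already meeting the target keep
#' their natural path (and are clamped from any later cycle where they
#' would drift past the target). Uncontrolled factors pass through.
#'
#' @param biomarkers Named list / data frame of natural-path values for
#'   this cycle (`hba1c`, `sbp`, `dbp`, `ldl`; vectors allowed).
#' @param baseline_biomarkers The baseline (cycle-0) values, same shape.
#' @param scenario A [scenario()].
#' @param cycle Year index, `>= 1`.
#' @param prior_cvd Logical vector (drives the 1.8 mmol/L LDL target).
#' @return Named list of adjusted biomarker vectors.
#' @export
apply_control <- function(biomarkers, baseline_biomarkers, scenario,
                          cycle, prior_cvd = FALSE) {
  if (cycle < 1) stop2("cycle must be >= 1")
  cf <- scenario$controlled_factors
  out <- list(hba1c = biomarkers$hba1c, sbp = biomarkers$sbp,
              dbp = biomarkers$dbp, ldl = biomarkers$ldl,
              bmi = biomarkers$bmi)
  if (!length(cf)) return(out)
  k <- scenario$time_to_target
  tg <- scenario$targets; at <- scenario$attainment
  if ("hba1c" %in% cf)
    out$hba1c <- control_component(biomarkers$hba1c,
                                   baseline_biomarkers$hba1c,
                                   tg$hba1c, at$hba1c, cycle, k)
  if ("bp" %in% cf) {
    out$sbp <- control_component(biomarkers$sbp, baseline_biomarkers$sbp,
                                 tg$sbp, at$sbp, cycle, k)
    out$dbp <- control_component(biomarkers$dbp, baseline_biomarkers$dbp,
                                 tg$dbp, at$dbp, cycle, k)
  }
  if ("ldl" %in% cf) {
    thr <- ifelse(prior_cvd, tg$ldl_cvd, tg$ldl)
    att <- ifelse(prior_cvd, at$ldl_cvd, at$ldl)
    out$ldl <- control_component(biomarkers$ldl, baseline_biomarkers$ldl,
                                 thr, att, cycle, k)
  }
  out
}

#' Draw the covered subpopulation for a partial-coverage scenario
#'
#' Simple random sample without replacement of `round(coverage * n)`
#' persons flagged as achieving control; everyone else follows the
#' natural path. Reproducible given the seed.
#'
#' @param cohort Cohort data frame.
#' @param coverage Fraction in (0, 1].
#' @param seed Integer seed.
#' @return Logical vector, `TRUE` for covered persons.
#' @export
coverage_mask <- function(cohort, coverage, seed) {
  if (coverage <= 0 || coverage > 1) stop2("coverage must be in (0, 1]")
  n <- nrow(cohort)
  if (coverage == 1) return(rep(TRUE, n))
  k <- round(coverage * n)
  set.seed(seed)
  mask <- rep(FALSE, n)
  mask[sample.int(n, k)] <- TRUE
  mask
}
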