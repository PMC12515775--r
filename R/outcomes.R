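#' Outcome vocabulary
#'
#' The 13 modelled outcomes: all-cause mortality plus 12 diabetes-related
#' complications. Every risk-equation catalog must cover all of them.
#'
#' @return Character vector of outcome names.
#' @export
outcome_names <- function() {
  c("mortality",
    "haemodialysis",
    "myocardial_infarction",
    "ischaemic_heart_disease",
    "heart_failure",
    "cerebrovascular_disease",
    "peripheral_vascular_disease",
    "neuropathy",
    "lower_limb_amputation",
    "skin_ulcer",
    "chronic_kidney_disease",
    "retinopathy",
    "cataract")
}

#' Complication names (the 12 non-fatal outcomes)
#' @return Character vector.
#' @export
complication_names <- function() {
  setdiff(outcome_names(), "mortality")
}

#' Biomarker vocabulary
#'
#' The four biomarkers with modelled annual time-paths. Diastolic blood
#' pressure is carried alongside systolic for target classification but has
#' no progression model of its own.
#'
#' @return Character vector: `bmi`, `hba1c`, `sbp`, `ldl`.
#' @export
biomarker_names <- function() c("bmi", "hba1c", "sbp", "ldl")

# survival families supported for time-to-event outcomes
.surv_families <- c("exponential", "weibull", "loglogistic", "lognormal",
                    "gompertz", "flexible_parametric")
.all_families <- c(.surv_families, "logistic")

# physiological clamp bounds used at generation and progression time
.biomarker_bounds <- list(
  bmi   = c(12, 60),
  hba1c = c(4, 20),
  sbp   = c(70, 250),
  dbp   = c(40, 150),
  ldl   = c(0.3, 12)
)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

assert_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop2(sprintf("`%s` must be a single number in [%s, %s]", name, lo, hi))
  invisible(x)
}
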