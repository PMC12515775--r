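#' Cohort profile: the statistical margins a synthetic cohort must match
#'
#' A `cohort_profile` describes the baseline population to synthesise: size,
#' sex split, age / diabetes-duration / BMI moments, the marginal fractions
#' of people failing each risk-factor target (HbA1c >= 7%, BP >= 130/80,
#' LDL >= 2.6 mmol/L or >= 1.8 with prior cardiovascular disease) and the
#' joint fraction failing at least one of the three. The default profile
#' encodes the 2021 Hong Kong type 2 diabetes population margins
#' (n = 526672, 50.3% female, mean age 68.2 y, mean duration 6.7 y,
#' mean BMI 25.8 kg/m2; target failure 47.6% / 68.3% / 18.9%, any 84.9%).
#'
#' Standard deviations, biomarker correlations, smoking and prior-CVD
#' prevalence are not published for this cohort; the defaults below are
#' stated assumptions, exposed here rather than hard-coded.
#'
#' @param n Cohort size.
#' @param prop_female Fraction female.
#' @param age_mean,age_sd,age_bounds Age distribution (years), truncated
#'   normal; the location is re-calibrated so the *truncated* mean equals
#'   `age_mean`.
#' @param duration_mean,duration_sd,duration_bounds Diabetes duration
#'   (years), truncated normal, mean-calibrated likewise.
#' @param bmi_mean,bmi_sd BMI (kg/m2), truncated to physiological bounds.
#' @param hba1c_sd,sbp_sd,ldl_sd Biomarker standard deviations; the
#'   locations are calibrated so the target-failure fractions are met.
#' @param fail_hba1c,fail_bp,fail_ldl Marginal target-failure fractions.
#' @param fail_any Fraction failing at least one of the three targets.
#' @param prior_cvd_prev Prevalence of pre-existing cardiovascular disease
#'   (drives the 1.8 mmol/L LDL target).
#' @param smoker_prev Current-smoker prevalence.
#' @param missing_rates Named numeric, missingness probability per
#'   biomarker (subset of `bmi`, `hba1c`, `sbp`, `ldl`); default none.
#' @param bmi_factor_loading Correlation of BMI with the shared latent
#'   factor that links the three target biomarkers.
#' @param seed Integer seed; the cohort is a pure function of the profile.
#' @return An object of class `cohort_profile`.
#' @export
cohort_profile <- function(n = 526672L,
                           prop_female = 0.503,
                           age_mean = 68.2, age_sd = 11.5,
                           age_bounds = c(25, 100),
                           duration_mean = 6.7, duration_sd = 6.0,
                           duration_bounds = c(0, 60),
                           bmi_mean = 25.8, bmi_sd = 4.3,
                           hba1c_sd = 1.5, sbp_sd = 16, ldl_sd = 0.85,
                           fail_hba1c = 0.476, fail_bp = 0.683,
                           fail_ldl = 0.189, fail_any = 0.849,
                           prior_cvd_prev = 0.20,
                           smoker_prev = 0.15,
                           missing_rates = NULL,
                           bmi_factor_loading = 0.2,
                           seed = 20210101L) {
  p <- list(n = as.integer(n), prop_female = prop_female,
            age_mean = age_mean, age_sd = age_sd, age_bounds = age_bounds,
            duration_mean = duration_mean, duration_sd = duration_sd,
            duration_bounds = duration_bounds,
            bmi_mean = bmi_mean, bmi_sd = bmi_sd,
            hba1c_sd = hba1c_sd, sbp_sd = sbp_sd, ldl_sd = ldl_sd,
            fail_hba1c = fail_hba1c, fail_bp = fail_bp,
            fail_ldl = fail_ldl, fail_any = fail_any,
            prior_cvd_prev = prior_cvd_prev, smoker_prev = smoker_prev,
            missing_rates = missing_rates %||% numeric(0),
            bmi_factor_loading = bmi_factor_loading,
            seed = as.integer(seed))
  class(p) <- "cohort_profile"
  validate_profile(p)
  p
}

validate_profile <- function(p) {
  fr <- c(p$fail_hba1c, p$fail_bp, p$fail_ldl, p$fail_any,
          p$prop_female, p$prior_cvd_prev, p$smoker_prev)
  if (any(fr < 0 | fr > 1))
    stop2("all profile fractions must lie in [0, 1]")
  if (p$fail_any < max(p$fail_hba1c, p$fail_bp, p$fail_ldl))
    stop2("inconsistent profile: joint failure fraction (",
          p$fail_any, ") is below the largest marginal (",
          max(p$fail_hba1c, p$fail_bp, p$fail_ldl), ")")
  indep_any <- 1 - (1 - p$fail_hba1c) * (1 - p$fail_bp) * (1 - p$fail_ldl)
  if (p$fail_any > indep_any + 1e-9)
    stop2("inconsistent profile: joint failure fraction exceeds the ",
          "independence bound ", round(indep_any, 4),
          " (positive-dependence generator cannot reach it)")
  sds <- c(p$age_sd, p$duration_sd, p$bmi_sd, p$hba1c_sd, p$sbp_sd, p$ldl_sd)
  if (any(sds < 0)) stop2("profile standard deviations must be >= 0")
  if (p$n < 0) stop2("profile n must be >= 0")
  if (length(p$missing_rates) &&
      (is.null(names(p$missing_rates)) ||
       !all(names(p$missing_rates) %in% biomarker_names())))
    stop2("missing_rates must be named with a subset of: ",
          paste(biomarker_names(), collapse = ", "))
  invisible(p)
}

#' @export
print.cohort_profile <- function(x, ...) {
  cat("<cohort_profile> n =", x$n,
      sprintf("| %.1f%% female | age %.1f (%.1f)", 100 * x$prop_female,
              x$age_mean, x$age_sd), "\n")
  cat(sprintf("  target failure: HbA1c %.1f%%, BP %.1f%%, LDL %.1f%%, any %.1f%%\n",
              100 * x$fail_hba1c, 100 * x$fail_bp, 100 * x$fail_ldl,
              100 * x$fail_any))
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

# mean of a normal(mu, sd) truncated to [lo, hi]
truncnorm_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd; b <- (hi - mu) / sd
  z <- pnorm(b) - pnorm(a)
  mu + sd * (dnorm(a) - dnorm(b)) / z
}

# location such that the truncated mean equals `target`
truncnorm_calibrate_mu <- function(target, sd, lo, hi) {
  if (sd == 0) return(target)
  uniroot(function(m) truncnorm_mean(m, sd, lo, hi) - target,
          interval = c(target - 5 * sd, target + 5 * sd),
          tol = 1e-10)$root
}

# draw from truncated normal by inverse CDF (vectorised, reproducible)
rtruncnorm <- function(n, mu, sd, lo, hi) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) return(rep(mu, n))
  plo <- pnorm(lo, mu, sd); phi <- pnorm(hi, mu, sd)
  qnorm(plo + runif(n) * (phi - plo), mu, sd)
}

# LDL location such that the mixture failure fraction matches:
# (1-pcvd) P(ldl >= 2.6) + pcvd P(ldl >= 1.8) = fail_ldl
ldl_calibrate_mu <- function(fail_ldl, sd, pcvd,
                             thr0 = 2.6, thr1 = 1.8) {
  f <- function(mu) {
    (1 - pcvd) * pnorm(thr0, mu, sd, lower.tail = FALSE) +
      pcvd * pnorm(thr1, mu, sd, lower.tail = FALSE) - fail_ldl
  }
  uniroot(f, interval = c(-5, 10), tol = 1e-12)$root
}

# P(meets all three targets) under the one-factor latent model with
# loading sqrt(rho) on each of the three target biomarkers.
# a_* are standard-normal thresholds: fail iff z > a.
joint_none_prob <- function(rho, a_h, a_b, a_l0, a_l1, pcvd) {
  if (rho <= 0) {
    ph <- pnorm(a_h); pb <- pnorm(a_b)
    return(ph * pb * ((1 - pcvd) * pnorm(a_l0) + pcvd * pnorm(a_l1)))
  }
  s <- sqrt(rho); r <- sqrt(1 - rho)
  integrand <- function(u, al) {
    dnorm(u) * pnorm((a_h - s * u) / r) * pnorm((a_b - s * u) / r) *
      pnorm((al - s * u) / r)
  }
  i0 <- integrate(integrand, -8, 8, al = a_l0, rel.tol = 1e-10)$value
  i1 <- integrate(integrand, -8, 8, al = a_l1, rel.tol = 1e-10)$value
  (1 - pcvd) * i0 + pcvd * i1
}

# calibrate the shared-factor correlation rho so that
# P(fail at least one target) = fail_any
calibrate_rho <- function(p, a_h, a_b, a_l0, a_l1) {
  target_none <- 1 - p$fail_any
  f <- function(rho) joint_none_prob(rho, a_h, a_b, a_l0, a_l1,
                                     p$prior_cvd_prev) - target_none
  f0 <- f(0)
  if (abs(f0) < 1e-12) return(0)
  if (f0 > 0)
    stop2("profile joint failure fraction exceeds the independence bound")
  uniroot(f, interval = c(0, 0.98), tol = 1e-10)$root
}
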