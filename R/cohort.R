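#' Generate a synthetic baseline cohort
#'
#' Draws `profile$n` patient records whose realised margins converge, as n
#' grows, to the profile's sex split, age / duration / BMI means and the
#' four target-failure fractions. Target-failure flags are *derived from
#' the generated biomarkers*, never sampled separately, so tabulating the
#' cohort reproduces the profile fractions by construction.
#'
#' Mechanism: the three target biomarkers (HbA1c, systolic BP, LDL) share
#' a latent one-factor Gaussian structure; the factor correlation is
#' calibrated numerically so the joint any-target-failure fraction matches
#' the profile, and each biomarker's location is anchored to its target
#' threshold so the marginal failure fraction is exact in distribution.
#' Diastolic BP is systolic minus a positive gap (>= 50 mmHg, lognormal
#' excess), so `dbp < sbp` always and the 130/80 joint BP rule reduces to
#' the calibrated systolic margin. Values are clamped to physiological
#' bounds that never straddle a target threshold.
#'
#' @param profile A [cohort_profile()].
#' @return A `data.frame`, one row per person, with columns
#'   `person_id`, `age`, `sex` (factor female/male), `duration`, `bmi`,
#'   `hba1c`, `sbp`, `dbp`, `ldl`, `smoker`, `prior_cvd`,
#'   `hist_<complication>` prior-event flags, and `missing_<biomarker>`
#'   audit masks. The generating profile and seed are attached as
#'   attributes `profile` and `seed`.
#' @export
generate_cohort <- function(profile) {
  stopifnot(inherits(profile, "cohort_profile"))
  validate_profile(profile)
  p <- profile
  n <- p$n
  if (n == 0L) {
    out <- empty_cohort()
    attr(out, "profile") <- p
    attr(out, "seed") <- p$seed
    return(out)
  }

  set.seed(p$seed)
  female <- runif(n) < p$prop_female
  sex <- factor(ifelse(female, "female", "male"),
                levels = c("female", "male"))

  mu_age <- truncnorm_calibrate_mu(p$age_mean, p$age_sd,
                                   p$age_bounds[1], p$age_bounds[2])
  age <- rtruncnorm(n, mu_age, p$age_sd, p$age_bounds[1], p$age_bounds[2])
  mu_dur <- truncnorm_calibrate_mu(p$duration_mean, p$duration_sd,
                                   p$duration_bounds[1], p$duration_bounds[2])
  duration <- rtruncnorm(n, mu_dur, p$duration_sd,
                         p$duration_bounds[1], p$duration_bounds[2])
  duration <- pmin(duration, age - 18)

  prior_cvd <- runif(n) < p$prior_cvd_prev
  smoker <- runif(n) < p$smoker_prev

  # threshold anchoring on the standard-normal scale
  a_h <- qnorm(1 - p$fail_hba1c)
  a_b <- qnorm(1 - p$fail_bp)
  mu_l <- ldl_calibrate_mu(p$fail_ldl, p$ldl_sd, p$prior_cvd_prev)
  a_l0 <- (2.6 - mu_l) / p$ldl_sd
  a_l1 <- (1.8 - mu_l) / p$ldl_sd
  rho <- calibrate_rho(p, a_h, a_b, a_l0, a_l1)

  u <- rnorm(n)
  s <- sqrt(rho); r <- sqrt(1 - rho)
  z_h <- s * u + r * rnorm(n)
  z_b <- s * u + r * rnorm(n)
  z_l <- s * u + r * rnorm(n)
  lam <- p$bmi_factor_loading
  z_bmi <- lam * u + sqrt(1 - lam^2) * rnorm(n)

  hba1c <- clamp(7.0 + p$hba1c_sd * (z_h - a_h),
                 .biomarker_bounds$hba1c[1], .biomarker_bounds$hba1c[2])
  sbp <- clamp(130 + p$sbp_sd * (z_b - a_b),
               .biomarker_bounds$sbp[1], .biomarker_bounds$sbp[2])
  gap <- 50 + rlnorm(n, meanlog = log(5), sdlog = 0.5)
  dbp <- clamp(sbp - gap, .biomarker_bounds$dbp[1], .biomarker_bounds$dbp[2])
  dbp <- pmin(dbp, sbp - 1)  # dbp < sbp even after clamping
  ldl <- clamp(mu_l + p$ldl_sd * z_l,
               .biomarker_bounds$ldl[1], .biomarker_bounds$ldl[2])
  bmi <- clamp(p$bmi_mean + p$bmi_sd * z_bmi,
               .biomarker_bounds$bmi[1], .biomarker_bounds$bmi[2])

  hist <- history_flags(n, prior_cvd)

  out <- data.frame(person_id = sprintf("P%07d", seq_len(n)),
                    age = age, sex = sex, duration = duration,
                    bmi = bmi, hba1c = hba1c, sbp = sbp, dbp = dbp,
                    ldl = ldl, smoker = smoker, prior_cvd = prior_cvd,
                    stringsAsFactors = FALSE)
  out <- cbind(out, hist)
  for (b in biomarker_names()) {
    mcol <- paste0("missing_", b)
    out[[mcol]] <- FALSE
    rate <- unname(p$missing_rates[b])
    if (length(rate) == 1L && !is.na(rate) && rate > 0) {
      mask <- runif(n) < rate
      out[[b]][mask] <- NA_real_
      out[[mcol]] <- mask
    }
  }
  attr(out, "profile") <- p
  attr(out, "seed") <- p$seed
  out
}

# baseline prevalence of prior complications; prior CVD implies one of the
# three macrovascular events. Prevalences are synthetic stated values.
.history_prev <- c(retinopathy = 0.10, chronic_kidney_disease = 0.08,
                   cataract = 0.12, neuropathy = 0.05,
                   peripheral_vascular_disease = 0.02, heart_failure = 0.04,
                   skin_ulcer = 0.02, lower_limb_amputation = 0.005,
                   haemodialysis = 0.005)

history_flags <- function(n, prior_cvd) {
  out <- as.data.frame(setNames(
    lapply(complication_names(), function(o) rep(FALSE, n)),
    paste0("hist_", complication_names())))
  cvd_type <- sample(c("myocardial_infarction", "ischaemic_heart_disease",
                       "cerebrovascular_disease"),
                     n, replace = TRUE, prob = c(0.3, 0.4, 0.3))
  for (o in c("myocardial_infarction", "ischaemic_heart_disease",
              "cerebrovascular_disease"))
    out[[paste0("hist_", o)]] <- prior_cvd & cvd_type == o
  for (o in names(.history_prev))
    out[[paste0("hist_", o)]] <- runif(n) < .history_prev[[o]]
  out
}

empty_cohort <- function() {
  base <- data.frame(person_id = character(0), age = numeric(0),
                     sex = factor(character(0),
                                  levels = c("female", "male")),
                     duration = numeric(0), bmi = numeric(0),
                     hba1c = numeric(0), sbp = numeric(0),
                     dbp = numeric(0), ldl = numeric(0),
                     smoker = logical(0), prior_cvd = logical(0),
                     stringsAsFactors = FALSE)
  for (o in complication_names()) base[[paste0("hist_", o)]] <- logical(0)
  for (b in biomarker_names()) base[[paste0("missing_", b)]] <- logical(0)
  base
}

#' Impute missing baseline biomarkers by sex-specific sample means
#'
#' Each missing biomarker value is replaced by the mean of the observed
#' values of that biomarker among persons of the same sex. Observed values
#' are untouched and the `missing_*` audit masks are preserved, so the
#' operation is idempotent.
#'
#' @param cohort A cohort data frame from [generate_cohort()] or
#'   [read_cohort()].
#' @return The cohort with no missing biomarker values.
#' @export
impute_missing <- function(cohort) {
  for (b in biomarker_names()) {
    v <- cohort[[b]]
    miss <- is.na(v)
    if (!any(miss)) next
    for (sx in levels(cohort$sex)) {
      in_sex <- cohort$sex == sx
      need <- miss & in_sex
      if (!any(need)) next
      obs <- v[in_sex & !miss]
      if (length(obs) == 0L)
        stop2("cannot impute `", b, "` for sex = ", sx,
              ": no observed values in that stratum")
      v[need] <- mean(obs)
    }
    cohort[[b]] <- v
  }
  cohort
}

#' Write / read a cohort as delimited text
#'
#' The cohort table is written as plain CSV; the generating seed and
#' profile margins go to a JSON sidecar `<path>.meta.json` so a round trip
#' preserves provenance.
#'
#' @param cohort Cohort data frame.
#' @param path Output CSV path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns
#'   the cohort data frame.
#' @export
write_cohort <- function(cohort, path) {
  data.table::fwrite(as.data.frame(cohort), path)
  meta <- list(seed = attr(cohort, "seed"), n = nrow(cohort),
               columns = names(cohort))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  x <- as.data.frame(data.table::fread(path))
  x$sex <- factor(x$sex, levels = c("female", "male"))
  for (cl in grep("^(hist_|missing_)|^(smoker|prior_cvd)$", names(x),
                  value = TRUE))
    x[[cl]] <- as.logical(x[[cl]])
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path)
    attr(x, "seed") <- meta$seed
  }
  x
}
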