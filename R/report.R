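#' Render a Table-1-style baseline target-failure table
#'
#' Counts and percentages of people failing each risk-factor target
#' (HbA1c, BP, LDL, and any of the three), overall and by sex.
#' Percentages are `count / n_total * 100` rounded to 1 decimal place;
#' male and female counts sum to the total count per row by
#' construction. Either tabulate a cohort, or feed externally supplied
#' counts (e.g. a published table) to recompute percentages.
#'
#' @param cohort Imputed cohort data frame; or `NULL` when `counts` is
#'   given.
#' @param counts Optional numeric matrix with rows `hba1c`, `bp`,
#'   `ldl`, `combined` and columns `all`, `male`, `female` of
#'   failure counts.
#' @param n_total Total population size (required with `counts`).
#' @return Data frame: `factor`, `n_fail`, `pct`, `n_fail_male`,
#'   `pct_male`, `n_fail_female`, `pct_female`.
#' @export
render_table1 <- function(cohort = NULL, counts = NULL, n_total = NULL) {
  rows <- c("hba1c", "bp", "ldl", "combined")
  if (is.null(counts)) {
    if (is.null(cohort)) stop2("supply either a cohort or counts")
    n_total <- nrow(cohort)
    if (n_total == 0L) {
      return(data.frame(factor = rows, n_fail = 0, pct = NA_real_,
                        n_fail_male = 0, pct_male = NA_real_,
                        n_fail_female = 0, pct_female = NA_real_))
    }
    flags <- target_attainment(cohort)
    male <- cohort$sex == "male"
    fl <- cbind(hba1c = !flags$hba1c_met, bp = !flags$bp_met,
                ldl = !flags$ldl_met, combined = !flags$all_met)
    counts <- rbind(all = colSums(fl), male = colSums(fl & male),
                    female = colSums(fl & !male))
    counts <- t(counts)
  } else {
    counts <- as.matrix(counts)[rows, c("all", "male", "female")]
    if (is.null(n_total)) stop2("n_total is required with counts")
    if (any(abs(counts[, "male"] + counts[, "female"] -
                counts[, "all"]) > 0))
      stop2("male + female counts must sum to the total count")
  }
  pct <- function(x) round(100 * x / n_total, 1)
  data.frame(factor = rows,
             n_fail = unname(counts[, "all"]),
             pct = pct(unname(counts[, "all"])),
             n_fail_male = unname(counts[, "male"]),
             pct_male = pct(unname(counts[, "male"])),
             n_fail_female = unname(counts[, "female"]),
             pct_female = pct(unname(counts[, "female"])))
}

#' Run the full analysis pipeline
#'
#' Generate (or load) a cohort, impute, classify baseline target
#' attainment, simulate the natural path and each requested scenario
#' under common random numbers, convert ledgers to health-economic
#' outcomes, and write Table-1/2/3-shaped CSVs plus the
#' per-complication decomposition and run metadata. Deterministic given
#' the configuration; rerunning writes byte-identical tables.
#'
#' @param config Named list (or path to a JSON file) with entries:
#'   `n` (synthetic cohort size) or `cohort_path`; `profile` (list of
#'   [cohort_profile()] overrides); `scenarios` (preset names among
#'   hba1c/bp/ldl/combined); `horizon`; `horizons` (reporting horizons);
#'   `master_seed`; `outdir`; optional `equation_catalog`,
#'   `biomarker_catalog`, `utility_catalog`, `cost_catalog` file paths;
#'   optional `time_to_target`, `coverage`.
#' @return Invisibly, a list with the cohort, ledgers, outcome tables
#'   and output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  outdir <- config$outdir %||% stop2("config$outdir is required")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$master_seed %||% 1L)
  horizon <- as.integer(config$horizon %||% 10L)
  horizons <- as.numeric(config$horizons %||% c(5, 10))
  horizons <- horizons[horizons <= horizon]
  stage <- function(nm, expr) tryCatch(expr, error = function(e)
    stop2("[", nm, "] ", conditionMessage(e)))

  cohort <- stage("cohort", {
    if (!is.null(config$cohort_path)) read_cohort(config$cohort_path)
    else {
      prof_args <- config$profile %||% list()
      prof_args$n <- config$n %||% prof_args$n %||% 5000L
      prof_args$seed <- prof_args$seed %||% seed
      generate_cohort(do.call(cohort_profile, prof_args))
    }
  })
  cohort <- stage("impute", impute_missing(cohort))

  equations <- stage("catalogs", {
    if (!is.null(config$equation_catalog))
      read_equation_catalog(config$equation_catalog)
    else default_equation_catalog()
  })
  bm_catalog <- if (!is.null(config$biomarker_catalog))
    read_biomarker_catalog(config$biomarker_catalog) else
      default_biomarker_catalog()
  ucat <- if (!is.null(config$utility_catalog))
    read_utility_catalog(config$utility_catalog) else utility_catalog()
  ccat <- if (!is.null(config$cost_catalog))
    read_cost_catalog(config$cost_catalog) else cost_catalog()

  presets <- scenario_presets(horizon,
                              config$time_to_target %||% 1L,
                              config$coverage %||% 1)
  wanted <- config$scenarios %||% c("hba1c", "bp", "ldl", "combined")
  bad <- setdiff(wanted, setdiff(names(presets), "natural"))
  if (length(bad)) stop2("[scenarios] unknown preset(s): ",
                         paste(bad, collapse = ", "))

  t1 <- stage("classify", render_table1(cohort))
  base_ledger <- stage("simulate",
                       simulate_cohort(cohort, equations, bm_catalog,
                                       NULL, horizon, seed))
  deltas <- list(); comp <- list(); ledgers <- list(natural = base_ledger)
  for (w in wanted) {
    led <- stage(paste0("simulate:", w),
                 simulate_cohort(cohort, equations, bm_catalog,
                                 presets[[w]], horizon, seed))
    ledgers[[w]] <- led
    d <- stage(paste0("economics:", w),
               aggregate_scenario_delta(base_ledger, led, cohort,
                                        presets[[w]], ucat, ccat,
                                        horizons))
    d$scenario <- w
    deltas[[w]] <- d
    cm <- composition_by_complication(base_ledger, led, ucat, ccat,
                                      horizon)
    cm$scenario <- w
    comp[[w]] <- cm
  }
  delta_tab <- data.table::rbindlist(deltas)
  comp_tab <- data.table::rbindlist(comp)

  tab2 <- format_population_table(delta_tab)
  tab3 <- format_perperson_table(delta_tab)

  paths <- c(table1 = file.path(outdir, "table1_target_failure.csv"),
             table2 = file.path(outdir, "table2_population.csv"),
             table3 = file.path(outdir, "table3_per_person.csv"),
             composition = file.path(outdir, "composition.csv"),
             deltas = file.path(outdir, "scenario_deltas.csv"))
  data.table::fwrite(t1, paths["table1"])
  data.table::fwrite(tab2, paths["table2"])
  data.table::fwrite(tab3, paths["table3"])
  data.table::fwrite(comp_tab, paths["composition"])
  data.table::fwrite(delta_tab, paths["deltas"])

  meta <- list(master_seed = seed, horizon = horizon,
               horizons = horizons, n = nrow(cohort),
               scenarios = wanted,
               config_hash = config_hash(config),
               generated = "t2dsim run_pipeline")
  jsonlite::write_json(meta, file.path(outdir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(cohort = cohort, table1 = t1, table2 = tab2,
                 table3 = tab3, deltas = delta_tab,
                 composition = comp_tab, ledgers = ledgers,
                 paths = paths, meta = meta))
}

# population-level table: sums to integers for QALYs/LYs, 2 dp costs
format_population_table <- function(delta_tab) {
  d <- data.table::copy(delta_tab)
  d$value <- ifelse(d$measure == "cost_saving",
                    round(d$population, 2), round(d$population))
  data.table::dcast(d, scenario + measure ~ stratum + horizon,
                    value.var = "value")
}

# per-person table: QALYs/LYs to 4 dp, costs to 2 dp
format_perperson_table <- function(delta_tab) {
  d <- data.table::copy(delta_tab)
  d$value <- ifelse(d$measure == "cost_saving",
                    round(d$per_person, 2), round(d$per_person, 4))
  data.table::dcast(d, scenario + measure ~ stratum + horizon,
                    value.var = "value")
}

# order-independent structural hash of the configuration (djb2-style on
# the canonical JSON serialisation; metadata only, not cryptographic)
config_hash <- function(config) {
  s <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE,
                        digits = NA)
  h <- 5381
  for (c in utf8ToInt(as.character(s))) h <- (h * 33 + c) %% 2147483647
  sprintf("%08x", as.integer(h))
}
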