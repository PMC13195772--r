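#' Assemble and validate a pipeline run configuration
#'
#' Inputs may be in-memory objects or file paths (CSV for tables, YAML for
#' the RR registry); paths are validated at configuration time, before any
#' computation.
#'
#' @param surveys named list, survey year -> survey data.frame or CSV path.
#' @param mortality death records data.frame or CSV path (columns year, sex,
#'   age, icd10).
#' @param benchmark per-capita benchmark data.frame (year, litres_per_capita)
#'   or CSV path.
#' @param registry an [rr_registry()] or YAML path.
#' @param populations data.frame (sex, age_group, population).
#' @param years analysis years (default: all years in `benchmark`).
#' @param coverage calibration coverage fraction.
#' @param cap consumption cap, grams/day.
#' @param grams_per_drink grams of pure alcohol per standard drink.
#' @param grid_n integration grid size.
#' @param standard_weights age-standardization weights.
#' @param mc list of [simulation_spec()] arguments (n_iterations, toggles).
#' @param seed master seed.
#' @param outdir optional output directory for CSV artifacts and manifest.
#' @return object of class `run_config`.
#' @export
run_config <- function(surveys, mortality, benchmark, registry, populations,
                       years = NULL, coverage = 1, cap = 150,
                       grams_per_drink = 14, grid_n = 1501,
                       standard_weights = who_standard_weights(),
                       mc = list(n_iterations = 10000), seed = 1L,
                       outdir = NULL) {
  check_path <- function(x, what) {
    if (is.character(x) && length(x) == 1 && !file.exists(x)) {
      stop(what, " file does not exist: ", x)
    }
    x
  }
  stopifnot(length(surveys) >= 1, !is.null(names(surveys)))
  for (y in names(surveys)) check_path(surveys[[y]], paste("survey", y))
  check_path(mortality, "mortality")
  check_path(benchmark, "benchmark")
  check_path(registry, "registry")
  stopifnot(all(c("sex", "age_group", "population") %in% names(populations)))
  cfg <- list(surveys = surveys, mortality = mortality, benchmark = benchmark,
              registry = registry, populations = populations, years = years,
              coverage = coverage, cap = cap,
              grams_per_drink = grams_per_drink, grid_n = grid_n,
              standard_weights = standard_weights, mc = mc,
              seed = as.integer(seed), outdir = outdir)
  structure(cfg, class = "run_config")
}

read_table_arg <- function(x) {
  if (is.character(x) && length(x) == 1) {
    utils::read.csv(x, stringsAsFactors = FALSE)
  } else {
    x
  }
}

#' Nearest survey year for an analysis year
#'
#' Surveys are biennial while mortality is annual; non-survey years use the
#' nearest survey year's exposure, ties broken toward the earlier year.
#'
#' @param year analysis year(s).
#' @param survey_years available survey years.
#' @return the assigned survey year(s).
#' @export
nearest_survey_year <- function(year, survey_years) {
  survey_years <- sort(as.integer(survey_years))
  vapply(as.integer(year), function(y) {
    d <- abs(survey_years - y)
    survey_years[which(d == min(d))[1]]   # earlier year wins ties
  }, integer(1))
}

#' Run the full attributable-mortality pipeline
#'
#' Stages: per-survey-year exposure estimation (status prevalences,
#' benchmark calibration, gamma fits, carry-forward), per-year AAF tables,
#' ICD-10 death mapping and attribution, crude and age-standardized rate
#' tables, and Monte Carlo percentile intervals that reuse one AAF draw
#' matrix per year for every derived quantity (full dependence preserved:
#' sums are taken per iteration, then percentiles). When `outdir` is set,
#' all tables are written as CSV together with a YAML run manifest (config
#' hash, seed, calibration factors, warnings).
#'
#' @param config a [run_config()].
#' @return list with `exposure`, `aafs`, `cells` (attributed deaths),
#'   `rates`, `intervals`, and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  reg <- if (is.character(config$registry)) {
    load_rr_registry(config$registry)
  } else {
    config$registry
  }
  benchmark <- read_table_arg(config$benchmark)
  mortality <- read_table_arg(config$mortality)
  years <- config$years %||% sort(unique(benchmark$year))
  warnings_log <- character(0)

  survey_years <- sort(as.integer(names(config$surveys)))
  exposure_by_sy <- list()
  for (sy in survey_years) {
    survey <- read_table_arg(config$surveys[[as.character(sy)]])
    bench_y <- benchmark$litres_per_capita[
      benchmark$year == nearest_survey_year(sy, benchmark$year)]
    ex <- withCallingHandlers(
      build_exposure(survey, bench_y[1], year = sy,
                     coverage = config$coverage, cap = config$cap,
                     grams_per_drink = config$grams_per_drink),
      warning = function(w) {
        warnings_log <<- c(warnings_log, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
    exposure_by_sy[[as.character(sy)]] <- ex
  }

  death_table <- build_death_table(mortality, reg)

  exposure_all <- list()
  aafs_all <- list()
  cells_all <- list()
  rates_all <- list()
  intervals_all <- list()
  for (y in years) {
    sy <- nearest_survey_year(y, survey_years)
    ex <- exposure_by_sy[[as.character(sy)]]
    ex$year <- y
    exposure_all[[as.character(y)]] <- ex
    aafs <- aaf_table(ex, reg, grid_n = config$grid_n)
    aafs_all[[as.character(y)]] <- aafs

    dt_y <- death_table
    dt_y$counts <- dt_y$counts[dt_y$counts$year == y, ]
    dt_y$totals <- dt_y$totals[dt_y$totals$year == y, ]
    if (nrow(dt_y$counts) == 0) next
    cells <- attributable_deaths(dt_y, aafs)
    cells_all[[as.character(y)]] <- cells
    rates_all[[as.character(y)]] <-
      rate_table(cells, dt_y, config$populations,
                 standard_weights = config$standard_weights)

    mc_args <- config$mc
    mc_args$seed <- (config$seed + y) %% .Machine$integer.max
    spec <- do.call(simulation_spec, mc_args)
    sim <- simulate_aafs(ex, reg, spec, grid_n = config$grid_n)
    intervals_all[[as.character(y)]] <-
      derived_intervals(sim, cells, dt_y, config$populations,
                        config$standard_weights)
  }

  out <- list(
    exposure = do.call(rbind, exposure_all),
    aafs = do.call(rbind, aafs_all),
    cells = do.call(rbind, cells_all),
    rates = do.call(rbind, rates_all),
    intervals = do.call(rbind, intervals_all)
  )
  rownames(out$exposure) <- rownames(out$aafs) <- rownames(out$cells) <-
    rownames(out$rates) <- rownames(out$intervals) <- NULL
  tf <- tempfile(fileext = ".rds")
  on.exit(unlink(tf), add = TRUE)
  saveRDS(unclass(config)[setdiff(names(config), "outdir")], tf, version = 2)
  out$manifest <- list(
    config_md5 = unname(tools::md5sum(tf)),
    seed = config$seed, years = as.integer(years),
    survey_years = survey_years,
    coverage = config$coverage, cap = config$cap,
    grid_n = config$grid_n,
    n_iterations = out$intervals$n_iter[1] %||% config$mc$n_iterations,
    calibration_factors = stats::setNames(
      vapply(exposure_by_sy, function(e) e$calibration_factor[1], 0),
      names(exposure_by_sy)),
    warnings = warnings_log,
    r_version = as.character(getRversion())
  )
  if (!is.null(config$outdir)) write_run_outputs(out, config)
  out
}

# per-iteration transforms of the AAF draw matrix: attributable counts,
# crude and age-standardized rates, proportion of total deaths
derived_intervals <- function(sim, cells, death_table, populations,
                              standard_weights) {
  key <- function(d) paste(d$sex, d$age_group, d$cause, sep = "|")
  deaths <- numeric(nrow(sim$cells))
  m <- match(key(sim$cells), key(cells))
  deaths[!is.na(m)] <- cells$deaths[m[!is.na(m)]]
  year <- cells$year[1]

  rows <- list()
  for (sx in c("male", "female", "all")) {
    in_g <- if (sx == "all") rep(TRUE, nrow(sim$cells)) else sim$cells$sex == sx
    pops <- populations[if (sx == "all") TRUE else populations$sex == sx, ]
    pop_g <- stats::aggregate(population ~ age_group, pops, sum)
    total <- sum(death_table$totals$total[
      if (sx == "all") TRUE else death_table$totals$sex == sx])
    # draws x age-group attributable sums
    ag_labels <- names(standard_weights)
    attr_ag <- vapply(ag_labels, function(ag) {
      sel <- in_g & sim$cells$age_group == ag
      if (!any(sel)) return(rep(0, nrow(sim$draws)))
      as.vector(sim$draws[, sel, drop = FALSE] %*% deaths[sel])
    }, numeric(nrow(sim$draws)))
    attr_ag <- matrix(attr_ag, nrow = nrow(sim$draws),
                      dimnames = list(NULL, ag_labels))
    attr_draws <- rowSums(attr_ag)
    pop_m <- pop_g$population[match(ag_labels, pop_g$age_group)]
    asr_draws <- as.vector(attr_ag %*% (standard_weights[ag_labels] / pop_m)) * 1e5
    point_attr <- sum(sim$point[in_g] * deaths[in_g])
    ci_a <- percentile_ci(attr_draws)
    ci_r <- percentile_ci(asr_draws)
    ci_p <- percentile_ci(100 * attr_draws / total)
    rows[[sx]] <- data.frame(
      year = year, sex = sx,
      attributable = point_attr,
      attributable_lo = ci_a[["lo"]], attributable_hi = ci_a[["hi"]],
      asr = age_standardize(
        vapply(ag_labels, function(ag)
          sum(sim$point[in_g & sim$cells$age_group == ag] *
                deaths[in_g & sim$cells$age_group == ag]), 0) / pop_m * 1e5,
        standard_weights, ag_labels),
      asr_lo = ci_r[["lo"]], asr_hi = ci_r[["hi"]],
      proportion_pct = proportion_of_total(point_attr, total),
      proportion_lo = ci_p[["lo"]], proportion_hi = ci_p[["hi"]],
      n_iter = sim$spec$n_iterations, seed = sim$spec$seed,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

write_run_outputs <- function(out, config) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    utils::write.csv(df, file.path(config$outdir, paste0(name, ".csv")),
                     row.names = FALSE)
  }
  wr(out$exposure, "exposure")
  wr(out$aafs, "aaf")
  wr(out$cells, "attributable_deaths")
  wr(out$rates, "rates")
  wr(out$intervals, "intervals")
  yaml::write_yaml(out$manifest, file.path(config$outdir, "manifest.yaml"),
                   precision = 15)
  invisible(config$outdir)
}

#' Trend tables for reporting
#'
#' Reshapes a [run_pipeline()] result into the five standard trend tables:
#' attributable proportion of total deaths by sex and year, age-standardized
#' attributable rates by sex and year, attributable rates by sex x age group
#' and year, and cause composition of attributable deaths by sex x age group
#' and year (one table per sex).
#'
#' @param result a [run_pipeline()] result.
#' @param populations data.frame (sex, age_group, population) for the
#'   sex-by-age rate table.
#' @return named list of five data.frames: `proportion_by_sex`,
#'   `asr_by_sex`, `rates_by_sex_age`, `causes_female`, `causes_male`.
#' @export
report_tables <- function(result, populations) {
  iv <- result$intervals
  prop <- iv[c("year", "sex", "proportion_pct", "proportion_lo", "proportion_hi")]
  asr <- iv[c("year", "sex", "asr", "asr_lo", "asr_hi")]
  by_age <- stats::aggregate(attributable ~ year + sex + age_group,
                             result$cells, sum)
  key <- function(d) paste(d$sex, d$age_group)
  by_age$population <-
    populations$population[match(key(by_age), key(populations))]
  by_age$rate <- by_age$attributable / by_age$population * 1e5
  comp <- stats::aggregate(attributable ~ year + sex + age_group + cause,
                           result$cells, sum)
  list(
    proportion_by_sex = prop,
    asr_by_sex = asr,
    rates_by_sex_age = by_age,
    causes_female = comp[comp$sex == "female", ],
    causes_male = comp[comp$sex == "male", ]
  )
}
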