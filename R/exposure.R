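#' Survey-weighted drinker-status prevalences for one stratum
#'
#' Horvitz-Thompson style weighted shares of lifetime abstainers, former and
#' current drinkers, plus the weighted HED probability among current
#' drinkers.
#'
#' @param survey survey data.frame (see [generate_survey()] for columns).
#' @param sex,age_group the stratum to estimate.
#' @return named numeric vector (p_abstainer, p_former, p_current, p_hed);
#'   the first three sum to 1. Attribute "n" carries the respondent count,
#'   "n_current" the current-drinker count.
#' @export
weighted_prevalence <- function(survey, sex, age_group) {
  rows <- survey[survey$sex == sex & survey$age_group == age_group, ]
  rows <- rows[!is.na(rows$weight) & rows$weight > 0, ]
  if (nrow(rows) == 0) {
    stop("no respondents with positive weight in stratum ",
         sex, "/", age_group)
  }
  status <- classify_status(rows$past_year, rows$past_month)
  keep <- !is.na(status)
  rows <- rows[keep, ]
  status <- status[keep]
  w <- rows$weight
  share <- function(s) sum(w[status == s]) / sum(w)
  cur <- status == "current"
  p_hed <- if (any(cur)) {
    hed <- hed_status(rows$sex[cur], rows$quantity[cur], rows$hed_frequency[cur])
    sum(w[cur][hed]) / sum(w[cur])
  } else {
    NA_real_
  }
  out <- c(p_abstainer = share("abstainer"), p_former = share("former"),
           p_current = share("current"), p_hed = p_hed)
  attr(out, "n") <- nrow(rows)
  attr(out, "n_current") <- sum(cur)
  out
}

#' Calibrate survey consumption to a per-capita benchmark
#'
#' Self-reported consumption underestimates true population consumption;
#' recorded-plus-unrecorded per-capita benchmarks (litres of pure alcohol per
#' person 15+ per year) anchor the total. All current drinkers' grams/day are
#' multiplied by a single factor f = (coverage x benchmark, in grams/day per
#' capita) / (survey-implied grams/day per capita), where the survey-implied
#' per-capita is the weighted mean over all respondents (drinkers and
#' non-drinkers). Calibration is exactly multiplicative: ratios between
#' drinkers are preserved.
#'
#' @param grams grams/day of current drinkers.
#' @param weights their survey weights.
#' @param total_weight summed weight of the full survey population
#'   (drinkers and non-drinkers) sharing the benchmark denominator.
#' @param benchmark per-capita consumption, litres/person-year (> 0).
#' @param coverage fraction of the benchmark the survey population is
#'   expected to account for, in (0, 1] (default 1).
#' @return list with `grams` (calibrated values) and `factor` (the
#'   multiplier applied, recorded for audit).
#' @export
calibrate_consumption <- function(grams, weights, total_weight,
                                  benchmark, coverage = 1) {
  stopifnot(length(grams) == length(weights), total_weight > 0)
  if (benchmark <= 0) stop("benchmark must be positive")
  if (coverage <= 0 || coverage > 1) stop("coverage must be in (0, 1]")
  survey_percap <- sum(grams * weights) / total_weight
  if (survey_percap <= 0) {
    stop("survey-implied per-capita consumption is zero; cannot calibrate")
  }
  target <- coverage * litres_per_year_to_grams_per_day(benchmark)
  f <- target / survey_percap
  list(grams = grams * f, factor = f)
}

#' Weighted maximum-likelihood gamma fit
#'
#' Smooths an empirical consumption distribution by a gamma density. The
#' weighted MLE solves log(k) - digamma(k) = log(weighted mean) - weighted
#' mean of logs for the shape k (by root bracketing), with scale = weighted
#' mean / k. When the root cannot be bracketed (e.g. near-zero weighted
#' log-variance) the weighted method of moments is used instead, with a
#' warning; a zero-variance sample is flagged as degenerate.
#'
#' @param x strictly positive consumption values (grams/day); at least 10.
#' @param weights optional positive weights (default equal).
#' @param min_n minimum number of positive observations (default 10).
#' @return named vector (shape, scale); attribute "method" is "mle",
#'   "moments" or "degenerate".
#' @export
fit_gamma <- function(x, weights = NULL, min_n = 10) {
  x <- x[!is.na(x)]
  if (is.null(weights)) weights <- rep(1, length(x))
  keep <- x > 0 & weights > 0
  x <- x[keep]
  weights <- weights[keep]
  if (length(x) < min_n) {
    stop("fewer than ", min_n, " positive consumption values; cannot fit gamma")
  }
  w <- weights / sum(weights)
  m <- sum(w * x)
  s <- log(m) - sum(w * log(x))       # >= 0 by Jensen; 0 iff all values equal
  method <- "mle"
  if (s < 1e-12) {
    out <- c(shape = Inf, scale = 0)
    attr(out, "method") <- "degenerate"
    warning("zero-variance consumption sample; gamma fit degenerate")
    return(out)
  }
  k <- tryCatch(
    stats::uniroot(function(k) log(k) - digamma(k) - s,
                   interval = c(1e-8, 1e8), tol = 1e-10)$root,
    error = function(e) NA_real_
  )
  if (is.na(k) || !is.finite(k) || k <= 0) {
    v <- sum(w * (x - m)^2)
    k <- m^2 / v
    method <- "moments"
    warning("gamma likelihood optimization failed; using weighted method of moments")
  }
  out <- c(shape = k, scale = m / k)
  attr(out, "method") <- method
  out
}

#' Carry the oldest surveyed age group forward to older strata
#'
#' Surveys cover ages 15-64 only; exposure for age groups above the survey
#' ceiling is assumed to equal the oldest surveyed group's distribution (per
#' sex and year). Carried strata are flagged `imputed`.
#'
#' @param exposure exposure data.frame (one row per stratum; columns `sex`,
#'   `age_group`, optionally `year`).
#' @param age_groups full ordered set of analysis age groups (default
#'   [default_age_groups()]).
#' @return the exposure data.frame completed to all `age_groups`, with a
#'   logical `imputed` column.
#' @export
carry_forward_oldest <- function(exposure, age_groups = default_age_groups()) {
  if (!"imputed" %in% names(exposure)) exposure$imputed <- FALSE
  if (!"year" %in% names(exposure)) exposure$year <- NA_integer_
  out <- exposure
  for (yr in unique(exposure$year)) for (sx in unique(exposure$sex)) {
    sub <- exposure[exposure$sex == sx &
                      (is.na(yr) | exposure$year %in% yr), ]
    present <- intersect(age_groups, sub$age_group)
    if (length(present) == 0) {
      stop("no surveyed age group for sex ", sx, "; cannot carry forward")
    }
    oldest <- present[length(present)]
    missing_groups <- setdiff(age_groups, sub$age_group)
    # only groups older than the oldest surveyed group inherit
    missing_groups <- missing_groups[match(missing_groups, age_groups) >
                                       match(oldest, age_groups)]
    for (ag in missing_groups) {
      row <- sub[sub$age_group == oldest, ][1, ]
      row$age_group <- ag
      row$imputed <- TRUE
      out <- rbind(out, row)
    }
  }
  out[order(out$year, out$sex, match(out$age_group, age_groups)), ]
}

#' Build per-stratum exposure distributions from a survey
#'
#' The full exposure stage: classify drinker status, estimate weighted
#' prevalences and HED probability, quantify each current drinker's
#' grams/day from the quantity-frequency items, calibrate all values to the
#' per-capita benchmark with a single survey-wide factor, fit a gamma
#' distribution per stratum (weighted MLE), and complete missing older
#' strata by carry-forward. Strata with fewer than `min_n` positive values
#' borrow the same-sex adjacent age group's gamma parameters, with a
#' warning and the `imputed` flag set.
#'
#' @param survey survey microdata (see [generate_survey()] columns).
#' @param benchmark per-capita benchmark in litres/person-year.
#' @param year calendar year recorded on the output (default NA).
#' @param coverage calibration coverage fraction in (0, 1].
#' @param cap consumption cap in grams/day (default 150).
#' @param grams_per_drink grams of pure alcohol per standard drink.
#' @param age_groups analysis age groups to complete by carry-forward.
#' @param min_n minimum positive observations for a stratum fit.
#' @return exposure data.frame, one row per sex x age group, with columns
#'   year, sex, age_group, p_abstainer, p_former, p_current, p_hed, shape,
#'   scale, cap, calibration_factor, n, n_current, imputed.
#' @export
build_exposure <- function(survey, benchmark, year = NA_integer_,
                           coverage = 1, cap = 150, grams_per_drink = 14,
                           age_groups = default_age_groups(), min_n = 10) {
  status <- classify_status(survey$past_year, survey$past_month)
  survey <- survey[!is.na(status) & survey$weight > 0, ]
  status <- status[!is.na(status)]
  grams <- ifelse(status == "current",
                  grams_per_day(survey$frequency, survey$quantity,
                                grams_per_drink),
                  0)
  cur <- status == "current"
  cal <- calibrate_consumption(grams[cur], survey$weight[cur],
                               total_weight = sum(survey$weight),
                               benchmark = benchmark, coverage = coverage)
  grams_cal <- grams
  grams_cal[cur] <- pmin(cal$grams, cap)

  strata <- unique(survey[c("sex", "age_group")])
  strata <- strata[order(strata$sex, match(strata$age_group, age_groups)), ]
  rows <- list()
  for (i in seq_len(nrow(strata))) {
    sx <- strata$sex[i]
    ag <- strata$age_group[i]
    prev <- weighted_prevalence(survey, sx, ag)
    in_str <- cur & survey$sex == sx & survey$age_group == ag
    g <- grams_cal[in_str]
    w <- survey$weight[in_str]
    fit <- tryCatch(fit_gamma(g, w, min_n = min_n), error = function(e) NULL)
    rows[[i]] <- data.frame(
      year = year, sex = sx, age_group = ag,
      p_abstainer = prev[["p_abstainer"]], p_former = prev[["p_former"]],
      p_current = prev[["p_current"]], p_hed = prev[["p_hed"]],
      shape = if (is.null(fit)) NA_real_ else fit[["shape"]],
      scale = if (is.null(fit)) NA_real_ else fit[["scale"]],
      cap = cap, calibration_factor = cal$factor,
      n = attr(prev, "n"), n_current = attr(prev, "n_current"),
      imputed = FALSE, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)

  # sparse strata borrow the same-sex adjacent age group's gamma parameters
  for (i in which(is.na(out$shape))) {
    sx <- out$sex[i]
    pos <- match(out$age_group[i], age_groups)
    neighbors <- order(abs(match(out$age_group, age_groups) - pos))
    donor <- neighbors[out$sex[neighbors] == sx & !is.na(out$shape[neighbors])][1]
    if (is.na(donor)) {
      stop("no same-sex stratum with a gamma fit to borrow for ",
           sx, "/", out$age_group[i])
    }
    out$shape[i] <- out$shape[donor]
    out$scale[i] <- out$scale[donor]
    out$imputed[i] <- TRUE
    warning("stratum ", sx, "/", out$age_group[i],
            " too sparse to fit; borrowing gamma parameters from ",
            out$sex[donor], "/", out$age_group[donor])
  }
  carry_forward_oldest(out, age_groups)
}
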