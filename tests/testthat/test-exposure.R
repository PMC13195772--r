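test_that("weighted prevalences are Horvitz-Thompson shares summing to one", {
  sv <- data.frame(
    sex = "male", age_group = "30-44", weight = c(3, 1),
    past_year = c("yes", "yes"), past_month = c("yes", "no"),
    frequency = c("2-3_per_week", "monthly_or_less"),
    quantity = c("3-4", "1-2"), hed_frequency = "never",
    stringsAsFactors = FALSE
  )
  prev <- weighted_prevalence(sv, "male", "30-44")
  expect_equal(prev[["p_current"]], 0.75)
  expect_equal(prev[["p_former"]], 0.25)
  expect_equal(sum(prev[c("p_abstainer", "p_former", "p_current")]), 1,
               tolerance = 1e-12)
  # equal weights reduce to unweighted proportions
  sv$weight <- 2
  expect_equal(weighted_prevalence(sv, "male", "30-44")[["p_current"]], 0.5)
  expect_error(weighted_prevalence(sv, "female", "30-44"), "no respondents")
})

test_that("benchmark calibration is an exact multiplicative rescale", {
  g <- c(5, 10, 40)
  w <- c(1, 2, 1)
  total_w <- 10   # drinkers plus non-drinkers
  implied <- sum(g * w) / total_w
  # benchmark equal to what the survey already implies: factor 1
  cal <- calibrate_consumption(g, w, total_w,
                               grams_per_day_to_litres_per_year(implied))
  expect_equal(cal$factor, 1, tolerance = 1e-12)
  expect_equal(cal$grams, g, tolerance = 1e-12)
  # survey captures half the benchmark: all values double
  cal2 <- calibrate_consumption(g, w, total_w,
                                grams_per_day_to_litres_per_year(2 * implied))
  expect_equal(cal2$factor, 2, tolerance = 1e-12)
  expect_equal(cal2$grams, 2 * g, tolerance = 1e-12)
  # ratios between drinkers preserved exactly
  cal3 <- calibrate_consumption(g, w, total_w, 7.3, coverage = 0.8)
  expect_equal(cal3$grams[2] / cal3$grams[1], g[2] / g[1], tolerance = 1e-12)
  tgt <- 0.8 * litres_per_year_to_grams_per_day(7.3)
  expect_equal(sum(cal3$grams * w) / total_w, tgt, tolerance = 1e-9)
  expect_error(calibrate_consumption(c(0, 0), c(1, 1), 4, 7.3),
               "cannot calibrate")
  expect_error(calibrate_consumption(g, w, total_w, -1), "benchmark")
  expect_error(calibrate_consumption(g, w, total_w, 7.3, coverage = 1.4),
               "coverage")
})

test_that("weighted gamma MLE recovers known parameters", {
  set.seed(42)
  x <- rgamma(5000, shape = 2, scale = 10)
  fit <- fit_gamma(x)
  expect_lt(abs(fit[["shape"]] / 2 - 1), 0.10)
  expect_lt(abs(fit[["scale"]] / 10 - 1), 0.10)
  # fitted mean tracks the sample mean closely (MLE moment identity)
  expect_equal(fit[["shape"]] * fit[["scale"]], mean(x), tolerance = 1e-6)
  # equal weights match no weights
  fit_w <- fit_gamma(x, weights = rep(3.7, length(x)))
  expect_equal(unclass(fit_w), unclass(fit), tolerance = 1e-9)
  # independent route: unweighted MLE from fitdistrplus agrees
  skip_if_not_installed("fitdistrplus")
  ref <- fitdistrplus::fitdist(x, "gamma")
  expect_equal(fit[["shape"]], unname(ref$estimate["shape"]), tolerance = 1e-3)
  expect_equal(fit[["scale"]], 1 / unname(ref$estimate["rate"]), tolerance = 1e-3)
})

test_that("gamma fit guards sparse and degenerate inputs", {
  expect_error(fit_gamma(c(1, 2, 3)), "fewer than 10")
  expect_warning(fit <- fit_gamma(rep(5, 20)), "degenerate")
  expect_equal(attr(fit, "method"), "degenerate")
  # weighting matters: upweighting large values raises the fitted mean
  x <- c(rep(2, 50), rep(20, 50))
  w_hi <- c(rep(1, 50), rep(5, 50))
  expect_gt(fit_gamma(x, w_hi)[["shape"]] * fit_gamma(x, w_hi)[["scale"]],
            fit_gamma(x)[["shape"]] * fit_gamma(x)[["scale"]])
})

test_that("the oldest surveyed age group carries forward to older strata", {
  ex <- data.frame(
    year = 2015L, sex = rep(c("male", "female"), each = 3),
    age_group = rep(c("15-29", "30-44", "45-59"), 2),
    p_abstainer = 0.3, p_former = 0.2, p_current = 0.5, p_hed = 0.3,
    shape = rep(c(1.5, 1.7, 1.8), 2), scale = 10, cap = 150,
    stringsAsFactors = FALSE
  )
  out <- carry_forward_oldest(ex)
  expect_equal(nrow(out), 8)
  m60 <- out[out$sex == "male" & out$age_group == "60+", ]
  expect_equal(m60$shape, 1.8)   # copied from 45-59
  expect_true(m60$imputed)
  expect_false(any(out$imputed[out$age_group != "60+"]))
  # complete exposure set is a no-op
  out2 <- carry_forward_oldest(out)
  expect_equal(nrow(out2), nrow(out))
  expect_identical(out2$imputed, out$imputed)
})

test_that("full exposure stage recovers scenario truth from a synthetic survey", {
  sc <- default_scenario()
  sv <- generate_survey(sc, 10000, seed = 77)
  bm <- generate_benchmark(sc, undercoverage = 0.6)
  ex <- build_exposure(sv, bm$litres_per_capita[1], year = 2015,
                       coverage = 0.6)
  st <- sc$strata
  m <- match(paste(ex$sex, ex$age_group), paste(st$sex, st$age_group))
  # calibrated per-capita equals truth to numerical precision
  truth_percap <- sum(st$population * st$p_current * st$shape * st$scale) /
    sum(st$population)
  status <- classify_status(sv$past_year, sv$past_month)
  g <- ifelse(status == "current",
              grams_per_day(sv$frequency, sv$quantity), 0) *
    ex$calibration_factor[1]
  expect_equal(sum(g * sv$weight) / sum(sv$weight), truth_percap,
               tolerance = 1e-6)
  # gamma parameters within 15% (categorization coarsening included)
  expect_true(all(abs(ex$shape / st$shape[m] - 1) < 0.15))
  expect_true(all(abs(ex$scale / st$scale[m] - 1) < 0.15))
  # fitted mean within 5% of the weighted sample mean per stratum
  for (i in seq_len(nrow(ex))) {
    sel <- status == "current" & sv$sex == ex$sex[i] &
      sv$age_group == ex$age_group[i]
    wm <- sum(g[sel] * sv$weight[sel]) / sum(sv$weight[sel])
    expect_lt(abs(ex$shape[i] * ex$scale[i] / wm - 1), 0.05)
  }
})
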