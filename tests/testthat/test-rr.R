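test_that("RR functional forms evaluate to their closed forms", {
  lin <- rr_function("c", "all", "all", "current", "log-linear", 0.01)
  expect_equal(rr_evaluate(lin, 100), exp(1))
  expect_equal(rr_evaluate(lin, 0), 1)
  quad <- rr_function("c", "all", "all", "current", "log-quadratic",
                      c(0.01, -2e-5))
  expect_equal(rr_evaluate(quad, 50), exp(0.01 * 50 - 2e-5 * 2500))
  expect_equal(rr_evaluate(quad, 0), 1)
  frm <- rr_function("c", "all", "all", "former", "constant", log(1.2))
  expect_equal(rr_evaluate(frm, c(0, 30, 150)), rep(1.2, 3))
  expect_error(rr_evaluate(lin, -1), "non-negative")
  expect_error(rr_evaluate(lin, 200), "validity range")
  # monotone in the slope for fixed positive dose
  slopes <- seq(-0.01, 0.03, by = 0.005)
  vals <- vapply(slopes, function(b) {
    rr_evaluate(rr_function("c", "all", "all", "current", "log-linear", b), 40)
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("coefficient constructors enforce form arity and PSD covariance", {
  expect_error(rr_function("c", "all", "all", "current", "log-linear",
                           c(1, 2)), "1 coefficient")
  expect_error(rr_function("c", "all", "all", "current", "log-quadratic",
                           0.1), "2 coefficient")
  expect_error(rr_function("c", "all", "all", "current", "log-quadratic",
                           c(0.1, 0), cov = matrix(c(1, 2, 2, 1), 2)),
               "positive semi-definite")
  expect_error(rr_function("c", "all", "all", "current", "log-quadratic",
                           c(0.1, 0), cov = matrix(c(1, 0.5, 0.2, 1), 2)),
               "symmetric")
})

test_that("coefficient draws follow the stated (multivariate) normal law", {
  # zero covariance is a point mass
  fn0 <- rr_function("c", "all", "all", "current", "log-linear", 0.02)
  expect_equal(rr_draw(fn0, 5), matrix(0.02, 5, 1))
  # single coefficient: mean within 3 SE, SD within 10%
  fn1 <- rr_function("c", "all", "all", "current", "log-linear", 0.02,
                     cov = 0.004^2)
  set.seed(1)
  d <- rr_draw(fn1, 10000)
  expect_lt(abs(mean(d) - 0.02), 3 * 0.004 / sqrt(10000))
  expect_lt(abs(sd(d) / 0.004 - 1), 0.10)
  # two coefficients: empirical correlation within 0.05 of specified
  Sigma <- matrix(c(1e-4, -0.6 * 1e-4 * 0.5, -0.6 * 1e-4 * 0.5, 1e-4 * 0.25),
                  2, 2) # correlation -0.6
  fn2 <- rr_function("c", "all", "all", "current", "log-quadratic",
                     c(0.01, -1e-5), cov = Sigma)
  set.seed(2)
  d2 <- rr_draw(fn2, 10000)
  expect_lt(abs(cor(d2[, 1], d2[, 2]) - (-0.6)), 0.05)
  # seeded draws reproduce
  set.seed(3); a <- rr_draw(fn2, 10)
  set.seed(3); b <- rr_draw(fn2, 10)
  expect_identical(a, b)
})

test_that("registry validation lists missing coverage and code conflicts", {
  # missing former-drinker function
  expect_error(rr_registry(list(c1 = list(
    icd10 = "K70", attribution = "partially_attributable",
    hed_stratified = FALSE,
    functions = list(rr_function("c1", "all", "all", "current",
                                 "log-linear", 0.01))
  ))), "missing former")
  # two causes claiming K70
  expect_error(rr_registry(list(
    c1 = list(icd10 = "K70", attribution = "fully_attributable",
              hed_stratified = FALSE, functions = list()),
    c2 = list(icd10 = "K70-K74", attribution = "fully_attributable",
              hed_stratified = FALSE, functions = list())
  )), "multiple causes")
  # fully attributable causes must not carry RR functions
  expect_error(rr_registry(list(c1 = list(
    icd10 = "F10", attribution = "fully_attributable",
    hed_stratified = FALSE,
    functions = list(rr_function("c1", "all", "all", "current",
                                 "log-linear", 0.01))
  ))), "fully attributable")
})

test_that("the shipped illustrative registry loads and round-trips exactly", {
  path <- system.file("extdata", "rr_registry_illustrative.yaml",
                      package = "aafmort")
  reg <- load_rr_registry(path)
  # covers both sexes and all four age groups for each partial cause
  for (nm in names(reg$causes)) {
    ca <- reg$causes[[nm]]
    if (ca$attribution != "partially_attributable") next
    for (sx in c("male", "female")) for (ag in default_age_groups()) {
      grp <- if (ca$hed_stratified) "current_hed" else "current"
      expect_s3_class(rr_lookup(reg, nm, sx, ag, grp), "rr_function")
    }
  }
  # load -> serialize -> load preserves coefficients to 1e-12
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_rr_registry(reg, tmp)
  reg2 <- load_rr_registry(tmp)
  coefs <- function(r) unlist(lapply(r$causes, function(ca)
    lapply(ca$functions, function(f) c(f$beta, f$cov))))
  expect_equal(coefs(reg2), coefs(reg), tolerance = 1e-12)
  # exact sex-specific entries beat wildcards
  fn <- rr_lookup(reg, "liver_cirrhosis", "female", "30-44", "current")
  expect_equal(fn$sex, "female")
})
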