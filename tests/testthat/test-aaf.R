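test_that("trapezoidal rule handles identities and matches adaptive quadrature", {
  x <- aaf_grid(150, 1501)
  dens <- trunc_gamma_density(x, 2, 10, 150)
  # zero integrand integrates to zero; proper density to one
  expect_equal(trapezoid_integral(x, dens, rep(0, length(x))), 0)
  # the renormalized density is a proper distribution (quadrature identity)
  expect_equal(integrate(function(v) trunc_gamma_density(v, 2, 10, 150),
                         0, 150, rel.tol = 1e-9)$value, 1, tolerance = 1e-6)
  # the bare rule carries a small discretization leak near the origin,
  # which the AAF routines correct for (see the constant-RR tests)
  expect_equal(trapezoid_integral(x, dens), 1, tolerance = 2e-5)
  expect_equal(trapezoid_integral(x, dens, rep(3.7, length(x))), 3.7,
               tolerance = 2e-5)
  # against stats::integrate on a log-linear excess-risk integrand
  f <- function(v) trunc_gamma_density(v, 2, 10, 150) * (exp(0.01 * v) - 1)
  ref <- integrate(f, 0, 150, rel.tol = 1e-10)$value
  expect_equal(trapezoid_integral(x, dens, exp(0.01 * x) - 1), ref,
               tolerance = 1e-6)
  expect_error(trapezoid_integral(x, dens[-1]), "lengths differ")
  expect_error(trapezoid_integral(rev(x), dens), "ascending")
})

test_that("constant-RR AAFs equal the closed form p(RR-1)/(p(RR-1)+1)", {
  for (p in c(0.1, 0.3, 0.5, 0.8)) {
    for (rr in c(0.7, 0.9, 1, 1.5, 2, 4)) {
      est <- compute_aaf(fixture_exposure(p_current = p),
                         rr_function("c", "all", "all", "current",
                                     "constant", log(rr)),
                         rr_function("c", "all", "all", "former",
                                     "constant", 0))
      expect_equal(est$aaf, p * (rr - 1) / (p * (rr - 1) + 1),
                   tolerance = 1e-9,
                   label = sprintf("AAF(p=%g, RR=%g)", p, rr))
    }
  }
  # worked negative case: protective RR 0.8 at p = 0.5 gives -1/9
  est <- compute_aaf(fixture_exposure(p_current = 0.5),
                     rr_function("c", "all", "all", "current", "constant",
                                 log(0.8)),
                     rr_function("c", "all", "all", "former", "constant", 0))
  expect_equal(est$aaf, -1 / 9, tolerance = 1e-9)
  # former drinkers enter through the constant excess term
  est2 <- compute_aaf(fixture_exposure(p_former = 0.2, p_current = 0.5),
                      rr_function("c", "all", "all", "current", "constant",
                                  log(2)),
                      rr_function("c", "all", "all", "former", "constant",
                                  log(1.3)))
  n_num <- 0.2 * 0.3 + 0.5 * 1
  expect_equal(est2$aaf, n_num / (n_num + 1), tolerance = 1e-9)
})

test_that("trapezoidal AAF matches the quadrature oracle on random fixtures", {
  set.seed(314)
  for (r in 1:50) {
    ex <- fixture_exposure(
      p_former = runif(1, 0, 0.3),
      p_current = runif(1, 0.2, 0.7),
      shape = runif(1, 1.5, 4),
      scale = runif(1, 5, 20)
    )
    fn_c <- rr_function("c", "all", "all", "current", "log-quadratic",
                        c(runif(1, 0.005, 0.02), runif(1, -6e-5, 6e-5)))
    fn_f <- rr_function("c", "all", "all", "former", "constant",
                        log(runif(1, 0.9, 1.5)))
    est <- compute_aaf(ex, fn_c, fn_f)
    ref <- quadrature_aaf(ex, fn_c, fn_f)
    expect_equal(est$aaf, ref, tolerance = 1e-6,
                 label = sprintf("fixture %d", r))
  }
})

test_that("HED decomposition collapses to the plain integral when risks agree", {
  fn <- rr_function("c", "all", "all", "current", "log-linear", 0.012)
  fn_n <- rr_function("c", "all", "all", "current_non_hed", "log-linear", 0.012)
  fn_h <- rr_function("c", "all", "all", "current_hed", "log-linear", 0.012)
  fn_f <- rr_function("c", "all", "all", "former", "constant", log(1.2))
  for (ph in c(0, 0.3, 1)) {
    ex <- fixture_exposure(p_former = 0.15, p_current = 0.55, p_hed = ph)
    a1 <- compute_aaf_hed(ex, fn_n, fn_h, fn_f)
    a2 <- compute_aaf(ex, fn, fn_f)
    expect_equal(a1$aaf, a2$aaf, tolerance = 1e-10,
                 label = sprintf("p_hed=%g", ph))
  }
  # p_hed = 1 with constant HED risk reproduces the constant closed form
  exh <- fixture_exposure(p_former = 0, p_current = 0.5, p_hed = 1)
  cn <- rr_function("c", "all", "all", "current_non_hed", "constant", 0)
  ch <- rr_function("c", "all", "all", "current_hed", "constant", log(2))
  est <- compute_aaf_hed(exh, cn, ch,
                         rr_function("c", "all", "all", "former",
                                     "constant", 0))
  expect_equal(est$aaf, 1 / 3, tolerance = 1e-9)
  expect_error(compute_aaf_hed(within(exh, rm(p_hed)), cn, ch, fn_f),
               "p_hed")
})

test_that("all consumption above the split is carried by the HED risk curve", {
  # with p_hed = 0, risk above 60 g still follows the HED function
  ex <- fixture_exposure(p_former = 0, p_current = 0.6, p_hed = 0,
                         shape = 2, scale = 20)
  cn <- rr_function("c", "all", "all", "current_non_hed", "constant", 0)
  ch <- rr_function("c", "all", "all", "current_hed", "constant", log(3))
  est <- compute_aaf_hed(ex, cn, ch,
                         rr_function("c", "all", "all", "former",
                                     "constant", 0))
  mass_hi <- integrate(function(v) trunc_gamma_density(v, 2, 20, 150),
                       60, 150, rel.tol = 1e-10)$value
  n_ref <- 0.6 * mass_hi * 2    # (RR - 1) on the upper segment only
  expect_equal(est$aaf, n_ref / (n_ref + 1), tolerance = 1e-5)
  expect_equal(est$components[["current_hed_sub_threshold"]], 0)
  expect_equal(est$components[["current_non_hed"]], 0)
})

test_that("component breakdown reassembles the numerator and converges in grid size", {
  ex <- fixture_exposure(p_former = 0.2, p_current = 0.5, p_hed = 0.4)
  fn_n <- rr_function("c", "all", "all", "current_non_hed", "log-quadratic",
                      c(-0.005, 6e-5))
  fn_h <- rr_function("c", "all", "all", "current_hed", "log-linear", 0.01)
  fn_f <- rr_function("c", "all", "all", "former", "constant", log(1.2))
  est <- compute_aaf_hed(ex, fn_n, fn_h, fn_f)
  expect_equal(sum(est$components), est$numerator, tolerance = 1e-10)
  expect_equal(est$aaf, est$numerator / (est$numerator + 1), tolerance = 1e-12)
  # refining the grid tenfold moves the estimate by less than 1e-5
  est_fine <- compute_aaf_hed(ex, fn_n, fn_h, fn_f, grid_n = 15001)
  expect_lt(abs(est$aaf - est_fine$aaf), 1e-5)
  est2 <- compute_aaf(ex, fn_h, fn_f)
  est2_fine <- compute_aaf(ex, fn_h, fn_f, grid_n = 15001)
  expect_lt(abs(est2$aaf - est2_fine$aaf), 1e-5)
})

test_that("pointwise-larger risk functions never lower the AAF", {
  set.seed(99)
  fn_f <- rr_function("c", "all", "all", "former", "constant", 0)
  for (r in 1:20) {
    ex <- fixture_exposure(p_current = runif(1, 0.2, 0.7),
                           shape = runif(1, 1.2, 3), scale = runif(1, 6, 18))
    b <- runif(1, 0, 0.02)
    lo <- compute_aaf(ex, rr_function("c", "all", "all", "current",
                                      "log-linear", b), fn_f)
    hi <- compute_aaf(ex, rr_function("c", "all", "all", "current",
                                      "log-linear", b + runif(1, 0, 0.01)),
                      fn_f)
    expect_gte(hi$aaf, lo$aaf)
  }
})

test_that("fully attributable causes bypass integration with AAF exactly 1", {
  reg <- rr_registry(list(
    aud = list(icd10 = "F10", attribution = "fully_attributable",
               hed_stratified = FALSE, functions = list()),
    cirr = constant_rr_registry()$causes$fixture_cause
  ))
  est <- fully_attributable_aaf(reg, "aud")
  expect_identical(est$aaf, 1)
  expect_true(all(est$components == 0))
  expect_error(fully_attributable_aaf(reg, "cirr"), "not fully attributable")
  expect_error(fully_attributable_aaf(reg, "nope"), "unknown cause")
})
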