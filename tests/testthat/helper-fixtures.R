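# Shared fixtures: small scenarios and minimal registries built in code.

# registry with a single partially attributable cause and constant RR
# functions; the constant-RR closed form p (RR - 1) / (p (RR - 1) + 1)
# then serves as an analytic oracle for the integration pipeline
constant_rr_registry <- function(rr_current = 2, rr_former = 1,
                                 hed_stratified = FALSE,
                                 rr_hed = rr_current) {
  fns <- if (hed_stratified) {
    list(
      rr_function("fixture_cause", "all", "all", "current_non_hed",
                  "constant", log(rr_current)),
      rr_function("fixture_cause", "all", "all", "current_hed",
                  "constant", log(rr_hed)),
      rr_function("fixture_cause", "all", "all", "former",
                  "constant", log(rr_former))
    )
  } else {
    list(
      rr_function("fixture_cause", "all", "all", "current",
                  "constant", log(rr_current)),
      rr_function("fixture_cause", "all", "all", "former",
                  "constant", log(rr_former))
    )
  }
  rr_registry(list(fixture_cause = list(
    icd10 = "K70", attribution = "partially_attributable",
    hed_stratified = hed_stratified, functions = fns
  )))
}

# one-stratum exposure row, defaults chosen for analytic tractability
fixture_exposure <- function(p_former = 0, p_current = 0.5, p_hed = 0.3,
                             shape = 2, scale = 10, cap = 150,
                             sex = "male", age_group = "30-44") {
  data.frame(sex = sex, age_group = age_group, year = 2015L,
             p_abstainer = 1 - p_former - p_current,
             p_former = p_former, p_current = p_current, p_hed = p_hed,
             shape = shape, scale = scale, cap = cap,
             n = 1000L, n_current = 500L,
             stringsAsFactors = FALSE)
}

# one-stratum scenario for fast end-to-end tests
tiny_scenario <- function(p_current = 0.5, p_former = 0.1, p_hed = 0.3,
                          shape = 1.6, scale = 12, rate = 50,
                          registry = NULL, seed = 1L, years = 2015L) {
  reg <- registry %||% constant_rr_registry()
  strata <- data.frame(
    sex = "male", age_group = "30-44", population = 1e6,
    p_abstainer = 1 - p_current - p_former, p_former = p_former,
    p_current = p_current, shape = shape, scale = scale, p_hed = p_hed,
    stringsAsFactors = FALSE
  )
  rates <- stats::setNames(rep(rate, length(reg$causes)), names(reg$causes))
  population_scenario(strata, reg, rates, years = years, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# adaptive-quadrature AAF oracle, independent of the trapezoid code path
quadrature_aaf <- function(exposure, fn_current, fn_former) {
  e <- as.list(exposure)
  dens <- function(x) trunc_gamma_density(x, e$shape, e$scale, e$cap)
  int <- stats::integrate(function(x) dens(x) * (rr_evaluate(fn_current, x) - 1),
                          0, e$cap, rel.tol = 1e-10, abs.tol = 1e-13,
                          subdivisions = 500L)$value
  n_num <- e$p_former * (rr_evaluate(fn_former, 0) - 1) + e$p_current * int
  n_num / (n_num + 1)
}
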