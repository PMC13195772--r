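#' Parametric relative-risk functions
#'
#' A relative-risk (RR) function maps average daily pure-alcohol intake
#' (grams/day) to mortality risk relative to lifetime abstention, for one
#' cause, sex, age group, and drinker group. Three functional forms on the
#' log-RR scale are supported: `constant` (former drinkers; RR = exp(b0)),
#' `log-linear` (RR = exp(b1 x)), and `log-quadratic` (RR = exp(b1 x +
#' b2 x^2)). A coefficient covariance matrix on the same scale feeds Monte
#' Carlo uncertainty draws.
#'
#' @param cause cause-category name.
#' @param sex "male", "female" or "all".
#' @param age_group age-group label or "all".
#' @param group drinker group: "former", "current", "current_non_hed" or
#'   "current_hed".
#' @param form "constant", "log-linear" or "log-quadratic".
#' @param beta numeric coefficient vector on the log-RR scale (length 1 for
#'   constant and log-linear, 2 for log-quadratic).
#' @param cov coefficient covariance matrix (or a scalar variance for
#'   1-coefficient forms); must be symmetric positive semi-definite.
#' @param range upper validity bound in grams/day (default 150).
#' @return an object of class `rr_function`.
#' @export
rr_function <- function(cause, sex, age_group, group, form, beta,
                        cov = NULL, range = 150) {
  group <- match.arg(group, c("former", "current", "current_non_hed", "current_hed"))
  form <- match.arg(form, c("constant", "log-linear", "log-quadratic"))
  beta <- as.numeric(beta)
  n_coef <- c("constant" = 1L, "log-linear" = 1L, "log-quadratic" = 2L)[[form]]
  if (length(beta) != n_coef) {
    stop(sprintf("form '%s' requires %d coefficient(s), got %d",
                 form, n_coef, length(beta)))
  }
  if (is.null(cov)) cov <- matrix(0, n_coef, n_coef)
  cov <- as.matrix(cov)
  if (!all(dim(cov) == n_coef)) {
    stop("covariance dimension does not match coefficient length")
  }
  if (max(abs(cov - t(cov))) > 1e-12) stop("covariance matrix is not symmetric")
  ev <- eigen((cov + t(cov)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1)) {
    stop("covariance matrix is not positive semi-definite")
  }
  stopifnot(is.numeric(range), range > 0)
  structure(
    list(cause = cause, sex = sex, age_group = age_group, group = group,
         form = form, beta = beta, cov = cov, range = range),
    class = "rr_function"
  )
}

#' Evaluate a relative-risk function at given consumption levels
#'
#' Current-drinker forms return RR = 1 at x = 0 (no exposure, no excess
#' risk); the constant form for former drinkers returns exp(b0) everywhere.
#' RR values below 1 (protective ranges) are permitted.
#'
#' @param fn an [rr_function()].
#' @param x grams of pure alcohol per day, non-negative (vectorized).
#' @param beta optional coefficient vector overriding `fn$beta` (used for
#'   Monte Carlo draws).
#' @return RR values, strictly positive.
#' @export
rr_evaluate <- function(fn, x, beta = fn$beta) {
  stopifnot(inherits(fn, "rr_function"))
  if (any(x < 0)) stop("consumption must be non-negative")
  if (any(x > fn$range + 1e-9)) {
    stop(sprintf("consumption exceeds validity range [0, %g] g/day", fn$range))
  }
  out <- switch(fn$form,
    "constant"      = rep(exp(beta[1]), length(x)),
    "log-linear"    = exp(beta[1] * x),
    "log-quadratic" = exp(beta[1] * x + beta[2] * x^2)
  )
  if (fn$form == "constant" && fn$group != "former") out[x == 0] <- 1
  out
}

#' Draw relative-risk coefficients from their sampling distribution
#'
#' Single-coefficient functions draw from a normal distribution, multi-
#' coefficient functions from a multivariate normal, both on the log-RR
#' scale. A zero covariance returns the point estimate exactly.
#'
#' @param fn an [rr_function()].
#' @param n number of draws (default 1).
#' @return an `n` x `length(beta)` matrix of coefficient draws.
#' @export
rr_draw <- function(fn, n = 1) {
  stopifnot(inherits(fn, "rr_function"), n >= 1)
  p <- length(fn$beta)
  if (all(fn$cov == 0)) {
    return(matrix(fn$beta, nrow = n, ncol = p, byrow = TRUE))
  }
  if (p == 1) {
    matrix(stats::rnorm(n, fn$beta, sqrt(fn$cov[1, 1])), ncol = 1)
  } else {
    MASS::mvrnorm(n, mu = fn$beta, Sigma = fn$cov)
  }
}

#' Relative-risk registry and cause catalog
#'
#' The registry couples a cause catalog (ICD-10 code lists, attribution type,
#' HED-stratification flag) with the RR functions for every partially
#' attributable cause. Fully attributable causes carry no RR functions
#' (their attributable fraction is 1 by definition).
#'
#' @param causes a named list; each element has fields `icd10` (character
#'   vector of codes, prefixes, or "A00-A09" style ranges), `attribution`
#'   ("fully_attributable" or "partially_attributable"), `hed_stratified`
#'   (logical), and for partial causes `functions`, a list of
#'   [rr_function()]s covering former plus current (or current_non_hed +
#'   current_hed when HED-stratified) for both sexes and all age groups
#'   ("all" wildcards allowed).
#' @param sexes,age_groups the sex and age-group labels the registry must
#'   cover.
#' @return an object of class `rr_registry`.
#' @export
rr_registry <- function(causes,
                        sexes = c("male", "female"),
                        age_groups = default_age_groups()) {
  stopifnot(is.list(causes), length(names(causes)) == length(causes))
  reg <- structure(list(causes = causes, sexes = sexes, age_groups = age_groups),
                   class = "rr_registry")
  validate_registry(reg)
  reg
}

validate_registry <- function(reg) {
  causes <- reg$causes
  # overlapping ICD-10 claims across causes
  claims <- lapply(causes, function(ca) expand_icd10(ca$icd10))
  all_codes <- unlist(claims, use.names = FALSE)
  dup <- unique(all_codes[duplicated(all_codes)])
  if (length(dup) > 0) {
    owners <- names(causes)[vapply(claims, function(cl) any(dup %in% cl), logical(1))]
    stop("ICD-10 code(s) claimed by multiple causes: ",
         paste(dup, collapse = ", "), " (causes: ",
         paste(owners, collapse = ", "), ")")
  }
  for (nm in names(causes)) {
    ca <- causes[[nm]]
    if (!ca$attribution %in% c("fully_attributable", "partially_attributable")) {
      stop("cause '", nm, "': unknown attribution type '", ca$attribution, "'")
    }
    if (ca$attribution == "fully_attributable") {
      if (length(ca$functions) > 0) {
        stop("cause '", nm, "' is fully attributable but has RR functions")
      }
      next
    }
    needed <- if (isTRUE(ca$hed_stratified)) {
      c("former", "current_non_hed", "current_hed")
    } else {
      c("former", "current")
    }
    for (sx in reg$sexes) for (ag in reg$age_groups) for (gr in needed) {
      fn <- rr_lookup(reg, nm, sx, ag, gr, required = FALSE)
      if (is.null(fn)) {
        stop(sprintf("cause '%s': missing %s RR function for sex=%s age_group=%s",
                     nm, gr, sx, ag))
      }
    }
  }
  invisible(reg)
}

#' Look up the RR function for a cause/sex/age-group/drinker-group cell
#'
#' Exact sex and age-group entries take precedence over "all" wildcards.
#'
#' @param reg an [rr_registry()].
#' @param cause,sex,age_group,group the cell to resolve.
#' @param required error (TRUE, default) or return NULL when absent.
#' @return an [rr_function()] or NULL.
#' @export
rr_lookup <- function(reg, cause, sex, age_group, group, required = TRUE) {
  ca <- reg$causes[[cause]]
  if (is.null(ca)) stop("unknown cause: ", cause)
  best <- NULL
  best_score <- -1L
  for (fn in ca$functions) {
    if (fn$group != group) next
    sex_ok <- fn$sex == sex || fn$sex == "all"
    age_ok <- fn$age_group == age_group || fn$age_group == "all"
    if (!sex_ok || !age_ok) next
    score <- (fn$sex == sex) + (fn$age_group == age_group)
    if (score > best_score) {
      best <- fn
      best_score <- score
    }
  }
  if (is.null(best) && required) {
    stop(sprintf("no %s RR function for cause=%s sex=%s age_group=%s",
                 group, cause, sex, age_group))
  }
  best
}

#' Read and write a relative-risk registry as YAML
#'
#' The on-disk format is a map `causes:` with, per cause, `icd10`,
#' `attribution`, `hed_stratified`, and `functions` entries carrying
#' `sex`, `age_group`, `group`, `form`, `beta`, `cov` (row-major list of
#' rows), and `range`. Round-trips exactly.
#'
#' @param path YAML file path.
#' @param reg an [rr_registry()].
#' @param sexes,age_groups coverage labels to validate against.
#' @return `load_rr_registry` returns the validated registry;
#'   `write_rr_registry` returns `path` invisibly.
#' @export
load_rr_registry <- function(path,
                             sexes = c("male", "female"),
                             age_groups = default_age_groups()) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$causes)) stop("registry file has no 'causes' map: ", path)
  causes <- lapply(raw$causes, function(ca) {
    fns <- lapply(ca$functions, function(f) {
      cov <- if (is.null(f$cov)) NULL else do.call(rbind, lapply(f$cov, as.numeric))
      rr_function(cause = ca$name %||% NA_character_, sex = f$sex,
                  age_group = as.character(f$age_group), group = f$group,
                  form = f$form, beta = as.numeric(f$beta), cov = cov,
                  range = f$range %||% 150)
    })
    list(icd10 = as.character(ca$icd10),
         attribution = ca$attribution,
         hed_stratified = isTRUE(ca$hed_stratified),
         functions = fns)
  })
  for (nm in names(causes)) {
    causes[[nm]]$functions <- lapply(causes[[nm]]$functions, function(f) {
      f$cause <- nm
      f
    })
  }
  rr_registry(causes, sexes = sexes, age_groups = age_groups)
}

#' @rdname load_rr_registry
#' @export
write_rr_registry <- function(reg, path) {
  stopifnot(inherits(reg, "rr_registry"))
  out <- list(causes = lapply(reg$causes, function(ca) {
    list(icd10 = as.list(ca$icd10),
         attribution = ca$attribution,
         hed_stratified = isTRUE(ca$hed_stratified),
         functions = lapply(ca$functions, function(f) {
           list(sex = f$sex, age_group = f$age_group, group = f$group,
                form = f$form, beta = as.list(f$beta),
                cov = apply(f$cov, 1, as.list, simplify = FALSE),
                range = f$range)
         }))
  }))
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Illustrative relative-risk parameter set
#'
#' The RR coefficients behind published comparative-risk assessments come
#' from meta-analyses and are supplied to this package as configuration.
#' This builder ships an ILLUSTRATIVE, non-canonical set so the pipeline
#' runs out of the box: a fully attributable cause (alcohol use disorders),
#' a log-linear liver-cirrhosis curve with sex-specific slopes, a J-shaped
#' (log-quadratic, protective at low doses) ischemic heart disease curve
#' stratified by HED, and HED-stratified log-linear injury curves. Replace
#' it with published coefficient tables via [load_rr_registry()] for any
#' substantive analysis.
#'
#' @param age_groups age-group labels the registry must cover.
#' @return an [rr_registry()].
#' @export
illustrative_registry <- function(age_groups = default_age_groups()) {
  fn <- function(cause, sex, group, form, beta, cov, age_group = "all") {
    rr_function(cause, sex, age_group, group, form, beta, cov)
  }
  causes <- list(
    alcohol_use_disorders = list(
      icd10 = c("F10", "X45", "K860"),
      attribution = "fully_attributable",
      hed_stratified = FALSE,
      functions = list()
    ),
    liver_cirrhosis = list(
      icd10 = c("K70", "K74"),
      attribution = "partially_attributable",
      hed_stratified = FALSE,
      functions = list(
        fn("liver_cirrhosis", "male", "current", "log-linear",
           beta = 0.018, cov = 4e-6),
        fn("liver_cirrhosis", "female", "current", "log-linear",
           beta = 0.023, cov = 6e-6),
        fn("liver_cirrhosis", "all", "former", "constant",
           beta = log(1.31), cov = 0.01)
      )
    ),
    ischemic_heart_disease = list(
      icd10 = c("I20-I25"),
      attribution = "partially_attributable",
      hed_stratified = TRUE,
      functions = list(
        fn("ischemic_heart_disease", "all", "current_non_hed", "log-quadratic",
           beta = c(-0.0075, 8e-5),
           cov = matrix(c(4e-6, -1.5e-8, -1.5e-8, 2.5e-10), 2, 2)),
        fn("ischemic_heart_disease", "all", "current_hed", "log-linear",
           beta = 0.0045, cov = 2.5e-6),
        fn("ischemic_heart_disease", "all", "former", "constant",
           beta = log(1.12), cov = 0.004)
      )
    ),
    motor_vehicle_injuries = list(
      icd10 = c("V01-V89"),
      attribution = "partially_attributable",
      hed_stratified = TRUE,
      functions = list(
        fn("motor_vehicle_injuries", "all", "current_non_hed", "log-linear",
           beta = 0.004, cov = 2e-6),
        fn("motor_vehicle_injuries", "all", "current_hed", "log-linear",
           beta = 0.011, cov = 4e-6),
        fn("motor_vehicle_injuries", "all", "former", "constant",
           beta = 0, cov = 0.002)
      )
    )
  )
  rr_registry(causes, age_groups = age_groups)
}
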