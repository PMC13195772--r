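#' Truncated-renormalized gamma consumption density
#'
#' The fitted gamma consumption distribution is capped at `cap` grams/day and
#' renormalized so it remains a proper density on (0, cap], as the
#' attributable-fraction integral requires.
#'
#' @param x grams/day (vectorized).
#' @param shape,scale gamma parameters (grams/day scale).
#' @param cap truncation point in grams/day.
#' @return density values; zero outside (0, cap].
#' @export
trunc_gamma_density <- function(x, shape, scale, cap = 150) {
  stopifnot(shape > 0, scale > 0, cap > 0)
  d <- stats::dgamma(x, shape = shape, scale = scale) /
    stats::pgamma(cap, shape = shape, scale = scale)
  d[x > cap | x <= 0] <- 0
  d
}

#' Integration grid for the attributable-fraction integral
#'
#' Equally spaced points from 0 to `cap`; the default (cap 150, 1501 points)
#' gives a 0.1 g/day step. The point mass at exactly zero consumption belongs
#' to abstainers and former drinkers, not the integral: integrands are zero
#' at the origin, so including the 0 endpoint only anchors the first
#' trapezoid.
#'
#' @param cap upper limit in grams/day.
#' @param n number of grid points.
#' @return ascending numeric vector of length `n`.
#' @export
aaf_grid <- function(cap = 150, n = 1501) {
  stopifnot(cap > 0, n >= 2)
  seq(0, cap, length.out = n)
}

#' Composite trapezoidal rule for density-weighted integrands
#'
#' @param x ascending grid (grams/day).
#' @param density density values on `x`.
#' @param integrand integrand values on `x` (default 1, giving the density's
#'   own integral).
#' @return the trapezoidal approximation of `integral(density * integrand)`.
#' @export
trapezoid_integral <- function(x, density, integrand = rep(1, length(x))) {
  n <- length(x)
  if (length(density) != n || length(integrand) != n) {
    stop("grid, density and integrand lengths differ")
  }
  if (n < 2 || any(diff(x) <= 0)) stop("grid must be ascending with >= 2 points")
  f <- density * integrand
  sum(diff(x) * (f[-1] + f[-n]) / 2)
}

aaf_estimate <- function(aaf, components, grid_n, cause = NA_character_) {
  structure(list(aaf = aaf, numerator = sum(components),
                 components = components, grid_n = grid_n, cause = cause),
            class = "aaf_estimate")
}

# Risk value of a current-drinker form in the zero-consumption limit: the
# constant form carries exp(b0) arbitrarily close to 0, the dose-response
# forms tend to 1. Used by the mass-conservation correction below.
rr_zero_limit <- function(fn, beta = fn$beta) {
  if (fn$form == "constant") exp(beta[1]) else 1
}

# Trapezoidal integral of density x excess risk over [a, b], refined so the
# 0.1 g grid keeps quadrature-level accuracy near the density's origin
# singularity:
#   * the linear part of the excess risk, b1 x, is integrated exactly
#     against the truncated gamma via its incomplete-gamma first moment;
#   * the trapezoid handles only the O(x^2) residual;
#   * density mass the trapezoid loses on the segment is assigned the
#     residual excess risk at the segment's lower end -- exact for constant
#     risks, so a constant-RR cause reproduces its closed-form AAF to float
#     precision.
segment_excess_integral <- function(x, sel, dens, fn, e, a, b,
                                    beta = fn$beta) {
  xs <- x[sel]
  ds <- dens[sel]
  lin <- if (fn$form %in% c("log-linear", "log-quadratic")) beta[1] else 0
  res <- rr_evaluate(fn, xs, beta = beta) - 1 - lin * xs
  raw <- trapezoid_integral(xs, ds, res)
  norm <- stats::pgamma(e$cap, e$shape, scale = e$scale)
  mass_exact <- (stats::pgamma(b, e$shape, scale = e$scale) -
                   stats::pgamma(a, e$shape, scale = e$scale)) / norm
  mass_grid <- trapezoid_integral(xs, ds)
  xmean_exact <- e$shape * e$scale *
    (stats::pgamma(b, e$shape + 1, scale = e$scale) -
       stats::pgamma(a, e$shape + 1, scale = e$scale)) / norm
  edge_res <- if (a <= 0) rr_zero_limit(fn, beta) - 1
    else rr_evaluate(fn, a, beta = beta) - 1 - lin * a
  raw + lin * xmean_exact + (mass_exact - mass_grid) * edge_res
}

exposure_fields <- function(exposure) {
  need <- c("p_former", "p_current", "shape", "scale", "cap")
  exposure <- as.list(exposure)
  missing_f <- setdiff(need, names(exposure))
  if (length(missing_f) > 0) {
    stop("exposure is missing field(s): ", paste(missing_f, collapse = ", "))
  }
  exposure
}

#' Alcohol-attributable fraction for one stratum and cause
#'
#' Computes AAF = N / (N + 1) with population excess risk
#' N = p_former (RR_former - 1) + integral over (0, cap] of
#' p_current f(x) (RR_current(x) - 1) dx, where f is the truncated-
#' renormalized gamma consumption density. The integral is approximated by
#' the composite trapezoidal rule. Protective risk ranges (RR < 1) produce
#' negative contributions and are retained.
#'
#' @param exposure a list or one-row data.frame with `p_former`, `p_current`,
#'   `shape`, `scale`, `cap` (and `p_hed` for the HED-stratified variant).
#' @param fn_current,fn_former [rr_function()]s for current and former
#'   drinkers.
#' @param grid_n number of integration grid points (default 1501).
#' @param split_g internal quadrature split point in grams/day; shared with
#'   the HED-stratified variant so the two routes agree exactly when their
#'   risk functions coincide.
#' @return an `aaf_estimate`: point AAF, numerator, component breakdown
#'   (former, current_non_hed, current_hed_sub_threshold,
#'   current_hed_above_threshold), and the grid size used.
#' @export
compute_aaf <- function(exposure, fn_current, fn_former, grid_n = 1501,
                        split_g = 60) {
  e <- exposure_fields(exposure)
  x <- aaf_grid(e$cap, grid_n)
  if (!any(abs(x - split_g) < 1e-9)) x <- sort(c(x, split_g))
  dens <- trunc_gamma_density(x, e$shape, e$scale, e$cap)
  former <- e$p_former * (rr_evaluate(fn_former, 0) - 1)
  current <- e$p_current *
    (segment_excess_integral(x, x <= split_g, dens, fn_current, e, 0, split_g) +
       segment_excess_integral(x, x >= split_g, dens, fn_current, e,
                               split_g, e$cap))
  comps <- c(former = former, current_non_hed = current,
             current_hed_sub_threshold = 0, current_hed_above_threshold = 0)
  n_num <- sum(comps)
  aaf_estimate(n_num / (n_num + 1), comps, length(x))
}

#' HED-stratified alcohol-attributable fraction
#'
#' For causes whose risk functions distinguish heavy episodic drinkers
#' (injuries, ischemic heart disease, ischemic stroke), the current-drinker
#' integral splits at a threshold (default 60 g/day): below it, density mass
#' is mixed between the non-HED and HED risk curves with weights
#' (1 - p_hed) and p_hed; above it, all consumption is treated under the HED
#' risk curve. The threshold operates only inside the integration step, never
#' as a classification rule on respondents. With `excess_risk = FALSE` the
#' integrands use RR(x) instead of RR(x) - 1 (a literal reading of the
#' decomposition, available for sensitivity analysis only; the default
#' excess-risk form is required for the N/(N+1) transform to be an
#' attributable fraction).
#'
#' @inheritParams compute_aaf
#' @param fn_non_hed,fn_hed,fn_former [rr_function()]s for the three drinker
#'   groups.
#' @param hed_threshold_g split point in grams/day (default 60).
#' @param excess_risk integrate RR - 1 (TRUE, default) or RR.
#' @return an `aaf_estimate` (see [compute_aaf()]).
#' @export
compute_aaf_hed <- function(exposure, fn_non_hed, fn_hed, fn_former,
                            grid_n = 1501, hed_threshold_g = 60,
                            excess_risk = TRUE) {
  e <- exposure_fields(exposure)
  if (is.null(e$p_hed) || is.na(e$p_hed)) {
    stop("exposure has no p_hed; required for an HED-stratified cause")
  }
  stopifnot(hed_threshold_g > 0, hed_threshold_g < e$cap)
  x <- aaf_grid(e$cap, grid_n)
  if (!any(abs(x - hed_threshold_g) < 1e-9)) {
    x <- sort(c(x, hed_threshold_g))
  }
  dens <- trunc_gamma_density(x, e$shape, e$scale, e$cap)
  lo <- x <= hed_threshold_g
  hi <- x >= hed_threshold_g
  if (excess_risk) {
    int_n_lo <- segment_excess_integral(x, lo, dens, fn_non_hed, e,
                                        0, hed_threshold_g)
    int_h_lo <- segment_excess_integral(x, lo, dens, fn_hed, e,
                                        0, hed_threshold_g)
    int_h_hi <- segment_excess_integral(x, hi, dens, fn_hed, e,
                                        hed_threshold_g, e$cap)
  } else {
    # literal decomposition (sensitivity only): integrate RR, not RR - 1
    int_n_lo <- trapezoid_integral(x[lo], dens[lo], rr_evaluate(fn_non_hed, x[lo]))
    int_h_lo <- trapezoid_integral(x[lo], dens[lo], rr_evaluate(fn_hed, x[lo]))
    int_h_hi <- trapezoid_integral(x[hi], dens[hi], rr_evaluate(fn_hed, x[hi]))
  }
  off <- if (excess_risk) 1 else 0
  comps <- c(
    former = e$p_former * (rr_evaluate(fn_former, 0) - off),
    current_non_hed = e$p_current * (1 - e$p_hed) * int_n_lo,
    current_hed_sub_threshold = e$p_current * e$p_hed * int_h_lo,
    current_hed_above_threshold = e$p_current * int_h_hi
  )
  n_num <- sum(comps)
  aaf_estimate(n_num / (n_num + 1), comps, length(x))
}

#' Attributable fraction for a fully alcohol-attributable cause
#'
#' Causes whose ICD-10 codes are alcohol-specific (e.g. alcohol use
#' disorders) have AAF = 1 by definition; no integration is involved.
#'
#' @param reg an [rr_registry()].
#' @param cause cause-category name flagged `fully_attributable`.
#' @return an `aaf_estimate` with AAF exactly 1 and zero components.
#' @export
fully_attributable_aaf <- function(reg, cause) {
  ca <- reg$causes[[cause]]
  if (is.null(ca)) stop("unknown cause: ", cause)
  if (ca$attribution != "fully_attributable") {
    stop("cause '", cause, "' is not fully attributable; use compute_aaf()")
  }
  aaf_estimate(1, c(former = 0, current_non_hed = 0,
                    current_hed_sub_threshold = 0,
                    current_hed_above_threshold = 0),
               grid_n = 0L, cause = cause)
}

#' AAF table over an exposure set and cause catalog
#'
#' Evaluates the attributable fraction for every exposure stratum and every
#' cause in the registry, dispatching to the HED-stratified integral where
#' the cause is flagged, and to the exact value 1 for fully attributable
#' causes.
#'
#' @param exposure data.frame of exposure strata (columns `sex`, `age_group`,
#'   optionally `year`, plus the fields of [compute_aaf()]).
#' @param reg an [rr_registry()].
#' @param grid_n integration grid size.
#' @return data.frame keyed by (year, sex, age_group, cause) with the point
#'   `aaf` and the four component-breakdown columns.
#' @export
aaf_table <- function(exposure, reg, grid_n = 1501) {
  rows <- list()
  for (i in seq_len(nrow(exposure))) {
    ex <- exposure[i, ]
    for (cause in names(reg$causes)) {
      ca <- reg$causes[[cause]]
      est <- if (ca$attribution == "fully_attributable") {
        fully_attributable_aaf(reg, cause)
      } else if (isTRUE(ca$hed_stratified)) {
        compute_aaf_hed(ex,
                        rr_lookup(reg, cause, ex$sex, ex$age_group, "current_non_hed"),
                        rr_lookup(reg, cause, ex$sex, ex$age_group, "current_hed"),
                        rr_lookup(reg, cause, ex$sex, ex$age_group, "former"),
                        grid_n = grid_n)
      } else {
        compute_aaf(ex,
                    rr_lookup(reg, cause, ex$sex, ex$age_group, "current"),
                    rr_lookup(reg, cause, ex$sex, ex$age_group, "former"),
                    grid_n = grid_n)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        year = if ("year" %in% names(ex)) ex$year else NA_integer_,
        sex = ex$sex, age_group = ex$age_group, cause = cause,
        aaf = est$aaf,
        former = est$components[["former"]],
        current_non_hed = est$components[["current_non_hed"]],
        current_hed_sub_threshold = est$components[["current_hed_sub_threshold"]],
        current_hed_above_threshold = est$components[["current_hed_above_threshold"]],
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
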