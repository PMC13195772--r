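#' Monte Carlo simulation specification
#'
#' Controls how sampling uncertainty is propagated through the AAF pipeline:
#' number of iterations, master seed, which sources are perturbed
#' (drinker-status prevalences, gamma consumption parameters, RR
#' coefficients), and optional effective sample sizes overriding the
#' per-stratum respondent counts.
#'
#' @param n_iterations number of Monte Carlo iterations (default 10000).
#' @param seed master seed; fixed seed gives identical interval output.
#' @param perturb_prevalence,perturb_consumption,perturb_rr logical toggles.
#' @param n_eff optional effective sample size overriding per-stratum
#'   respondent counts (single number).
#' @return object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_iterations = 10000, seed = 1L,
                            perturb_prevalence = TRUE,
                            perturb_consumption = TRUE,
                            perturb_rr = TRUE, n_eff = NULL) {
  stopifnot(n_iterations >= 1)
  structure(list(n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed),
                 perturb_prevalence = isTRUE(perturb_prevalence),
                 perturb_consumption = isTRUE(perturb_consumption),
                 perturb_rr = isTRUE(perturb_rr),
                 n_eff = n_eff),
            class = "simulation_spec")
}

#' Simulate a prevalence estimate's sampling distribution
#'
#' Binomial draw of the number of successes out of the effective sample
#' size, returned as a proportion.
#'
#' @param p true/estimated proportion in [0, 1].
#' @param n_eff effective sample size (>= 1).
#' @param n number of draws.
#' @param seed optional seed set before drawing.
#' @return numeric vector of simulated proportions.
#' @export
draw_prevalence <- function(p, n_eff, n = 1, seed = NULL) {
  stopifnot(p >= 0, p <= 1, n_eff >= 1)
  if (!is.null(seed)) set.seed(seed)
  stats::rbinom(n, size = round(n_eff), prob = p) / round(n_eff)
}

#' Parametric-bootstrap draw of gamma consumption parameters
#'
#' Simulates `n_eff` consumption values from the fitted gamma and refits,
#' returning the refitted (shape, scale) — the sampling distribution of the
#' estimator under the fitted model. Refit failures retry with fresh draws a
#' bounded number of times before erroring.
#'
#' @param exposure list or row with `shape` and `scale`.
#' @param n_eff number of values per bootstrap sample.
#' @param n number of draws.
#' @param seed optional seed set before drawing.
#' @param max_retries retry budget per draw (default 5).
#' @return an `n` x 2 matrix with columns shape, scale.
#' @export
draw_consumption <- function(exposure, n_eff, n = 1, seed = NULL,
                             max_retries = 5) {
  e <- as.list(exposure)
  stopifnot(e$shape > 0, e$scale > 0, n_eff >= 2)
  if (!is.null(seed)) set.seed(seed)
  out <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("shape", "scale")))
  for (t in seq_len(n)) {
    fit <- NULL
    for (r in seq_len(max_retries)) {
      xs <- stats::rgamma(n_eff, shape = e$shape, scale = e$scale)
      fit <- tryCatch(
        suppressWarnings(fit_gamma(xs, min_n = 2)),
        error = function(err) NULL
      )
      if (!is.null(fit) && all(is.finite(fit)) && all(fit > 0)) break
      fit <- NULL
    }
    if (is.null(fit)) {
      stop("gamma refit failed after ", max_retries, " retries at draw ", t)
    }
    out[t, ] <- fit
  }
  out
}

resolved_fn_key <- function(fn) {
  paste(fn$cause, fn$sex, fn$age_group, fn$group, sep = "|")
}

#' Monte Carlo AAF draws for an exposure set
#'
#' Per iteration, jointly redraws former- and current-drinker prevalences
#' and the HED share (binomial, at the stratum's effective sample sizes),
#' the gamma consumption parameters (parametric bootstrap), and the RR
#' coefficients (normal / multivariate normal on the log-RR scale), then
#' recomputes every stratum x cause AAF. RR coefficient draws are shared
#' across all strata resolving to the same registry function within an
#' iteration, so risk curves stay coherent. Stratum-level sampling draws use
#' independent substreams derived from the master seed. Fully attributable
#' causes are carried as constant draws at 1.
#'
#' @param exposure exposure data.frame (see [build_exposure()]).
#' @param reg an [rr_registry()].
#' @param spec a [simulation_spec()].
#' @param grid_n integration grid size (default 1501).
#' @return object of class `aaf_draws`: list with `draws` (n_iterations x
#'   n_cells matrix), `cells` (data.frame year, sex, age_group, cause),
#'   `point` (point AAFs from the unperturbed inputs), and `spec`.
#' @export
simulate_aafs <- function(exposure, reg, spec = simulation_spec(),
                          grid_n = 1501) {
  n_iter <- spec$n_iterations
  ns <- nrow(exposure)
  cap <- exposure$cap[1]
  x <- aaf_grid(cap, grid_n)
  if (!any(abs(x - 60) < 1e-9)) x <- sort(c(x, 60))
  m <- length(x)
  # trapezoid weight vectors: integral(f) = sum(wt * f)
  h <- diff(x)
  wt_full <- c(h / 2, 0) + c(0, h / 2)
  seg_weights <- function(sel) {
    hx <- diff(x[sel])
    w <- numeric(m)
    w[sel] <- c(hx / 2, 0) + c(0, hx / 2)
    w
  }
  lo <- x <= 60
  hi <- x >= 60
  wt_lo <- seg_weights(lo)
  wt_hi <- seg_weights(hi)
  i60 <- which(abs(x - 60) < 1e-9)[1]

  # --- stratum substreams: prevalence and consumption draws -----------------
  p_form <- p_cur <- p_hed <- matrix(NA_real_, n_iter, ns)
  shape_d <- scale_d <- matrix(NA_real_, n_iter, ns)
  for (i in seq_len(ns)) {
    set.seed((spec$seed + 7919L * i) %% .Machine$integer.max)
    n_eff <- spec$n_eff %||% exposure$n[i]
    n_eff_cur <- spec$n_eff %||% exposure$n_current[i]
    if (is.null(n_eff) || is.na(n_eff)) {
      stop("no effective sample size for stratum ", stratum_key(exposure[i, ]),
           "; supply spec$n_eff or exposure$n")
    }
    if (spec$perturb_prevalence) {
      p_form[, i] <- draw_prevalence(exposure$p_former[i], n_eff, n_iter)
      p_cur[, i] <- draw_prevalence(exposure$p_current[i], n_eff, n_iter)
      p_hed[, i] <- if (is.na(exposure$p_hed[i])) NA_real_ else
        draw_prevalence(exposure$p_hed[i], max(n_eff_cur, 1), n_iter)
    } else {
      p_form[, i] <- exposure$p_former[i]
      p_cur[, i] <- exposure$p_current[i]
      p_hed[, i] <- exposure$p_hed[i]
    }
    if (spec$perturb_consumption) {
      cons <- draw_consumption(exposure[i, ], max(n_eff_cur, 2), n_iter)
      shape_d[, i] <- cons[, "shape"]
      scale_d[, i] <- cons[, "scale"]
    } else {
      shape_d[, i] <- exposure$shape[i]
      scale_d[, i] <- exposure$scale[i]
    }
  }

  # --- cell bookkeeping and resolved RR functions ---------------------------
  cells <- list()
  for (i in seq_len(ns)) for (cause in names(reg$causes)) {
    ca <- reg$causes[[cause]]
    groups <- if (ca$attribution == "fully_attributable") character(0)
      else if (isTRUE(ca$hed_stratified)) c("former", "current_non_hed", "current_hed")
      else c("former", "current")
    fns <- lapply(groups, function(g)
      rr_lookup(reg, cause, exposure$sex[i], exposure$age_group[i], g))
    names(fns) <- groups
    cells[[length(cells) + 1L]] <- list(
      stratum = i, cause = cause, hed = isTRUE(ca$hed_stratified),
      full = ca$attribution == "fully_attributable", fns = fns)
  }

  uniq <- list()
  for (cl in cells) for (fn in cl$fns) uniq[[resolved_fn_key(fn)]] <- fn
  set.seed(spec$seed)
  beta_draws <- lapply(uniq[sort(names(uniq))], function(fn) {
    if (spec$perturb_rr) rr_draw(fn, n_iter)
    else matrix(fn$beta, n_iter, length(fn$beta), byrow = TRUE)
  })

  excess_at <- function(fn, beta) rr_evaluate(fn, x, beta = beta) - 1

  # --- main loop ------------------------------------------------------------
  draws <- matrix(NA_real_, n_iter, length(cells))
  point <- numeric(length(cells))
  dens_t <- vector("list", ns)
  # per-stratum grid masses and truncated first moments for the same
  # quadrature refinement segment_excess_integral() applies: the linear part
  # of each excess risk integrates exactly against the gamma, and lost
  # discretization mass carries the residual risk at the segment edge
  z_lo <- z_hi <- m_lo <- xm_lo <- xm_hi <- numeric(ns)
  fn_keys <- names(beta_draws)
  lin_coef <- function(k, beta) {
    if (uniq[[k]]$form %in% c("log-linear", "log-quadratic")) beta[1] else 0
  }
  for (t in seq_len(n_iter)) {
    for (i in seq_len(ns)) {
      sh <- shape_d[t, i]
      sl <- scale_d[t, i]
      d <- trunc_gamma_density(x, sh, sl, cap)
      dens_t[[i]] <- d
      z_lo[i] <- sum(wt_lo * d)
      z_hi[i] <- sum(wt_hi * d)
      norm <- stats::pgamma(cap, sh, scale = sl)
      m_lo[i] <- stats::pgamma(60, sh, scale = sl) / norm
      xm_all <- sh * sl * stats::pgamma(cap, sh + 1, scale = sl) / norm
      xm_lo[i] <- sh * sl * stats::pgamma(60, sh + 1, scale = sl) / norm
      xm_hi[i] <- xm_all - xm_lo[i]
    }
    beta_t <- lapply(fn_keys, function(k) beta_draws[[k]][t, ])
    names(beta_t) <- fn_keys
    exc_t <- lapply(fn_keys, function(k) excess_at(uniq[[k]], beta_t[[k]]))
    names(exc_t) <- fn_keys
    lin_t <- vapply(fn_keys, function(k) lin_coef(k, beta_t[[k]]), numeric(1))
    res_t <- lapply(fn_keys, function(k) exc_t[[k]] - lin_t[[k]] * x)
    names(res_t) <- fn_keys
    zero_res_t <- vapply(fn_keys, function(k)
      rr_zero_limit(uniq[[k]], beta_t[[k]]) - 1, numeric(1))
    seg_lo <- function(k, i, d) {
      sum(wt_lo * d * res_t[[k]]) + lin_t[[k]] * xm_lo[i] +
        (m_lo[i] - z_lo[i]) * zero_res_t[[k]]
    }
    seg_hi <- function(k, i, d) {
      sum(wt_hi * d * res_t[[k]]) + lin_t[[k]] * xm_hi[i] +
        ((1 - m_lo[i]) - z_hi[i]) * (exc_t[[k]][i60] - lin_t[[k]] * 60)
    }
    for (j in seq_along(cells)) {
      cl <- cells[[j]]
      if (cl$full) {
        draws[t, j] <- 1
        next
      }
      i <- cl$stratum
      d <- dens_t[[i]]
      form_exc <- exc_t[[resolved_fn_key(cl$fns[["former"]])]][1]
      n_num <- p_form[t, i] * form_exc
      if (cl$hed) {
        kn <- resolved_fn_key(cl$fns[["current_non_hed"]])
        kh <- resolved_fn_key(cl$fns[["current_hed"]])
        ph <- p_hed[t, i]
        n_num <- n_num + p_cur[t, i] *
          ((1 - ph) * seg_lo(kn, i, d) + ph * seg_lo(kh, i, d) +
             seg_hi(kh, i, d))
      } else {
        kc <- resolved_fn_key(cl$fns[["current"]])
        n_num <- n_num + p_cur[t, i] * (seg_lo(kc, i, d) + seg_hi(kc, i, d))
      }
      draws[t, j] <- n_num / (n_num + 1)
    }
  }

  # point AAFs from unperturbed inputs, same grid
  for (j in seq_along(cells)) {
    cl <- cells[[j]]
    if (cl$full) {
      point[j] <- 1
      next
    }
    ex <- exposure[cl$stratum, ]
    point[j] <- if (cl$hed) {
      compute_aaf_hed(ex, cl$fns[["current_non_hed"]], cl$fns[["current_hed"]],
                      cl$fns[["former"]], grid_n = grid_n)$aaf
    } else {
      compute_aaf(ex, cl$fns[["current"]], cl$fns[["former"]],
                  grid_n = grid_n)$aaf
    }
  }

  cell_df <- data.frame(
    year = if ("year" %in% names(exposure))
      exposure$year[vapply(cells, `[[`, 0L, "stratum")] else NA_integer_,
    sex = exposure$sex[vapply(cells, `[[`, 0L, "stratum")],
    age_group = exposure$age_group[vapply(cells, `[[`, 0L, "stratum")],
    cause = vapply(cells, `[[`, "", "cause"),
    stringsAsFactors = FALSE
  )
  structure(list(draws = draws, cells = cell_df, point = point, spec = spec),
            class = "aaf_draws")
}

#' Empirical percentile interval
#'
#' Percentiles by linear interpolation between order statistics
#' (`stats::quantile` type 7): the p-th percentile of sorted draws
#' x_(1) <= ... <= x_(n) is x_(k) + g (x_(k+1) - x_(k)) with
#' k = floor(1 + (n-1) p / 100) and g the fractional part.
#'
#' @param draws numeric vector of simulation draws (non-empty).
#' @param lower,upper percentile bounds (default 2.5 and 97.5).
#' @return named vector (lo, hi).
#' @export
percentile_ci <- function(draws, lower = 2.5, upper = 97.5) {
  draws <- draws[!is.na(draws)]
  if (length(draws) == 0) stop("no draws; cannot form a percentile interval")
  if (lower > upper) stop("lower percentile exceeds upper")
  q <- stats::quantile(draws, probs = c(lower, upper) / 100,
                       type = 7, names = FALSE)
  c(lo = q[1], hi = q[2])
}

#' Percentile intervals for every simulated cell
#'
#' @param sim an `aaf_draws` object from [simulate_aafs()].
#' @param lower,upper percentile bounds.
#' @return the cell data.frame with columns point, lo95, hi95, n_iter, seed.
#' @export
aaf_intervals <- function(sim, lower = 2.5, upper = 97.5) {
  stopifnot(inherits(sim, "aaf_draws"))
  ci <- t(apply(sim$draws, 2, percentile_ci, lower = lower, upper = upper))
  out <- sim$cells
  out$point <- sim$point
  out$lo95 <- ci[, 1]
  out$hi95 <- ci[, 2]
  out$n_iter <- sim$spec$n_iterations
  out$seed <- sim$spec$seed
  out
}
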