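#' Age-group conventions and the standard population
#'
#' Analyses run over four adult age groups: 15-29, 30-44, 45-59, 60+. The
#' survey frame covers ages 15-64 only, so the 60+ group is estimated from
#' respondents aged 60-64 (and groups above any survey ceiling inherit the
#' oldest surveyed group's exposure, see [carry_forward_oldest()]).
#'
#' @name strata
NULL

#' @rdname strata
#' @export
default_age_groups <- function() c("15-29", "30-44", "45-59", "60+")

#' @rdname strata
#' @param age integer ages in years (vectorized).
#' @return age-group label, or NA for ages below 15.
#' @export
age_to_group <- function(age) {
  cut(age, breaks = c(15, 30, 45, 60, Inf), right = FALSE,
      labels = default_age_groups())
}

#' WHO World Standard population weights collapsed to the analysis age groups
#'
#' Direct age standardization uses the WHO World Standard population
#' (2000-2025). Its 5-year band shares for ages 15+ are collapsed to the four
#' analysis groups and renormalized to sum to 1.
#'
#' @return named numeric vector of weights over [default_age_groups()],
#'   summing to 1.
#' @export
who_standard_weights <- function() {
  # WHO world standard 5-year band percentages, ages 15+ only
  w <- c("15-29" = 8.47 + 8.22 + 7.93,
         "30-44" = 7.61 + 7.15 + 6.59,
         "45-59" = 6.04 + 5.37 + 4.55,
         "60+"   = 3.72 + 2.96 + 2.21 + 1.52 + 0.91 + 0.63)
  w / sum(w)
}
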