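#' Unit conversions for pure alcohol
#'
#' Per-capita alcohol consumption benchmarks are reported in litres of pure
#' alcohol per person aged 15+ per year; the exposure model works in grams of
#' pure alcohol per day. Conversion uses the density of ethanol
#' (0.789 g/ml) and an average year of 365.25 days.
#'
#' @param grams_per_day grams of pure alcohol per person per day.
#' @param litres_per_year litres of pure alcohol per person per year.
#' @return the converted quantity, same length as the input.
#' @examples
#' litres_per_year_to_grams_per_day(grams_per_day_to_litres_per_year(20))
#' @name alcohol-units
NULL

ALCOHOL_DENSITY_G_PER_ML <- 0.789
DAYS_PER_YEAR <- 365.25

#' @rdname alcohol-units
#' @export
grams_per_day_to_litres_per_year <- function(grams_per_day) {
  grams_per_day * DAYS_PER_YEAR / (ALCOHOL_DENSITY_G_PER_ML * 1000)
}

#' @rdname alcohol-units
#' @export
litres_per_year_to_grams_per_day <- function(litres_per_year) {
  litres_per_year * ALCOHOL_DENSITY_G_PER_ML * 1000 / DAYS_PER_YEAR
}
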