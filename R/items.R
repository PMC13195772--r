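#' Survey item coding for alcohol quantity-frequency measurement
#'
#' The exposure model quantifies drinking from the first three AUDIT-C style
#' items: frequency of drinking, typical number of drinks per occasion, and
#' frequency of heavy episodic drinking (HED). Categories follow the standard
#' instrument; each is assigned a midpoint used to convert responses to an
#' average daily volume of pure alcohol.
#'
#' Frequency midpoints are occasions per day: "monthly or less" counts 0.5
#' occasions per average month (30.4375 days), "2-4 times a month" 3 per
#' month, "2-3 times a week" 2.5 per week, "4+ times a week" 5.5 per week
#' (midpoint of 4-7). Quantity midpoints are drinks per occasion: 1.5, 3.5,
#' 5.5, 8, and 12 for the open-ended "10 or more" category.
#'
#' @name survey-items
NULL

#' @rdname survey-items
#' @export
audit_frequency_levels <- function() {
  c("never", "monthly_or_less", "2-4_per_month", "2-3_per_week", "4+_per_week")
}

#' @rdname survey-items
#' @export
audit_quantity_levels <- function() {
  c("1-2", "3-4", "5-6", "7-9", "10+")
}

#' @rdname survey-items
#' @export
hed_frequency_levels <- function() {
  c("never", "less_than_monthly", "monthly", "weekly", "daily_or_almost")
}

DAYS_PER_MONTH <- 365.25 / 12

frequency_midpoints <- function() {
  c("never"           = 0,
    "monthly_or_less" = 0.5 / DAYS_PER_MONTH,
    "2-4_per_month"   = 3 / DAYS_PER_MONTH,
    "2-3_per_week"    = 2.5 / 7,
    "4+_per_week"     = 5.5 / 7)
}

quantity_midpoints <- function() {
  c("1-2" = 1.5, "3-4" = 3.5, "5-6" = 5.5, "7-9" = 8, "10+" = 12)
}

# lower bound of each quantity category in drinks per occasion: a respondent
# whose *typical* occasion already meets the sex-specific HED threshold is a
# heavy episodic drinker by definition, whatever the HED-frequency item says
quantity_lower_bounds <- function() {
  c("1-2" = 1, "3-4" = 3, "5-6" = 5, "7-9" = 7, "10+" = 10)
}

#' Sex-specific heavy-episodic-drinking thresholds (drinks per occasion)
#'
#' Five or more standard drinks on a single occasion for men, four or more
#' for women.
#'
#' @param sex "male" or "female" (vectorized).
#' @return threshold in drinks per occasion.
#' @export
hed_threshold <- function(sex) {
  sex <- check_sex(sex)
  ifelse(sex == "male", 5, 4)
}

check_sex <- function(sex) {
  sex <- as.character(sex)
  bad <- !sex %in% c("male", "female")
  if (any(bad)) {
    stop("unknown sex value(s): ", paste(unique(sex[bad]), collapse = ", "))
  }
  sex
}

#' Average daily pure-alcohol intake implied by quantity-frequency items
#'
#' Midpoint of drinks per occasion times occasions per day times grams of
#' pure alcohol per standard drink. Vectorized over respondents.
#'
#' @param frequency drinking-frequency category, one of
#'   [audit_frequency_levels()].
#' @param quantity typical drinks-per-occasion category, one of
#'   [audit_quantity_levels()].
#' @param grams_per_drink grams of pure alcohol per standard drink
#'   (default 14).
#' @return grams of pure alcohol per day, non-negative.
#' @examples
#' grams_per_day("2-3_per_week", "3-4") # 2.5/7 * 3.5 * 14 = 17.5
#' @export
grams_per_day <- function(frequency, quantity, grams_per_drink = 14) {
  stopifnot(is.numeric(grams_per_drink), grams_per_drink > 0)
  fm <- frequency_midpoints()
  qm <- quantity_midpoints()
  bad_f <- !frequency %in% names(fm)
  if (any(bad_f)) {
    stop("unknown frequency category: ",
         paste(unique(frequency[bad_f]), collapse = ", "))
  }
  bad_q <- !quantity %in% names(qm)
  if (any(bad_q)) {
    stop("unknown quantity category: ",
         paste(unique(quantity[bad_q]), collapse = ", "))
  }
  unname(fm[frequency] * qm[quantity] * grams_per_drink)
}

#' Classify drinker status from past-year and past-month indicators
#'
#' Lifetime/no-recent drinking hierarchy used throughout: respondents with no
#' past-year drinking are abstainers; past-year but not past-month drinkers
#' are former drinkers; past-month drinkers are current drinkers. Rows with a
#' missing indicator are returned as NA and counted; callers exclude them
#' with a logged tally.
#'
#' @param past_year,past_month "yes"/"no" indicators (vectorized; NA allowed).
#' @return character vector in {"abstainer","former","current"} with NA for
#'   unclassifiable rows; attribute "n_missing" carries the excluded count.
#' @export
classify_status <- function(past_year, past_month) {
  norm <- function(x) {
    x <- tolower(as.character(x))
    x[!x %in% c("yes", "no")] <- NA
    x
  }
  py <- norm(past_year)
  pm <- norm(past_month)
  out <- rep(NA_character_, length(py))
  out[py == "no"] <- "abstainer"
  out[py == "yes" & pm == "no"] <- "former"
  out[py == "yes" & pm == "yes"] <- "current"
  n_missing <- sum(is.na(out))
  if (n_missing > 0) {
    message(n_missing, " row(s) with missing drinking indicators flagged for exclusion")
  }
  attr(out, "n_missing") <- n_missing
  out
}

#' Heavy-episodic-drinking status of a current drinker
#'
#' A current drinker is HED when they report any past-month occasion meeting
#' the sex-specific threshold (5+ drinks for men, 4+ for women): either the
#' HED-frequency item is anything but "never", or the typical quantity itself
#' meets the threshold. `quantity` may be a category label (auto-HED only
#' when the category's lower bound meets the threshold) or a numeric drinks
#' count (compared directly).
#'
#' @param sex "male" or "female" (vectorized).
#' @param quantity typical drinks per occasion: category label or numeric.
#' @param hed_frequency HED-frequency category, one of
#'   [hed_frequency_levels()]; default "never".
#' @return logical vector.
#' @examples
#' hed_status("male", 5)                      # TRUE: meets 5+ threshold
#' hed_status("female", 4)                    # TRUE: meets 4+ threshold
#' hed_status("male", "3-4", "never")         # FALSE
#' @export
hed_status <- function(sex, quantity, hed_frequency = "never") {
  thr <- hed_threshold(sex)
  bad_h <- !hed_frequency %in% hed_frequency_levels()
  if (any(bad_h)) {
    stop("unknown HED-frequency category: ",
         paste(unique(hed_frequency[bad_h]), collapse = ", "))
  }
  if (is.numeric(quantity)) {
    typical_meets <- quantity >= thr
  } else {
    lb <- quantity_lower_bounds()
    bad_q <- !quantity %in% names(lb)
    if (any(bad_q)) {
      stop("unknown quantity category: ",
           paste(unique(quantity[bad_q]), collapse = ", "))
    }
    typical_meets <- unname(lb[quantity]) >= thr
  }
  typical_meets | (hed_frequency != "never")
}
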