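#' Expand ICD-10 catalog entries to three/four-character prefixes
#'
#' Catalog entries may be single codes ("K860"), three-character prefixes
#' ("K70"), or ranges over the last two digits ("I20-I25", both endpoints
#' inclusive, same letter).
#'
#' @param entries character vector of catalog entries.
#' @return character vector of code prefixes.
#' @export
expand_icd10 <- function(entries) {
  out <- character(0)
  for (e in entries) {
    e <- toupper(gsub("\\s", "", e))
    if (grepl("^[A-Z][0-9]{2}-[A-Z][0-9]{2}$", e)) {
      a <- sub("-.*", "", e)
      b <- sub(".*-", "", e)
      if (substr(a, 1, 1) != substr(b, 1, 1)) {
        stop("ICD-10 range must stay within one letter block: ", e)
      }
      lo <- as.integer(substr(a, 2, 3))
      hi <- as.integer(substr(b, 2, 3))
      if (hi < lo) stop("descending ICD-10 range: ", e)
      out <- c(out, sprintf("%s%02d", substr(a, 1, 1), lo:hi))
    } else if (grepl("^[A-Z][0-9]{2,3}$", e)) {
      out <- c(out, e)
    } else {
      stop("malformed ICD-10 catalog entry: ", e)
    }
  }
  unique(out)
}

#' Map ICD-10 codes to cause categories
#'
#' Codes are normalized (uppercased, decimal point removed) and matched by
#' longest prefix against the registry's cause catalog, so "K70.3" falls
#' under a "K70" entry while a four-character entry like "K860" beats the
#' "K86" block it sits in. Unmatched codes go to the "unmapped" bucket
#' (counted toward total deaths, zero attribution); malformed codes warn and
#' are unmapped.
#'
#' @param codes character vector of ICD-10 codes.
#' @param reg an [rr_registry()] (its cause catalog is used).
#' @return character vector of cause-category names, "unmapped" where no
#'   entry matches.
#' @export
map_icd10 <- function(codes, reg) {
  lut <- character(0)
  for (nm in names(reg$causes)) {
    pf <- expand_icd10(reg$causes[[nm]]$icd10)
    lut[pf] <- nm
  }
  norm <- toupper(gsub("\\.", "", trimws(as.character(codes))))
  ok <- grepl("^[A-Z][0-9]{2}", norm)
  if (any(!ok | norm == "")) {
    warning(sum(!ok), " malformed ICD-10 code(s) sent to the unmapped bucket")
  }
  out <- rep("unmapped", length(norm))
  for (width in c(4L, 3L)) {          # longest prefix wins
    pref <- substr(norm, 1, width)
    hit <- ok & out == "unmapped" & pref %in% names(lut)
    out[hit] <- lut[pref[hit]]
  }
  out
}

#' Aggregate death records into a cause-by-stratum table
#'
#' Maps each record's ICD-10 code to a cause category and counts deaths by
#' (year, sex, age group, cause). Deaths below age 15 are excluded from
#' attribution (the exposure frame starts at 15); by default they are also
#' excluded from the totals used for proportion denominators
#' (`include_under15_in_totals` restores them there).
#'
#' @param records data.frame with columns year, sex, age, icd10.
#' @param reg an [rr_registry()].
#' @param include_under15_in_totals logical (default FALSE).
#' @return object of class `death_table`: list with `counts` (year, sex,
#'   age_group, cause, deaths), `totals` (year, sex, age_group, total), and
#'   `unmapped` (year, unmapped count).
#' @export
build_death_table <- function(records, reg, include_under15_in_totals = FALSE) {
  stopifnot(all(c("year", "sex", "age", "icd10") %in% names(records)))
  records$cause <- map_icd10(records$icd10, reg)
  records$age_group <- as.character(age_to_group(records$age))
  under15 <- is.na(records$age_group)
  in_frame <- records[!under15, ]
  counts <- stats::aggregate(
    list(deaths = rep(1L, nrow(in_frame))),
    in_frame[c("year", "sex", "age_group", "cause")], sum)
  tot_src <- if (include_under15_in_totals) {
    records$age_group[under15] <- "<15"
    records
  } else {
    in_frame
  }
  totals <- stats::aggregate(
    list(total = rep(1L, nrow(tot_src))),
    tot_src[c("year", "sex", "age_group")], sum)
  unm <- in_frame[in_frame$cause == "unmapped", ]
  unmapped <- if (nrow(unm) == 0) {
    data.frame(year = unique(records$year), unmapped = 0L)
  } else {
    stats::aggregate(list(unmapped = rep(1L, nrow(unm))), unm["year"], sum)
  }
  structure(list(counts = counts, totals = totals, unmapped = unmapped),
            class = "death_table")
}

#' Apply attributable fractions to death counts
#'
#' Attributable deaths per cell are AAF times the death count; fully
#' attributable causes contribute their whole count (AAF 1), unmapped deaths
#' contribute zero, and negative AAFs (protective causes) yield negative
#' cells that are retained in sums.
#'
#' @param death_table a [build_death_table()] result.
#' @param aafs AAF table from [aaf_table()] (columns year, sex, age_group,
#'   cause, aaf); a table with all-NA year applies to every year.
#' @return data.frame of cells: year, sex, age_group, cause, deaths, aaf,
#'   attributable.
#' @export
attributable_deaths <- function(death_table, aafs) {
  stopifnot(inherits(death_table, "death_table"))
  cells <- death_table$counts[death_table$counts$cause != "unmapped", ]
  by_year <- !all(is.na(aafs$year))
  key <- function(d, with_year) {
    paste(if (with_year) d$year else "", d$sex, d$age_group, d$cause, sep = "|")
  }
  m <- match(key(cells, by_year), key(aafs, by_year))
  if (anyNA(m)) {
    miss <- cells[is.na(m), ]
    stop("no AAF for non-empty cell(s): ",
         paste(key(miss, by_year)[seq_len(min(5, nrow(miss)))], collapse = "; "))
  }
  cells$aaf <- aafs$aaf[m]
  cells$attributable <- cells$aaf * cells$deaths
  cells
}

#' Percentage of deaths attributable to alcohol
#'
#' @param attributable attributable death counts per group.
#' @param total total death counts per group (> 0; zero totals return NA
#'   with a message).
#' @return 100 x attributable / total.
#' @export
proportion_of_total <- function(attributable, total) {
  out <- ifelse(total > 0, 100 * attributable / total, NA_real_)
  if (any(total <= 0)) {
    message(sum(total <= 0), " group(s) with zero total deaths; proportion undefined")
  }
  out
}

#' Direct age standardization of stratum rates
#'
#' @param rates stratum rates (any per-population scale, typically per
#'   100,000), named by or aligned with `age_group`.
#' @param weights standard-population weights named by age group, summing
#'   to 1 (default [who_standard_weights()]).
#' @param age_group age-group labels aligned with `rates` (default: the
#'   names of `weights`).
#' @return the standardized rate, on the scale of `rates`.
#' @export
age_standardize <- function(rates, weights = who_standard_weights(),
                            age_group = names(weights)) {
  if (abs(sum(weights) - 1) > 1e-9) stop("standard weights must sum to 1")
  if (length(rates) != length(age_group)) {
    stop("rates and age_group lengths differ")
  }
  miss <- setdiff(names(weights), age_group)
  if (length(miss) > 0) {
    stop("no stratum rate for standard age group(s): ",
         paste(miss, collapse = ", "))
  }
  sum(weights[age_group] * rates)
}

#' Crude and age-standardized attributable mortality rates
#'
#' Per year and sex (plus an overall row per year): total attributable
#' deaths, population, crude and age-standardized rates per 100,000, and the
#' attributable percentage of total deaths.
#'
#' @param cells output of [attributable_deaths()].
#' @param death_table the matching [build_death_table()] result (for
#'   proportion denominators).
#' @param populations data.frame with columns sex, age_group, population.
#' @param standard_weights standardization weights (default
#'   [who_standard_weights()]).
#' @return data.frame keyed by (year, sex) with sex = "all" rows appended.
#' @export
rate_table <- function(cells, death_table, populations,
                       standard_weights = who_standard_weights()) {
  stopifnot(all(c("sex", "age_group", "population") %in% names(populations)))
  one <- function(cl, tt, pop) {
    ag <- stats::aggregate(attributable ~ age_group, cl, sum)
    pop_g <- stats::aggregate(population ~ age_group, pop, sum)
    m <- match(names(standard_weights), ag$age_group)
    pm <- match(names(standard_weights), pop_g$age_group)
    if (anyNA(pm)) {
      stop("missing population for age group(s): ",
           paste(names(standard_weights)[is.na(pm)], collapse = ", "))
    }
    attr_g <- ifelse(is.na(m), 0, ag$attributable[m])
    r_g <- attr_g / pop_g$population[pm] * 1e5
    total_attr <- sum(attr_g)
    total_pop <- sum(pop_g$population[pm])
    data.frame(
      attributable = total_attr, population = total_pop,
      crude_rate = total_attr / total_pop * 1e5,
      asr = age_standardize(r_g, standard_weights, names(standard_weights)),
      proportion_pct = proportion_of_total(total_attr, sum(tt$total))
    )
  }
  out <- list()
  for (yr in sort(unique(cells$year))) {
    cl_y <- cells[cells$year == yr, ]
    tt_y <- death_table$totals[death_table$totals$year == yr, ]
    for (sx in c("male", "female")) {
      row <- one(cl_y[cl_y$sex == sx, ], tt_y[tt_y$sex == sx, ],
                 populations[populations$sex == sx, ])
      out[[length(out) + 1L]] <- cbind(year = yr, sex = sx, row)
    }
    out[[length(out) + 1L]] <- cbind(year = yr, sex = "all",
                                     one(cl_y, tt_y, populations))
  }
  do.call(rbind, out)
}
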