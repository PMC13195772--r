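#!/usr/bin/env Rscript
# Stage 4 — death attribution and rates.
#
# Maps ICD-10 codes to cause categories, applies each year's AAFs (exposure
# from the nearest survey year) to the death counts, and produces crude and
# WHO-standard age-standardized attributable mortality rates by sex and
# overall, plus the trend tables grouped the way the study reports them.

library(aafmort)

reg <- load_rr_registry("results/data/rr_registry.yaml")
mort <- read.csv("results/data/mortality.csv")
pops <- read.csv("results/data/populations.csv")
aafs <- read.csv("results/aaf.csv")
dt <- build_death_table(mort, reg)

years <- sort(unique(mort$year))
survey_years <- sort(unique(aafs$year))
cells <- list()
rates <- list()
for (y in years) {
  ay <- aafs[aafs$year == nearest_survey_year(y, survey_years), ]
  ay$year <- NA_integer_
  dt_y <- dt
  dt_y$counts <- dt$counts[dt$counts$year == y, ]
  dt_y$totals <- dt$totals[dt$totals$year == y, ]
  cl <- attributable_deaths(dt_y, ay)
  cells[[as.character(y)]] <- cl
  rates[[as.character(y)]] <- rate_table(cl, dt_y, pops)
}
cells <- do.call(rbind, cells)
rates <- do.call(rbind, rates)
write.csv(cells, "results/attributable_deaths.csv", row.names = FALSE)
write.csv(rates, "results/rates.csv", row.names = FALSE)

rep <- report_tables(list(cells = cells,
                          intervals = cbind(rates,
                                            proportion_lo = NA, proportion_hi = NA,
                                            asr_lo = NA, asr_hi = NA)),
                     pops)
for (nm in names(rep)) {
  write.csv(rep[[nm]], sprintf("results/report_%s.csv", nm), row.names = FALSE)
}

all_rates <- rates[rates$sex == "all", ]
cat(sprintf("attributable share of deaths: %.1f%% (%d) to %.1f%% (%d)\n",
            all_rates$proportion_pct[1], all_rates$year[1],
            all_rates$proportion_pct[nrow(all_rates)],
            all_rates$year[nrow(all_rates)]))
for (sx in c("male", "female")) {
  r <- rates[rates$sex == sx, ]
  cat(sprintf("%s age-standardized attributable rate: %.1f per 100,000 (%d)\n",
              sx, r$asr[1], r$year[1]))
}
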