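#!/usr/bin/env Rscript
# Stage 1 — simulate the study inputs.
#
# Generates the synthetic analogue of the study's three data sources from
# the default two-sex x four-age-group scenario: biennial survey microdata,
# annual mortality records with ICD-10 codes, and the per-capita
# pure-alcohol benchmark series (with 60% survey undercoverage, so the
# calibration stage has real work to do). The scenario's ground truth is
# exported alongside so later stages can be checked against it.

library(aafmort)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 1L

dir.create("results/data", recursive = TRUE, showWarnings = FALSE)
sc <- default_scenario(years = 2015:2017, seed = seed)

for (sy in c(2015L, 2017L)) {
  sv <- generate_survey(sc, 10000, seed = seed + sy %% 100L)
  write.csv(sv, sprintf("results/data/survey_%d.csv", sy), row.names = FALSE)
  cat(sprintf("survey %d: %d respondents, %.1f%% current drinkers\n",
              sy, nrow(sv), 100 * mean(sv$past_month == "yes")))
}

mort <- do.call(rbind, lapply(sc$years, function(y) {
  generate_mortality(sc, y, seed = seed + (y %% 1000L))
}))
write.csv(mort, "results/data/mortality.csv", row.names = FALSE)
cat(sprintf("mortality: %d death records over %d-%d\n",
            nrow(mort), min(sc$years), max(sc$years)))

bm <- generate_benchmark(sc, undercoverage = 0.6)
write.csv(bm, "results/data/benchmark.csv", row.names = FALSE)
cat(sprintf("benchmark: %.2f litres pure alcohol per capita 15+ per year\n",
            bm$litres_per_capita[1]))

write_rr_registry(sc$registry, "results/data/rr_registry.yaml")
write.csv(sc$strata[c("sex", "age_group", "population")],
          "results/data/populations.csv", row.names = FALSE)

truth <- export_ground_truth(sc)
write.csv(truth, "results/data/ground_truth.csv", row.names = FALSE)
write.csv(attr(truth, "asr"), "results/data/ground_truth_asr.csv",
          row.names = FALSE)
cat(sprintf("ground truth: %d stratum x cause AAFs; true overall ASR %.2f per 100,000\n",
            nrow(truth), attr(truth, "asr")$asr_true[3]))
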