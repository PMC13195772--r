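#!/usr/bin/env Rscript
# Stage 3 — alcohol-attributable fractions.
#
# Evaluates the attributable fraction for every stratum x cause by
# trapezoidal integration of the calibrated gamma density against the
# registry's relative-risk curves (HED-stratified for injuries and ischemic
# heart disease), and compares point estimates with the scenario's ground
# truth computed by adaptive quadrature.

library(aafmort)

reg <- load_rr_registry("results/data/rr_registry.yaml")
exposure <- read.csv("results/exposure.csv")
aafs <- do.call(rbind, lapply(split(exposure, exposure$year),
                              aaf_table, reg = reg))
write.csv(aafs, "results/aaf.csv", row.names = FALSE)

truth <- read.csv("results/data/ground_truth.csv")
key <- function(d) paste(d$sex, d$age_group, d$cause)
first <- aafs[aafs$year == min(aafs$year), ]
tr <- truth$aaf_true[match(key(first), key(truth))]
partial <- first$aaf < 1
cat(sprintf("%d stratum x cause AAFs per year; partial causes range %.3f to %.3f\n",
            nrow(first), min(first$aaf[partial]), max(first$aaf[partial])))
cat(sprintf("median |estimated - true| among partial causes: %.4f\n",
            median(abs(first$aaf - tr)[partial])))
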