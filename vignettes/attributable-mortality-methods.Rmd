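---
title: "Estimating alcohol-attributable mortality: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating alcohol-attributable mortality: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aafmort)
```

# The estimation problem

Alcohol contributes to deaths from many causes — liver cirrhosis, several
cardiovascular diseases, injuries, some cancers — but death certificates
record only the underlying cause, not whether drinking was involved. The
standard comparative-risk solution is indirect: combine the population's
exposure distribution (how much people drink) with dose-response relative
risks from meta-analyses to obtain, per cause, the *alcohol-attributable
fraction* (AAF) — the share of deaths from that cause that would not occur
in a counterfactual population of lifetime abstainers. Applied to registry
death counts, AAFs yield attributable death counts, proportions of total
mortality, and age-standardized attributable rates, trackable over time and
across sex and age groups.

This package implements that pipeline end to end, together with a
synthetic-data generator whose ground truth is known exactly, so every
stage can be validated without access to confidential registry or survey
microdata.

# The attributable-fraction model

For a partially attributable cause in one stratum (sex x age group x year),
the population excess risk is

$$N \;=\; P_{\mathrm{form}}\,(RR_{\mathrm{form}} - 1)
\;+\; p_{\mathrm{cd}} \int_{0}^{150} f(x)\,\big(RR_{\mathrm{cd}}(x) - 1\big)\,dx ,$$

and the attributable fraction is \(AAF = N / (N + 1)\). Here
\(P_{\mathrm{form}}\) is the prevalence of former drinkers (drank in the
past year but not the past month), \(p_{\mathrm{cd}}\) the prevalence of
current drinkers, \(f\) the current drinkers' consumption density in grams
of pure alcohol per day, truncated and renormalized on \((0, 150]\), and
\(RR(\cdot)\) the cause's relative-risk curve relative to lifetime
abstention. The point mass at zero consumption belongs to abstainers and
former drinkers, not to the integral. Protective risk segments
(\(RR < 1\), as in the J-shaped ischemic heart disease curve) contribute
negative excess risk and are retained, so AAFs can be negative; causes
whose ICD-10 codes are alcohol-specific carry \(AAF = 1\) identically.

For injuries, ischemic heart disease and ischemic stroke, the risk curves
distinguish heavy episodic drinkers (HED: 5+ drinks on one occasion for
men, 4+ for women). The current-drinker integral then splits at a 60 g/day
threshold used *only inside the integration*:

$$\int_0^{60}\! P_{\mathrm{NHED}}(x)\big(RR_{\mathrm{NHED}}(x)-1\big)dx
+ \int_0^{60}\! P_{\mathrm{HED}}(x)\big(RR_{\mathrm{HED}}(x)-1\big)dx
+ \int_{60}^{150}\! P_{\mathrm{CD}}(x)\big(RR_{\mathrm{HED}}(x)-1\big)dx ,$$

with \(P_{\mathrm{NHED}} = (1-p_{\mathrm{hed}})\,p_{\mathrm{cd}} f\) and
\(P_{\mathrm{HED}} = p_{\mathrm{hed}}\,p_{\mathrm{cd}} f\) below the
threshold. Two modelling commitments are involved, both exposed as
options:

* **Excess risk, not raw risk.** The integrands use \(RR - 1\); a literal
  \(P\,RR\) variant is available (`excess_risk = FALSE` in
  `compute_aaf_hed()`) for sensitivity analysis only, since the
  \(N/(N+1)\) transform is an attributable fraction only for excess risk.
* **Mass above 60 g follows the HED curve.** All consumption above the
  threshold — including that of survey-classified non-HED drinkers — is
  assigned the HED risk function: with one fitted density per stratum, a
  drinker averaging more than 60 g/day is treated as exhibiting the
  heavy-drinking risk profile regardless of the episodic item. When the two
  curves coincide the decomposition collapses exactly to the plain
  integral (this identity is tested to 1e-10).

Both drinker groups share one consumption density per stratum; HED and
non-HED differ only in mixing weights below the threshold. This mirrors
fitting a single gamma per sex-age group and avoids estimating separate
distributions from sparse HED subsamples.

# Exposure modelling

Surveys measure drinking with the first three AUDIT-C style items. The
quantification chain is:

1. **Status**: no past-year drinking = lifetime-or-current abstainer;
   past-year but not past-month = former; past-month = current. Rows with
   missing indicators are excluded with a logged count.
2. **Volume**: category midpoints — frequency mapped to occasions/day
   ("monthly or less" = 0.5/30.44, "2-4 per month" = 3/30.44, "2-3 per
   week" = 2.5/7, "4+ per week" = 5.5/7) times drinks-per-occasion
   midpoints (1.5, 3.5, 5.5, 8, 12) times grams per standard drink
   (default 14 g, configurable — national drink definitions differ).
3. **HED**: a current drinker is HED when any past-month occasion meets
   the sex threshold: the HED-frequency item is not "never", or the typical
   quantity itself reaches 5 (men) / 4 (women) drinks.
4. **Calibration**: self-report understates consumption, so all drinkers'
   grams/day are rescaled by one survey-wide factor that matches the
   weighted per-capita consumption to coverage x benchmark, where the
   benchmark is the recorded-plus-unrecorded per-capita figure (litres of
   pure alcohol per person 15+ per year; conversion uses ethanol density
   0.789 g/ml and a 365.25-day year). Coverage defaults to 1.0 and is a
   configuration knob — parts of the comparative-risk literature use 0.8.
   Calibration is exactly multiplicative, preserving consumption ratios.
5. **Smoothing**: a gamma distribution is fitted per stratum by weighted
   maximum likelihood (root-bracketed profile score, tolerance 1e-10),
   falling back to weighted method of moments with a warning if the
   optimizer fails; a zero-variance sample is flagged degenerate. At least
   10 positive observations are required; sparser strata borrow the
   same-sex adjacent age group's parameters, flagged and logged.
6. **Carry-forward**: the survey frame ends at 64, so age groups above the
   oldest surveyed group inherit its distribution (per sex and year),
   flagged `imputed`.

Calibration is applied to individual values *before* the gamma fit; the
reverse order (calibrating fitted parameters) is algebraically close but
not identical once the 150 g cap binds, and the chosen order keeps the cap
meaningful on the calibrated scale. Former-drinker prevalence is estimated
per stratum, not pooled.

# Relative-risk registry

Published meta-analytic coefficient tables are proprietary to their
sources and are **not** bundled; the registry is configuration-driven
(YAML), with three functional forms on the log-RR scale — constant
(former drinkers), log-linear, and log-quadratic — plus a coefficient
covariance matrix per function for uncertainty propagation, and per-sex /
per-age entries with "all" wildcards. The shipped
`rr_registry_illustrative.yaml` is explicitly illustrative: shaped like the
literature (log-linear cirrhosis slopes higher for women, a J-shaped
non-HED ischemic heart disease curve, steeper HED injury slopes) but not
citable numbers. Any substantive analysis must substitute published
coefficients via `load_rr_registry()`.

# Numerical choices

* **Quadrature.** The AAF integral uses the composite trapezoidal rule on
  1,501 equally spaced points over \([0, 150]\) (0.1 g step), the grid the
  method prescribes. Two refinements keep the 0.1 g grid at adaptive-
  quadrature accuracy: the linear part \(\beta_1 x\) of each dose-response
  excess risk integrates exactly against the truncated gamma via its
  incomplete-gamma first moment, and density mass lost to discretization
  near the origin (where the gamma density has unbounded curvature for
  shape < 2) is reassigned at the residual risk of the segment's lower
  edge. Constant-risk causes thereby reproduce their closed form
  \(p(RR-1)/(p(RR-1)+1)\) to float precision, and randomized
  gamma x log-quadratic fixtures agree with `stats::integrate` to 1e-6
  relative. The non-stratified integral shares the HED path's 60 g split
  internally so the two routes agree exactly when risks coincide.
* **Truncation.** The gamma density is truncated at 150 g/day and
  renormalized, keeping it a proper density as the integral requires.
  Grid refinement from 1,501 to 15,001 points moves AAFs by < 1e-5.
* **Percentiles.** Interval endpoints use linear interpolation between
  order statistics (`stats::quantile` type 7): the 2.5th percentile of
  draws 1..10,000 is 250.975.
* **Ties and degeneracy.** Nearest-survey-year assignment breaks ties
  toward the earlier year. Zero covariance returns coefficients as a point
  mass. Empty strata, unparseable ICD-10 codes, missing AAFs for non-empty
  cells, and descending ICD ranges raise errors naming the offender;
  malformed codes go to the unmapped bucket with a warning and still count
  toward total deaths.

# Uncertainty propagation

Each Monte Carlo iteration (default 10,000) jointly redraws former- and
current-drinker prevalences and the HED share (binomial at the stratum's
effective sample sizes — respondent counts by default, design effects
ignored), the gamma parameters (parametric bootstrap: simulate the
stratum's current-drinker sample size from the fitted gamma and refit),
and the RR coefficients (normal for one coefficient, multivariate normal
otherwise, on the log-RR scale). One draw of a registry function is shared
by every stratum that resolves to it within an iteration, keeping risk
curves coherent; stratum-level sampling draws use independent substreams
derived from the master seed, so the whole CI table is reproducible from
the seed. Intervals are 2.5/97.5 percentiles of the draws. Derived
quantities — attributable counts, crude and standardized rates,
proportions — are transformed per iteration from the *same* draw matrix
and only then reduced to percentiles, preserving dependence; endpoint
values are never summed.

The phrase "prevalence of current drinkers simulated using a gamma
distribution" admits no literal reading (a proportion is not
gamma-distributed); it is implemented as the parametric bootstrap of the
consumption distribution above, with current-drinker prevalence perturbed
binomially alongside former — each source has its own toggle in
`simulation_spec()`.

# The synthetic-data generator

`population_scenario()` fixes the truth: per-stratum population, status
probabilities, gamma consumption parameters, HED probability among current
drinkers, per-cause counterfactual mortality rates, and the true RR
registry. From it:

* `generate_survey()` draws respondents proportional to stratum
  population (weights = population / sample size), ages within the 15-64
  frame (so the 60+ group is represented by ages 60-64, exercising the
  oldest-group assumption), statuses from the stratum probabilities, and
  current drinkers' grams/day from the true gamma. Items are produced by
  inverting the same midpoint mapping the exposure stage applies — nearest
  on the log scale, which best preserves the arithmetic- and log-mean
  statistics the gamma MLE consumes. HED status is the heavy tail: a
  drinker is HED exactly when their consumption exceeds the gamma's
  \((1 - p_{\mathrm{hed}})\) quantile, so the marginal HED share equals
  the scenario's parameter while HED correlates with volume as in real
  data, and the items stay consistent with `hed_status()`.
* `generate_mortality()` draws stratum x cause death counts as Poisson
  with mean population x counterfactual rate x \((1 + N)\), \(N\) being
  the true excess risk — so the generated deaths' true attributable
  fraction is exactly the scenario AAF — and tags each death with an
  ICD-10 code from the cause's list (sometimes with a random fourth
  character, to exercise prefix matching).
* `generate_benchmark()` reports the truth-implied per-capita figure
  divided by an undercoverage fraction, so calibration with coverage equal
  to that fraction recovers the truth exactly.
* `export_ground_truth()` computes true AAFs by adaptive quadrature
  (`stats::integrate`, a route independent of the trapezoid code), expected
  and attributable death counts, and true age-standardized rates.

What the generator does *not* emulate: the three-stage cluster design's
variance structure (only weights are emulated, so design effects on CI
width are untested), item nonresponse, recall patterns that vary with
consumption, secular trends within a scenario, and cause-specific age
profiles beyond the configured baseline rates. Passing recovery tests
therefore demonstrate correctness of the estimation machinery under the
stated sampling model, not robustness to real-survey complications —
in particular, category coarsening introduces a small bias in fitted gamma
parameters (a few percent at realistic grids) that the Monte Carlo
intervals, which model sampling and coefficient uncertainty only, do not
cover.

# Age standardization and attribution conventions

Rates are standardized directly with the WHO World Standard population
collapsed to the four analysis age groups (15-29, 30-44, 45-59, 60+) and
renormalized over ages 15+; the weights are a configurable argument.
Deaths under 15 are excluded from attribution (the exposure frame starts
at 15) and, by default, from proportion denominators — a switch restores
them there. Negative attributable cells from protective AAFs are retained
in sums. ICD-10 mapping uses longest-prefix matching, so a four-character
catalog entry overrides its three-character block, and supports
"I20-I25"-style ranges.

# Problem sizes used in the validation suite

The packaged tests run the full chain at the sizes the method's own
conventions suggest: surveys of 10,000 respondents for recovery checks
(one stratum when the target is the fitted distribution itself),
2-sex x 4-age x multi-cause scenarios for end-to-end attribution, 200
seeded mortality replicates for the Poisson expectation check, 200
randomized single-stratum scenarios at 2,000 iterations for interval
calibration (intervals cover the true AAF in 90-99% of scenarios), and
10,000 iterations in the workflow scripts. The generator's defaults —
prevalences, gamma parameters with means of 10-28 g/day, HED shares
declining with age, age-graded baseline rates — were fixed once as
representative of a middle-income national population and are not tuned.

# Known limitations

* The illustrative RR coefficients are placeholders; substantive estimates
  require published meta-analytic tables, and results are only as good as
  those inputs.
* One calibration factor per survey year: differential underreporting by
  sex, age or region is not modelled.
* Single underlying cause of death only; no garbage-code redistribution or
  multiple-cause analysis.
* Effective sample sizes ignore design effects, so intervals are
  anti-conservative for cluster-sampled surveys.
* Exposure above the survey age ceiling is assumed identical to the oldest
  surveyed group, which likely misstates risk for the very old.
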