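test_that("ICD-10 entries expand and map by longest prefix", {
  expect_equal(expand_icd10("I20-I25"), paste0("I", 20:25))
  expect_equal(expand_icd10(c("K70", "K860")), c("K70", "K860"))
  expect_error(expand_icd10("I20-J25"), "one letter block")
  expect_error(expand_icd10("I25-I20"), "descending")
  expect_error(expand_icd10("7K0"), "malformed")

  reg <- illustrative_registry()
  # dotted subcodes fall under their 3-character block
  expect_equal(map_icd10("K70.3", reg), "liver_cirrhosis")
  expect_equal(map_icd10("k741", reg), "liver_cirrhosis")
  # range boundaries resolve on both ends
  expect_equal(map_icd10(c("I20", "I25", "I259"), reg),
               rep("ischemic_heart_disease", 3))
  expect_equal(map_icd10("I26", reg), "unmapped")
  # 4-character entry beats its 3-character block: K860 maps, K861 does not
  expect_equal(map_icd10(c("K860", "K861"), reg),
               c("alcohol_use_disorders", "unmapped"))
  expect_warning(out <- map_icd10(c("??", "K70"), reg), "malformed")
  expect_equal(out, c("unmapped", "liver_cirrhosis"))
})

test_that("death tables conserve record counts across causes and the unmapped bucket", {
  sc <- default_scenario()
  rec <- generate_mortality(sc, 2015L, seed = 4)
  # salt in some codes outside the catalog and some under-15 deaths
  extra <- data.frame(year = 2015L, sex = "male", age = c(40, 40, 10),
                      icd10 = c("C61", "J45", "V03"), cause_true = NA,
                      stringsAsFactors = FALSE)
  dt <- build_death_table(rbind(rec, extra), sc$registry)
  expect_equal(sum(dt$counts$deaths), nrow(rec) + 2)  # under-15 excluded
  expect_equal(dt$unmapped$unmapped, 2)
  # mapped + unmapped equals totals in every stratum-year
  expect_equal(sum(dt$counts$deaths), sum(dt$totals$total))
  # under-15 deaths can be restored to the denominators
  dt2 <- build_death_table(rbind(rec, extra), sc$registry,
                          include_under15_in_totals = TRUE)
  expect_equal(sum(dt2$totals$total), nrow(rec) + 3)
})

test_that("attributable deaths are AAF times counts, linear in counts", {
  reg <- constant_rr_registry()
  rec <- data.frame(year = 2015L, sex = "male",
                    age = c(35, 35, 35), icd10 = "K70",
                    stringsAsFactors = FALSE)
  dt <- build_death_table(rec, reg)
  aafs <- data.frame(year = NA_integer_, sex = "male", age_group = "30-44",
                     cause = "fixture_cause", aaf = 1 / 3)
  cells <- attributable_deaths(dt, aafs)
  expect_equal(cells$attributable, 1)
  # doubling counts doubles attribution exactly
  dt2 <- build_death_table(rbind(rec, rec), reg)
  expect_equal(attributable_deaths(dt2, aafs)$attributable, 2)
  # a missing AAF for a non-empty cell is an error naming the cell
  bad <- aafs
  bad$age_group <- "45-59"
  expect_error(attributable_deaths(dt, bad), "30-44")
})

test_that("proportions and the weighted-mean identity across sexes hold", {
  expect_equal(proportion_of_total(146, 1000), 14.6)
  expect_equal(proportion_of_total(0, 500), 0)
  expect_message(p <- proportion_of_total(c(1, 0), c(10, 0)), "zero total")
  expect_true(is.na(p[2]))
  # overall proportion is the deaths-weighted mean of sex-specific ones
  attr_s <- c(male = 120, female = 40)
  tot_s <- c(male = 900, female = 700)
  overall <- proportion_of_total(sum(attr_s), sum(tot_s))
  weighted <- sum(proportion_of_total(attr_s, tot_s) * tot_s) / sum(tot_s)
  expect_equal(overall, weighted, tolerance = 1e-9)
})

test_that("direct standardization satisfies its invariance identities", {
  w <- c("15-29" = 0.25, "30-44" = 0.75, "45-59" = 0, "60+" = 0)
  expect_equal(age_standardize(c(10, 30, 5, 5), w, names(w)), 25)
  # equal stratum rates are invariant under any weights
  for (r in 1:5) {
    set.seed(r)
    wr <- runif(4)
    wr <- wr / sum(wr)
    names(wr) <- default_age_groups()
    expect_equal(age_standardize(rep(12.3, 4), wr, names(wr)), 12.3,
                 tolerance = 1e-12)
  }
  # weights equal to observed population shares reproduce the crude rate
  pop <- c(4e5, 3e5, 2e5, 1e5)
  deaths <- c(40, 90, 80, 70)
  rates <- deaths / pop * 1e5
  w_self <- pop / sum(pop)
  names(w_self) <- default_age_groups()
  crude <- sum(deaths) / sum(pop) * 1e5
  expect_equal(age_standardize(rates, w_self, names(w_self)), crude,
               tolerance = 1e-9)
  expect_error(age_standardize(rates, w_self * 2, names(w_self)), "sum to 1")
  expect_error(age_standardize(rates[1:3], who_standard_weights(),
                               default_age_groups()[1:3]),
               "no stratum rate")
})

test_that("rate tables aggregate strata consistently with crude-rate identities", {
  sc <- default_scenario()
  rec <- generate_mortality(sc, 2015L, seed = 6)
  dt <- build_death_table(rec, sc$registry)
  truth <- export_ground_truth(sc)
  aafs <- data.frame(year = NA_integer_, truth[c("sex", "age_group", "cause")],
                     aaf = truth$aaf_true)
  cells <- attributable_deaths(dt, aafs)
  pops <- sc$strata[c("sex", "age_group", "population")]
  rt <- rate_table(cells, dt, pops)
  # crude rate recomputed from totals matches the table
  for (sx in c("male", "female")) {
    row <- rt[rt$sex == sx, ]
    expect_equal(row$crude_rate,
                 row$attributable / row$population * 1e5, tolerance = 1e-9)
  }
  all_row <- rt[rt$sex == "all", ]
  expect_equal(all_row$attributable,
               sum(rt$attributable[rt$sex != "all"]), tolerance = 1e-9)
  # proportions stay within [0, 100] when all AAFs are non-negative... the
  # illustrative IHD curve can be net-protective, so only sanity-bound here
  expect_true(all(rt$proportion_pct < 100))
})
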