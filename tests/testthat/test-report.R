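index <- as.Date("2023-04-06")

test_that("venn cells partition the difficult group", {
  sim <- generate_cohort(scenario_config(n_persons = 1000, seed = 37))
  fl <- classify_cohort(sim$registry, index)
  vn <- venn_counts(fl)
  expect_equal(nrow(vn), 31L)
  expect_equal(sum(vn$count), sum(fl$difficult))
  # margins: summing cells containing a category recovers its prevalence
  for (abbrev in c("AR", "VFswitch")) {
    col <- c(AR = "advanced_resistance",
             VFswitch = "multi_switch_failure")[[abbrev]]
    expect_equal(sum(vn$count[vn[[abbrev]]]), sum(fl[[col]]))
  }
})

test_that("venn display suppression hides small cells but keeps counts", {
  fl <- data.table::data.table(
    person_id = sprintf("P%02d", 1:19),
    advanced_resistance = c(rep(TRUE, 19)),
    four_drug_regimen = c(rep(TRUE, 9), rep(FALSE, 10)),
    salvage_therapy = FALSE, recent_virologic_failure = FALSE,
    multi_switch_failure = FALSE)
  fl[, difficult := TRUE]
  vn <- venn_counts(fl, min_cell = 10)
  cell9 <- vn[vn$subset_id == "AR+4DR", ]
  cell10 <- vn[vn$subset_id == "AR", ]
  expect_equal(cell9$count, 9L); expect_false(cell9$display)
  expect_equal(cell10$count, 10L); expect_true(cell10$display)
  one <- venn_counts(fl[1, ])
  expect_equal(one$count[one$subset_id == "AR+4DR"], 1L)
  expect_equal(sum(one$count), 1L)
})

test_that("baseline table reports medians, counts and missingness by group", {
  sim <- generate_cohort(scenario_config(n_persons = 1500, seed = 43))
  fl <- classify_cohort(sim$registry, index)
  t1 <- table1(sim$registry, fl, index)
  # difficult group is generated older: medians must reflect that
  age <- t1[t1$variable == "current_age" & t1$level == "median", ]
  expect_gt(age$median[age$group == "difficult"],
            age$median[age$group == "non_difficult"] - 1)
  yr <- t1[t1$variable == "first_positive_test_year" & t1$level == "median", ]
  expect_lt(yr$median[yr$group == "difficult"],
            yr$median[yr$group == "non_difficult"])
  # categorical counts sum to group size
  sexes <- t1[t1$variable == "sex" & t1$group == "difficult", ]
  expect_equal(sum(sexes$n), sum(fl$difficult))
  # missing counts match the injected missingness
  miss <- t1[t1$variable == "risk_group" & t1$level == "missing", ]
  expect_equal(sum(miss$n[miss$group %in% c("difficult", "non_difficult")]),
               sum(is.na(sim$registry$persons$risk_group)))
  # single-person group: degenerate IQR equals that person's value
  solo <- mini_registry(episodes = ep_row("P1", c("DTG", "3TC"),
                                          "2015-01-01"))
  fls <- classify_cohort(solo, index)
  t1s <- table1(solo, fls, index)
  cd4 <- t1s[t1s$variable == "first_cd4" & t1s$level == "median" &
               t1s$group == "non_difficult", ]
  expect_equal(cd4$median, 350)
  expect_equal(cd4$q1, cd4$q3)
})

test_that("per-category suppression rates are consistent with the venn cells", {
  sim <- generate_cohort(scenario_config(n_persons = 1500, seed = 47))
  fl <- classify_cohort(sim$registry, index)
  oc <- derive_outcomes(sim$registry, index)
  sbc <- suppression_by_category(fl, oc)
  expect_true(all(sbc$rate >= 0 & sbc$rate <= 1, na.rm = TRUE))
  # assessed persons per venn cell sum to the difficult assessed count
  assessed <- oc$eligible_suppression & !is.na(oc$suppressed)
  expect_equal(sbc$n_assessed[sbc$category == "difficult"],
               sum(fl$difficult & assessed))
  # everyone suppressed means every rate is 1
  oc2 <- data.table::copy(oc)
  oc2[, suppressed := ifelse(is.na(suppressed), NA, TRUE)]
  sbc2 <- suppression_by_category(fl, oc2)
  expect_true(all(sbc2$rate[sbc2$n_assessed > 0] == 1))
})

test_that("run configuration YAML overrides thresholds", {
  cfgfile <- tempfile(fileext = ".yaml")
  writeLines(c("index_date: 2023-04-06", "min_cell: 5", "thresholds:",
               "  min_art_days: 1000"), cfgfile)
  rc <- read_run_config(cfgfile)
  expect_equal(rc$index_date, index)
  expect_equal(rc$min_cell, 5L)
  expect_equal(rc$thresholds$min_art_days, 1000L)
  expect_equal(rc$thresholds$switch_within_days, 183L)  # untouched default
  bare <- tempfile(fileext = ".yaml")
  writeLines("min_cell: 3", bare)
  expect_error(read_run_config(bare), "index_date")
})

test_that("the pipeline writes a deterministic, complete report", {
  cfg <- scenario_config(n_persons = 600, seed = 53)
  out1 <- tempfile(); out2 <- tempfile()
  res <- run_pipeline(config = cfg, out_dir = out1)
  run_pipeline(config = cfg, out_dir = out2)
  files <- c("flags.csv", "table1.csv", "table2.csv", "venn.csv",
             "suppression_by_category.csv", "sensitivity.csv",
             "manifest.json")
  for (f in files) {
    expect_true(file.exists(file.path(out1, f)))
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
  # every printed percentage equals numerator/denominator
  vn <- data.table::fread(file.path(out1, "venn.csv"))
  expect_equal(sum(vn$count), sum(res$flags$difficult))
  # a registry directory missing one table aborts with its name
  dir <- tempfile()
  write_registry(res$registry, dir)
  file.remove(file.path(dir, "resistance.csv"))
  expect_error(run_pipeline(input_dir = dir, out_dir = tempfile(),
                            index_date = index), "resistance.csv")
})
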