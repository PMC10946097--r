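index <- as.Date("2023-04-06")
cat33 <- default_drug_catalog()
th <- dtt_thresholds()

res_rows <- function(drugs, levels, date = "2020-01-01")
  data.table::data.table(person_id = "P1", test_date = as.Date(date),
                         drug_code = drugs, level = levels)

test_that("advanced resistance needs two drugs over two classes at intermediate level", {
  expect_true(classify_advanced_resistance(
    res_rows(c("EFV", "3TC"), c("high", "high")), cat33))
  expect_false(classify_advanced_resistance(
    res_rows(c("3TC", "FTC"), c("high", "intermediate")), cat33))
  expect_false(classify_advanced_resistance(
    res_rows(c("EFV", "DRV"), c("low", "low")), cat33))
  expect_false(classify_advanced_resistance(res_rows(character(0),
                                                     character(0)), cat33))
  # cumulative across tests: the per-drug maximum decides
  two_tests <- rbind(res_rows("EFV", "low", "2010-01-01"),
                     res_rows("EFV", "high", "2015-01-01"),
                     res_rows("3TC", "intermediate", "2015-01-01"))
  expect_true(classify_advanced_resistance(two_tests, cat33))
})

test_that("advanced resistance agrees with an exhaustive oracle on random maps", {
  set.seed(31)
  pool <- cat33$drug_code[!cat33$is_booster]
  for (i in 1:200) {
    k <- sample(1:6, 1)
    res <- data.table::data.table(
      person_id = "P1",
      test_date = as.Date("2015-06-01") + sample(0:1000, k),
      drug_code = sample(pool, k),
      level = sample(c("susceptible", "low", "intermediate", "high"), k,
                     replace = TRUE))
    expect_identical(classify_advanced_resistance(res, cat33),
                     oracle_advanced_resistance(res, cat33))
  }
})

test_that("four-drug regimen requires a past two- or three-drug regimen", {
  hist4 <- rbind(ep_row("P1", c("DTG", "3TC", "TDF"), "2015-01-01",
                        "2020-01-01"),
                 ep_row("P1", c("DRV", "RTV", "DTG", "TDF", "FTC"),
                        "2020-01-01"))
  r <- build_regimens(hist4)
  expect_true(classify_four_drug_regimen(r, index, cat33, th))
  # lifelong four-drug therapy: no qualifying past regimen
  life <- build_regimens(ep_row("P1", c("DRV", "RTV", "DTG", "TDF", "FTC"),
                                "2010-01-01"))
  expect_false(classify_four_drug_regimen(life, index, cat33, th))
  # currently on three drugs
  cur3 <- rbind(ep_row("P1", c("AZT", "3TC"), "2000-01-01", "2010-01-01"),
                ep_row("P1", c("DTG", "3TC", "TDF"), "2010-01-01"))
  expect_false(classify_four_drug_regimen(build_regimens(cur3), index,
                                          cat33, th))
})

test_that("salvage therapy flags marker drugs and intensified dosing", {
  expect_true(classify_salvage_therapy(
    ep_row("P1", c("ETR", "DTG", "TDF"), "2020-01-01"), index, cat33))
  expect_false(classify_salvage_therapy(
    ep_row("P1", c("DTG", "3TC"), "2020-01-01"), index, cat33))
  dtg_bid <- ep_row("P1", c("DTG", "3TC"), "2020-01-01",
                    dosing = c("BID", "QD"))
  expect_true(classify_salvage_therapy(dtg_bid, index, cat33))
  drv_boosted <- ep_row("P1", c("DRV", "RTV", "TDF", "FTC"), "2020-01-01",
                        dosing = c("BID", "QD", "QD", "QD"))
  expect_true(classify_salvage_therapy(drv_boosted, index, cat33))
  drv_bare <- ep_row("P1", c("DRV", "TDF", "FTC"), "2020-01-01",
                     dosing = c("BID", "QD", "QD"))
  expect_false(classify_salvage_therapy(drv_bare, index, cat33))
  # a past etravirine regimen does not count, only the current one
  past_etr <- rbind(ep_row("P1", "ETR", "2010-01-01", "2015-01-01"),
                    ep_row("P1", c("DTG", "3TC"), "2015-01-01"))
  expect_false(classify_salvage_therapy(past_etr, index, cat33))
  # unknown dosing is conservatively not BID
  unk <- ep_row("P1", c("DTG", "3TC"), "2020-01-01",
                dosing = c("UNKNOWN", "QD"))
  expect_false(classify_salvage_therapy(unk, index, cat33))
})

test_that("recent virologic failure needs spacing, window and ART duration", {
  long_art <- build_regimens(ep_row("P1", c("DTG", "3TC", "TDF"),
                                    "2013-01-01"))
  vl2 <- function(d1, d2, v1 = 250, v2 = 400)
    vl_row("P1", c(index - d1, index - d2), c(v1, v2))
  expect_true(classify_recent_virologic_failure(vl2(300, 100), long_art,
                                                index, th))
  expect_false(classify_recent_virologic_failure(vl2(160, 100), long_art,
                                                 index, th))
  short_art <- build_regimens(ep_row("P1", c("DTG", "3TC", "TDF"),
                                     index - 1095))
  expect_false(classify_recent_virologic_failure(vl2(300, 100), short_art,
                                                 index, th))
  # below-limit results never qualify
  bl <- vl_row("P1", c(index - 300, index - 100), c(400, 400),
               below = c(TRUE, TRUE))
  expect_false(classify_recent_virologic_failure(bl, long_art, index, th))
})

test_that("recent virologic failure agrees with an all-pairs oracle", {
  set.seed(41)
  long_art <- build_regimens(ep_row("P1", c("DTG", "3TC", "TDF"),
                                    "2010-01-01"))
  art_days <- art_duration_days(long_art, index)
  for (i in 1:300) {
    vl <- random_vl_history(index)
    expect_identical(
      classify_recent_virologic_failure(vl, long_art, index, th),
      oracle_recent_vf(vl, art_days, index, th))
  }
})

test_that("repeated switches require two adjacent failing regimens", {
  reg3 <- build_regimens(rbind(
    ep_row("P1", c("AZT", "3TC", "EFV"), "2010-01-01", "2011-01-01"),
    ep_row("P1", c("TDF", "FTC", "ATV", "RTV"), "2011-01-01", "2012-01-01"),
    ep_row("P1", c("ABC", "3TC", "DTG"), "2012-01-01")))
  fail2 <- vl_row("P1", c("2010-11-01", "2011-09-01"), c(120, 80))
  expect_true(classify_multi_switch_failure(reg3, fail2, th))
  # second failure years before the switch: not within six months
  slow <- vl_row("P1", c("2010-11-01", "2011-02-01"), c(120, 80))
  expect_false(classify_multi_switch_failure(reg3, slow, th))
  # non-consecutive failing regimens
  reg4 <- build_regimens(rbind(
    ep_row("P1", c("AZT", "3TC", "EFV"), "2010-01-01", "2011-01-01"),
    ep_row("P1", c("TDF", "FTC", "ATV", "RTV"), "2011-01-01", "2015-01-01"),
    ep_row("P1", c("ABC", "3TC", "DTG"), "2015-01-01", "2016-01-01"),
    ep_row("P1", c("BIC", "TAF", "FTC"), "2016-01-01")))
  skipfail <- vl_row("P1", c("2010-11-01", "2015-10-01"), c(300, 300))
  expect_false(classify_multi_switch_failure(reg4, skipfail, th))
  # qualifying pattern entirely before 2008 is ignored
  pre <- build_regimens(rbind(
    ep_row("P1", c("AZT", "3TC", "EFV"), "2004-01-01", "2005-01-01"),
    ep_row("P1", c("AZT", "3TC", "LPV", "RTV"), "2005-01-01", "2006-01-01"),
    ep_row("P1", c("ABC", "3TC", "DTG"), "2006-01-01")))
  prevl <- vl_row("P1", c("2004-11-01", "2005-11-01"), c(500, 400))
  expect_false(classify_multi_switch_failure(pre, prevl, th))
})

test_that("repeated switches agree with a brute-force oracle on random histories", {
  set.seed(51)
  for (i in 1:300) {
    reg <- random_regimen_history(index)
    vl <- random_vl_history(index)
    vl$date <- as.Date(index) - sample.int(6000, nrow(vl))
    expect_identical(classify_multi_switch_failure(reg, vl, th),
                     oracle_multi_switch(reg, vl, th))
  }
})

test_that("adding evidence never withdraws a resistance or failure flag", {
  set.seed(61)
  pool <- cat33$drug_code[!cat33$is_booster]
  long_art <- build_regimens(ep_row("P1", c("DTG", "3TC", "TDF"),
                                    "2010-01-01"))
  for (i in 1:50) {
    k <- sample(1:4, 1)
    res <- data.table::data.table(
      person_id = "P1", test_date = as.Date("2016-01-01"),
      drug_code = sample(pool, k),
      level = sample(c("low", "intermediate", "high"), k, replace = TRUE))
    before <- classify_advanced_resistance(res, cat33)
    extra <- data.table::data.table(
      person_id = "P1", test_date = as.Date("2018-01-01"),
      drug_code = sample(pool, 1),
      level = sample(c("susceptible", "low", "intermediate", "high"), 1))
    after <- classify_advanced_resistance(rbind(res, extra), cat33)
    if (before) expect_true(after)

    vl <- random_vl_history(index)
    b2 <- classify_recent_virologic_failure(vl, long_art, index, th)
    vl2 <- rbind(vl, vl_row("P1", index - sample.int(360, 1),
                            round(exp(runif(1, log(10), log(1e4))))))
    a2 <- classify_recent_virologic_failure(vl2, long_art, index, th)
    if (b2) expect_true(a2)
  }
})

test_that("cohort classification is consistent, deterministic and guarded", {
  sim <- generate_cohort(scenario_config(n_persons = 150, seed = 3))
  fl1 <- classify_cohort(sim$registry, index)
  fl2 <- classify_cohort(sim$registry, index)
  expect_identical(fl1, fl2)
  # difficult is exactly the union of the five flags
  expect_equal(fl1$difficult,
               Reduce(`|`, lapply(flag_cols, function(cc) fl1[[cc]])))
  # empty cohort gives an empty table
  empty <- generate_cohort(scenario_config(n_persons = 0, seed = 1))
  expect_equal(nrow(classify_cohort(empty$registry, index)), 0L)
  # duplicate ids are rejected
  dup <- sim$registry
  dup$persons <- rbind(dup$persons, dup$persons[1, ])
  expect_error(classify_cohort(dup, index), "duplicate")
  # single-person entry point agrees with the cohort path
  one <- classify_person(sim$registry, sim$registry$persons$person_id[1],
                         index)
  expect_equal(unlist(one[, flag_cols, with = FALSE]),
               unlist(fl1[1, flag_cols, with = FALSE]))
})
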