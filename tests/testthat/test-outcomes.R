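index <- as.Date("2023-04-06")

test_that("suppression uses the last available measurement below 50 copies", {
  ep <- ep_row("P1", c("DTG", "3TC"), "2015-01-01")
  below <- vl_row("P1", c(index - 300, index - 60), c(400, 20),
                  below = c(FALSE, TRUE))
  r <- suppression_outcome(below, ep, index)
  expect_true(r$eligible)
  expect_true(r$suppressed)
  high <- vl_row("P1", c(index - 300, index - 60), c(20, 320),
                 below = c(TRUE, FALSE))
  expect_false(suppression_outcome(high, ep, index)$suppressed)
  # a "<400" result cannot confirm suppression below 50
  coarse <- vl_row("P1", index - 60, 400, below = TRUE)
  expect_false(suppression_outcome(coarse, ep, index)$suppressed)
})

test_that("recent ART starters are excluded and stale series are missing", {
  starter <- ep_row("P1", c("BIC", "TAF", "FTC"), index - 90)
  r <- suppression_outcome(vl_row("P1", index - 30, 20, TRUE), starter, index)
  expect_false(r$eligible)
  # last measurement older than 12 months: assessed as missing
  ep <- ep_row("P1", c("DTG", "3TC"), "2015-01-01")
  stale <- vl_row("P1", index - 500, 20, TRUE)
  r2 <- suppression_outcome(stale, ep, index)
  expect_true(r2$eligible)
  expect_true(is.na(r2$suppressed))
})

test_that("satisfaction dichotomizes at 5 on the 1-6 scale", {
  expect_equal(dichotomize_satisfaction(c(4, 5, 6, NA)),
               c(FALSE, TRUE, TRUE, NA))
  expect_error(dichotomize_satisfaction(7), "1-6")
})

test_that("outcome derivation respects windows and per-item missingness", {
  qn <- data.table::data.table(
    person_id = "P1", date = index - 100, physical_health = 5L,
    psychological_health = NA_integer_, missed_doses_last_week = 1L)
  reg <- mini_registry(episodes = ep_row("P1", c("DTG", "3TC"), "2015-01-01"),
                       viral_loads = vl_row("P1", index - 60, 20, TRUE),
                       questionnaires = qn)
  oc <- derive_outcomes(reg, index)
  expect_true(oc$eligible_pro)
  expect_true(oc$physical_satisfied)
  expect_true(is.na(oc$psychological_satisfied))
  expect_equal(oc$adherence_band, "1-2")
  # questionnaire older than 24 months is out of window
  qn_old <- data.table::copy(qn)[, date := index - 800]
  oc2 <- derive_outcomes(mini_registry(
    episodes = ep_row("P1", c("DTG", "3TC"), "2015-01-01"),
    viral_loads = vl_row("P1", index - 60, 20, TRUE),
    questionnaires = qn_old), index)
  expect_false(oc2$eligible_pro)
  expect_true(is.na(oc2$physical_satisfied))
})

test_that("sensitivity analysis removes the recent-failure category", {
  sim <- generate_cohort(scenario_config(n_persons = 1200, seed = 23))
  fl <- classify_cohort(sim$registry, index)
  oc <- derive_outcomes(sim$registry, index)
  sens <- sensitivity_excluding_recent_vf(fl, oc)
  expect_equal(sens$n_analyzed +
                 sum(fl$recent_virologic_failure &
                       oc$eligible_suppression & !is.na(oc$suppressed)),
               sum(oc$eligible_suppression & !is.na(oc$suppressed)))
  # no recent-failure members: identical to the main comparison
  fl0 <- data.table::copy(fl)[, recent_virologic_failure := FALSE]
  fl0[, difficult := advanced_resistance | four_drug_regimen |
        salvage_therapy | multi_switch_failure]
  sens0 <- sensitivity_excluding_recent_vf(fl0, oc)
  assessed <- oc$eligible_suppression & !is.na(oc$suppressed)
  expect_equal(sens0$counts[["a"]],
               sum(fl0$difficult & assessed & oc$suppressed %in% TRUE))
  # degenerate when every difficult person is a recent-failure member
  fl1 <- data.table::copy(fl)
  fl1[, c(flag_cols) := FALSE]
  fl1[1:5, recent_virologic_failure := TRUE]
  fl1[, difficult := recent_virologic_failure]
  expect_true(sensitivity_excluding_recent_vf(fl1, oc)$degenerate)
})

test_that("registry io round-trips and validates its inputs", {
  sim <- generate_cohort(scenario_config(n_persons = 80, seed = 29))
  dir <- tempfile()
  write_registry(sim$registry, dir)
  back <- read_registry(dir)
  for (tab in c("persons", "episodes", "viral_loads", "resistance",
                "questionnaires"))
    expect_equal(as.data.frame(back[[tab]]),
                 as.data.frame(sim$registry[[tab]]))
  # missing file is a hard, named error
  file.remove(file.path(dir, "viral_loads.csv"))
  expect_error(read_registry(dir), "viral_loads.csv")
  # referential integrity: episode for an unknown person
  bad <- data.table::copy(sim$registry)
  bad$episodes$person_id[1] <- "GHOST"
  expect_error(hiv_registry(bad$persons, bad$episodes, bad$viral_loads,
                            bad$resistance, bad$questionnaires), "GHOST")
  # Likert range violation
  bad2 <- data.table::copy(sim$registry)
  if (nrow(bad2$questionnaires)) {
    bad2$questionnaires$physical_health[1] <- 9L
    expect_error(hiv_registry(bad2$persons, bad2$episodes, bad2$viral_loads,
                              bad2$resistance, bad2$questionnaires), "Likert")
  }
})
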