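#' Scenario configuration for the synthetic registry generator
#'
#' Defaults mirror the marginal structure of the Swedish national HIV
#' cohort in 2023 that the package's rules were designed for: cohort size
#' 8531, the five category prevalences (about 2.2%, 0.6%, 1.7%, 0.7% and
#' 6.1%, union about 9.4%), resistance-testing coverage 67%, questionnaire
#' coverage 48%, and suppression probabilities 95% (non-difficult) versus
#' the value implied by a suppression odds ratio of 0.29 (about 84.6%).
#' Category overlap is induced by pairwise enrichment factors
#' (`P(A | B) = enrichment * P(A)`, with the complement-conditional solved
#' so the marginal is preserved): most recent-failure cases also have
#' repeated switches, and salvage therapy is concentrated among people
#' with advanced resistance.
#'
#' @param n_persons Cohort size.
#' @param index_date Data-extraction date at which everyone is classified.
#' @param prevalence Named vector of the five target category prevalences.
#' @param enrichment Named list of pairwise enrichment factors
#'   (`rvf_given_msf`, `ar_given_msf`, `st_given_ar`, `fdr_given_ar`).
#' @param p_suppressed_nondifficult Suppression probability among
#'   non-difficult persons.
#' @param suppression_or True crude odds ratio of suppression for
#'   difficult vs non-difficult; fixes the difficult-group probability.
#' @param p_physical,p_psychological Named vectors
#'   (`difficult`, `nondifficult`) of satisfaction probabilities.
#' @param questionnaire_coverage Fraction with a questionnaire within the
#'   24-month window.
#' @param resistance_coverage Fraction of the cohort with at least one
#'   resistance test (plants for advanced resistance are always tested).
#' @param vl_interval_days Length-2 vector: uniform range of days between
#'   routine viral-load measurements.
#' @param recent_art_frac Fraction of otherwise unremarkable persons whose
#'   first ART start falls within 6 months of the index date (excluded
#'   from outcome analyses).
#' @param missing_vl_frac Fraction (of persons not planted as recent
#'   virologic failure) with no viral load in the last 12 months.
#' @param seed Mandatory integer seed.
#' @return A validated list of class `scenario_config`.
#' @export
scenario_config <- function(n_persons = 8531L,
                            index_date = as.Date("2023-04-06"),
                            prevalence = c(advanced_resistance = 188 / 8531,
                                           four_drug_regimen = 51 / 8531,
                                           salvage_therapy = 141 / 8531,
                                           recent_virologic_failure = 59 / 8531,
                                           multi_switch_failure = 519 / 8531),
                            enrichment = list(rvf_given_msf = 11.5,
                                              ar_given_msf = 4,
                                              st_given_ar = 14.5,
                                              fdr_given_ar = 3),
                            p_suppressed_nondifficult = 0.95,
                            suppression_or = 0.29,
                            p_physical = c(difficult = 0.55,
                                           nondifficult = 0.63),
                            p_psychological = c(difficult = 0.64,
                                                nondifficult = 0.66),
                            questionnaire_coverage = 0.48,
                            resistance_coverage = 0.67,
                            vl_interval_days = c(120, 360),
                            recent_art_frac = 0.022,
                            missing_vl_frac = 0.03,
                            seed) {
  if (missing(seed) || is.null(seed)) stop("scenario_config: seed is mandatory")
  need <- c("advanced_resistance", "four_drug_regimen", "salvage_therapy",
            "recent_virologic_failure", "multi_switch_failure")
  if (!all(need %in% names(prevalence)))
    stop("prevalence must name all five categories")
  prevalence <- prevalence[need]
  fr <- c(prevalence, questionnaire_coverage, resistance_coverage,
          p_suppressed_nondifficult, p_physical, p_psychological,
          recent_art_frac, missing_vl_frac)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  cfg <- list(
    n_persons = as.integer(n_persons),
    index_date = as.Date(index_date),
    prevalence = prevalence,
    enrichment = enrichment,
    p_suppressed_nondifficult = p_suppressed_nondifficult,
    suppression_or = suppression_or,
    p_physical = p_physical, p_psychological = p_psychological,
    questionnaire_coverage = questionnaire_coverage,
    resistance_coverage = resistance_coverage,
    vl_interval_days = vl_interval_days,
    recent_art_frac = recent_art_frac,
    missing_vl_frac = missing_vl_frac,
    seed = as.integer(seed)
  )
  ## feasibility of the overlap structure is checked here so an
  ## impossible configuration fails before any sampling
  sample_category_flags(0L, cfg)
  structure(cfg, class = "scenario_config")
}

## conditional probability pair (P(A|B), P(A|!B)) preserving marginal pA
cond_pair <- function(pA, pB, enrich, what) {
  if (pA == 0) return(c(0, 0))
  pAB <- enrich * pA
  if (pAB > 1) pAB <- 1
  rest <- pA - pB * pAB
  if (rest < 0)
    stop("infeasible overlap: enrichment for ", what,
         " exceeds the marginal prevalence")
  c(pAB, if (pB < 1) rest / (1 - pB) else 0)
}

## draw the five planted category flags for n persons
sample_category_flags <- function(n, cfg) {
  p <- cfg$prevalence; e <- cfg$enrichment
  p_rvf <- cond_pair(p[["recent_virologic_failure"]],
                     p[["multi_switch_failure"]], e$rvf_given_msf,
                     "recent_virologic_failure | multi_switch_failure")
  p_ar <- cond_pair(p[["advanced_resistance"]],
                    p[["multi_switch_failure"]], e$ar_given_msf,
                    "advanced_resistance | multi_switch_failure")
  p_st <- cond_pair(p[["salvage_therapy"]], p[["advanced_resistance"]],
                    e$st_given_ar, "salvage_therapy | advanced_resistance")
  p_fdr <- cond_pair(p[["four_drug_regimen"]], p[["advanced_resistance"]],
                     e$fdr_given_ar, "four_drug_regimen | advanced_resistance")
  if (n == 0)
    return(data.table::data.table(advanced_resistance = logical(0),
                                  four_drug_regimen = logical(0),
                                  salvage_therapy = logical(0),
                                  recent_virologic_failure = logical(0),
                                  multi_switch_failure = logical(0)))
  msf <- stats::runif(n) < p[["multi_switch_failure"]]
  rvf <- stats::runif(n) < ifelse(msf, p_rvf[1], p_rvf[2])
  ar <- stats::runif(n) < ifelse(msf, p_ar[1], p_ar[2])
  st <- stats::runif(n) < ifelse(ar, p_st[1], p_st[2])
  fdr <- stats::runif(n) < ifelse(ar, p_fdr[1], p_fdr[2])
  data.table::data.table(advanced_resistance = ar, four_drug_regimen = fdr,
                         salvage_therapy = st,
                         recent_virologic_failure = rvf,
                         multi_switch_failure = msf)
}

## regimen templates (drug sets only; all QD unless marked)
historic_templates <- list(
  c("AZT", "3TC"), c("AZT", "DDI"),
  c("AZT", "3TC", "EFV"), c("D4T", "3TC", "NVP"), c("AZT", "3TC", "IDV"),
  c("TDF", "FTC", "EFV"), c("AZT", "3TC", "LPV", "RTV"),
  c("TDF", "FTC", "ATV", "RTV"), c("TDF", "FTC", "DRV", "RTV"),
  c("ABC", "3TC", "EFV"), c("TDF", "FTC", "RAL"), c("ABC", "3TC", "DTG")
)
current_templates <- list(
  c("BIC", "TAF", "FTC"), c("ABC", "3TC", "DTG"), c("DTG", "3TC"),
  c("TAF", "FTC", "RPV"), c("TDF", "FTC", "DOR"),
  c("TAF", "FTC", "DRV", "COBI"), c("TDF", "FTC", "EFV")
)

same_set <- function(a, b) length(a) == length(b) && all(sort(a) == sort(b))

pick_template <- function(pool, avoid = NULL) {
  for (i in 1:20) {
    tmpl <- pool[[sample.int(length(pool), 1L)]]
    if (is.null(avoid) || !same_set(tmpl, avoid)) return(tmpl)
  }
  tmpl
}

## current-regimen drug set + per-drug dosing, chosen to satisfy exactly
## the planted salvage / four-drug flags
current_for_flags <- function(st, fdr) {
  if (st && fdr) {
    drugs <- c("DRV", "RTV", "DTG", "TDF", "FTC")
    dosing <- c("BID", "QD", "QD", "QD", "QD")
  } else if (st) {
    kind <- sample(c("drv_bid", "etr", "dtg_bid"), 1L,
                   prob = c(0.55, 0.28, 0.17))
    if (kind == "drv_bid") {
      drugs <- c("DRV", "RTV", "TDF", "FTC")
      dosing <- c("BID", "QD", "QD", "QD")
    } else if (kind == "etr") {
      drugs <- c("ETR", "DTG", "TDF")
      dosing <- c("BID", "QD", "QD")
    } else {
      drugs <- c("DTG", "3TC")
      dosing <- c("BID", "QD")
    }
  } else if (fdr) {
    drugs <- c("DTG", "TDF", "FTC", "DOR")
    dosing <- rep("QD", 4)
  } else {
    drugs <- pick_template(current_templates)
    dosing <- rep("QD", length(drugs))
  }
  list(drugs = drugs, dosing = dosing)
}

#' Generate a synthetic registry with planted ground-truth labels
#'
#' Builds, for every person, a longitudinal history that *provably*
#' satisfies exactly the planted category flags under the classifier's
#' documented conventions — plants are constructed, not rejection-sampled.
#' Recent-failure plants receive two viral loads >= 200 copies/mL placed
#' 95-180 days apart inside the final year on >= 5 years of ART;
#' switch-after-failure plants receive 2-3 consecutive failing regimens
#' (failing measurement followed by a switch within at most 150 days)
#' after 2008; non-plants violate each rule by an explicit margin (all
#' routine measurements below the limit, spacing below 90 days, levels
#' below intermediate, counts below thresholds, failures dated before
#' 2008). Outcomes, demographics and missingness (questionnaire
#' non-response, untested persons, people without a recent viral load,
#' recent ART starters) are drawn from the configured probabilities.
#'
#' @param config A [scenario_config()].
#' @return List with `registry` (an [hiv_registry()]) and `labels`, the
#'   planted per-person flags and intended outcomes. `labels` is written
#'   for validation only and must never feed the classifier.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  n <- config$n_persons
  index <- as.numeric(config$index_date)
  num2008 <- as.numeric(as.Date("2008-01-01"))
  ids <- sprintf("P%06d", seq_len(n))

  flags <- sample_category_flags(n, config)
  ar <- flags$advanced_resistance; fdr <- flags$four_drug_regimen
  st <- flags$salvage_therapy; rvf <- flags$recent_virologic_failure
  msf <- flags$multi_switch_failure
  difficult <- ar | fdr | st | rvf | msf

  ## outcome intentions
  odds_nd <- config$p_suppressed_nondifficult /
    (1 - config$p_suppressed_nondifficult)
  p_supp_diff <- config$suppression_or * odds_nd /
    (1 + config$suppression_or * odds_nd)
  suppressed <- stats::runif(n) <
    ifelse(difficult, p_supp_diff, config$p_suppressed_nondifficult)
  recent_art <- !difficult & stats::runif(n) < config$recent_art_frac
  missing_vl <- !rvf & !recent_art & stats::runif(n) < config$missing_vl_frac
  suppressed[recent_art | missing_vl] <- NA

  ## near-miss assignments (exercise rule margins without firing them)
  nm_pair <- !rvf & !recent_art & !missing_vl & !is.na(suppressed) &
    suppressed & stats::runif(n) < 0.03
  nm_single <- !msf & !recent_art & !nm_pair & stats::runif(n) < 0.08
  nm_pre2008 <- !msf & !recent_art & stats::runif(n) < 0.05

  ## demographics, conditioned on difficult-to-treat status
  p_w <- ifelse(difficult, 0.45, 0.39)
  sex <- ifelse(stats::runif(n) < p_w, "woman", "man")
  sex[!difficult & stats::runif(n) < 0.003] <- NA
  age <- round(ifelse(difficult, stats::rnorm(n, 53.5, 11),
                      stats::rnorm(n, 51, 11.5)))
  age <- pmin(pmax(age, 18), 88)
  birth <- index - round(age * 365.25) - sample.int(360, n, replace = TRUE)
  rg_lv <- c("heterosexual", "MSM", "IDU", "other")
  risk <- character(n)
  risk[difficult] <- sample(rg_lv, sum(difficult), replace = TRUE,
                            prob = c(0.54, 0.285, 0.04, 0.135))
  risk[!difficult] <- sample(rg_lv, sum(!difficult), replace = TRUE,
                             prob = c(0.51, 0.325, 0.04, 0.125))
  risk[stats::runif(n) < ifelse(difficult, 0.004, 0.016)] <- NA
  born_swe <- stats::runif(n) < ifelse(difficult, 0.31, 0.33)
  born_swe[stats::runif(n) < 0.011] <- NA
  first_cd4 <- round(exp(stats::rnorm(n, log(ifelse(difficult, 295, 370)),
                                      0.75)))
  first_cd4 <- pmin(pmax(first_cd4, 1), 2000)
  nadir <- round(first_cd4 * stats::runif(n, ifelse(difficult, 0.2, 0.35),
                                          ifelse(difficult, 0.7, 0.95)))
  first_vl <- round(stats::rnorm(n, ifelse(difficult, 4.7, 4.4),
                                 ifelse(difficult, 0.85, 0.9)), 1)
  first_vl <- pmin(pmax(first_vl, 1.3), 7)

  ## ART start year by group, pulled earlier when the plants need room
  art_year <- round(ifelse(difficult, stats::rnorm(n, 2004, 8),
                           stats::rnorm(n, 2010, 7.5)))
  art_year <- pmin(pmax(art_year, 1987), 2022)
  art_year[rvf] <- pmin(art_year[rvf], 2016)
  art_year[msf] <- pmin(art_year[msf], 2011)
  art_start <- as.numeric(as.Date(sprintf("%d-01-01", art_year))) +
    sample.int(360, n, replace = TRUE)
  art_start <- pmin(art_start, index - 400)
  art_start[fdr] <- pmin(art_start[fdr], index - 900)
  art_start[rvf] <- pmin(art_start[rvf], index - 2200)
  art_start[msf] <- pmin(art_start[msf], index - 4200)
  art_start[recent_art] <- index - round(stats::runif(sum(recent_art),
                                                      30, 182))
  diag_date <- art_start - round(stats::runif(n, 30, 700))
  birth <- pmin(birth, diag_date - 16 * 365)
  diag_year <- as.integer(format(as.Date(diag_date,
                                         origin = "1970-01-01"), "%Y"))
  diag_year[stats::runif(n) < ifelse(difficult, 0.005, 0.017)] <- NA

  ep_l <- vector("list", n); vl_l <- vector("list", n)
  rs_l <- vector("list", n); qn_l <- vector("list", n)

  ## resistance testing coverage, plants always tested
  p_ar_marg <- config$prevalence[["advanced_resistance"]]
  p_test_rest <- if (p_ar_marg < 1 &&
                     config$resistance_coverage > p_ar_marg)
    (config$resistance_coverage - p_ar_marg) / (1 - p_ar_marg) else 0
  tested <- ar | stats::runif(n) < p_test_rest

  vmin <- config$vl_interval_days[1]; vmax <- config$vl_interval_days[2]

  for (i in seq_len(n)) {
    h <- build_person_history(
      art_start = art_start[i], index = index, num2008 = num2008,
      fdr = fdr[i], st = st[i], rvf = rvf[i], msf = msf[i],
      recent_art = recent_art[i], nm_pair = nm_pair[i],
      nm_single = nm_single[i], nm_pre2008 = nm_pre2008[i],
      suppressed = suppressed[i], missing_vl = missing_vl[i],
      vmin = vmin, vmax = vmax)
    m <- length(h$ep_drug)
    ep_l[[i]] <- list(person_id = rep(ids[i], m), drug_code = h$ep_drug,
                      start_date = h$ep_start, end_date = h$ep_end,
                      dosing = h$ep_dosing)
    k <- length(h$vl_date)
    vl_l[[i]] <- list(person_id = rep(ids[i], k), date = h$vl_date,
                      value_copies_per_ml = h$vl_value,
                      below_limit = h$vl_below)
    if (tested[i]) {
      r <- make_resistance(ar[i], art_start[i], index)
      rs_l[[i]] <- list(person_id = rep(ids[i], length(r$drug)),
                        test_date = r$date, drug_code = r$drug,
                        level = r$level)
    }
    if (stats::runif(1) < config$questionnaire_coverage) {
      qd <- index - round(stats::runif(1, 0, 728))
      p_ph <- if (difficult[i]) config$p_physical[["difficult"]] else
        config$p_physical[["nondifficult"]]
      p_ps <- if (difficult[i]) config$p_psychological[["difficult"]] else
        config$p_psychological[["nondifficult"]]
      ph_sat <- stats::runif(1) < p_ph
      ps_sat <- stats::runif(1) < p_ps
      ph <- if (ph_sat) sample(5:6, 1) else sample(1:4, 1)
      ps <- if (stats::runif(1) < 0.0015) NA_integer_ else
        if (ps_sat) sample(5:6, 1) else sample(1:4, 1)
      pr_miss <- if (difficult[i]) c(0.82, 0.14, 0.04) else
        c(0.88, 0.105, 0.015)
      band <- sample(1:3, 1, prob = pr_miss)
      missed <- c(0L, sample(1:2, 1), sample(3:7, 1))[band]
      if (stats::runif(1) < 0.01) missed <- NA_integer_
      qn_l[[i]] <- list(person_id = ids[i], date = qd,
                        physical_health = ph,
                        psychological_health = if (is.na(ps)) NA_integer_
                          else as.integer(ps),
                        missed_doses_last_week = missed,
                        ph_sat = ph_sat,
                        ps_sat = if (is.na(ps)) NA else ps_sat)
    }
  }

  bind <- function(lst, cols, date_cols) {
    lst <- lst[!vapply(lst, is.null, NA)]
    dt <- if (length(lst)) data.table::rbindlist(lst) else
      data.table::as.data.table(
        stats::setNames(rep(list(logical(0)), length(cols)), cols))
    for (col in intersect(cols, names(dt)))
      if (col %in% date_cols && nrow(dt))
        data.table::set(dt, j = col,
                        value = as.Date(dt[[col]], origin = "1970-01-01"))
    if (!nrow(dt))
      dt <- data.table::as.data.table(stats::setNames(
        c(list(character(0)),
          rep(list(numeric(0)), length(cols) - 1L)), cols))
    dt
  }
  episodes <- bind(ep_l, registry_schemas$episodes, c("start_date", "end_date"))
  viral_loads <- bind(vl_l, registry_schemas$viral_loads, "date")
  if (nrow(viral_loads))
    viral_loads[, below_limit := as.logical(below_limit)]
  resistance <- bind(rs_l, registry_schemas$resistance, "test_date")
  if (nrow(resistance))
    resistance[, test_date := as.Date(test_date, origin = "1970-01-01")]
  qn_full <- bind(qn_l, c(registry_schemas$questionnaires, "ph_sat", "ps_sat"),
                  "date")
  questionnaires <- if (nrow(qn_full))
    qn_full[, registry_schemas$questionnaires, with = FALSE] else
      data.table::as.data.table(stats::setNames(
        list(character(0), as.Date(character(0)), integer(0), integer(0),
             integer(0)), registry_schemas$questionnaires))

  persons <- data.table::data.table(
    person_id = ids, sex_at_birth = sex,
    birth_date = as.Date(birth, origin = "1970-01-01"),
    first_positive_test_year = diag_year, risk_group = risk,
    born_in_sweden = born_swe, first_cd4 = first_cd4, nadir_cd4 = nadir,
    first_vl_log10 = first_vl)

  labels <- data.table::data.table(
    person_id = ids, advanced_resistance = ar, four_drug_regimen = fdr,
    salvage_therapy = st, recent_virologic_failure = rvf,
    multi_switch_failure = msf, difficult = difficult,
    suppressed = suppressed,
    physical_satisfied = NA, psychological_satisfied = NA)
  if (nrow(qn_full)) {
    rows <- match(qn_full$person_id, ids)
    labels$physical_satisfied[rows] <- qn_full$ph_sat
    labels$psychological_satisfied[rows] <- qn_full$ps_sat
  }

  list(registry = hiv_registry(persons, episodes, viral_loads, resistance,
                               questionnaires),
       labels = labels)
}
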