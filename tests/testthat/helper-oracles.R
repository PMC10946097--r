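# Independent brute-force oracles and tiny random-history generators used
# by the property tests. These deliberately avoid the package's interval
# arithmetic: everything is a literal day-by-day or all-pairs scan.

# day-by-day scan: regimens as maximal runs of constant non-empty drug sets
day_sweep_regimens <- function(episodes, horizon) {
  s <- as.numeric(episodes$start_date)
  e <- ifelse(is.na(episodes$end_date), horizon + 1,
              as.numeric(episodes$end_date))
  days <- seq(min(s), horizon)
  key <- vapply(days, function(d)
    paste(sort(unique(as.character(
      episodes$drug_code[s <= d & e > d]))), collapse = "|"), "")
  out <- list()
  run_start <- 1L
  for (i in seq_along(days)) {
    if (i == length(days) || key[i + 1] != key[i]) {
      if (key[run_start] != "")
        out[[length(out) + 1L]] <- list(
          start = days[run_start], end = days[i] + 1,
          drugs = strsplit(key[run_start], "|", fixed = TRUE)[[1]])
      run_start <- i + 1L
    }
  }
  out
}

# all-pairs scan for the recent-failure viral-load condition
oracle_recent_vf <- function(vl, art_days, index_date,
                             th = dtt_thresholds()) {
  if (art_days < th$min_art_days) return(FALSE)
  if (nrow(vl) < 2) return(FALSE)
  quant <- is.na(vl$below_limit) | !vl$below_limit
  ok <- quant & vl$value_copies_per_ml >= th$vf_recent_threshold &
    vl$date > as.Date(index_date) - th$recent_window_days &
    vl$date <= as.Date(index_date)
  d <- as.numeric(vl$date[ok])
  if (length(d) < 2) return(FALSE)
  for (i in seq_along(d)) for (j in seq_along(d))
    if (i != j && abs(d[i] - d[j]) >= th$min_days_apart) return(TRUE)
  FALSE
}

# literal scan over every adjacent regimen pair and every measurement
oracle_multi_switch <- function(regimens, vl, th = dtt_thresholds()) {
  n <- nrow(regimens)
  if (n < 2 || nrow(vl) == 0) return(FALSE)
  s <- as.numeric(regimens$start_date)
  e <- ifelse(is.na(regimens$end_date), Inf, as.numeric(regimens$end_date))
  failing <- function(i) {
    if (i >= n) return(FALSE)   # no next regimen, no switch
    for (j in seq_len(nrow(vl))) {
      quant <- is.na(vl$below_limit[j]) || !vl$below_limit[j]
      if (quant && vl$value_copies_per_ml[j] >= th$vf_switch_threshold &&
          vl$date[j] >= th$switch_rule_since &&
          as.numeric(vl$date[j]) >= s[i] && as.numeric(vl$date[j]) < e[i] &&
          s[i + 1] - as.numeric(vl$date[j]) <= th$switch_within_days)
        return(TRUE)
    }
    FALSE
  }
  for (i in seq_len(n - 1))
    if (failing(i) && failing(i + 1)) return(TRUE)
  FALSE
}

# exhaustive check of the advanced-resistance rule from a per-drug map
oracle_advanced_resistance <- function(res, catalog) {
  if (nrow(res) == 0) return(FALSE)
  lev <- c(susceptible = 1, low = 2, intermediate = 3, high = 4)
  drugs <- unique(res$drug_code)
  best <- vapply(drugs, function(d)
    max(lev[res$level[res$drug_code == d]]), 0)
  hit <- drugs[best >= 3]
  if (length(hit) < 2) return(FALSE)
  cls <- catalog$drug_class[match(hit, catalog$drug_code)]
  for (i in seq_along(hit)) for (j in seq_along(hit))
    if (i < j && cls[i] != cls[j]) return(TRUE)
  FALSE
}

# exact two-sided permutation p-value for the Mann-Whitney U statistic
exact_mw_p <- function(a, b) {
  pooled <- c(a, b)
  nA <- length(a); N <- length(pooled)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - nA * (nA + 1) / 2
  u_obs <- u_of(seq_len(nA))
  mu <- nA * (N - nA) / 2
  combos <- utils::combn(N, nA)
  us <- apply(combos, 2, u_of)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# small random histories for the oracle-equivalence properties
random_vl_history <- function(index_date, n_max = 8) {
  n <- sample.int(n_max, 1)
  data.table::data.table(
    person_id = "X",
    date = as.Date(index_date) - sample.int(700, n),
    value_copies_per_ml = round(exp(runif(n, log(10), log(5e4)))),
    below_limit = runif(n) < 0.3)
}

random_regimen_history <- function(index_date, n_max = 5) {
  k <- sample.int(n_max, 1)
  index <- as.numeric(as.Date(index_date))
  starts <- sort(index - sample(100:6000, k))
  ends <- c(starts[-1] - sample(c(0, 0, 30, 90), k - 1, replace = TRUE),
            if (runif(1) < 0.7) NA else index - sample.int(90, 1))
  ends[!is.na(ends) & ends <= starts] <- starts[!is.na(ends) &
                                                  ends <= starts] + 1
  data.table::data.table(
    start_date = as.Date(starts, origin = "1970-01-01"),
    end_date = as.Date(ends, origin = "1970-01-01"),
    drugs = replicate(k, c("DTG", "3TC"), simplify = FALSE))
}

# minimal single-person registry around explicit sub-tables
mini_registry <- function(episodes = NULL, viral_loads = NULL,
                          resistance = NULL, questionnaires = NULL,
                          id = "P1") {
  blank_ep <- data.table::data.table(
    person_id = character(0), drug_code = character(0),
    start_date = as.Date(character(0)), end_date = as.Date(character(0)),
    dosing = character(0))
  blank_vl <- data.table::data.table(
    person_id = character(0), date = as.Date(character(0)),
    value_copies_per_ml = numeric(0), below_limit = logical(0))
  blank_rs <- data.table::data.table(
    person_id = character(0), test_date = as.Date(character(0)),
    drug_code = character(0), level = character(0))
  blank_qn <- data.table::data.table(
    person_id = character(0), date = as.Date(character(0)),
    physical_health = integer(0), psychological_health = integer(0),
    missed_doses_last_week = integer(0))
  persons <- data.table::data.table(
    person_id = id, sex_at_birth = "man",
    birth_date = as.Date("1970-06-15"), first_positive_test_year = 2005L,
    risk_group = "heterosexual", born_in_sweden = TRUE, first_cd4 = 350,
    nadir_cd4 = 200, first_vl_log10 = 4.5)
  hiv_registry(persons,
               if (is.null(episodes)) blank_ep else episodes,
               if (is.null(viral_loads)) blank_vl else viral_loads,
               if (is.null(resistance)) blank_rs else resistance,
               if (is.null(questionnaires)) blank_qn else questionnaires)
}

ep_row <- function(id, drug, start, end = NA, dosing = "QD") {
  data.table::data.table(person_id = id, drug_code = drug,
                         start_date = as.Date(start),
                         end_date = as.Date(end), dosing = dosing)
}

vl_row <- function(id, date, value, below = FALSE) {
  data.table::data.table(person_id = id, date = as.Date(date),
                         value_copies_per_ml = value, below_limit = below)
}

flag_cols <- c("advanced_resistance", "four_drug_regimen",
               "salvage_therapy", "recent_virologic_failure",
               "multi_switch_failure")
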