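#' Category rules for difficult-to-treat HIV
#'
#' Five overlapping categories, evaluated per person at an index
#' date (normally the data-extraction date). A person is classified as
#' having difficult-to-treat HIV when at least one rule fires:
#'
#' * **Advanced resistance** — intermediate or high-level interpreted
#'   resistance to at least 2 antiretrovirals spanning at least 2 drug
#'   classes, cumulative over all tests ever recorded.
#' * **Four-drug regimen** — currently on a regimen of >= 4 non-booster
#'   drugs, having been on a 2- or 3-drug regimen in the past.
#' * **Salvage therapy** — current regimen contains ibalizumab,
#'   fostemsavir, enfuvirtide, maraviroc, or etravirine; or twice-daily
#'   dolutegravir; or twice-daily darunavir together with a booster.
#' * **Recent virologic failure** — two viral loads >= 200 copies/mL at
#'   least 3 months apart within the past 12 months, in a person with >= 5
#'   years of cumulative ART exposure.
#' * **>= 2 switches following failure** — at least two consecutive
#'   regimens each "failed": a viral load >= 50 copies/mL measured on the
#'   regimen on or after 2008-01-01, with the next regimen starting within
#'   6 months of that measurement.
#'
#' All day-unit cutoffs come from [dtt_thresholds()].
#'
#' @name category_rules
NULL

salvage_marker_drugs <- c("IBA", "FTR", "ENF", "MVC", "ETR")

level_rank <- function(level) match(level, resistance_levels)

#' @describeIn category_rules Advanced resistance from cumulative per-drug
#'   interpreted resistance levels.
#' @param resistance One person's resistance results (`drug_code`, `level`,
#'   `test_date`).
#' @param catalog A drug catalog, see [default_drug_catalog()].
#' @return Each rule returns a single logical.
#' @export
classify_advanced_resistance <- function(resistance, catalog) {
  if (is.null(resistance) || nrow(resistance) == 0) return(FALSE)
  rk <- level_rank(resistance$level)
  if (anyNA(rk))
    stop("invalid resistance level(s): ",
         paste(unique(resistance$level[is.na(rk)]), collapse = ", "))
  best <- tapply(rk, resistance$drug_code, max)
  hit <- names(best)[best >= level_rank("intermediate")]
  if (length(hit) < 2) return(FALSE)
  cls <- catalog_lookup(hit, catalog, "drug_class")
  length(unique(cls)) >= 2
}

#' @describeIn category_rules Currently on >= 4 non-booster drugs after a
#'   past 2- or 3-drug regimen.
#' @param regimens One person's regimens from [build_regimens()].
#' @param index_date Classification date.
#' @param thresholds A [dtt_thresholds()] list.
#' @export
classify_four_drug_regimen <- function(regimens, index_date, catalog,
                                       thresholds = dtt_thresholds()) {
  cur <- current_regimen(regimens, index_date)
  if (is.null(cur)) return(FALSE)
  if (nonbooster_count(cur$drugs[[1]], catalog) < thresholds$four_dr_min)
    return(FALSE)
  past <- regimens[regimens$start_date < cur$start_date, ]
  if (nrow(past) == 0) return(FALSE)
  counts <- vapply(past$drugs, nonbooster_count, 0L, catalog = catalog)
  any(counts %in% c(2L, 3L))
}

#' @describeIn category_rules Current regimen contains a salvage agent or
#'   intensified (BID) dolutegravir / boosted darunavir. Dosing `UNKNOWN`
#'   counts as not BID.
#' @param episodes One person's raw episodes (needed for per-drug dosing).
#' @export
classify_salvage_therapy <- function(episodes, index_date, catalog) {
  act <- active_episodes_at(episodes, index_date)
  if (is.null(act) || nrow(act) == 0) return(FALSE)
  if (any(act$drug_code %in% salvage_marker_drugs)) return(TRUE)
  bid <- !is.na(act$dosing) & act$dosing == "BID"
  if (any(act$drug_code == "DTG" & bid)) return(TRUE)
  if (any(act$drug_code == "DRV" & bid)) {
    boosted <- any(catalog_lookup(unique(act$drug_code), catalog,
                                  "is_booster"))
    if (boosted) return(TRUE)
  }
  FALSE
}

#' @describeIn category_rules Two high viral loads >= 3 months apart in the
#'   last 12 months on long-standing ART.
#' @param viral_loads One person's viral loads.
#' @export
classify_recent_virologic_failure <- function(viral_loads, regimens,
                                              index_date,
                                              thresholds = dtt_thresholds()) {
  index_date <- as.Date(index_date)
  th <- thresholds
  if (art_duration_days(regimens, index_date) < th$min_art_days) return(FALSE)
  vl <- viral_loads
  if (is.null(vl) || nrow(vl) == 0) return(FALSE)
  quant <- is.na(vl$below_limit) | !vl$below_limit
  hi <- quant & vl$value_copies_per_ml >= th$vf_recent_threshold &
    vl$date > index_date - th$recent_window_days & vl$date <= index_date
  d <- vl$date[hi]
  length(d) >= 2 &&
    as.numeric(max(d) - min(d)) >= th$min_days_apart
}

#' @describeIn category_rules At least two consecutive regimens failed and
#'   were switched within 6 months of the failing measurement, since 2008.
#' @export
classify_multi_switch_failure <- function(regimens, viral_loads,
                                          thresholds = dtt_thresholds()) {
  if (is.null(regimens) || nrow(regimens) < 2) return(FALSE)
  th <- thresholds
  vl <- viral_loads
  if (is.null(vl) || nrow(vl) == 0) return(FALSE)
  quant <- is.na(vl$below_limit) | !vl$below_limit
  q <- quant & vl$value_copies_per_ml >= th$vf_switch_threshold &
    vl$date >= th$switch_rule_since
  d <- as.numeric(vl$date[q])
  if (length(d) < 2) return(FALSE)
  s <- as.numeric(regimens$start_date)
  e <- ifelse(is.na(regimens$end_date), Inf, as.numeric(regimens$end_date))
  n <- nrow(regimens)
  ## only regimens with a successor can fail (the switch is part of the
  ## definition), so the last regimen is never a failing one
  fails <- vapply(seq_len(n - 1L), function(i) {
    inside <- d >= s[i] & d < e[i]
    any(inside & s[i + 1L] - d <= th$switch_within_days)
  }, NA)
  length(fails) >= 2 && any(fails[-length(fails)] & fails[-1L])
}

#' Classify one person at an index date
#'
#' Applies all five category rules (see [category_rules]) and derives the
#' overall difficult-to-treat flag as their union.
#'
#' @param registry An [hiv_registry()].
#' @param person_id Identifier present in `registry$persons`.
#' @param index_date Classification date.
#' @param catalog A drug catalog.
#' @param thresholds A [dtt_thresholds()] list.
#' @return One-row `data.table` with `person_id`, the five category flags,
#'   `difficult`, and audit columns (`art_days`, `n_regimens`,
#'   `current_nonbooster`).
#' @export
classify_person <- function(registry, person_id, index_date,
                            catalog = default_drug_catalog(),
                            thresholds = dtt_thresholds()) {
  if (!person_id %in% registry$persons$person_id)
    stop("unknown person_id: ", person_id)
  pv <- person_view(registry, person_id)
  classify_one(person_id, pv$episodes, pv$viral_loads, pv$resistance,
               as.Date(index_date), catalog, thresholds)
}

classify_one <- function(id, episodes, viral_loads, resistance, index_date,
                         catalog, thresholds) {
  regimens <- build_regimens(episodes, thresholds$gap_tolerance_days)
  ar <- classify_advanced_resistance(resistance, catalog)
  fdr <- classify_four_drug_regimen(regimens, index_date, catalog, thresholds)
  st <- classify_salvage_therapy(episodes, index_date, catalog)
  rvf <- classify_recent_virologic_failure(viral_loads, regimens, index_date,
                                           thresholds)
  msf <- classify_multi_switch_failure(regimens, viral_loads, thresholds)
  cur <- current_regimen(regimens, index_date)
  data.table::data.table(
    person_id = id,
    advanced_resistance = ar,
    four_drug_regimen = fdr,
    salvage_therapy = st,
    recent_virologic_failure = rvf,
    multi_switch_failure = msf,
    difficult = ar || fdr || st || rvf || msf,
    art_days = art_duration_days(regimens, index_date),
    n_regimens = nrow(regimens),
    current_nonbooster = if (is.null(cur)) 0L else
      nonbooster_count(cur$drugs[[1]], catalog)
  )
}

#' Classify every person in a registry
#'
#' Vectorized application of the five category rules to a whole cohort.
#' The resistance and recent-failure rules are evaluated table-wide; the
#' regimen-based rules are evaluated per person on that person's episode
#' history.
#'
#' @inheritParams classify_person
#' @return A `data.table` with one row per person (same order as
#'   `registry$persons`): the five category flags, `difficult`, and audit
#'   columns. Deterministic: identical inputs give identical output.
#' @export
classify_cohort <- function(registry, index_date,
                            catalog = default_drug_catalog(),
                            thresholds = dtt_thresholds()) {
  stopifnot(inherits(registry, "hiv_registry"))
  index_date <- as.Date(index_date)
  th <- thresholds
  ids <- registry$persons$person_id
  if (anyDuplicated(ids)) stop("duplicate person_id in persons table")
  n <- length(ids)
  flags <- data.table::data.table(
    person_id = ids,
    advanced_resistance = logical(n), four_drug_regimen = logical(n),
    salvage_therapy = logical(n), recent_virologic_failure = logical(n),
    multi_switch_failure = logical(n), difficult = logical(n),
    art_days = integer(n), n_regimens = integer(n),
    current_nonbooster = integer(n)
  )
  if (n == 0) return(flags)

  ## advanced resistance: table-wide
  rs <- registry$resistance
  if (nrow(rs)) {
    rk <- data.table::data.table(person_id = rs$person_id,
                                 drug_code = rs$drug_code,
                                 lvl = level_rank(rs$level))
    best <- rk[, list(lvl = max(lvl)), by = c("person_id", "drug_code")]
    best <- best[best$lvl >= level_rank("intermediate"), ]
    if (nrow(best)) {
      best[, drug_class := catalog_lookup(drug_code, catalog, "drug_class")]
      ar_ids <- best[, list(
        ok = length(unique(drug_code)) >= 2 &&
          length(unique(drug_class)) >= 2), by = "person_id"]
      flags[match(ar_ids$person_id[ar_ids$ok], ids),
            advanced_resistance := TRUE]
    }
  }

  ## recent virologic failure, viral-load condition: table-wide
  vl <- registry$viral_loads
  rvf_vl_ok <- character(0)
  if (nrow(vl)) {
    quant <- is.na(vl$below_limit) | !vl$below_limit
    hi <- vl[quant & vl$value_copies_per_ml >= th$vf_recent_threshold &
               vl$date > index_date - th$recent_window_days &
               vl$date <= index_date, ]
    if (nrow(hi)) {
      ok <- hi[, list(ok = .N >= 2 &&
                        as.numeric(max(date) - min(date)) >=
                          th$min_days_apart), by = "person_id"]
      rvf_vl_ok <- ok$person_id[ok$ok]
    }
  }

  ## qualifying measurements for the switch rule, grouped per person
  ## (positional: element i belongs to ids[i])
  pid_levels <- as.character(ids)
  q_dates <- rep(list(NULL), n)
  if (nrow(vl)) {
    quant <- is.na(vl$below_limit) | !vl$below_limit
    q <- vl[quant & vl$value_copies_per_ml >= th$vf_switch_threshold &
              vl$date >= th$switch_rule_since, ]
    if (nrow(q)) {
      qs <- split(as.numeric(q$date),
                  factor(as.character(q$person_id), levels = pid_levels))
      q_dates[lengths(qs) > 0] <- qs[lengths(qs) > 0]
    }
  }

  ep <- registry$episodes
  ep_idx <- rep(list(NULL), n)
  ed <- character(0); es <- numeric(0); ee <- numeric(0); edos <- character(0)
  if (nrow(ep)) {
    if (anyNA(ep$start_date))
      stop("rejected episode record: missing start_date")
    ed <- as.character(ep$drug_code)
    es <- as.numeric(ep$start_date)
    ee <- ifelse(is.na(ep$end_date), Inf, as.numeric(ep$end_date))
    if (any(ee < es))
      stop("rejected episode record: end_date before start_date")
    unknown <- setdiff(unique(ed), catalog$drug_code)
    if (length(unknown))
      stop("drug code(s) not in catalog: ", paste(unknown, collapse = ", "))
    eps <- split(seq_len(nrow(ep)),
                 factor(as.character(ep$person_id), levels = pid_levels))
    ep_idx[lengths(eps) > 0] <- eps[lengths(eps) > 0]
  }
  booster_codes <- catalog$drug_code[catalog$is_booster]
  index_num <- as.numeric(index_date)

  for (i in seq_len(n)) {
    idx <- ep_idx[[i]]
    if (is.null(idx)) {
      data.table::set(flags, i, c("art_days", "n_regimens",
                                  "current_nonbooster"),
                      list(0L, 0L, 0L))
      next
    }
    r <- regimens_core(ed[idx], es[idx], ee[idx], th$gap_tolerance_days)
    m <- length(r$s)
    art <- as.integer(sum(pmax(0, pmin(r$e, index_num) - r$s)))
    cur_j <- which(r$s <= index_num & r$e > index_num)
    nb <- vapply(r$sets, function(d) sum(!d %in% booster_codes), 0L)
    cur_nb <- if (length(cur_j)) nb[cur_j[1]] else 0L
    fdr <- length(cur_j) > 0 && cur_nb >= th$four_dr_min &&
      any(nb[r$s < r$s[cur_j[1]]] %in% c(2L, 3L))
    ## salvage: active episodes at the index date, with dosing
    act <- idx[es[idx] <= index_num & ee[idx] > index_num]
    st <- FALSE
    if (length(act)) {
      adrug <- ed[act]
      bid <- !is.na(ep$dosing[act]) & ep$dosing[act] == "BID"
      st <- any(adrug %in% salvage_marker_drugs) ||
        any(adrug == "DTG" & bid) ||
        (any(adrug == "DRV" & bid) && any(adrug %in% booster_codes))
    }
    msf <- FALSE
    d <- q_dates[[i]]
    if (!is.null(d) && length(d) >= 2 && m >= 3) {
      fails <- vapply(seq_len(m - 1L), function(k) {
        inside <- d >= r$s[k] & d < r$e[k]
        any(inside & r$s[k + 1L] - d <= th$switch_within_days)
      }, NA)
      msf <- any(fails[-length(fails)] & fails[-1L])
    }
    data.table::set(flags, i, c("four_drug_regimen", "salvage_therapy",
                                "multi_switch_failure", "art_days",
                                "n_regimens", "current_nonbooster"),
                    list(fdr, st, msf, art, m, cur_nb))
  }
  if (length(rvf_vl_ok)) {
    rows <- match(rvf_vl_ok, ids)
    rows <- rows[flags$art_days[rows] >= th$min_art_days]
    if (length(rows)) flags[rows, recent_virologic_failure := TRUE]
  }
  flags[, difficult := advanced_resistance | four_drug_regimen |
          salvage_therapy | recent_virologic_failure | multi_switch_failure]
  flags[]
}
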