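## Construction of one synthetic person's longitudinal history.
##
## The planted flags must hold *exactly* under the classifier's
## conventions, so every construction keeps an explicit safety margin:
##  - routine ("background") viral loads are below-limit results and can
##    never satisfy a failure rule;
##  - failing measurements for the switch rule sit >450 days before the
##    index date, outside the recent-failure window;
##  - near-miss constructions (spacing < 90 d, single failing regimen,
##    pre-2008 failures) are placed so no rule can fire by accident.
build_person_history <- function(art_start, index, num2008, fdr, st, rvf,
                                 msf, recent_art, nm_pair, nm_single,
                                 nm_pre2008, suppressed, missing_vl,
                                 vmin, vmax) {
  cur <- current_for_flags(st, fdr)

  if (recent_art) {
    ## newly started: one open regimen, baseline viraemia then first
    ## on-treatment measurement
    m <- length(cur$drugs)
    return(list(
      ep_drug = cur$drugs, ep_start = rep(art_start, m),
      ep_end = rep(NA_real_, m), ep_dosing = cur$dosing,
      vl_date = c(art_start - round(stats::runif(1, 5, 30)),
                  art_start + round(stats::runif(1, 25, 60))),
      vl_value = c(round(exp(stats::runif(1, log(5e3), log(5e5)))), 20),
      vl_below = c(FALSE, TRUE)))
  }

  last_allowed <- index - if (rvf || nm_pair) 420 else 60
  fail_date <- numeric(0); fail_value <- numeric(0)

  if (msf) {
    f <- sample(2:3, 1L)
    dur <- round(stats::runif(f, 200, 650))
    E <- index - round(stats::runif(1, 450, 1500))
    earliest <- max(art_start, num2008)
    B <- E - sum(dur)
    if (B < earliest) { B <- earliest; E <- B + sum(dur) }
    block_starts <- B + cumsum(c(0, dur[-f]))
    block_ends <- block_starts + dur
    ## pre-block filler regimens
    pre_starts <- numeric(0); pre_ends <- numeric(0)
    if (B - art_start > 500) {
      if (B - art_start > 1200 && stats::runif(1) < 0.5) {
        cut <- round(stats::runif(1, art_start + 200, B - 200))
        pre_starts <- c(art_start, cut); pre_ends <- c(cut, B)
      } else {
        pre_starts <- art_start; pre_ends <- B
      }
    } else {
      art_start <- B
    }
    ## post-block regimens; the first one is the switch target
    room <- last_allowed - E
    if (room > 400 && stats::runif(1) < 0.5) {
      c2 <- E + round(stats::runif(1, 150, room - 50))
      post_starts <- c(E, c2); post_ends <- c(c2, NA_real_)
    } else {
      post_starts <- E; post_ends <- NA_real_
    }
    starts <- c(pre_starts, block_starts, post_starts)
    ends <- c(pre_ends, block_ends, post_ends)
    ## failing measurement in each block regimen, switch within 150 d
    fail_date <- block_ends - round(stats::runif(f, 10, 150))
    fail_date <- pmax(fail_date, block_starts + 1)
    fail_value <- round(exp(stats::runif(f, log(60), log(5000))))
  } else {
    k <- sample.int(4L, 1L, prob = c(0.3, 0.35, 0.25, 0.1))
    if (fdr) k <- max(k, 2L)
    if (nm_pre2008 && art_start < num2008 - 1500) {
      c1 <- art_start + round(stats::runif(1, 250, 500))
      c2 <- c1 + round(stats::runif(1, 250, 500))
      k_rest <- max(k - 2L, 1L)
      bp <- if (k_rest > 1)
        sort(round(stats::runif(k_rest - 1L, c2 + 180, last_allowed)))
      else numeric(0)
      starts <- c(art_start, c1, c2, bp)
      ends <- c(c1, c2, bp, NA_real_)
      ## failed twice with prompt switches, entirely before 2008: the
      ## date condition must be the only reason the rule stays silent
      fail_date <- c(c1, c2) - round(stats::runif(2, 10, 150))
      fail_value <- round(exp(stats::runif(2, log(60), log(3000))))
    } else {
      nm_pre2008 <- FALSE
      if (art_start + 180 >= last_allowed) k <- 1L
      bp <- if (k > 1)
        sort(round(stats::runif(k - 1L, art_start + 180, last_allowed)))
      else numeric(0)
      bp <- unique(bp)
      starts <- c(art_start, bp)
      ends <- c(bp, NA_real_)
      ## occasional treatment gap (not for recent-failure plants, whose
      ## cumulative exposure must stay above the 5-year threshold)
      if (!rvf && length(starts) >= 2 && stats::runif(1) < 0.15) {
        j <- if (length(starts) == 2) 2L else
          sample(2:length(starts), 1L)
        lim <- (if (is.na(ends[j])) index - 60 else ends[j]) - starts[j] - 30
        if (lim > 30)
          starts[j] <- starts[j] + round(stats::runif(1, 30, min(lim, 400)))
      }
    }
    if (nm_single && !nm_pre2008 && length(starts) >= 2) {
      ## exactly one failing regimen, ending well before the recent
      ## window so the confirming pair can never arise
      cand <- which(!is.na(ends) & ends <= index - 380 &
                      ends - 160 >= pmax(starts, num2008) + 1)
      if (length(cand)) {
        j <- cand[sample.int(length(cand), 1L)]
        vd <- ends[j] - round(stats::runif(1, 10, 150))
        vd <- max(vd, max(starts[j], num2008) + 1)
        fail_date <- c(fail_date, vd)
        fail_value <- c(fail_value,
                        round(exp(stats::runif(1, log(60), log(3000)))))
      }
    }
  }

  ## drug sets, assigned backwards so adjacent regimens always differ
  nreg <- length(starts)
  sets <- vector("list", nreg); dosings <- vector("list", nreg)
  sets[[nreg]] <- cur$drugs; dosings[[nreg]] <- cur$dosing
  if (nreg > 1) {
    for (j in (nreg - 1L):1L) {
      tmpl <- pick_template(historic_templates, avoid = sets[[j + 1L]])
      sets[[j]] <- tmpl
      dosings[[j]] <- rep("QD", length(tmpl))
    }
  }

  ep_drug <- unlist(sets)
  ep_start <- rep(starts, lengths(sets))
  ep_end <- rep(ends, lengths(sets))
  ep_dosing <- unlist(dosings)

  ## background below-limit measurements
  bg_stop <- if (missing_vl) index - 400 else index - 220
  vl_date <- numeric(0)
  if (bg_stop > art_start + 60) {
    k_est <- ceiling((bg_stop - art_start) / vmin) + 1L
    gaps <- round(stats::runif(k_est, vmin, vmax))
    d <- art_start + 45 + cumsum(gaps)
    vl_date <- d[d < bg_stop]
  }
  vl_value <- rep(20, length(vl_date))
  vl_below <- rep(TRUE, length(vl_date))

  add <- function(dates, values, below) {
    vl_date <<- c(vl_date, dates)
    vl_value <<- c(vl_value, values)
    vl_below <<- c(vl_below, below)
  }
  if (length(fail_date))
    add(fail_date, fail_value, rep(FALSE, length(fail_date)))
  if (rvf) {
    d2 <- index - round(stats::runif(1, 95, 150))
    d1 <- d2 - round(stats::runif(1, 95, 180))
    add(c(d1, d2), round(exp(stats::runif(2, log(250), log(2e4)))),
        c(FALSE, FALSE))
    if (isTRUE(suppressed))
      add(index - round(stats::runif(1, 14, 80)), 20, TRUE)
  } else if (nm_pair) {
    ## two high measurements only 60 days apart: spacing is the only
    ## reason recent failure stays FALSE
    add(c(index - 300, index - 240),
        round(exp(stats::runif(2, log(250), log(2000)))), c(FALSE, FALSE))
    add(index - round(stats::runif(1, 14, 200)), 20, TRUE)
  } else if (!missing_vl) {
    fdate <- index - round(stats::runif(1, 14, 200))
    if (isTRUE(suppressed)) add(fdate, 20, TRUE)
    else add(fdate, round(exp(stats::runif(1, log(60), log(1e5)))), FALSE)
  }

  list(ep_drug = ep_drug, ep_start = ep_start, ep_end = ep_end,
       ep_dosing = ep_dosing, vl_date = vl_date, vl_value = vl_value,
       vl_below = vl_below)
}

resistance_pools <- list(
  NRTI = c("3TC", "FTC", "AZT", "ABC", "TDF"),
  NNRTI = c("EFV", "NVP", "RPV"),
  PI = c("LPV", "ATV", "DRV"),
  INSTI = c("RAL", "DTG")
)

## one resistance test; plants get >= 2 drugs at >= intermediate level in
## >= 2 classes, non-plants stay below the rule by construction
make_resistance <- function(is_ar, art_start, index) {
  hi <- index - 30
  lo <- min(art_start + 100, hi - 1)
  date <- round(stats::runif(1, lo, hi))
  if (is_ar) {
    ncls <- sample(2:3, 1L)
    cls <- sample(names(resistance_pools), ncls)
    drug <- vapply(cls, function(cl)
      sample(resistance_pools[[cl]], 1L), "")
    level <- sample(c("intermediate", "high"), ncls, replace = TRUE)
    extra <- setdiff(resistance_pools$NRTI, drug)
    nx <- sample(0:2, 1L)
    if (nx) {
      drug <- c(drug, sample(extra, nx))
      level <- c(level, sample(c("susceptible", "low"), nx, replace = TRUE))
    }
  } else {
    pat <- sample(c("clean", "lowlevel", "single_high", "same_class"), 1L,
                  prob = c(0.45, 0.25, 0.15, 0.15))
    if (pat == "clean") {
      drug <- sample(unlist(resistance_pools), sample(2:4, 1L))
      level <- rep("susceptible", length(drug))
    } else if (pat == "lowlevel") {
      drug <- sample(unlist(resistance_pools), sample(2:4, 1L))
      level <- sample(c("susceptible", "low"), length(drug), replace = TRUE)
    } else if (pat == "single_high") {
      drug <- c(sample(unlist(resistance_pools), 1L))
      level <- "high"
      more <- sample(setdiff(unlist(resistance_pools), drug), 2L)
      drug <- c(drug, more); level <- c(level, "susceptible", "low")
    } else {
      ## two high-level calls confined to one class
      drug <- c("3TC", "FTC")
      level <- c("high", "high")
      more <- sample(unlist(resistance_pools[c("PI", "INSTI")]), 1L)
      drug <- c(drug, more); level <- c(level, "susceptible")
    }
  }
  keep <- !duplicated(drug)
  list(date = rep(date, sum(keep)), drug = drug[keep], level = level[keep])
}

#' Hand-derived boundary histories for the category rules
#'
#' A fixed, deterministic set of persons sitting exactly on (or one unit
#' off) every decision boundary of the five rules: confirming viral loads
#' 90 vs 89 days apart and 200 vs 199 copies/mL, cumulative ART of 1826
#' vs 1825 days, switches 183 vs 184 days after the failing measurement,
#' failures before vs after 2008-01-01, four-drug counting with and
#' without a past 2-3-drug regimen, twice-daily dolutegravir/darunavir
#' with and without a booster, and a regimen ending exactly on the index
#' date (not current under the half-open convention). The expected flags
#' are derived by hand from the documented conventions.
#'
#' @param index_date Index date the cases are built around.
#' @return List with `registry` (an [hiv_registry()]) and `expected`, one
#'   row per person with the five expected category flags.
#' @export
generate_adversarial_histories <- function(index_date = as.Date("2023-04-06")) {
  index <- as.Date(index_date)
  ep <- list(); vl <- list(); rs <- list(); expect <- list()
  pid <- character(0)

  std_regimen <- function(id, drugs, start, end = NA, dosing = NULL) {
    if (is.null(dosing)) dosing <- rep("QD", length(drugs))
    list(person_id = rep(id, length(drugs)), drug_code = drugs,
         start_date = rep(as.numeric(as.Date(start)), length(drugs)),
         end_date = rep(if (is.na(end)) NA_real_ else
           as.numeric(as.Date(end)), length(drugs)),
         dosing = dosing)
  }
  add_case <- function(id, episodes, vls = NULL, res = NULL,
                       ar = FALSE, fdr = FALSE, st = FALSE, rvf = FALSE,
                       msf = FALSE) {
    pid <<- c(pid, id)
    ep[[id]] <<- data.table::rbindlist(episodes)
    if (!is.null(vls)) vl[[id]] <<- vls
    if (!is.null(res)) rs[[id]] <<- res
    expect[[id]] <<- data.table::data.table(
      person_id = id, advanced_resistance = ar, four_drug_regimen = fdr,
      salvage_therapy = st, recent_virologic_failure = rvf,
      multi_switch_failure = msf)
  }
  vls <- function(id, offsets, values, below = NULL) {
    if (is.null(below)) below <- rep(FALSE, length(values))
    list(person_id = rep(id, length(offsets)),
         date = as.numeric(index) - offsets,
         value_copies_per_ml = values, below_limit = below)
  }
  res_rows <- function(id, drugs, levels) {
    list(person_id = rep(id, length(drugs)),
         test_date = rep(as.numeric(index) - 400, length(drugs)),
         drug_code = drugs, level = levels)
  }
  long_art <- list(std_regimen("x", c("DTG", "3TC", "TDF"), "2015-01-01"))

  with_id <- function(id, reg) lapply(reg, function(r) {
    r$person_id <- rep(id, length(r$person_id)); r })

  ## recent virologic failure: spacing boundary 90 / 89 days
  add_case("ADV01", with_id("ADV01", long_art),
           vls("ADV01", c(210, 120), c(250, 300)), rvf = TRUE)
  add_case("ADV02", with_id("ADV02", long_art),
           vls("ADV02", c(209, 120), c(250, 300)), rvf = FALSE)
  ## value boundary 200 / 199 copies/mL
  add_case("ADV03", with_id("ADV03", long_art),
           vls("ADV03", c(220, 120), c(200, 200)), rvf = TRUE)
  add_case("ADV04", with_id("ADV04", long_art),
           vls("ADV04", c(220, 120), c(199, 199)), rvf = FALSE)
  ## cumulative ART boundary 1826 / 1825 days
  add_case("ADV05",
           list(std_regimen("ADV05", c("DTG", "3TC", "TDF"),
                            as.character(index - 1826))),
           vls("ADV05", c(220, 120), c(400, 400)), rvf = TRUE)
  add_case("ADV06",
           list(std_regimen("ADV06", c("DTG", "3TC", "TDF"),
                            as.character(index - 1825))),
           vls("ADV06", c(220, 120), c(400, 400)), rvf = FALSE)

  ## switches after failure: switch exactly 183 / 184 days after the VL
  msf_reg <- function(id) list(
    std_regimen(id, c("AZT", "3TC", "EFV"), "2010-01-01", "2011-01-01"),
    std_regimen(id, c("TDF", "FTC", "ATV", "RTV"), "2011-01-01",
                "2012-01-01"),
    std_regimen(id, c("ABC", "3TC", "DTG"), "2012-01-01"))
  d183 <- function(switch_day, lag)
    as.numeric(index) - (as.numeric(index) - as.numeric(as.Date(switch_day))) - lag
  msf_vl <- function(id, lag) list(
    person_id = rep(id, 2),
    date = c(as.numeric(as.Date("2011-01-01")) - lag,
             as.numeric(as.Date("2012-01-01")) - lag),
    value_copies_per_ml = c(120, 80), below_limit = c(FALSE, FALSE))
  add_case("ADV07", msf_reg("ADV07"), msf_vl("ADV07", 183), msf = TRUE)
  add_case("ADV08", msf_reg("ADV08"), msf_vl("ADV08", 184), msf = FALSE)
  ## identical pattern shifted entirely before 2008
  pre_reg <- function(id) list(
    std_regimen(id, c("AZT", "3TC", "EFV"), "2004-01-01", "2005-01-01"),
    std_regimen(id, c("AZT", "3TC", "LPV", "RTV"), "2005-01-01",
                "2006-01-01"),
    std_regimen(id, c("ABC", "3TC", "DTG"), "2006-01-01"))
  pre_vl <- function(id) list(
    person_id = rep(id, 2),
    date = c(as.numeric(as.Date("2004-11-01")),
             as.numeric(as.Date("2005-11-01"))),
    value_copies_per_ml = c(500, 400), below_limit = c(FALSE, FALSE))
  add_case("ADV09", pre_reg("ADV09"), pre_vl("ADV09"), msf = FALSE)

  ## four-drug counting
  add_case("ADV10", list(
    std_regimen("ADV10", c("AZT", "3TC", "EFV"), "2010-01-01", "2015-01-01"),
    std_regimen("ADV10", c("DRV", "RTV", "DTG", "TDF", "FTC"),
                "2015-01-01")), fdr = TRUE)
  add_case("ADV11", list(
    std_regimen("ADV11", c("DRV", "RTV", "DTG", "TDF", "FTC"),
                "2010-01-01")), fdr = FALSE)
  add_case("ADV12", list(
    std_regimen("ADV12", c("AZT", "3TC", "EFV"), "2010-01-01", "2015-01-01"),
    std_regimen("ADV12", c("ABC", "3TC", "DTG"), "2015-01-01")),
    fdr = FALSE)

  ## salvage: boosted darunavir BID with and without the booster
  add_case("ADV13", list(
    std_regimen("ADV13", c("DRV", "RTV", "TDF", "FTC"), "2018-01-01",
                dosing = c("BID", "QD", "QD", "QD"))), st = TRUE)
  add_case("ADV14", list(
    std_regimen("ADV14", c("DRV", "TDF", "FTC"), "2018-01-01",
                dosing = c("BID", "QD", "QD"))), st = FALSE)
  add_case("ADV15", list(
    std_regimen("ADV15", c("DTG", "3TC"), "2018-01-01",
                dosing = c("BID", "QD"))), st = TRUE)
  add_case("ADV16", list(
    std_regimen("ADV16", c("DTG", "3TC"), "2018-01-01",
                dosing = c("QD", "QD"))), st = FALSE)
  add_case("ADV17", list(
    std_regimen("ADV17", c("ETR", "DTG", "TDF"), "2018-01-01",
                dosing = c("BID", "QD", "QD"))), st = TRUE)

  ## advanced resistance: class span and level floor
  plain <- function(id) list(std_regimen(id, c("DTG", "3TC"), "2018-01-01"))
  add_case("ADV18", plain("ADV18"),
           res = res_rows("ADV18", c("EFV", "3TC"),
                          c("high", "intermediate")), ar = TRUE)
  add_case("ADV19", plain("ADV19"),
           res = res_rows("ADV19", c("3TC", "FTC"), c("high", "high")),
           ar = FALSE)
  add_case("ADV20", plain("ADV20"),
           res = res_rows("ADV20", c("EFV", "DRV"), c("low", "low")),
           ar = FALSE)

  ## half-open convention: regimen ending on the index date is not current
  add_case("ADV21", list(
    std_regimen("ADV21", c("DRV", "RTV", "DTG", "TDF", "FTC"), "2010-01-01",
                as.character(index))))

  mk <- function(lst) if (length(lst)) data.table::rbindlist(lst) else NULL
  episodes <- data.table::rbindlist(ep)
  episodes[, start_date := as.Date(start_date, origin = "1970-01-01")]
  episodes[, end_date := as.Date(end_date, origin = "1970-01-01")]
  viral <- mk(vl)
  if (is.null(viral))
    viral <- data.table::data.table(person_id = character(0),
                                    date = numeric(0),
                                    value_copies_per_ml = numeric(0),
                                    below_limit = logical(0))
  viral[, date := as.Date(date, origin = "1970-01-01")]
  resist <- mk(rs)
  if (is.null(resist))
    resist <- data.table::data.table(person_id = character(0),
                                     test_date = numeric(0),
                                     drug_code = character(0),
                                     level = character(0))
  resist[, test_date := as.Date(test_date, origin = "1970-01-01")]
  persons <- data.table::data.table(
    person_id = pid, sex_at_birth = "man",
    birth_date = as.Date("1970-06-15"),
    first_positive_test_year = 2005L, risk_group = "heterosexual",
    born_in_sweden = TRUE, first_cd4 = 350, nadir_cd4 = 200,
    first_vl_log10 = 4.5)
  questionnaires <- data.table::data.table(
    person_id = character(0), date = as.Date(character(0)),
    physical_health = integer(0), psychological_health = integer(0),
    missed_doses_last_week = integer(0))
  list(registry = hiv_registry(persons, episodes, viral, resist,
                               questionnaires),
       expected = data.table::rbindlist(expect))
}
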