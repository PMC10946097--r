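#' Dichotomize a 1-6 satisfaction Likert item
#'
#' Scores of 5 or 6 ("satisfied" / "very satisfied") count as satisfied,
#' matching how the register's health questionnaire has been analyzed
#' previously.
#'
#' @param likert Integer vector with values 1-6 (NA allowed).
#' @return Logical vector; NA stays NA.
#' @export
dichotomize_satisfaction <- function(likert) {
  bad <- !is.na(likert) & (likert < 1 | likert > 6)
  if (any(bad))
    stop("Likert value(s) outside 1-6: ",
         paste(unique(likert[bad]), collapse = ", "))
  ifelse(is.na(likert), NA, likert >= 5)
}

#' Viral-suppression outcome for one person
#'
#' A person is *ineligible* when their first-ever ART start lies within
#' `art_start_exclusion_days` before the index date ("starting ART
#' < 6 months ago"). Among eligible persons, suppression is assessed when
#' a viral load was recorded during the last 12 months and is defined on
#' the *last available* measurement: suppressed iff it is below 50
#' copies/mL (a "< limit" result counts when the assay limit is at most
#' 50).
#'
#' @param viral_loads One person's viral loads.
#' @param episodes One person's treatment episodes.
#' @param index_date Index date.
#' @param thresholds A [dtt_thresholds()] list.
#' @return List with `eligible` (logical) and `suppressed` (logical or NA
#'   when no recent measurement exists or the person is ineligible).
#' @export
suppression_outcome <- function(viral_loads, episodes, index_date,
                                thresholds = dtt_thresholds()) {
  index_date <- as.Date(index_date)
  th <- thresholds
  fs <- first_art_start(episodes)
  if (!is.na(fs) && fs > index_date - th$art_start_exclusion_days)
    return(list(eligible = FALSE, suppressed = NA))
  vl <- viral_loads
  if (!is.null(vl) && nrow(vl)) vl <- vl[vl$date <= index_date, ]
  if (is.null(vl) || nrow(vl) == 0 ||
      max(vl$date) <= index_date - th$recent_window_days)
    return(list(eligible = TRUE, suppressed = NA))
  last <- vl[which.max(as.numeric(vl$date)), ]
  supp <- vl_is_suppressed(last$value_copies_per_ml, last$below_limit,
                           th$suppression_threshold)
  list(eligible = TRUE, suppressed = supp)
}

vl_is_suppressed <- function(value, below_limit, threshold = 50) {
  below <- !is.na(below_limit) & below_limit
  ifelse(below, value <= threshold, value < threshold)
}

#' Derive the treatment-outcome table for a cohort
#'
#' Computes, per person: suppression eligibility and status (see
#' [suppression_outcome()]); whether a health questionnaire exists within
#' the patient-reported-outcome window (24 months); the dichotomized
#' physical and psychological satisfaction items from the most recent such
#' questionnaire (per-item missingness preserved); and the missed-doses
#' adherence band ("0", "1-2", ">=3").
#'
#' @param registry An [hiv_registry()].
#' @param index_date Index date.
#' @param thresholds A [dtt_thresholds()] list.
#' @return A `data.table` with one row per person: `person_id`,
#'   `eligible_suppression`, `suppressed`, `eligible_pro`,
#'   `physical_satisfied`, `psychological_satisfied`, `adherence_band`.
#' @export
derive_outcomes <- function(registry, index_date,
                            thresholds = dtt_thresholds()) {
  stopifnot(inherits(registry, "hiv_registry"))
  index_date <- as.Date(index_date)
  th <- thresholds
  ids <- registry$persons$person_id
  out <- data.table::data.table(
    person_id = ids,
    eligible_suppression = TRUE,
    suppressed = NA,
    eligible_pro = FALSE,
    physical_satisfied = NA,
    psychological_satisfied = NA,
    adherence_band = NA_character_
  )
  if (!length(ids)) return(out)

  ## eligibility: first ART start within the exclusion window
  ep <- registry$episodes
  if (nrow(ep)) {
    firsts <- ep[, list(fs = min(start_date)), by = "person_id"]
    recent <- firsts$person_id[firsts$fs >
                                 index_date - th$art_start_exclusion_days]
    if (length(recent))
      out[match(recent, ids), eligible_suppression := FALSE]
  }

  ## last available viral load, assessed when one exists in the window
  vl <- registry$viral_loads[registry$viral_loads$date <= index_date, ]
  if (nrow(vl)) {
    data.table::setorderv(vl, c("person_id", "date"))
    last <- vl[, utils::tail(.SD, 1L), by = "person_id"]
    last <- last[last$date > index_date - th$recent_window_days, ]
    if (nrow(last)) {
      rows <- match(last$person_id, ids)
      supp <- vl_is_suppressed(last$value_copies_per_ml, last$below_limit,
                               th$suppression_threshold)
      out[rows, suppressed := supp]
    }
  }
  out[!out$eligible_suppression, suppressed := NA]

  ## most recent questionnaire within the PRO window
  qn <- registry$questionnaires
  if (nrow(qn)) {
    qn <- qn[qn$date <= index_date & qn$date > index_date - th$pro_window_days, ]
    if (nrow(qn)) {
      data.table::setorderv(qn, c("person_id", "date"))
      lastq <- qn[, utils::tail(.SD, 1L), by = "person_id"]
      rows <- match(lastq$person_id, ids)
      out[rows, `:=`(
        eligible_pro = TRUE,
        physical_satisfied = dichotomize_satisfaction(lastq$physical_health),
        psychological_satisfied =
          dichotomize_satisfaction(lastq$psychological_health),
        adherence_band = adherence_band(lastq$missed_doses_last_week)
      )]
    }
  }
  out[]
}

adherence_band <- function(missed) {
  ifelse(is.na(missed), NA_character_,
         ifelse(missed == 0, "0", ifelse(missed <= 2, "1-2", ">=3")))
}

#' Suppression comparison excluding the recent-virologic-failure category
#'
#' People in the recent-virologic-failure category have, by construction,
#' incomplete suppression; this sensitivity analysis removes them from the
#' analysis entirely and recomputes the suppression comparison between the
#' remaining difficult and non-difficult groups.
#'
#' @param flags Classification table from [classify_cohort()].
#' @param outcomes Outcome table from [derive_outcomes()].
#' @return List with the 2x2 counts, per-group suppression rates, the
#'   chi-squared p-value and crude odds ratio (NULL when a cell is empty),
#'   and `degenerate = TRUE` when either comparison group is empty.
#' @export
sensitivity_excluding_recent_vf <- function(flags, outcomes) {
  keep <- flags$person_id[!flags$recent_virologic_failure]
  f <- flags[match(keep, flags$person_id), ]
  o <- outcomes[match(keep, outcomes$person_id), ]
  assessed <- o$eligible_suppression & !is.na(o$suppressed)
  diff <- f$difficult[assessed]; supp <- o$suppressed[assessed]
  a <- sum(diff & supp); b <- sum(diff & !supp)
  cc <- sum(!diff & supp); d <- sum(!diff & !supp)
  degenerate <- (a + b) == 0 || (cc + d) == 0
  res <- list(
    n_analyzed = length(diff),
    counts = c(a = a, b = b, c = cc, d = d),
    rate_difficult = if ((a + b) > 0) a / (a + b) else NA_real_,
    rate_nondifficult = if ((cc + d) > 0) cc / (cc + d) else NA_real_,
    p_value = NA_real_, odds_ratio = NULL,
    degenerate = degenerate
  )
  if (!degenerate && all(c(a + cc, b + d) > 0)) {
    res$p_value <- chi_squared(matrix(c(a, b, cc, d), nrow = 2,
                                      byrow = TRUE))$p_value
    if (all(c(a, b, cc, d) > 0))
      res$odds_ratio <- odds_ratio_2x2(a, b, cc, d,
                                       outcome = "viral_suppression")
  }
  res
}
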