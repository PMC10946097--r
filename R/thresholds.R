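#' Day-unit thresholds behind the category rules
#'
#' The category definitions are phrased in months and years ("at least
#' 3 months apart", "within the past 12 months", "on ART for >= 5 years",
#' "switch within 6 months"). For reproducibility the classifier works with
#' fixed day equivalents, all collected here and overridable for
#' sensitivity runs.
#'
#' @param min_days_apart Minimum spacing in days between the two confirming
#'   viral loads of recent virologic failure ("3 months"; default 90).
#' @param recent_window_days Look-back window for recent virologic failure
#'   ("12 months"; default 365).
#' @param min_art_days Minimum cumulative time on therapy for recent
#'   virologic failure ("5 years"; default 1826).
#' @param switch_within_days Maximum delay from a failing viral load to the
#'   start of the next regimen for a switch to count as failure-related
#'   ("6 months"; default 183).
#' @param vf_recent_threshold Viral-load threshold in copies/mL for recent
#'   virologic failure (default 200).
#' @param vf_switch_threshold Viral-load threshold in copies/mL for the
#'   switches-after-failure rule (default 50).
#' @param suppression_threshold Viral-load threshold in copies/mL below
#'   which the last measurement counts as suppressed (default 50).
#' @param switch_rule_since Failing measurements before this date are
#'   ignored by the switches-after-failure rule (default 2008-01-01, when
#'   the register reached national coverage).
#' @param four_dr_min Minimum number of non-booster drugs for a regimen to
#'   count as a four-drug regimen (default 4, counted as "at least").
#' @param art_start_exclusion_days Outcome analyses exclude people whose
#'   first ART start is within this many days of the index date
#'   ("starting ART < 6 months ago"; default 183).
#' @param pro_window_days Questionnaire look-back for the patient-reported
#'   outcomes ("the last 24 months"; default 730).
#' @param gap_tolerance_days Treatment gaps no longer than this merge
#'   adjacent identical regimens (default 0: any gap separates).
#'
#' @return A named list of class `dtt_thresholds`.
#' @examples
#' th <- dtt_thresholds()
#' th$min_art_days
#' @export
dtt_thresholds <- function(min_days_apart = 90L,
                           recent_window_days = 365L,
                           min_art_days = 1826L,
                           switch_within_days = 183L,
                           vf_recent_threshold = 200,
                           vf_switch_threshold = 50,
                           suppression_threshold = 50,
                           switch_rule_since = as.Date("2008-01-01"),
                           four_dr_min = 4L,
                           art_start_exclusion_days = 183L,
                           pro_window_days = 730L,
                           gap_tolerance_days = 0L) {
  th <- list(
    min_days_apart = as.integer(min_days_apart),
    recent_window_days = as.integer(recent_window_days),
    min_art_days = as.integer(min_art_days),
    switch_within_days = as.integer(switch_within_days),
    vf_recent_threshold = as.numeric(vf_recent_threshold),
    vf_switch_threshold = as.numeric(vf_switch_threshold),
    suppression_threshold = as.numeric(suppression_threshold),
    switch_rule_since = as.Date(switch_rule_since),
    four_dr_min = as.integer(four_dr_min),
    art_start_exclusion_days = as.integer(art_start_exclusion_days),
    pro_window_days = as.integer(pro_window_days),
    gap_tolerance_days = as.integer(gap_tolerance_days)
  )
  stopifnot(th$min_days_apart >= 0, th$recent_window_days > 0,
            th$min_art_days >= 0, th$switch_within_days >= 0,
            th$four_dr_min >= 1)
  structure(th, class = "dtt_thresholds")
}
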