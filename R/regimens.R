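#' Build regimens from per-drug treatment episodes
#'
#' The register records antiretroviral exposure one drug at a time. A
#' *regimen* is the derived object the category rules reason about: a
#' maximal calendar interval over which the set of simultaneously active
#' drugs is constant. Intervals are half-open `[start, end)`; days covered
#' by no drug are treatment gaps, not regimens. Overlapping duplicate
#' records for the same drug are merged with a warning; records whose end
#' precedes their start are rejected.
#'
#' @param episodes Data frame of one person's episodes (`drug_code`,
#'   `start_date`, `end_date`, with `NA` end = ongoing).
#' @param gap_tolerance_days Gaps of at most this many days between two
#'   intervals with the identical drug set are bridged into one regimen.
#'   The default 0 bridges only contiguous intervals.
#' @return A `data.table` with one row per regimen, chronologically ordered:
#'   `start_date`, `end_date` (`NA` = ongoing) and `drugs`, a list column of
#'   sorted drug-code vectors. Consecutive rows always differ in `drugs`
#'   unless separated by a gap longer than the tolerance.
#' @examples
#' ep <- data.frame(
#'   drug_code = c("TDF", "FTC", "DTG"),
#'   start_date = as.Date(c("2015-01-01", "2015-01-01", "2016-06-01")),
#'   end_date = as.Date(c(NA, NA, NA))
#' )
#' build_regimens(ep)
#' @export
build_regimens <- function(episodes, gap_tolerance_days = 0L) {
  empty <- data.table::data.table(start_date = as.Date(character()),
                                  end_date = as.Date(character()),
                                  drugs = list())
  if (is.null(episodes) || nrow(episodes) == 0) return(empty)
  if (anyNA(episodes$start_date))
    stop("rejected episode record: missing start_date")
  s <- as.numeric(episodes$start_date)
  e <- ifelse(is.na(episodes$end_date), Inf, as.numeric(episodes$end_date))
  if (any(e < s))
    stop("rejected episode record: end_date before start_date")
  r <- regimens_core(as.character(episodes$drug_code), s, e,
                     gap_tolerance_days)
  if (!length(r$s)) return(empty)
  data.table::data.table(
    start_date = as.Date(r$s, origin = "1970-01-01"),
    end_date = as.Date(ifelse(is.finite(r$e), r$e, NA),
                       origin = "1970-01-01"),
    drugs = r$sets
  )
}

## interval sweep on plain vectors (numeric days, Inf = ongoing); shared
## by build_regimens and the cohort classifier's per-person loop
regimens_core <- function(drug, s, e, gap_tolerance_days = 0L) {
  ## merge same-drug records that touch or overlap
  if (anyDuplicated(drug)) {
    ms <- numeric(0); me <- numeric(0); md <- character(0)
    overlapped <- FALSE
    for (d in unique(drug)) {
      i <- which(drug == d)
      o <- i[order(s[i], e[i])]
      cs <- s[o[1]]; ce <- e[o[1]]
      for (k in o[-1]) {
        if (s[k] <= ce) {                    # touching or overlapping
          if (s[k] < ce) overlapped <- TRUE
          ce <- max(ce, e[k])
        } else {
          ms <- c(ms, cs); me <- c(me, ce); md <- c(md, d)
          cs <- s[k]; ce <- e[k]
        }
      }
      ms <- c(ms, cs); me <- c(me, ce); md <- c(md, d)
    }
    if (overlapped)
      warning("overlapping duplicate episode(s) for the same drug were merged")
  } else {
    ms <- s; me <- e; md <- drug
  }

  ## sweep over breakpoints; each [bp_i, bp_i+1) has one active set
  bp <- sort(unique(c(ms, me[is.finite(me)])))
  n_iv <- if (any(is.infinite(me))) length(bp) else length(bp) - 1L
  iv_start <- bp[seq_len(n_iv)]
  iv_end <- c(bp[-1], Inf)[seq_len(n_iv)]
  sets <- lapply(seq_len(n_iv), function(i)
    sort(unique(md[ms <= iv_start[i] & me > iv_start[i]])))
  keep <- lengths(sets) > 0
  iv_start <- iv_start[keep]; iv_end <- iv_end[keep]; sets <- sets[keep]
  if (!length(iv_start)) return(list(s = numeric(0), e = numeric(0),
                                     sets = list()))

  ## merge adjacent identical sets separated by at most the gap tolerance
  keys <- vapply(sets, paste, "", collapse = "|")
  drop <- logical(length(iv_start))
  rk <- 1L
  for (i in seq_along(iv_start)[-1]) {
    if (keys[i] == keys[rk] && is.finite(iv_end[rk]) &&
        iv_start[i] - iv_end[rk] <= gap_tolerance_days) {
      iv_end[rk] <- iv_end[i]
      drop[i] <- TRUE
    } else rk <- i
  }
  list(s = iv_start[!drop], e = iv_end[!drop], sets = sets[!drop])
}

#' Regimen active on a given date
#'
#' Returns the regimen whose half-open interval `[start, end)` contains
#' `index_date`; a regimen ending exactly on the index date is therefore
#' not current.
#'
#' @param regimens Output of [build_regimens()].
#' @param index_date The date of interest (e.g. the data-extraction date).
#' @return A one-row `data.table`, or `NULL` when no regimen covers the
#'   date.
#' @export
current_regimen <- function(regimens, index_date) {
  if (is.null(regimens) || nrow(regimens) == 0) return(NULL)
  index_date <- as.Date(index_date)
  hit <- regimens$start_date <= index_date &
    (is.na(regimens$end_date) | regimens$end_date > index_date)
  if (!any(hit)) return(NULL)
  regimens[which(hit)[1], ]
}

#' Count the non-booster drugs of a regimen
#'
#' Pharmacokinetic boosters (ritonavir-as-booster, cobicistat) carry no
#' counted antiviral activity and are excluded from all drug counts.
#'
#' @param drugs Character vector of drug codes (a regimen's drug set), or a
#'   one-row regimen as returned by [current_regimen()].
#' @param catalog A drug catalog (see [default_drug_catalog()]).
#' @return Integer count of distinct non-booster drugs.
#' @examples
#' nonbooster_count(c("DRV", "RTV", "TDF", "FTC"), default_drug_catalog())
#' @export
nonbooster_count <- function(drugs, catalog) {
  if (is.data.frame(drugs)) drugs <- drugs$drugs[[1]]
  drugs <- unique(as.character(drugs))
  if (!length(drugs)) return(0L)
  sum(!catalog_lookup(drugs, catalog, "is_booster"))
}

#' Cumulative days on antiretroviral therapy
#'
#' Counts calendar days up to (and excluding) the index date on which at
#' least one regimen was active. Treatment gaps are excluded, so this is
#' exposure time, not time since first start.
#'
#' @inheritParams current_regimen
#' @return Integer number of days.
#' @export
art_duration_days <- function(regimens, index_date) {
  if (is.null(regimens) || nrow(regimens) == 0) return(0L)
  index <- as.numeric(as.Date(index_date))
  s <- as.numeric(regimens$start_date)
  e <- ifelse(is.na(regimens$end_date), index, as.numeric(regimens$end_date))
  e <- pmin(e, index)
  as.integer(sum(pmax(0, e - s)))
}

## episodes active on a date (half-open), with dosing — used by the
## salvage rule, which needs per-drug dosing flags
active_episodes_at <- function(episodes, index_date) {
  if (is.null(episodes) || nrow(episodes) == 0) return(episodes)
  index_date <- as.Date(index_date)
  act <- episodes$start_date <= index_date &
    (is.na(episodes$end_date) | episodes$end_date > index_date)
  episodes[act, ]
}

## first-ever ART start (NA when never treated)
first_art_start <- function(episodes) {
  if (is.null(episodes) || nrow(episodes) == 0) return(as.Date(NA))
  min(episodes$start_date)
}
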