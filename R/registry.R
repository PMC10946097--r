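#' Assemble and validate an HIV registry extract
#'
#' An `hiv_registry` bundles the five tables of a registry extract. All
#' tables are keyed by `person_id`; dates are `Date`s and episode intervals
#' are half-open `[start_date, end_date)` with `NA` end dates meaning the
#' exposure is ongoing at extraction.
#'
#' Table schemas:
#' \describe{
#'   \item{persons}{`person_id`, `sex_at_birth` ("man"/"woman"/NA),
#'     `birth_date`, `first_positive_test_year`, `risk_group`
#'     ("heterosexual"/"MSM"/"IDU"/"other"/NA), `born_in_sweden`,
#'     `first_cd4`, `nadir_cd4`, `first_vl_log10`.}
#'   \item{episodes}{`person_id`, `drug_code`, `start_date`, `end_date`
#'     (NA = ongoing), `dosing` ("QD"/"BID"/"OTHER"/"UNKNOWN").}
#'   \item{viral_loads}{`person_id`, `date`, `value_copies_per_ml`,
#'     `below_limit` (TRUE when the laboratory reported "< limit"; the
#'     value then holds the assay limit).}
#'   \item{resistance}{`person_id`, `test_date`, `drug_code`, `level`
#'     ("susceptible" < "low" < "intermediate" < "high").}
#'   \item{questionnaires}{`person_id`, `date`, `physical_health` (1-6 or
#'     NA), `psychological_health` (1-6 or NA), `missed_doses_last_week`.}
#' }
#'
#' @param persons,episodes,viral_loads,resistance,questionnaires Data
#'   frames following the schemas above. All but `persons` may be empty.
#' @return A list of five `data.table`s with class `hiv_registry`.
#' @seealso [read_registry()], [write_registry()], [generate_cohort()]
#' @export
hiv_registry <- function(persons, episodes, viral_loads, resistance,
                         questionnaires) {
  reg <- list(
    persons = data.table::as.data.table(persons),
    episodes = data.table::as.data.table(episodes),
    viral_loads = data.table::as.data.table(viral_loads),
    resistance = data.table::as.data.table(resistance),
    questionnaires = data.table::as.data.table(questionnaires)
  )
  validate_registry(reg)
}

registry_schemas <- list(
  persons = c("person_id", "sex_at_birth", "birth_date",
              "first_positive_test_year", "risk_group", "born_in_sweden",
              "first_cd4", "nadir_cd4", "first_vl_log10"),
  episodes = c("person_id", "drug_code", "start_date", "end_date", "dosing"),
  viral_loads = c("person_id", "date", "value_copies_per_ml", "below_limit"),
  resistance = c("person_id", "test_date", "drug_code", "level"),
  questionnaires = c("person_id", "date", "physical_health",
                     "psychological_health", "missed_doses_last_week")
)

resistance_levels <- c("susceptible", "low", "intermediate", "high")
dosing_levels <- c("QD", "BID", "OTHER", "UNKNOWN")

validate_registry <- function(reg) {
  for (tab in names(registry_schemas)) {
    miss <- setdiff(registry_schemas[[tab]], names(reg[[tab]]))
    if (length(miss))
      stop(sprintf("table '%s' is missing column(s): %s", tab,
                   paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(reg$persons$person_id))
    stop("duplicate person_id in persons table")
  for (tab in c("episodes", "viral_loads", "resistance", "questionnaires")) {
    orphan <- setdiff(reg[[tab]]$person_id, reg$persons$person_id)
    if (length(orphan))
      stop(sprintf("table '%s' references unknown person_id(s): %s", tab,
                   paste(utils::head(orphan, 5), collapse = ", ")))
  }
  ep <- reg$episodes
  if (nrow(ep)) {
    if (anyNA(ep$start_date)) stop("episode with missing start_date")
    bad <- !is.na(ep$end_date) & ep$end_date < ep$start_date
    if (any(bad))
      stop(sprintf("%d episode(s) with end_date before start_date", sum(bad)))
    bad_dose <- !ep$dosing %in% dosing_levels
    if (any(bad_dose))
      stop("invalid dosing value(s): ",
           paste(unique(ep$dosing[bad_dose]), collapse = ", "))
  }
  vl <- reg$viral_loads
  if (nrow(vl)) {
    if (anyNA(vl$date)) stop("viral load with missing date")
    if (any(vl$value_copies_per_ml < 0, na.rm = TRUE))
      stop("negative viral load value")
  }
  rs <- reg$resistance
  if (nrow(rs)) {
    bad <- !rs$level %in% resistance_levels
    if (any(bad))
      stop("invalid resistance level(s): ",
           paste(unique(rs$level[bad]), collapse = ", "))
    if (anyDuplicated(rs[, c("person_id", "test_date", "drug_code")]))
      stop("duplicate (person, test_date, drug) in resistance table")
  }
  qn <- reg$questionnaires
  if (nrow(qn)) {
    for (col in c("physical_health", "psychological_health")) {
      v <- qn[[col]]
      if (any(!is.na(v) & (v < 1 | v > 6)))
        stop(sprintf("%s outside the 1-6 Likert range", col))
    }
  }
  structure(reg, class = "hiv_registry")
}

#' @export
print.hiv_registry <- function(x, ...) {
  cat(sprintf(
    "<hiv_registry> %d persons | %d episodes | %d viral loads | %d resistance results | %d questionnaires\n",
    nrow(x$persons), nrow(x$episodes), nrow(x$viral_loads),
    nrow(x$resistance), nrow(x$questionnaires)))
  invisible(x)
}

registry_files <- c(persons = "persons.csv", episodes = "regimen_episodes.csv",
                    viral_loads = "viral_loads.csv",
                    resistance = "resistance.csv",
                    questionnaires = "questionnaires.csv")

#' Read a registry extract from a directory of CSV files
#'
#' Expects `persons.csv`, `regimen_episodes.csv`, `viral_loads.csv`,
#' `resistance.csv` and `questionnaires.csv` (UTF-8, header row, ISO-8601
#' dates). Validates schemas and cross-table referential integrity.
#'
#' @param dir Directory containing the five CSV files.
#' @return An [hiv_registry()] object.
#' @export
read_registry <- function(dir) {
  paths <- file.path(dir, registry_files)
  missing <- !file.exists(paths)
  if (any(missing))
    stop("missing registry file(s): ",
         paste(registry_files[missing], collapse = ", "))
  names(paths) <- names(registry_files)
  rd <- function(p) data.table::fread(p, na.strings = c("", "NA"))
  tabs <- lapply(paths, rd)
  for (col in c("birth_date")) set_date(tabs$persons, col)
  for (col in c("start_date", "end_date")) set_date(tabs$episodes, col)
  set_date(tabs$viral_loads, "date")
  set_date(tabs$resistance, "test_date")
  set_date(tabs$questionnaires, "date")
  if (nrow(tabs$viral_loads))
    tabs$viral_loads[, below_limit := as.logical(below_limit)]
  hiv_registry(tabs$persons, tabs$episodes, tabs$viral_loads,
               tabs$resistance, tabs$questionnaires)
}

set_date <- function(dt, col) {
  if (nrow(dt) == 0) {
    data.table::set(dt, j = col, value = as.Date(character()))
    return(invisible(dt))
  }
  v <- dt[[col]]
  if (inherits(v, "IDate")) {
    data.table::set(dt, j = col,
                    value = as.Date(as.numeric(v), origin = "1970-01-01"))
    return(invisible(dt))
  }
  if (inherits(v, "Date")) return(invisible(dt))
  out <- as.Date(as.character(v), format = "%Y-%m-%d")
  bad <- !is.na(v) & is.na(out)
  if (any(bad))
    stop(sprintf("column '%s' has %d unparseable date(s), e.g. '%s'",
                 col, sum(bad), as.character(v[bad][1])))
  data.table::set(dt, j = col, value = out)
  invisible(dt)
}

#' Write a registry extract to a directory of CSV files
#'
#' Inverse of [read_registry()]; writes the five tables with ISO-8601 dates.
#'
#' @param registry An [hiv_registry()] object.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_registry <- function(registry, dir) {
  stopifnot(inherits(registry, "hiv_registry"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tab in names(registry_files))
    data.table::fwrite(registry[[tab]], file.path(dir, registry_files[[tab]]))
  invisible(dir)
}

## subset all tables of a registry to one person (internal)
person_view <- function(registry, id) {
  lapply(registry[c("episodes", "viral_loads", "resistance",
                    "questionnaires")],
         function(dt) dt[dt$person_id == id, ])
}
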