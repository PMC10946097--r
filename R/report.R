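category_cols <- c(AR = "advanced_resistance", `4DR` = "four_drug_regimen",
                   ST = "salvage_therapy", VF12mo = "recent_virologic_failure",
                   VFswitch = "multi_switch_failure")

#' Counts of all category intersections (Venn cells)
#'
#' Tabulates, among people classified as difficult-to-treat, all 31
#' non-empty subsets of the five categories. Cells below `min_cell` are
#' flagged for display suppression (small-cell anonymity) but their counts
#' are retained in the returned table; the cells always partition the
#' difficult group, so their counts sum to the number of difficult
#' persons.
#'
#' @param flags Classification table from [classify_cohort()].
#' @param min_cell Display threshold; cells with fewer persons get
#'   `display = FALSE`.
#' @return A `data.table` with one row per subset: `subset_id` (e.g.
#'   `"AR+ST"`), the five membership indicator columns, `count`,
#'   `display`.
#' @export
venn_counts <- function(flags, min_cell = 10L) {
  grid <- do.call(data.table::CJ,
                  stats::setNames(rep(list(c(FALSE, TRUE)), 5),
                                  names(category_cols)))
  grid <- grid[rowSums(grid) > 0, ]
  key_of <- function(m) apply(m, 1L, function(r)
    paste(names(category_cols)[as.logical(r)], collapse = "+"))
  grid_key <- key_of(grid)
  diff_rows <- flags[flags$difficult, category_cols, with = FALSE]
  counts <- integer(nrow(grid))
  if (nrow(diff_rows)) {
    obs <- table(key_of(as.matrix(diff_rows)))
    counts <- as.integer(ifelse(grid_key %in% names(obs),
                                obs[grid_key], 0L))
  }
  out <- data.table::data.table(subset_id = grid_key)
  out <- cbind(out, grid)
  out[, `:=`(count = counts, display = counts >= min_cell)]
  data.table::setorderv(out, "count", order = -1L)
  out[]
}

group_membership <- function(flags) {
  c(list(non_difficult = !flags$difficult, difficult = flags$difficult),
    stats::setNames(lapply(category_cols, function(col) flags[[col]]),
                    names(category_cols)))
}

#' Baseline characteristics by difficult-to-treat status
#'
#' Summarizes demographics and laboratory firsts for the non-difficult
#' group, the difficult group overall, and each of the five categories:
#' median (IQR) for continuous variables, n (%) for categorical ones,
#' with explicit missing counts. The p-value compares difficult against
#' non-difficult (Mann-Whitney for continuous, Pearson chi-squared for
#' categorical).
#'
#' @param registry An [hiv_registry()].
#' @param flags Classification table from [classify_cohort()] (row order
#'   must match `registry$persons`).
#' @param index_date Index date (for current age).
#' @param min_cell Cells below this count in the five per-category columns
#'   get `display = FALSE`; counts are retained.
#' @return A long `data.table`: `variable`, `level` (categorical level,
#'   `"median"` or `"missing"`), `group`, `n`, `pct`, `median`, `q1`,
#'   `q3`, `p_value` (repeated within variable), `display`.
#' @export
table1 <- function(registry, flags, index_date, min_cell = 10L) {
  stopifnot(identical(registry$persons$person_id, flags$person_id))
  p <- registry$persons
  index_date <- as.Date(index_date)
  dat <- data.table::data.table(
    sex = p$sex_at_birth,
    current_age = as.numeric(index_date - p$birth_date) / 365.25,
    first_positive_test_year = as.numeric(p$first_positive_test_year),
    first_cd4 = p$first_cd4, nadir_cd4 = p$nadir_cd4,
    first_vl_log10 = p$first_vl_log10,
    risk_group = p$risk_group,
    born_in_sweden = ifelse(is.na(p$born_in_sweden), NA_character_,
                            ifelse(p$born_in_sweden, "yes", "no")),
    has_resistance_test = ifelse(
      p$person_id %in% unique(registry$resistance$person_id), "yes", "no"))
  groups <- group_membership(flags)
  cont <- c("current_age", "first_positive_test_year", "first_cd4",
            "nadir_cd4", "first_vl_log10")
  catv <- c("sex", "risk_group", "born_in_sweden", "has_resistance_test")
  rows <- list()
  for (v in cont) {
    x <- dat[[v]]
    pv <- tryCatch(
      mann_whitney(x[groups$difficult], x[groups$non_difficult])$p_value,
      error = function(e) NA_real_)
    for (g in names(groups)) {
      xs <- x[groups[[g]]]
      qs <- stats::quantile(xs, c(0.25, 0.5, 0.75), na.rm = TRUE,
                            names = FALSE, type = 7)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        variable = v, level = c("median", "missing"), group = g,
        n = c(sum(!is.na(xs)), sum(is.na(xs))),
        pct = c(NA, if (length(xs)) sum(is.na(xs)) / length(xs) else NA),
        median = c(qs[2], NA), q1 = c(qs[1], NA), q3 = c(qs[3], NA),
        p_value = pv)
    }
  }
  for (v in catv) {
    x <- dat[[v]]
    lv <- sort(unique(x[!is.na(x)]))
    tab <- rbind(table(factor(x[groups$difficult], levels = lv)),
                 table(factor(x[groups$non_difficult], levels = lv)))
    pv <- tryCatch(chi_squared(tab[, colSums(tab) > 0, drop = FALSE])$p_value,
                   error = function(e) NA_real_)
    for (g in names(groups)) {
      xs <- x[groups[[g]]]
      cnt <- as.integer(table(factor(xs, levels = lv)))
      nm <- sum(is.na(xs))
      denom <- length(xs)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        variable = v, level = c(lv, "missing"), group = g,
        n = c(cnt, nm),
        pct = if (denom) c(cnt, nm) / denom else NA,
        median = NA_real_, q1 = NA_real_, q3 = NA_real_, p_value = pv)
    }
  }
  out <- data.table::rbindlist(rows)
  out[, display := !(group %in% names(category_cols)) | is.na(n) |
        n >= min_cell | n == 0]
  out[]
}

#' Suppression rates per category
#'
#' One row for the non-difficult group, the difficult group overall, and
#' each of the five categories (people contribute to every category they
#' belong to). Assessed = eligible for the suppression outcome with a
#' recorded viral load in the last 12 months.
#'
#' @param flags Classification table from [classify_cohort()].
#' @param outcomes Outcome table from [derive_outcomes()] (same persons).
#' @return A `data.table`: `category`, `n_assessed`, `n_suppressed`,
#'   `rate`.
#' @export
suppression_by_category <- function(flags, outcomes) {
  stopifnot(identical(flags$person_id, outcomes$person_id))
  assessed <- outcomes$eligible_suppression & !is.na(outcomes$suppressed)
  supp <- assessed & outcomes$suppressed %in% TRUE
  groups <- group_membership(flags)
  data.table::data.table(
    category = names(groups),
    n_assessed = vapply(groups, function(m) sum(m & assessed), 0L),
    n_suppressed = vapply(groups, function(m) sum(m & supp), 0L)
  )[, rate := ifelse(n_assessed > 0, n_suppressed / n_assessed, NA_real_)][]
}

#' Round half-up to a percentage integer (display convention)
#'
#' @param x Proportions in `[0, 1]`.
#' @return Integer percentages, ties rounded away from zero.
#' @export
percent_display <- function(x) floor(x * 100 + 0.5)

#' Read a pipeline run configuration from YAML
#'
#' A run configuration holds `index_date`, optional `min_cell`, an
#' optional `catalog` path and an optional `thresholds` block whose
#' entries override the [dtt_thresholds()] defaults, e.g.
#'
#' ```yaml
#' index_date: 2023-04-06
#' min_cell: 10
#' thresholds:
#'   min_art_days: 1826
#'   switch_within_days: 183
#' ```
#'
#' @param path YAML file.
#' @return List with `index_date`, `min_cell`, `catalog` (a loaded catalog
#'   or the default) and `thresholds` (a [dtt_thresholds()] list).
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$index_date)) stop("run config must set index_date")
  th <- do.call(dtt_thresholds,
                if (is.null(y$thresholds)) list() else y$thresholds)
  list(index_date = as.Date(y$index_date),
       min_cell = if (is.null(y$min_cell)) 10L else as.integer(y$min_cell),
       catalog = if (is.null(y$catalog)) default_drug_catalog() else
         load_drug_catalog(y$catalog),
       thresholds = th)
}

#' Run the full analysis pipeline
#'
#' Classify, derive outcomes, fit the outcome models and write the
#' report tables (`flags.csv`, `table1.csv`, `table2.csv`,
#' `venn.csv`, `suppression_by_category.csv`, `sensitivity.csv`) plus a
#' JSON run manifest recording the seed, index date, thresholds and
#' excluded-row counts.
#'
#' @param input_dir Directory with the five registry CSV files; `NULL` to
#'   simulate instead.
#' @param config A [scenario_config()], required when `input_dir` is
#'   `NULL`.
#' @param out_dir Output directory (created).
#' @param index_date Index date; defaults to the config's.
#' @param catalog Drug catalog.
#' @param thresholds A [dtt_thresholds()] list.
#' @param min_cell Display-suppression threshold for small cells.
#' @return Invisibly, a list with all computed tables.
#' @export
run_pipeline <- function(input_dir = NULL, config = NULL, out_dir,
                         index_date = NULL,
                         catalog = default_drug_catalog(),
                         thresholds = dtt_thresholds(), min_cell = 10L) {
  if (is.null(input_dir)) {
    if (is.null(config))
      stop("either input_dir or config must be given")
    sim <- generate_cohort(config)
    registry <- sim$registry
    if (is.null(index_date)) index_date <- config$index_date
  } else {
    registry <- read_registry(input_dir)
    if (is.null(index_date))
      stop("index_date is required when reading a registry from disk")
  }
  index_date <- as.Date(index_date)
  flags <- classify_cohort(registry, index_date, catalog, thresholds)
  outcomes <- derive_outcomes(registry, index_date, thresholds)
  models <- fit_outcome_models(flags, outcomes, registry$persons, index_date)
  t1 <- table1(registry, flags, index_date, min_cell)
  venn <- venn_counts(flags, min_cell)
  supp <- suppression_by_category(flags, outcomes)
  sens <- sensitivity_excluding_recent_vf(flags, outcomes)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(flags, file.path(out_dir, "flags.csv"))
  data.table::fwrite(t1, file.path(out_dir, "table1.csv"))
  data.table::fwrite(models, file.path(out_dir, "table2.csv"))
  data.table::fwrite(venn, file.path(out_dir, "venn.csv"))
  data.table::fwrite(supp, file.path(out_dir, "suppression_by_category.csv"))
  sens_dt <- data.table::data.table(
    n_analyzed = sens$n_analyzed, a = sens$counts[["a"]],
    b = sens$counts[["b"]], c = sens$counts[["c"]], d = sens$counts[["d"]],
    rate_difficult = sens$rate_difficult,
    rate_nondifficult = sens$rate_nondifficult, p_value = sens$p_value,
    odds_ratio = if (is.null(sens$odds_ratio)) NA_real_ else
      sens$odds_ratio$odds_ratio,
    degenerate = sens$degenerate)
  data.table::fwrite(sens_dt, file.path(out_dir, "sensitivity.csv"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("dtthiv")),
    index_date = as.character(index_date),
    seed = if (!is.null(config)) config$seed else NULL,
    simulated = is.null(input_dir),
    n_persons = nrow(registry$persons),
    thresholds = lapply(unclass(thresholds), as.character),
    min_cell = min_cell,
    n_difficult = sum(flags$difficult),
    excluded_recent_art_start = sum(!outcomes$eligible_suppression),
    missing_recent_vl = sum(outcomes$eligible_suppression &
                              is.na(outcomes$suppressed)),
    adjusted_model_dropped = attr(models, "dropped"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(list(registry = registry, flags = flags, outcomes = outcomes,
                 models = models, table1 = t1, venn = venn,
                 suppression = supp, sensitivity = sens))
}
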