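#' Mann-Whitney U test (normal approximation)
#'
#' Two-sided rank-sum comparison of two groups, as used for the continuous
#' baseline characteristics. The p-value uses the normal approximation
#' with tie correction and continuity correction; the returned statistic is
#' the Mann-Whitney U for the first group, in `[0, nA * nB]`.
#'
#' @param a,b Numeric vectors; missing values are dropped.
#' @return List with `U` and `p_value`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$U   # complete separation: 0
#' @export
mann_whitney <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b))
    stop("mann_whitney: both groups need at least one non-missing value")
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                            correct = TRUE))
  list(U = unname(wt$statistic), p_value = unname(wt$p.value))
}

#' Pearson chi-squared test on a contingency table
#'
#' Pearson statistic without continuity correction, df = (r-1)(k-1), as
#' used for the categorical baseline characteristics.
#'
#' @param tab A matrix of non-negative counts (typically 2 x k). All row
#'   and column margins must be positive.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
chi_squared <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("chi_squared: negative counts")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("chi_squared: zero row or column margin")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

#' Odds ratio from a 2x2 table with Wald confidence interval
#'
#' For exposure/outcome counts `a` (exposed, event), `b` (exposed, no
#' event), `c` (unexposed, event), `d` (unexposed, no event):
#' OR = (a d)/(b c) with 95% CI `exp(log OR +/- 1.96 sqrt(1/a+1/b+1/c+1/d))`.
#'
#' @param a,b,c,d Non-negative counts; the Wald interval requires all four
#'   to be positive.
#' @param outcome Label stored in the result.
#' @return A one-row `data.table` (an `OrEstimate`): `outcome`,
#'   `n_analyzed`, the four counts, `odds_ratio`, `ci_low`, `ci_high`,
#'   `adjusted = FALSE`.
#' @examples
#' odds_ratio_2x2(20, 10, 10, 20)$odds_ratio  # 4
#' @export
odds_ratio_2x2 <- function(a, b, c, d, outcome = "outcome") {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0)) stop("odds_ratio_2x2: negative count")
  if (any(counts == 0))
    stop("odds_ratio_2x2: zero cell; an exact or penalized method would be ",
         "needed and is out of scope")
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  data.table::data.table(
    outcome = outcome, n_analyzed = sum(counts),
    a = a, b = b, c = c, d = d,
    odds_ratio = or,
    ci_low = exp(log(or) - 1.959964 * se),
    ci_high = exp(log(or) + 1.959964 * se),
    adjusted = FALSE
  )
}

or_from_glm <- function(fit, term, outcome, adjusted) {
  cf <- stats::coef(fit)
  if (!fit$converged || any(abs(cf) > 15))
    stop("logistic model for '", outcome, "' did not converge or shows ",
         "separation")
  se <- sqrt(diag(stats::vcov(fit)))[term]
  est <- cf[term]
  data.table::data.table(
    outcome = outcome, n_analyzed = stats::nobs(fit),
    a = NA_integer_, b = NA_integer_, c = NA_integer_, d = NA_integer_,
    odds_ratio = exp(est),
    ci_low = exp(est - 1.959964 * se),
    ci_high = exp(est + 1.959964 * se),
    adjusted = adjusted
  )
}

#' Crude and adjusted odds ratios for the three treatment outcomes
#'
#' For each outcome (viral suppression, satisfaction with physical health,
#' satisfaction with psychological health) fits two logistic regressions
#' with difficult-to-treat status as the exposure: a crude model
#' (`outcome ~ difficult`) and an adjusted model adding sex, current age
#' (linear, centered at 50 years for numerical stability — this does not
#' change the odds ratios) and risk group (reference: heterosexual).
#' Complete-case: rows with missing outcome are dropped per outcome; rows
#' with missing sex or risk group are dropped from the adjusted models.
#' The crude odds ratio is algebraically identical to the 2x2 odds ratio
#' on the same rows, and the four cell counts are reported alongside it.
#'
#' @param flags Classification table from [classify_cohort()] (needs
#'   `person_id`, `difficult`).
#' @param outcomes Outcome table from [derive_outcomes()].
#' @param persons The persons table (for sex, age, risk group);
#'   `current_age` is computed from `birth_date` and `index_date`.
#' @param index_date Index date used for current age.
#' @return A `data.table` of `OrEstimate` rows: crude and adjusted per
#'   outcome, plus an attribute `dropped` with per-model dropped-row
#'   counts.
#' @export
fit_outcome_models <- function(flags, outcomes, persons, index_date) {
  index_date <- as.Date(index_date)
  df <- merge(merge(flags[, c("person_id", "difficult")], outcomes,
                    by = "person_id"),
              persons[, c("person_id", "sex_at_birth", "birth_date",
                          "risk_group")], by = "person_id")
  df$age <- as.numeric(index_date - df$birth_date) / 365.25
  df$sex <- factor(df$sex_at_birth, levels = c("man", "woman"))
  df$risk <- factor(df$risk_group,
                    levels = c("heterosexual", "MSM", "IDU", "other"))
  specs <- list(
    list(name = "viral_suppression", col = "suppressed",
         keep_col = "eligible_suppression"),
    list(name = "physical_health", col = "physical_satisfied",
         keep_col = NULL),
    list(name = "psychological_health", col = "psychological_satisfied",
         keep_col = NULL)
  )
  out <- list(); dropped <- list()
  for (sp in specs) {
    d <- df
    if (!is.null(sp$keep_col)) d <- d[d[[sp$keep_col]] %in% TRUE, ]
    d$y <- d[[sp$col]]
    d <- d[!is.na(d$y) & !is.na(d$difficult), ]
    if (nrow(d) == 0 || length(unique(d$difficult)) < 2) {
      stop("outcome '", sp$name, "' has no informative complete cases")
    }
    crude <- stats::glm(y ~ difficult, family = stats::binomial(), data = d)
    out[[length(out) + 1L]] <-
      or_from_glm(crude, "difficultTRUE", sp$name, adjusted = FALSE)
    a <- sum(d$difficult & d$y);  b <- sum(d$difficult & !d$y)
    cc <- sum(!d$difficult & d$y); dd <- sum(!d$difficult & !d$y)
    data.table::set(out[[length(out)]], j = c("a", "b", "c", "d"),
                    value = list(a, b, cc, dd))
    dadj <- d[!is.na(d$sex) & !is.na(d$risk) & !is.na(d$age), ]
    dropped[[sp$name]] <- nrow(d) - nrow(dadj)
    adj <- stats::glm(y ~ difficult + sex + I(age - 50) + risk,
                      family = stats::binomial(), data = dadj)
    out[[length(out) + 1L]] <-
      or_from_glm(adj, "difficultTRUE", sp$name, adjusted = TRUE)
  }
  res <- data.table::rbindlist(out)
  data.table::setattr(res, "dropped", dropped)
  res
}
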