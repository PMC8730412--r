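#' Group comparisons and outcome regression protocol
#'
#' Nonparametric two-group comparisons for cohort tables, and the
#' univariate-screen-then-multivariate linear regression protocol linking
#' connectivity metrics to Bayley-III neurodevelopmental outcomes.
#'
#' @name outcome_models
NULL

#' Rank-sum comparison of a continuous variable
#'
#' Two-sided Mann-Whitney rank-sum test (exact enumeration when both
#' groups have at most 8 observations, normal approximation with tie
#' correction otherwise), with medians and type-7 interquartile ranges.
#'
#' @param values_A,values_B Numeric vectors; missing values are dropped.
#' @return List with `median_A`, `iqr_A` (length-2), `median_B`, `iqr_B`,
#'   `p`, `n_A`, `n_B`.
#' @export
compare_continuous <- function(values_A, values_B) {
  a <- values_A[!is.na(values_A)]
  b <- values_B[!is.na(values_B)]
  if (length(a) == 0 || length(b) == 0) {
    stop("both groups must contain non-missing values", call. = FALSE)
  }
  exact <- length(a) <= 8 && length(b) <= 8 && !anyDuplicated(c(a, b))
  p <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                           correct = TRUE)$p.value)
  list(median_A = stats::median(a),
       iqr_A = unname(stats::quantile(a, c(0.25, 0.75), type = 7)),
       median_B = stats::median(b),
       iqr_B = unname(stats::quantile(b, c(0.25, 0.75), type = 7)),
       p = p, n_A = length(a), n_B = length(b))
}

#' Categorical comparison (Fisher / chi-squared)
#'
#' Fisher's exact test (two-sided by the point-probability rule) when the
#' table is 2x2 or any expected count is below 5; Pearson's chi-squared
#' otherwise.
#'
#' @param table A 2 x k matrix of nonnegative integer counts.
#' @return The two-sided p-value, with attribute `method`.
#' @export
compare_categorical <- function(table) {
  table <- as.matrix(table)
  stopifnot(nrow(table) == 2, all(table >= 0), all(table == round(table)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero margin in contingency table", call. = FALSE)
  }
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (ncol(table) == 2 || any(expected < 5)) {
    p <- stats::fisher.test(table)$p.value
    attr(p, "method") <- "fisher"
  } else {
    p <- stats::chisq.test(table, correct = FALSE)$p.value
    attr(p, "method") <- "chisq"
  }
  p
}

#' Format a count with its percentage
#'
#' @param n Count.
#' @param denom Denominator.
#' @return String `"n (pp.p%)"` with the percentage to one decimal.
#' @export
fmt_count_pct <- function(n, denom) {
  sprintf("%d (%.1f%%)", n, round(100 * n / denom, 1))
}

fmt_median_iqr <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, type = 7)
  sprintf("%.2f (%.2f-%.2f)", q[2], q[1], q[3])
}

#' Cohort demographics / clinical comparison table
#'
#' Per-variable between-cohort comparison: medians with IQRs and a
#' rank-sum p for continuous variables, counts with percentages and a
#' Fisher p for binary variables.
#'
#' @param subjects Subject table with a `cohort` column (two levels).
#' @param continuous Names of continuous columns to compare.
#' @param binary Names of logical/binary columns to compare.
#' @return Data frame with one row per variable: formatted per-cohort
#'   summaries and the p-value.
#' @export
demographics_table <- function(subjects,
                               continuous = c("ga_birth", "ga_mri", "birth_weight"),
                               binary = c("male", "injury_on_mri")) {
  cohort <- droplevels(as.factor(subjects$cohort))
  stopifnot(nlevels(cohort) == 2)
  lv <- levels(cohort)
  rows <- list()
  for (v in binary) {
    x <- as.logical(subjects[[v]])
    nA <- sum(x[cohort == lv[1]], na.rm = TRUE)
    nB <- sum(x[cohort == lv[2]], na.rm = TRUE)
    dA <- sum(!is.na(x[cohort == lv[1]]))
    dB <- sum(!is.na(x[cohort == lv[2]]))
    tab <- rbind(c(nA, dA - nA), c(nB, dB - nB))
    rows[[v]] <- data.frame(
      variable = v,
      stat_A = fmt_count_pct(nA, dA), stat_B = fmt_count_pct(nB, dB),
      p = as.numeric(compare_categorical(tab)), stringsAsFactors = FALSE)
  }
  for (v in continuous) {
    x <- subjects[[v]]
    cc <- compare_continuous(x[cohort == lv[1]], x[cohort == lv[2]])
    rows[[v]] <- data.frame(
      variable = v,
      stat_A = fmt_median_iqr(x[cohort == lv[1]]),
      stat_B = fmt_median_iqr(x[cohort == lv[2]]),
      p = cc$p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "cohorts") <- lv
  out
}

# tidy one lm fit into term/estimate/CI/p rows plus model-level attributes
tidy_lm <- function(fit, terms = NULL) {
  sm <- summary(fit)
  co <- sm$coefficients
  ci <- suppressMessages(stats::confint(fit))
  keep <- rownames(co) != "(Intercept)"
  if (!is.null(terms)) keep <- keep & rownames(co) %in% terms
  out <- data.frame(term = rownames(co)[keep],
                    estimate = co[keep, 1],
                    ci_low = ci[rownames(co)[keep], 1],
                    ci_high = ci[rownames(co)[keep], 2],
                    p = co[keep, 4],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  fstat <- sm$fstatistic
  attr(out, "model_p") <- if (is.null(fstat)) NA_real_ else
    unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  attr(out, "n_used") <- length(stats::residuals(fit))
  out
}

#' Univariate screen of outcome predictors
#'
#' One simple linear regression of the outcome on each predictor.
#' Multi-level categorical predictors enter as dummy sets and are
#' screened on their overall F p-value; graph metrics should be supplied
#' already log-transformed (natural log). Predictors with p < `screen_p`
#' (default 0.1) form the selected set. Complete-case per predictor;
#' constant predictors are skipped with a warning.
#'
#' @param data Data frame holding the outcome and predictors.
#' @param outcome Name of the outcome column.
#' @param predictors Character vector of predictor column names.
#' @param screen_p Selection threshold (default 0.1).
#' @return A data frame of per-term results (columns `predictor`, `term`,
#'   `estimate`, `ci_low`, `ci_high`, `p`, `overall_p`, `n_used`,
#'   `selected`), with attribute `selected` (predictor names passing the
#'   screen).
#' @export
univariate_screen <- function(data, outcome, predictors, screen_p = 0.1) {
  rows <- list()
  selected <- character(0)
  for (v in predictors) {
    d <- data[!is.na(data[[outcome]]) & !is.na(data[[v]]), c(outcome, v)]
    x <- d[[v]]
    if (length(unique(x)) < 2) {
      warning("predictor '", v, "' constant after complete-case filtering; skipped",
              call. = FALSE)
      next
    }
    fit <- stats::lm(stats::reformulate(v, outcome), data = d)
    td <- tidy_lm(fit)
    categorical <- is.factor(x) || is.character(x)
    overall_p <- if (categorical) attr(td, "model_p") else td$p[1]
    td$predictor <- v
    td$overall_p <- overall_p
    td$n_used <- attr(td, "n_used")
    td$selected <- overall_p < screen_p
    if (overall_p < screen_p) selected <- c(selected, v)
    rows[[v]] <- td
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[, c("predictor", "term", "estimate", "ci_low", "ci_high",
                 "p", "overall_p", "n_used", "selected")]
  attr(out, "selected") <- selected
  out
}

#' Multivariate outcome model for one graph metric
#'
#' Ordinary least squares of the outcome on one (log) graph metric plus
#' the screened covariates. Corrected gestational age at MRI is included
#' a priori in every model; gestational age at birth is always excluded
#' as collinear with it. Because the graph metrics are not mathematically
#' independent, callers fit one model per metric.
#'
#' @param data Data frame with the outcome, the metric and covariates.
#' @param outcome Outcome column name.
#' @param metric Column name of the (log-transformed) metric.
#' @param covariates Screened covariate names.
#' @param always_include Covariates forced into the model (default
#'   `"ga_mri"`).
#' @param always_exclude Covariates dropped with a message (default
#'   `"ga_birth"`).
#' @return Data frame of term/estimate/CI/p rows with attributes
#'   `model_p` and `n_used`.
#' @export
multivariate_metric_model <- function(data, outcome, metric,
                                      covariates = character(0),
                                      always_include = "ga_mri",
                                      always_exclude = "ga_birth") {
  dropped <- intersect(covariates, always_exclude)
  if (length(dropped) > 0) {
    message("excluding ", paste(dropped, collapse = ", "),
            ": collinear with corrected gestational age at MRI")
  }
  covariates <- setdiff(union(covariates, always_include), always_exclude)
  vars <- unique(c(metric, covariates))
  d <- data[stats::complete.cases(data[, c(outcome, vars)]), c(outcome, vars)]
  X <- stats::model.matrix(stats::reformulate(vars), data = d)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[seq(qx$rank + 1, ncol(X))]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm(stats::reformulate(vars, outcome), data = d)
  tidy_lm(fit)
}

#' Univariate tract-outcome regression grid
#'
#' Simple linear regression of each language outcome on each tract
#' connectivity score: one row per tract x outcome cell. Cells with a
#' constant score are flagged not estimable.
#'
#' @param data Data frame containing tract scores and outcomes (one row
#'   per subject).
#' @param tracts Tract score column names (default the built-in five).
#' @param outcomes Outcome column names (default the four language
#'   outcomes: 12-18-month composite; 30-month composite, expressive,
#'   receptive).
#' @return Data frame with columns `tract`, `outcome`, `estimate`,
#'   `ci_low`, `ci_high`, `p`, `n_used`, `estimable`.
#' @export
tract_regressions <- function(data,
                              tracts = c("SLF1", "SLF2", "SLF3", "ILF", "AF"),
                              outcomes = c("language_12_18", "language_30",
                                           "expressive_30", "receptive_30")) {
  rows <- list()
  for (tr in tracts) {
    for (oc in outcomes) {
      d <- data[stats::complete.cases(data[, c(oc, tr)]), c(oc, tr)]
      if (nrow(d) < 3 || length(unique(d[[tr]])) < 2) {
        rows[[paste(tr, oc)]] <- data.frame(
          tract = tr, outcome = oc, estimate = NA_real_, ci_low = NA_real_,
          ci_high = NA_real_, p = NA_real_, n_used = nrow(d),
          estimable = FALSE, stringsAsFactors = FALSE)
        next
      }
      td <- tidy_lm(stats::lm(stats::reformulate(tr, oc), data = d))
      rows[[paste(tr, oc)]] <- data.frame(
        tract = tr, outcome = oc, estimate = td$estimate[1],
        ci_low = td$ci_low[1], ci_high = td$ci_high[1], p = td$p[1],
        n_used = attr(td, "n_used"), estimable = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
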