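# Cohort statistics layer: thin, explicit wrappers around base-R tests that
# return a uniform report record and enforce the preconditions of the study
# design (two-sided, alpha = 0.05, sample SD convention).

stat_report <- function(test, statistic, p_value, estimate = NULL,
                        group_sizes = NULL, detail = list()) {
  stopifnot(is.na(p_value) || (p_value >= 0 && p_value <= 1))
  structure(list(test = test, statistic = unname(statistic),
                 p_value = unname(p_value), estimate = estimate,
                 group_sizes = group_sizes, detail = detail),
            class = "stat_report")
}

#' @export
print.stat_report <- function(x, ...) {
  cat(sprintf("<stat_report> %s: statistic = %.4g, p = %.4g\n",
              x$test, x$statistic, x$p_value))
  if (!is.null(x$estimate) && is.numeric(x$estimate) &&
      length(x$estimate) <= 4)
    cat("  estimate:", paste(signif(unlist(x$estimate), 5), collapse = ", "), "\n")
  invisible(x)
}

smoking_indicator <- function(x) as.integer(x == "current")

#' Compare a variable between the sexes
#'
#' Two-sided t-test (pooled variance by default, Welch optional) for
#' normally distributed indicators, or Mann-Whitney U (normal approximation
#' with tie correction) for the rest — mirroring the usual split between WBC
#' and hemoglobin versus other clinical indicators.
#'
#' @param cohort Cohort `data.frame` with a `sex` column.
#' @param variable Name of the numeric column to compare.
#' @param method `"t_test"` or `"mann_whitney"`.
#' @param welch Use the Welch (unequal-variance) t-test.
#' @return A `stat_report` with the mean difference (M - F) as estimate.
#' @export
compare_sexes <- function(cohort, variable,
                          method = c("t_test", "mann_whitney"),
                          welch = FALSE) {
  method <- match.arg(method)
  x <- cohort[[variable]][cohort$sex == "M"]
  y <- cohort[[variable]][cohort$sex == "F"]
  if (length(x) < 2 || length(y) < 2)
    stop("need at least 2 subjects of each sex")
  sizes <- c(M = length(x), F = length(y))
  if (method == "t_test") {
    if (sd(x) == 0 && sd(y) == 0) stop("degenerate variance in both groups")
    ht <- t.test(x, y, var.equal = !welch)
    stat_report(if (welch) "Welch t-test" else "t-test (pooled variance)",
                ht$statistic, ht$p.value,
                estimate = list(mean_difference = mean(x) - mean(y)),
                group_sizes = sizes,
                detail = list(variable = variable, conf_int = unname(ht$conf.int)))
  } else {
    ht <- suppressWarnings(wilcox.test(x, y, exact = FALSE))
    stat_report("Mann-Whitney U (normal approximation)",
                ht$statistic, ht$p.value,
                estimate = list(mean_difference = mean(x) - mean(y)),
                group_sizes = sizes, detail = list(variable = variable))
  }
}

#' Correlation between two cohort variables
#'
#' Pearson for continuous clinical indicators, Spearman for the ordinal
#' smoking indicator. A positive or negative r gives the direction of direct
#' or inverse association. Two-sided p-value.
#'
#' @param cohort Cohort `data.frame`.
#' @param x,y Column names. `"smoking"` is converted to a 0/1 current-smoker
#'   indicator and forces Spearman.
#' @param method `"pearson"` or `"spearman"`.
#' @return A `stat_report` with `r` as estimate.
#' @export
correlate <- function(cohort, x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  vx <- cohort[[x]]
  vy <- cohort[[y]]
  if (x == "smoking") { vx <- smoking_indicator(vx); method <- "spearman" }
  if (y == "smoking") { vy <- smoking_indicator(vy); method <- "spearman" }
  ok <- !is.na(vx) & !is.na(vy)
  vx <- vx[ok]; vy <- vy[ok]
  if (length(vx) < 3) stop("need at least 3 paired observations")
  if (var(vx) == 0 || var(vy) == 0) stop("zero variance in x or y")
  ht <- suppressWarnings(cor.test(vx, vy, method = method, exact = FALSE))
  stat_report(paste0(method, " correlation"), ht$statistic, ht$p.value,
              estimate = list(r = unname(ht$estimate)),
              group_sizes = c(n = length(vx)),
              detail = list(x = x, y = y))
}

#' Multivariate (multiple linear) regression of a PET parameter
#'
#' Ordinary least squares of `response` on `predictors`. With
#' `predictors = "auto"` the predictor set is chosen as the clinical
#' indicators whose univariate correlation with the response is significant
#' at p < 0.05 (Pearson; Spearman for the smoking indicator), mirroring the
#' two-stage univariate-then-multivariate procedure. The selected set is
#' always recorded.
#'
#' @param cohort Cohort `data.frame`.
#' @param response Response column name.
#' @param predictors Character vector of predictor columns, or `"auto"`.
#' @param candidates Candidate predictors for auto-selection.
#' @return A `stat_report`; `estimate` holds the coefficient table
#'   (estimate, 95% CI, p), `detail$selected` the predictor set and
#'   `detail$r_squared` the fit.
#' @export
multivariate_regression <- function(cohort, response, predictors = "auto",
                                    candidates = c("age_y", "wbc_1e3_per_ul",
                                                   "hb_g_dl", "smoking")) {
  dat <- cohort
  dat$smoking_current <- smoking_indicator(dat$smoking)
  to_col <- function(p) if (p == "smoking") "smoking_current" else p
  if (identical(predictors, "auto")) {
    pv <- vapply(candidates, function(p) {
      correlate(cohort, p, response,
                method = if (p == "smoking") "spearman" else "pearson")$p_value
    }, numeric(1))
    predictors <- candidates[pv < 0.05]
    if (!length(predictors))
      stop("auto-selection found no predictor with univariate p < 0.05")
  }
  cols <- vapply(predictors, to_col, character(1))
  n <- nrow(dat)
  if (n <= length(cols) + 1) stop("need n > number of predictors + 1")
  fml <- stats::as.formula(paste(response, "~", paste(cols, collapse = " + ")))
  fit <- lm(fml, data = dat)
  if (fit$rank < length(cols) + 1 || anyNA(coef(fit)))
    stop("rank-deficient design matrix")
  sm <- summary(fit)
  ci <- confint(fit)
  coefs <- data.frame(term = rownames(sm$coefficients),
                      estimate = sm$coefficients[, 1],
                      ci_lower = ci[, 1], ci_upper = ci[, 2],
                      p_value = sm$coefficients[, 4],
                      row.names = NULL)
  stat_report("multivariate OLS regression",
              sm$fstatistic[["value"]],
              pf(sm$fstatistic[["value"]], sm$fstatistic[["numdf"]],
                 sm$fstatistic[["dendf"]], lower.tail = FALSE),
              estimate = coefs,
              group_sizes = c(n = n),
              detail = list(response = response, selected = predictors,
                            r_squared = sm$r.squared, fit = fit))
}

#' One-way ANOVA of a variable across Deauville score groups
#'
#' @param cohort Cohort `data.frame` with a `deauville_score` column.
#' @param variable Numeric column to compare across score groups.
#' @return A `stat_report` with the F statistic.
#' @export
anova_by_score <- function(cohort, variable) {
  g <- factor(cohort$deauville_score)
  sizes <- table(g)
  if (sum(sizes >= 2) < 2 || nlevels(droplevels(g)) < 2)
    stop("need at least 2 score groups with at least 2 members")
  dat <- data.frame(y = cohort[[variable]], g = g)
  fit <- aov(y ~ g, data = dat)
  sm <- summary(fit)[[1]]
  stat_report("one-way ANOVA", sm[["F value"]][1], sm[["Pr(>F)"]][1],
              group_sizes = as.integer(sizes),
              detail = list(variable = variable))
}

#' Association between two categorical cohort variables
#'
#' Chi-square test (without continuity correction) when all expected cell
#' counts are at least 5, otherwise Fisher's exact test — operationalizing
#' the "low frequencies" rule. The rule applied is recorded.
#'
#' @param cohort Cohort `data.frame`.
#' @param row_var,col_var Categorical column names.
#' @return A `stat_report`; `detail$rule` records which test ran.
#' @export
categorical_association <- function(cohort, row_var, col_var) {
  tab <- table(cohort[[row_var]], cohort[[col_var]])
  if (!sum(tab)) stop("empty table")
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("both variables need at least 2 observed levels")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(expected >= 5)) {
    ht <- chisq.test(tab, correct = FALSE)
    stat_report("chi-square", ht$statistic, ht$p.value,
                group_sizes = as.integer(tab),
                detail = list(rule = "chi-square (all expected counts >= 5)",
                              table = tab))
  } else {
    ht <- fisher.test(tab)
    stat_report("Fisher exact", NA_real_, ht$p.value,
                group_sizes = as.integer(tab),
                detail = list(rule = "Fisher exact (some expected count < 5)",
                              table = tab))
  }
}

#' Per-sex mean and standard deviation summary
#'
#' Reproduces the layout of a cohort characteristics table: mean and sample
#' (n-1) SD of every numeric variable, split by sex. A single-subject group
#' reports SD 0 with a flag.
#'
#' @param cohort Cohort `data.frame` with a `sex` column.
#' @param variables Columns to summarize; default all numeric columns.
#' @return `data.frame` with `variable`, `sex`, `n`, `mean`, `sd`,
#'   `single_subject`.
#' @export
summarize_cohort <- function(cohort, variables = NULL) {
  if (!nrow(cohort)) stop("empty cohort")
  if (is.null(variables))
    variables <- names(cohort)[vapply(cohort, is.numeric, logical(1))]
  out <- expand.grid(variable = variables, sex = c("M", "F"),
                     stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(out)), function(i) {
    v <- cohort[[out$variable[i]]][cohort$sex == out$sex[i]]
    v <- v[!is.na(v)]
    n <- length(v)
    data.frame(n = n,
               mean = if (n) mean(v) else NA_real_,
               sd = if (n > 1) sd(v) else if (n == 1) 0 else NA_real_,
               single_subject = n == 1L)
  })
  cbind(out, do.call(rbind, res))
}
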