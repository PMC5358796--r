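#' Intraclass correlation for grading consistency
#'
#' Consistency of ordinal grades across replicate raters, computed from
#' the classical two-way ANOVA decomposition of the samples x raters
#' matrix. The default form is ICC(3,1) -- two-way mixed effects, single
#' measurement, consistency -- appropriate when the same fixed raters
#' graded every sample:
#' `(MS_rows - MS_error) / (MS_rows + (k - 1) * MS_error)`.
#' A one-way form, ICC(1,1), is available by flag.
#'
#' @param ratings Numeric matrix or data frame, samples in rows, raters in
#'   columns; no missing cells, at least 2 of each.
#' @param model `"two_way_mixed_consistency"` (default) or `"one_way"`.
#' @return An object of class `icc_fit`: list with `icc`, `model`,
#'   `n_samples`, `n_raters`, `ms_rows`, `ms_cols`, `ms_error`. When the
#'   between-sample variance is zero the coefficient is undefined and
#'   `icc` is `NA` with a warning.
#' @examples
#' r <- cbind(a = c(0, 1, 2, 3), b = c(0, 1, 2, 3))
#' icc_consistency(r)$icc  # identical raters: 1
#' @export
icc_consistency <- function(ratings,
                            model = c("two_way_mixed_consistency", "one_way")) {
  model <- match.arg(model)
  x <- as.matrix(ratings)
  if (anyNA(x)) stop("ratings must have no missing cells")
  n <- nrow(x)
  k <- ncol(x)
  if (n < 2 || k < 2) stop("need at least 2 samples and 2 raters")

  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ss_total <- sum((x - grand)^2)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  ms_rows <- ss_rows / (n - 1)
  ms_cols <- ss_cols / (k - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))

  icc <- switch(model,
    two_way_mixed_consistency = {
      denom <- ms_rows + (k - 1) * ms_err
      if (denom <= 0) NA_real_ else (ms_rows - ms_err) / denom
    },
    one_way = {
      ms_within <- (ss_cols + ss_err) / (n * (k - 1))
      denom <- ms_rows + (k - 1) * ms_within
      if (denom <= 0) NA_real_ else (ms_rows - ms_within) / denom
    }
  )
  if (is.na(icc)) {
    warning("zero between-sample variance: ICC is undefined")
  }
  structure(
    list(icc = icc, model = model, n_samples = n, n_raters = k,
         ms_rows = ms_rows, ms_cols = ms_cols, ms_error = ms_err),
    class = "icc_fit"
  )
}

#' @export
print.icc_fit <- function(x, ...) {
  cat("Intraclass correlation (", x$model, ")\n", sep = "")
  cat("  ICC =", format(x$icc, digits = 4),
      " [", x$n_samples, "samples x", x$n_raters, "raters ]\n")
  invisible(x)
}

#' @export
tidy.icc_fit <- function(x, ...) {
  tibble::tibble(
    term = "icc", estimate = x$icc, model = x$model,
    n_samples = x$n_samples, n_raters = x$n_raters
  )
}

#' @export
glance.icc_fit <- function(x, ...) {
  tibble::tibble(
    icc = x$icc, model = x$model, n_samples = x$n_samples,
    n_raters = x$n_raters, ms_rows = x$ms_rows, ms_error = x$ms_error
  )
}

check_groups <- function(values, group) {
  if (length(values) != length(group)) {
    stop("values and group must have the same length")
  }
  g <- factor(group)
  sizes <- table(g)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(sizes == 0)) stop("every group must be non-empty")
  if (length(values) <= nlevels(g)) {
    stop("total n must exceed the number of groups")
  }
  g
}

#' One-way analysis of variance
#'
#' Classical between/within decomposition via [stats::aov()], returned as
#' a tidy one-row summary.
#'
#' @param values Numeric response.
#' @param group Group labels, same length as `values`; at least 2 groups,
#'   each non-empty.
#' @return A one-row tibble: `df_between`, `df_within`, `ss_between`,
#'   `ss_within`, `f_statistic`, `p_value`.
#' @export
one_way_anova <- function(values, group) {
  g <- check_groups(values, group)
  fit <- stats::aov(values ~ g)
  tab <- summary(fit)[[1]]
  tibble::tibble(
    df_between = tab$Df[1],
    df_within = tab$Df[2],
    ss_between = tab$`Sum Sq`[1],
    ss_within = tab$`Sum Sq`[2],
    f_statistic = tab$`F value`[1],
    p_value = tab$`Pr(>F)`[1]
  )
}

#' Tukey honest significant differences
#'
#' Pairwise post hoc comparisons after a one-way ANOVA, based on the
#' studentized range and the within-group mean square, via
#' [stats::TukeyHSD()].
#'
#' @inheritParams one_way_anova
#' @param conf_level Confidence level for the intervals.
#' @return A tibble with one row per pair: `group_1`, `group_2`,
#'   `difference`, `conf_low`, `conf_high`, `p_adjusted`.
#' @export
tukey_hsd <- function(values, group, conf_level = 0.95) {
  g <- check_groups(values, group)
  fit <- stats::aov(values ~ g)
  tab <- stats::TukeyHSD(fit, conf.level = conf_level)$g
  pairs <- strsplit(rownames(tab), "-", fixed = TRUE)
  tibble::tibble(
    group_1 = vapply(pairs, `[`, "", 2),
    group_2 = vapply(pairs, `[`, "", 1),
    difference = unname(tab[, "diff"]),
    conf_low = unname(tab[, "lwr"]),
    conf_high = unname(tab[, "upr"]),
    p_adjusted = unname(tab[, "p adj"])
  )
}

#' Two-sided independent-samples t-test
#'
#' Wrapper around [stats::t.test()] defaulting to the Welch form (the
#' printed per-grade SDs differ several-fold between severity groups, so
#' equal variances are not assumed). When both samples have zero variance
#' the statistic is undefined and reported as `NA` with a warning.
#'
#' @param a,b Numeric samples, each with at least 2 values.
#' @param var_equal If `TRUE`, pool variances (classical t-test).
#' @return A one-row tibble: `t_statistic`, `df`, `p_value`, `mean_a`,
#'   `mean_b`.
#' @export
independent_t <- function(a, b, var_equal = FALSE) {
  if (length(a) < 2 || length(b) < 2) {
    stop("each sample needs at least 2 values")
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    warning("both samples have zero variance: t is undefined")
    return(tibble::tibble(
      t_statistic = NA_real_, df = NA_real_, p_value = NA_real_,
      mean_a = mean(a), mean_b = mean(b)
    ))
  }
  ht <- stats::t.test(a, b, var.equal = var_equal)
  tibble::tibble(
    t_statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    mean_a = mean(a),
    mean_b = mean(b)
  )
}

#' Ordinary least-squares regression of a descriptor on grade
#'
#' Simple linear regression via [stats::lm()], reported as slope,
#' intercept and the coefficient of determination -- the form in which
#' interface descriptors are related to the OARSI cartilage grade.
#'
#' @param x Predictor (e.g. OARSI grade); at least 3 values, not all
#'   equal.
#' @param y Response (descriptor values), same length.
#' @return An object of class `bci_lm`: list with `slope`, `intercept`,
#'   `r_squared`, `n` and the underlying `fit`.
#' @export
linear_regression <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete observations")
  if (stats::sd(x) == 0) stop("predictor is degenerate (all values equal)")
  fit <- stats::lm(y ~ x)
  # 1 - SS_res / SS_tot directly (summary.lm warns on exact fits)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  structure(
    list(
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r_squared = r2,
      n = length(x),
      fit = fit
    ),
    class = "bci_lm"
  )
}

#' @export
print.bci_lm <- function(x, ...) {
  cat("Linear regression: slope", format(x$slope, digits = 4),
      "intercept", format(x$intercept, digits = 4),
      "R^2", format(x$r_squared, digits = 3),
      "(n =", paste0(x$n, ")"), "\n")
  invisible(x)
}

#' @export
tidy.bci_lm <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @export
glance.bci_lm <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, n = x$n)
}
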