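# Reproducibility and responsiveness statistics: two-way random-effects
# intraclass correlation with F-based 95% confidence interval, correlation
# with the study's R^2 classification scale, and two-group / multi-group
# significance tests with Bonferroni-adjusted pairwise comparisons.

#' Two-way random-effects intraclass correlation, ICC(2,1)
#'
#' Single-measure absolute-agreement ICC from the two-way ANOVA mean
#' squares (Shrout-Fleiss ICC(2,1) / McGraw-Wong ICC(A,1)), the formulation
#' matching a design in which both targets (scans) and raters are random
#' samples. A consistency variant, ICC(3,1), is available by flag.
#' Confidence bounds use the F-distribution approximation with
#' Satterthwaite degrees of freedom.
#'
#' @param table Either a wide numeric matrix/data frame (targets x raters)
#'   or a long data frame with columns `target`, `rater`, `value`.
#' @param type `"agreement"` (ICC(2,1), default) or `"consistency"`
#'   (ICC(3,1)).
#' @param conf_level Confidence level (default 0.95).
#' @return An `icc_result` with `icc`, `ci_low`, `ci_high`, `n_targets`,
#'   `n_raters`, `type`.
#' @export
icc <- function(table, type = c("agreement", "consistency"),
                conf_level = 0.95) {
  type <- match.arg(type)
  wide <- as_icc_matrix(table)
  n <- nrow(wide)
  k <- ncol(wide)
  if (n < 2L || k < 2L) stop_input("need at least 2 targets and 2 raters")
  if (any(!is.finite(wide))) stop_input("incomplete table: missing values are not imputed")

  long <- data.frame(
    value = as.vector(wide),
    target = factor(rep(seq_len(n), k)),
    rater = factor(rep(seq_len(k), each = n))
  )
  ms <- summary(stats::aov(value ~ target + rater, data = long))[[1]]
  msr <- ms["target", "Mean Sq"]
  msc <- ms["rater", "Mean Sq"]
  mse <- ms["Residuals", "Mean Sq"]
  alpha <- 1 - conf_level

  if (type == "consistency") {
    r <- (msr - mse) / (msr + (k - 1) * mse)
    fl <- (msr / mse) / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    fu <- (msr / mse) * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  } else {
    r <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
    if (mse == 0 && msc == 0) {
      ci <- c(1, 1) # degenerate: raters agree exactly
      r <- 1
    } else {
      a <- (k * r) / (n * (1 - r))
      b <- 1 + (k * r * (n - 1)) / (n * (1 - r))
      v <- (a * msc + b * mse)^2 /
        ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
      fl <- stats::qf(1 - alpha / 2, n - 1, v)
      fu <- stats::qf(1 - alpha / 2, v, n - 1)
      ci <- c(
        n * (msr - fl * mse) / (fl * (k * msc + (k * n - k - n) * mse) + n * msr),
        n * (fu * msr - mse) / (k * msc + (k * n - k - n) * mse + n * fu * msr)
      )
    }
  }
  structure(
    list(icc = r, ci_low = ci[1], ci_high = ci[2], conf_level = conf_level,
         n_targets = n, n_raters = k, type = type,
         mean_squares = c(rows = msr, cols = msc, error = mse)),
    class = "icc_result"
  )
}

as_icc_matrix <- function(table) {
  if (is.data.frame(table) && all(c("target", "rater", "value") %in% names(table))) {
    wide <- stats::xtabs(value ~ target + rater, data = table)
    counts <- stats::xtabs(~ target + rater, data = table)
    if (any(counts != 1)) stop_input("long table must have exactly one value per target x rater cell")
    return(matrix(as.numeric(wide), nrow = nrow(wide)))
  }
  m <- as.matrix(table)
  storage.mode(m) <- "double"
  m
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf(
    "ICC(%s, single measure) = %.3f, %d%% CI (%.3f-%.3f); %d targets x %d raters\n",
    if (x$type == "agreement") "2,1" else "3,1", x$icc,
    round(100 * x$conf_level), x$ci_low, x$ci_high, x$n_targets, x$n_raters
  ))
  invisible(x)
}

#' Classify an R-squared on the study's qualitative scale
#'
#' R^2 <= 0.3 poor, (0.3, 0.4] weak, (0.4, 0.5] weak-to-moderate,
#' (0.5, 0.6] moderate, (0.6, 0.7] moderate-to-good, (0.7, 0.8] good,
#' > 0.8 very good (touching boundaries read as left-open/right-closed).
#'
#' @param r_squared R^2 value(s) in \[0, 1\].
#' @return Character classification(s).
#' @export
classify_r_squared <- function(r_squared) {
  if (any(r_squared < 0 | r_squared > 1)) stop_input("r_squared must be in [0, 1]")
  labels <- c("poor", "weak", "weak-to-moderate", "moderate",
              "moderate-to-good", "good", "very-good")
  as.character(cut(r_squared, c(-Inf, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, Inf),
                   labels = labels, right = TRUE))
}

#' Responsiveness (correlation) of a parameter
#'
#' Pearson or Spearman correlation with the R^2-scale classification. With
#' `method = "auto"` a Shapiro-Wilk screen on both variables picks Pearson
#' when neither departs from normality at the 5% level, Spearman otherwise.
#'
#' @param x,y Equal-length numeric vectors (n >= 3).
#' @param method `"auto"`, `"pearson"` or `"spearman"`.
#' @return A `correlation_result` with `r`, `r_squared`, `p_value`,
#'   `method`, `classification`.
#' @export
responsiveness <- function(x, y, method = c("auto", "pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) < 3L) {
    stop_input("x and y must have equal length >= 3")
  }
  if (method == "auto") {
    normal <- function(v) {
      if (length(unique(v)) < 3L || length(v) > 5000L) return(FALSE)
      stats::shapiro.test(v)$p.value > 0.05
    }
    method <- if (normal(x) && normal(y)) "pearson" else "spearman"
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  r <- unname(ct$estimate)
  structure(
    list(r = r, r_squared = r^2, p_value = ct$p.value, method = method,
         classification = classify_r_squared(r^2), n = length(x)),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf(
    "%s correlation: r = %.3f (R^2 = %.3f, p = %.3g) - %s responsiveness (n = %d)\n",
    x$method, x$r, x$r_squared, x$p_value,
    x$classification, x$n
  ))
  invisible(x)
}

#' Group comparison tests
#'
#' Two groups: two-tailed Student's t-test. Three or more groups: one-way
#' ANOVA followed by all pairwise comparisons with Bonferroni adjustment
#' (pooled SD). Significance is assessed at p < 0.05.
#'
#' @param values Numeric measurements.
#' @param groups Group labels (coerced to factor), or pass a named list of
#'   numeric vectors as `values` and omit `groups`.
#' @return A `group_test_result`: for two groups `p_value`, `statistic`,
#'   `method`; for more, the ANOVA p-value and a long table of
#'   Bonferroni-adjusted pairwise p-values.
#' @export
group_tests <- function(values, groups = NULL) {
  if (is.list(values) && is.null(groups)) {
    groups <- rep(names(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop_input("need at least 2 groups")
  if (any(table(groups) < 2L)) stop_input("each group needs >= 2 observations")
  k <- nlevels(groups)
  if (k == 2L) {
    tt <- stats::t.test(values ~ groups, var.equal = TRUE)
    return(structure(
      list(method = "two-tailed Student's t-test", n_groups = 2L,
           p_value = tt$p.value, statistic = unname(tt$statistic),
           significant = tt$p.value < 0.05),
      class = "group_test_result"
    ))
  }
  fit <- stats::aov(values ~ groups)
  p_anova <- summary(fit)[[1]]["groups", "Pr(>F)"]
  pw <- stats::pairwise.t.test(values, groups, p.adjust.method = "bonferroni",
                               pool.sd = TRUE)
  pm <- pw$p.value
  pairs <- do.call(rbind, lapply(rownames(pm), function(a) {
    cols <- colnames(pm)[!is.na(pm[a, ])]
    if (length(cols) == 0) return(NULL)
    data.frame(group1 = cols, group2 = a, p_adjusted = pm[a, cols])
  }))
  rownames(pairs) <- NULL
  pairs$significant <- pairs$p_adjusted < 0.05
  structure(
    list(method = "one-way ANOVA + Bonferroni pairwise", n_groups = k,
         anova_p_value = p_anova, pairwise = pairs,
         n_comparisons = nrow(pairs)),
    class = "group_test_result"
  )
}

#' @export
print.group_test_result <- function(x, ...) {
  cat(x$method, "\n")
  if (x$n_groups == 2L) {
    cat(sprintf("  t = %.3f, p = %.4g (%ssignificant at 0.05)\n",
                x$statistic, x$p_value, if (x$significant) "" else "not "))
  } else {
    cat(sprintf("  ANOVA p = %.4g; %d Bonferroni-adjusted pairwise comparisons:\n",
                x$anova_p_value, x$n_comparisons))
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}
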