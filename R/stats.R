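#' Construct a statistical test result
#'
#' @param test_name label of the test.
#' @param statistic test statistic.
#' @param p_value p-value in [0, 1].
#' @param corrected_alpha significance level after any correction.
#' @param table optional contingency table the test was computed from.
#' @return An object of class `stat_test`; `significant` is
#'   `p_value < corrected_alpha`.
#' @export
stat_test_result <- function(test_name, statistic, p_value,
                             corrected_alpha = 0.05, table = NULL) {
  p_value <- check_number(p_value, "p_value", min = 0, max = 1)
  structure(list(test_name = test_name, statistic = as.numeric(statistic),
                 p_value = p_value, corrected_alpha = corrected_alpha,
                 significant = p_value < corrected_alpha, table = table),
            class = "stat_test")
}

#' @export
print.stat_test <- function(x, ...) {
  cat(sprintf("%s: statistic %.4g, p = %.4g (alpha = %.4g) -> %s\n",
              x$test_name, x$statistic, x$p_value, x$corrected_alpha,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' Chi-squared comparison of two classifiers' right/wrong counts
#'
#' Pearson chi-squared test (1 degree of freedom, no continuity correction)
#' on the 2 x 2 contingency table of right vs wrong answers of two
#' classification runs. Expected counts below 5 trigger a warning but not a
#' change of test.
#'
#' @param right_a,wrong_a counts for the first run.
#' @param right_b,wrong_b counts for the second run.
#' @param alpha base significance level.
#' @param m_comparisons Bonferroni divisor (number of planned comparisons).
#' @return A `stat_test`.
#' @export
chi2_accuracy_test <- function(right_a, wrong_a, right_b, wrong_b,
                               alpha = 0.05, m_comparisons = 1) {
  counts <- c(right_a, wrong_a, right_b, wrong_b)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop_invalid("counts must be non-negative numbers")
  }
  tab <- matrix(counts, nrow = 2L, byrow = TRUE,
                dimnames = list(c("a", "b"), c("right", "wrong")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop_with_class("emgdiff_degenerate_table",
                    "contingency table has a zero row or column total")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    warning("chi-squared expected count(s) below 5; interpret with caution")
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  stat_test_result("chi-squared (right vs wrong)",
                   unname(res$statistic), unname(res$p.value),
                   corrected_alpha = bonferroni(alpha, m_comparisons),
                   table = tab)
}

#' Bonferroni-corrected significance level
#'
#' @param alpha base level in (0, 1).
#' @param m number of comparisons (>= 1).
#' @return `alpha / m` (e.g. 0.05 over 4 comparisons gives 0.0125).
#' @export
bonferroni <- function(alpha, m) {
  alpha <- check_number(alpha, "alpha", min = 1e-12, max = 1 - 1e-12)
  m <- check_count(m, "m")
  alpha / m
}

#' Friedman rank test across conditions
#'
#' Nonparametric repeated-measures comparison of a continuous quantity
#' (e.g. the between-class separation index) measured under several
#' conditions on the same replication units (rows: folds or subjects).
#'
#' @param mat rows x conditions numeric matrix, no missing cells, at least
#'   two rows and two conditions.
#' @param alpha significance level.
#' @return A `stat_test`. When every row is constant across conditions the
#'   statistic is 0 and the p-value 1.
#' @export
friedman_test_matrix <- function(mat, alpha = 0.05) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L || ncol(mat) < 2L) {
    stop_invalid("need at least 2 rows and 2 conditions")
  }
  if (anyNA(mat)) stop_invalid("missing cells are not allowed")
  ranks <- t(apply(mat, 1L, rank))
  if (max(colSums(ranks)) - min(colSums(ranks)) < 1e-12) {
    return(stat_test_result("Friedman", 0, 1, corrected_alpha = alpha))
  }
  res <- stats::friedman.test(mat)
  stat_test_result("Friedman", unname(res$statistic), unname(res$p.value),
                   corrected_alpha = alpha)
}

#' Wilcoxon signed-rank planned comparison of paired values
#'
#' Exact distribution for up to 25 non-zero differences, normal
#' approximation beyond.
#'
#' @param paired_a,paired_b matched numeric vectors of equal length >= 2.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @param alpha significance level.
#' @return A `stat_test`. All-zero differences raise an error of class
#'   `emgdiff_degenerate_test`.
#' @export
wilcoxon_planned <- function(paired_a, paired_b,
                             alternative = c("two.sided", "greater", "less"),
                             alpha = 0.05) {
  alternative <- match.arg(alternative)
  if (length(paired_a) != length(paired_b) || length(paired_a) < 2L) {
    stop_invalid("paired_a and paired_b must have equal length >= 2")
  }
  d <- paired_a - paired_b
  if (all(d == 0)) {
    stop_with_class("emgdiff_degenerate_test",
                    "all paired differences are zero; signed-rank test undefined")
  }
  exact <- sum(d != 0) <= 25L
  res <- suppressWarnings(stats::wilcox.test(paired_a, paired_b, paired = TRUE,
                                             alternative = alternative,
                                             exact = exact, correct = !exact))
  stat_test_result("Wilcoxon signed-rank", unname(res$statistic),
                   unname(res$p.value), corrected_alpha = alpha)
}
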