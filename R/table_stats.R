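# Cohort-table statistics: Pearson 2x2 chi-square, pooled two-sample t from
# printed summaries, Mann-Whitney, and inverse reconstruction of integer
# confusion matrices from rounded printed metrics.

new_test_result <- function(statistic, df, p_value, method) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 method = method),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g\n", x$method,
              x$statistic, if (is.na(x$df)) "-" else x$df, x$p_value))
  invisible(x)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Pearson statistic `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with 1 degree
#' of freedom, without Yates continuity correction by default (the
#' convention under which the published cohort-table statistics reproduce);
#' the correction is available behind `correct`.
#'
#' @param a,b,c,d non-negative integer cell counts (row 1: group 1 yes/no,
#'   row 2: group 2 yes/no).
#' @param correct apply the Yates continuity correction.
#' @return a `test_result` with fields `statistic`, `df`, `p_value`.
#' @export
chi_square_2x2 <- function(a, b, c, d, correct = FALSE) {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) stop("counts must be non-negative")
  n <- sum(counts)
  if (n < 1) stop("empty table")
  m <- c(a + b, c + d, a + c, b + d)
  if (any(m == 0)) {
    warning("zero marginal: statistic defined as 0")
    return(new_test_result(0, 1L, 1, "chi2"))
  }
  num <- abs(a * d - b * c)
  if (correct) num <- max(0, num - n / 2)
  stat <- n * num^2 / prod(m)
  new_test_result(stat, 1L, stats::pchisq(stat, 1, lower.tail = FALSE),
                  "chi2")
}

#' Pooled two-sample t test from printed summaries
#'
#' Student's t with pooled variance, computed from group means, SDs and
#' sizes as printed in a cohort table; `df = n1 + n2 - 2`.
#'
#' @param mean1,sd1,n1 summary of group 1.
#' @param mean2,sd2,n2 summary of group 2.
#' @return a `test_result` (two-sided p).
#' @export
two_sample_t_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("need n >= 2 in both groups")
  if (sd1 <= 0 || sd2 <= 0) stop("SDs must be positive")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  new_test_result(t, as.integer(df), 2 * stats::pt(-abs(t), df), "t_pooled")
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two samples; reports the U statistic for `x` with
#' a tie-corrected normal-approximation p value (exact p for samples of at
#' most 8 without ties).
#'
#' @param x,y numeric samples.
#' @return a `test_result` (two-sided).
#' @export
mann_whitney_test <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  ties <- any(duplicated(c(x, y)))
  exact <- max(length(x), length(y)) <= 8 && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = FALSE))
  new_test_result(unname(wt$statistic), NA_integer_, min(1, wt$p.value),
                  "mann_whitney")
}

#' Reconstruct a confusion matrix from printed sensitivity and specificity
#'
#' Brute-force search over all integer `tp` in `[0, n_pos]` and `tn` in
#' `[0, n_neg]` for the counts whose percentages match the printed
#' (rounded) sensitivity and specificity within a tolerance. Fails loudly,
#' naming the infeasible constraint, when no counts match; warns and returns
#' all candidates when several do.
#'
#' @param n_pos,n_neg group sizes (positives, negatives).
#' @param sens_pct,spec_pct printed sensitivity and specificity percentages.
#' @param tolerance_pct half-width of the match window in percentage points;
#'   0.05 corresponds to exact rounding at one decimal.
#' @return a `confusion_matrix`; when the solution is ambiguous the
#'   attribute `"candidates"` lists every matching (tp, tn) pair.
#' @export
reconstruct_confusion <- function(n_pos, n_neg, sens_pct, spec_pct,
                                  tolerance_pct = 0.05) {
  stopifnot(n_pos >= 1, n_neg >= 1, tolerance_pct >= 0.05)
  tp_ok <- which(abs(100 * (0:n_pos) / n_pos - sens_pct) <= tolerance_pct) - 1L
  tn_ok <- which(abs(100 * (0:n_neg) / n_neg - spec_pct) <= tolerance_pct) - 1L
  if (length(tp_ok) == 0)
    stop(sprintf("no tp in [0, %d] yields sensitivity %.2f%% within %.2f",
                 n_pos, sens_pct, tolerance_pct))
  if (length(tn_ok) == 0)
    stop(sprintf("no tn in [0, %d] yields specificity %.2f%% within %.2f",
                 n_neg, spec_pct, tolerance_pct))
  grid <- expand.grid(tp = tp_ok, tn = tn_ok)
  if (nrow(grid) > 1)
    warning(sprintf("%d candidate count pairs match; returning the first",
                    nrow(grid)))
  cm <- new_confusion(grid$tp[1], n_pos - grid$tp[1],
                      n_neg - grid$tn[1], grid$tn[1])
  if (nrow(grid) > 1) attr(cm, "candidates") <- grid
  cm
}
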