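#' Per-class confusion counts
#'
#' For each class `k`: `TP = #(true == k & pred == k)`,
#' `FP = #(true != k & pred == k)`, `FN = #(true == k & pred != k)`, and
#' `total = TP + FP + FN`. Every misclassified item contributes one FP (to
#' the predicted class) and one FN (to the true class), so the FP and FN
#' column sums are always equal.
#'
#' @param y_true,y_pred Label vectors of equal length.
#' @param labels Label universe; defaults to the sorted union of observed
#'   labels.
#' @return Data frame with columns `class`, `tp`, `fp`, `fn`, `total`.
#' @export
confusion_counts <- function(y_true, y_pred,
                             labels = sort(unique(c(y_true, y_pred)))) {
  if (length(y_true) != length(y_pred)) {
    stop_usage("y_true and y_pred must have equal length")
  }
  tp <- vapply(labels, function(k) sum(y_true == k & y_pred == k), numeric(1))
  fp <- vapply(labels, function(k) sum(y_true != k & y_pred == k), numeric(1))
  fn <- vapply(labels, function(k) sum(y_true == k & y_pred != k), numeric(1))
  data.frame(class = labels, tp = as.integer(tp), fp = as.integer(fp),
             fn = as.integer(fn), total = as.integer(tp + fp + fn))
}

#' Confusion-count metrics, on the percentage scale
#'
#' The four metrics derived from one class's (TP, FP, FN) triple:
#' `precision = 100 TP / (TP + FP)`, `recall = 100 TP / (TP + FN)`,
#' `f1 = 100 * 2 TP / (2 TP + FP + FN)`, and `accuracy_paper =
#' 100 TP / (TP + FP + FN)`. The last is the critical success index
#' (threat score), not standard accuracy, but it is the quantity reported
#' per class in this line of work, so it is exposed under an explicit name.
#' It never exceeds precision or recall (same numerator, larger
#' denominator).
#'
#' @param tp,fp,fn Non-negative integer counts, not all zero.
#' @return List with `accuracy_paper`, `precision`, `recall`, `f1`
#'   (percentages).
#' @export
paper_metrics <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) stop_usage("counts must be non-negative")
  if (tp + fp + fn == 0) stop_usage("all counts zero: metrics undefined")
  if (tp + fp == 0) stop_degenerate("precision undefined: TP + FP = 0")
  if (tp + fn == 0) stop_degenerate("recall undefined: TP + FN = 0")
  list(accuracy_paper = 100 * tp / (tp + fp + fn),
       precision = 100 * tp / (tp + fp),
       recall = 100 * tp / (tp + fn),
       f1 = 100 * 2 * tp / (2 * tp + fp + fn))
}

#' F1 score from precision and recall percentages
#' @param precision,recall Percentages in (0, 100].
#' @return Harmonic mean `2 P R / (P + R)`, a percentage.
#' @export
f1_from_pr <- function(precision, recall) {
  if (precision + recall == 0) stop_degenerate("P + R = 0: F1 undefined")
  2 * precision * recall / (precision + recall)
}

#' Per-class metric table with a micro-aggregated total row
#'
#' @param counts Data frame from [confusion_counts()].
#' @return Data frame with one row per class plus a `"Total"` row whose
#'   metrics are computed from the summed counts.
#' @export
metrics_table <- function(counts) {
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    m <- paper_metrics(counts$tp[i], counts$fp[i], counts$fn[i])
    data.frame(class = as.character(counts$class[i]), tp = counts$tp[i],
               fp = counts$fp[i], fn = counts$fn[i], total = counts$total[i],
               accuracy = m$accuracy_paper, precision = m$precision,
               recall = m$recall, f1 = m$f1)
  })
  tot <- paper_metrics(sum(counts$tp), sum(counts$fp), sum(counts$fn))
  rows[[length(rows) + 1L]] <- data.frame(
    class = "Total", tp = sum(counts$tp), fp = sum(counts$fp),
    fn = sum(counts$fn), total = sum(counts$total),
    accuracy = tot$accuracy_paper, precision = tot$precision,
    recall = tot$recall, f1 = tot$f1)
  do.call(rbind, rows)
}

#' Pearson chi-square test of independence
#'
#' `X^2 = sum (O - E)^2 / E` with `E = row_total * col_total / N`,
#' `df = (R - 1)(C - 1)`, no continuity correction; the p-value is the
#' upper tail of the chi-square distribution.
#'
#' @param table Matrix (or data frame) of non-negative integer counts,
#'   e.g. maneuver classes x test group.
#' @return List with `statistic`, `df`, `p`, `expected`.
#' @export
chi_square_independence <- function(table) {
  O <- as.matrix(table)
  if (any(O < 0)) stop_usage("counts must be non-negative")
  rs <- rowSums(O); cs <- colSums(O); N <- sum(O)
  if (any(rs == 0) || any(cs == 0)) {
    stop_degenerate("zero row or column margin: expected counts undefined")
  }
  E <- outer(rs, cs) / N
  stat <- sum((O - E)^2 / E)
  df <- (nrow(O) - 1L) * (ncol(O) - 1L)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE), expected = E)
}

#' Upper-alpha critical value of the chi-square distribution
#' @param alpha Significance level in (0, 1).
#' @param df Degrees of freedom, >= 1.
#' @return The upper-`alpha` quantile.
#' @export
chi_square_critical <- function(alpha, df) {
  if (alpha <= 0 || alpha >= 1) stop_usage("alpha must be in (0, 1)")
  if (df < 1) stop_usage("df must be >= 1")
  stats::qchisq(alpha, df, lower.tail = FALSE)
}

#' Mann-Whitney U test
#'
#' `U_a` is computed from the rank sum of sample `a` using midranks for
#' ties. With `n_a + n_b <= 16` and no ties the p-value is exact, by full
#' enumeration of the rank assignments; otherwise a normal approximation
#' with tie correction and continuity correction is used. The `method`
#' field records which route was taken. `alternative = "less"` tests
#' whether `a` tends to be smaller than `b`.
#'
#' @param a,b Non-empty numeric samples.
#' @param alternative `"two_sided"`, `"less"` or `"greater"`.
#' @return List with `U` (of sample `a`), `U_b`, `p`, `method`,
#'   `alternative`.
#' @export
mann_whitney_u <- function(a, b,
                           alternative = c("two_sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (!length(a) || !length(b)) stop_usage("both samples must be non-empty")
  na <- length(a); nb <- length(b); N <- na + nb
  comb <- c(a, b)
  r <- rank(comb)  # midranks for ties
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  has_ties <- anyDuplicated(comb) > 0
  if (N <= 16 && !has_ties) {
    # Exact null distribution: U for every way the na ranks of `a` could
    # fall among the N ranks.
    sets <- utils::combn(N, na)  # with no ties the positions are the ranks
    u_all <- colSums(sets) - na * (na + 1) / 2
    p <- switch(alternative,
                less = mean(u_all <= U),
                greater = mean(u_all >= U),
                two_sided = min(1, 2 * min(mean(u_all <= U), mean(u_all >= U))))
    method <- "exact_enumeration"
  } else {
    mu <- na * nb / 2
    ties <- table(comb)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma <- sqrt(na * nb / 12 * ((N + 1) - tie_term))
    if (sigma == 0) stop_degenerate("all observations tied: U degenerate")
    p <- switch(alternative,
                less = stats::pnorm((U - mu + 0.5) / sigma),
                greater = stats::pnorm((U - mu - 0.5) / sigma,
                                       lower.tail = FALSE),
                two_sided = min(1, 2 * stats::pnorm(
                  (abs(U - mu) - 0.5) / sigma, lower.tail = FALSE)))
    method <- "normal_approximation"
  }
  list(U = U, U_b = na * nb - U, p = p, method = method,
       alternative = alternative)
}

#' ROC curve and area under it
#'
#' The curve is built by sweeping a decision threshold over the unique
#' scores (predicting positive when `score >= threshold`); the AUC is the
#' trapezoid area, which equals the pair-counting estimator with ties
#' counted one half.
#'
#' @param scores Numeric scores, higher meaning more likely positive.
#' @param labels Binary ground truth (logical, 0/1, or a two-level factor
#'   whose larger level is positive).
#' @return List of class `psm_roc` with `points` (data frame `threshold`,
#'   `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) {
    stop_usage("scores and labels must have equal length")
  }
  if (anyNA(scores) || anyNA(labels)) stop_usage("missing values not allowed")
  if (!any(labels) || all(labels)) {
    stop_degenerate("both label values must be present")
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(s) mean(scores[labels] >= s), numeric(1))
  fpr <- vapply(thr, function(s) mean(scores[!labels] >= s), numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
                 auc = auc),
            class = "psm_roc")
}
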