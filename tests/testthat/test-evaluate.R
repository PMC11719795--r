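table2 <- read.csv(extdata("class_confusion_counts.csv"))
table3 <- read.csv(extdata("grade_metrics_by_class.csv"))
table1 <- read.csv(extdata("class_distribution_by_group.csv"))

test_that("confusion counts follow the per-class TP/FP/FN definitions", {
  eq <- confusion_counts(c(1, 2, 3), c(1, 2, 3))
  expect_true(all(eq$fp == 0) && all(eq$fn == 0))

  toy <- confusion_counts(c(1, 1, 2), c(1, 2, 2))
  expect_equal(toy[toy$class == 1, c("tp", "fp", "fn")],
               data.frame(tp = 1L, fp = 0L, fn = 1L), ignore_attr = TRUE)
  expect_equal(toy[toy$class == 2, c("tp", "fp", "fn")],
               data.frame(tp = 1L, fp = 1L, fn = 0L), ignore_attr = TRUE)

  set.seed(23)
  yt <- sample(1:8, 200, replace = TRUE)
  yp <- sample(1:8, 200, replace = TRUE)
  cc <- confusion_counts(yt, yp, labels = 1:8)
  expect_equal(sum(cc$fp), sum(cc$fn))  # every miss is one FP and one FN
  expect_equal(sum(cc$tp) + sum(cc$fn), 200)
  expect_error(confusion_counts(1:3, 1:4), class = "psm_usage_error")
})

test_that("metric formulas reproduce every published per-class cell", {
  for (i in seq_len(nrow(table2))) {
    m <- paper_metrics(table2$tp[i], table2$fp[i], table2$fn[i])
    expect_equal(m$accuracy_paper, table2$accuracy[i], tolerance = 5e-4)
    expect_equal(m$precision, table2$precision[i], tolerance = 1e-8)
    expect_equal(m$recall, table2$recall[i], tolerance = 1e-8)
    expect_equal(m$f1, table2$f1[i], tolerance = 1e-7)
  }
  tot <- paper_metrics(sum(table2$tp), sum(table2$fp), sum(table2$fn))
  expect_equal(round(tot$accuracy_paper, 1), 94.7)
  expect_equal(tot$precision, 98.00664452, tolerance = 1e-8)
  expect_equal(tot$recall, 96.56301146, tolerance = 1e-8)
  expect_equal(tot$f1, 97.2794724, tolerance = 1e-7)

  m1 <- paper_metrics(1, 0, 0)
  expect_equal(unlist(m1), c(accuracy_paper = 100, precision = 100,
                             recall = 100, f1 = 100))
  expect_error(paper_metrics(0, 0, 0), class = "psm_usage_error")
  expect_error(paper_metrics(0, 0, 3), class = "psm_degenerate_error")
})

test_that("metrics_table micro-aggregation reproduces the published total row", {
  mt <- metrics_table(table2[, c("class", "tp", "fp", "fn", "total")])
  tot <- mt[mt$class == "Total", ]
  expect_equal(tot$tp, 590)
  expect_equal(tot$fp, 12)
  expect_equal(tot$fn, 21)
  expect_equal(round(tot$accuracy, 1), 94.7)
  expect_equal(tot$f1, 97.2794724, tolerance = 1e-7)
})

test_that("F1 from precision/recall reproduces the published grade table", {
  for (i in seq_len(nrow(table3))) {
    expect_equal(f1_from_pr(table3$precision[i], table3$recall[i]),
                 table3$f1[i], tolerance = 1e-7)
  }
  expect_equal(f1_from_pr(100, 100), 100)
  expect_error(f1_from_pr(0, 0), class = "psm_degenerate_error")
})

test_that("f1 equals the harmonic mean of the triple-derived precision/recall", {
  set.seed(24)
  for (i in 1:25) {
    tp <- sample(1:200, 1); fp <- sample(0:50, 1); fn <- sample(0:50, 1)
    m <- paper_metrics(tp, fp, fn)
    expect_equal(f1_from_pr(m$precision, m$recall), m$f1, tolerance = 1e-10)
    expect_lte(m$accuracy_paper, min(m$precision, m$recall) + 1e-12)
  }
})

test_that("chi-square independence reproduces the published statistic", {
  res <- chi_square_independence(as.matrix(table1[, c("control", "standardized")]))
  expect_equal(res$statistic, 62.17213413, tolerance = 1e-6 / 62)
  expect_equal(res$df, 7L)
  expect_lt(res$p, 0.00001)
  expect_gt(res$statistic, chi_square_critical(0.05, res$df))
})

test_that("chi-square matches the textbook E-matrix oracle and chisq.test", {
  flat <- chi_square_independence(matrix(10, 2, 2))
  expect_equal(flat$statistic, 0)

  set.seed(25)
  for (i in 1:10) {
    tab <- matrix(rpois(9, 20) + 1, 3, 3)
    res <- chi_square_independence(tab)
    # independent textbook summation
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    stat <- 0
    for (r in 1:3) for (cc in 1:3) stat <- stat + (tab[r, cc] - E[r, cc])^2 / E[r, cc]
    expect_equal(res$statistic, stat, tolerance = 1e-10)
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res$p, ref$p.value, tolerance = 1e-10)
    # permutation invariance over row order
    perm <- sample(3)
    expect_equal(chi_square_independence(tab[perm, ])$statistic,
                 res$statistic, tolerance = 1e-12)
  }
  expect_error(chi_square_independence(matrix(c(0, 0, 1, 2), 2, 2)),
               class = "psm_degenerate_error")
})

test_that("chi-square critical values match published and inverted values", {
  expect_equal(round(chi_square_critical(0.05, 7), 3), 14.067)
  expect_equal(round(chi_square_critical(0.05, 1), 4), 3.8415)
  expect_gt(chi_square_critical(0.01, 7), chi_square_critical(0.05, 7))
  # numerical inversion oracle: upper-tail CDF at the quantile equals alpha
  expect_equal(pchisq(chi_square_critical(0.05, 7), 7, lower.tail = FALSE), 0.05)
  expect_error(chi_square_critical(1.5, 7), class = "psm_usage_error")
})

test_that("Mann-Whitney exact route matches enumeration and wilcox.test", {
  res <- mann_whitney_u(c(1, 2), c(3, 4), alternative = "less")
  expect_equal(res$U, 0)
  expect_equal(res$p, 1 / 6)
  expect_equal(res$method, "exact_enumeration")
  ref <- wilcox.test(c(1, 2), c(3, 4), alternative = "less", exact = TRUE)
  expect_equal(res$p, ref$p.value)

  set.seed(26)
  for (i in 1:10) {
    a <- rnorm(sample(2:8, 1)); b <- rnorm(sample(2:8, 1))
    res <- mann_whitney_u(a, b, "two_sided")
    expect_equal(res$U + res$U_b, length(a) * length(b))
    if (res$method == "exact_enumeration") {
      ref <- wilcox.test(a, b, exact = TRUE)
      expect_equal(res$U, unname(ref$statistic))
      expect_equal(res$p, ref$p.value, tolerance = 1e-12)
    }
  }
})

test_that("Mann-Whitney large-sample route applies tie and continuity corrections", {
  set.seed(27)
  a <- round(rnorm(40, 0, 2)); b <- round(rnorm(45, 0.5, 2))  # ties by rounding
  res <- mann_whitney_u(a, b, "two_sided")
  expect_equal(res$method, "normal_approximation")
  ref <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(res$U, unname(ref$statistic))
  expect_equal(res$p, ref$p.value, tolerance = 1e-10)
  expect_error(mann_whitney_u(numeric(), b), class = "psm_usage_error")
})

test_that("ROC/AUC matches conventions and the pair-counting oracle", {
  perfect <- roc_auc(c(0.1, 0.2, 0.8, 0.9), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(perfect$auc, 1.0)
  ties <- roc_auc(rep(0.5, 10), rep(c(TRUE, FALSE), 5))
  expect_equal(ties$auc, 0.5)
  expect_error(roc_auc(1:4, rep(TRUE, 4)), class = "psm_degenerate_error")

  set.seed(28)
  scores <- rnorm(100); labels <- runif(100) < 0.4
  got <- roc_auc(scores, labels)$auc
  pos <- scores[labels]; neg <- scores[!labels]
  pairs <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  expect_equal(got, mean(pairs), tolerance = 1e-12)
  # complement identity for tie-free scores
  expect_equal(roc_auc(-scores, labels)$auc + got, 1, tolerance = 1e-12)
})

test_that("trapezoid AUC agrees with pROC on random data", {
  skip_if_not_installed("pROC")
  set.seed(29)
  scores <- rnorm(80); labels <- runif(80) < 0.5
  ref <- suppressMessages(pROC::auc(pROC::roc(
    labels, scores, quiet = TRUE, levels = c(FALSE, TRUE), direction = "<")))
  expect_equal(roc_auc(scores, labels)$auc, as.numeric(ref), tolerance = 1e-12)
})
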