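test_that("accessible-window sampling is contained, seeded and uniform", {
  acc <- GRanges("chr1", IRanges(c(1001, 9001), width = 2099))
  win <- sampleAccessibleWindows(acc, n = 500, width = 100, seed = 3)
  expect_length(win, 500L)
  expect_true(all(width(win) == 100))
  expect_true(all(countOverlaps(win, acc, type = "within") == 1))

  win2 <- sampleAccessibleWindows(acc, n = 500, width = 100, seed = 3)
  expect_identical(start(win), start(win2))

  # chi-square sanity: starts split evenly across two equal intervals
  big <- sampleAccessibleWindows(acc, n = 10000, width = 100, seed = 5)
  counts <- table(start(big) >= 9001)
  expect_gt(stats::chisq.test(as.numeric(counts))$p.value, 1e-3)

  tiny <- GRanges("chr1", IRanges(1, 50))
  expect_error(sampleAccessibleWindows(tiny, 10, width = 100), "too small")
})

test_that("fractionBelow counts strict exceedances", {
  expect_equal(fractionBelow(c(0.1, 0.1, 0.3, 0.1), 0.2), 0.75)
  expect_equal(fractionBelow(c(0.5, 0.9), 0.2), 0)
  set.seed(13)
  for (i in 1:5) {
    x <- runif(200)
    expect_equal(fractionBelow(x, 0.4), sum(x < 0.4) / 200)
  }
  expect_error(fractionBelow(numeric(0)), "no scores")
})

test_that("ROC sweep matches the all-pairs oracle and handles ties", {
  expect_equal(rocCurve(c(2, 3), c(0, 1))$auc, 1.0)
  same <- c(1, 2, 3, 4)
  expect_equal(rocCurve(same, same)$auc, 0.5)
  expect_equal(rocCurve(c(3, 1), c(2, 0))$auc, 0.75)

  # all-pairs comparison oracle (ties count one half) on random scores
  set.seed(17)
  for (i in 1:8) {
    pos <- sample(1:10, 30, replace = TRUE) + rnorm(30, 0, 0.01 * (i %% 2))
    neg <- sample(1:10, 40, replace = TRUE)
    oracle <- mean(outer(pos, neg, function(a, b)
      (a > b) + 0.5 * (a == b)))
    expect_equal(rocCurve(pos, neg)$auc, oracle)
  }

  r <- rocCurve(rnorm(50), rnorm(50))
  expect_true(all(diff(r$fpr) >= 0))
  expect_true(all(diff(r$tpr) >= 0))
  expect_equal(c(r$fpr[1], r$tpr[1]), c(0, 0))
  expect_equal(c(r$fpr[length(r$fpr)], r$tpr[length(r$tpr)]), c(1, 1))
})

test_that("ROC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(19)
  pos <- rnorm(80, 1)
  neg <- rnorm(120)
  ref <- suppressMessages(pROC::auc(pROC::roc(
    response = rep(c(1, 0), c(80, 120)), predictor = c(pos, neg),
    direction = "<", quiet = TRUE)))
  expect_equal(rocCurve(pos, neg)$auc, as.numeric(ref))
})

test_that("rank-sum test matches the exhaustive permutation oracle", {
  expect_equal(wilcoxonRankSum(1, 1)$p.value, 1)

  # x={1,2,3}, y={4,5,6}: one extreme assignment each tail of C(6,3)=20
  res <- wilcoxonRankSum(1:3, 4:6)
  expect_equal(res$p.value, 0.1)
  expect_equal(res$statistic, 0)

  # exhaustive permutation oracle on a random tie-free sample
  set.seed(23)
  x <- rnorm(4); y <- rnorm(5)
  W <- wilcoxonRankSum(x, y)$statistic
  pooled <- c(x, y)
  combs <- utils::combn(9, 4)
  stats <- apply(combs, 2, function(ix)
    sum(rank(pooled)[ix]) - 4 * 5 / 2)
  pOracle <- mean(abs(stats - 10) >= abs(W - 10))  # center 4*5/2 = 10
  expect_equal(wilcoxonRankSum(x, y)$p.value, pOracle)

  # statistic is invariant under monotone transforms of the pooled data
  expect_equal(wilcoxonRankSum(exp(x), exp(y))$statistic, W)
})

test_that("Spearman correlation is Pearson on mid-ranks", {
  x <- c(1, 3, 5, 7, 11)
  expect_equal(spearmanCor(x, x^3 + 2)$rho, 1)
  expect_equal(spearmanCor(x, rev(x))$rho, -1)

  # tied vector against the mid-rank formula
  a <- c(1, 2, 2, 4, 5, 5, 5)
  b <- c(3, 1, 4, 4, 6, 2, 7)
  expect_equal(spearmanCor(a, b)$rho,
               stats::cor(rank(a), rank(b)))
})

test_that("Fisher overlap matches the dhyper summation oracle", {
  mkwin <- function(n, offset = 0)
    GRanges("chr1", IRanges(seq(1 + offset, by = 200, length.out = n),
                            width = 100))
  feat <- function(wins, which)
    GRanges(rep("chr1", length(which)),
            IRanges(start(wins)[which] + 50, width = 6))

  # balanced 2x2 table -> p = 1
  a <- mkwin(10); b <- mkwin(10, offset = 5000)
  f <- c(feat(a, 1:5), feat(b, 1:5))
  res <- fisherOverlap(a, f, b)
  expect_equal(res$p.value, 1.0)

  # [[10,0],[0,10]] -> two-sided p = 2 / C(20,10)
  res2 <- fisherOverlap(a, feat(a, 1:10), b)
  expect_equal(res2$p.value, 2 / choose(20, 10))
  expect_equal(unname(res2$table[1, ]), c(10, 0))

  # dhyper summation oracle on random tables
  set.seed(29)
  for (i in 1:6) {
    na <- sample(5:12, 1); nb <- sample(5:12, 1)
    ka <- sample(0:na, 1); kb <- sample(0:nb, 1)
    if ((ka + kb) %in% c(0, na + nb)) next
    a <- mkwin(na); b <- mkwin(nb, offset = 10000)
    f <- c(feat(a, seq_len(ka)), feat(b, seq_len(kb)))
    got <- fisherOverlap(a, f, b)$p.value
    k <- ka + kb
    probs <- stats::dhyper(0:k, na, nb, k)
    oracle <- sum(probs[probs <= stats::dhyper(ka, na, nb, k) * (1 + 1e-7)])
    expect_equal(got, oracle, tolerance = 1e-8)
  }

  # planted enrichment: p decreases monotonically with problem size
  ps <- vapply(c(8, 16, 32), function(n) {
    a <- mkwin(n); b <- mkwin(n, offset = 1e5)
    fisherOverlap(a, feat(a, seq_len(n)), b)$p.value
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("log-binned boxplot summaries use type-7 quartiles", {
  one <- logBinSummary(c(1, 2, 3, 4, 5), nBins = 1L)
  expect_equal(nrow(one), 1L)
  expect_equal(one$q1, 2)
  expect_equal(one$median, 3)
  expect_equal(one$q3, 4)
  expect_equal(one$whiskerLo, 1)
  expect_equal(one$whiskerHi, 5)
  expect_length(one$outliers[[1]], 0L)

  eq <- logBinSummary(rep(7, 20), nBins = 3L)
  expect_equal(eq$q1, eq$q3)
  expect_length(eq$outliers[[1]], 0L)

  # an extreme value beyond Q3 + 1.5 IQR is flagged, whisker stops short
  vals <- c(1, 2, 3, 4, 100)
  out <- logBinSummary(rep(10, 5), values = vals, nBins = 1L)
  expect_equal(out$outliers[[1]], 100)
  expect_equal(out$whiskerHi, 4)
})

test_that("expression rank distributions measure uniformity in the top set", {
  tb <- data.frame(gene = sprintf("g%04d", 1:2000),
                   level = sort(rlnorm(2000, 3, 1.6), decreasing = TRUE))
  # evenly spaced subset: KS statistic near 0
  even <- tb$gene[seq(50, 1000, by = 50)]
  resEven <- expressionRankDistribution(even, tb, topN = 1000)
  expect_lt(resEven$statistic, 0.08)

  # top-10 subset: closed-form ECDF gap 1 - 10/topN
  top10 <- tb$gene[1:10]
  resTop <- expressionRankDistribution(top10, tb, topN = 1000)
  expect_equal(resTop$statistic, 1 - 10 / 1000, tolerance = 0.01)

  # ranks invariant to monotone rescaling of expression
  tb2 <- tb; tb2$level <- log(tb2$level + 1)
  expect_equal(expressionRankDistribution(even, tb2, topN = 1000)$ranks,
               resEven$ranks)

  expect_error(expressionRankDistribution("absent", tb, 1000), "no subset")
})
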