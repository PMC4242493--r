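test_that("profiles tabulate strand-oriented windows around the TSS", {
  # single gene, single fragment: profile is that fragment's indicator
  frag <- GRanges("chr1", IRanges(5000, 5199))
  seqlengths(frag) <- c(chr1 = 20000)
  tr <- baseCoverage(frag)
  p <- metageneProfile(tr, makeTss(5000, "+", seqlen = 20000),
                       halfWindow = 1000)
  v <- profileValues(p)
  off <- profileOffsets(p)
  expect_length(v, 2000L)
  expect_equal(off, -1000:999)
  expect_equal(v[off >= 0 & off <= 199], rep(1, 200))
  expect_equal(sum(v), 200)

  expect_error(metageneProfile(tr, makeTss(integer(0), seqlen = 20000),
                               1000), "empty")
  expect_error(metageneProfile(binCoverage(frag, 25L),
                               makeTss(5000, seqlen = 20000), 1000),
               "base-resolution")
})

test_that("opposite-strand genes with mirror signal contribute identically", {
  # + gene with signal 300 bp downstream; - gene with signal 300 bp
  # upstream in genome coordinates (= downstream on its own strand)
  frags <- GRanges("chr1", IRanges(c(5300, 14501), width = 200))
  seqlengths(frags) <- c(chr1 = 20000)
  tr <- baseCoverage(frags)
  pPlus <- metageneProfile(tr, makeTss(5000, "+", seqlen = 20000), 1000)
  pMinus <- metageneProfile(tr, makeTss(15000, "-", seqlen = 20000), 1000)
  expect_equal(profileValues(pPlus), profileValues(pMinus))
  peak <- profileOffsets(pMinus)[which.max(profileValues(pMinus))]
  expect_gt(peak, 0)
})

test_that("floor subtraction removes the lowest-decile mean and clamps", {
  const <- MetageneProfile(-50:49, rep(3.2, 100), 1L)
  expect_equal(profileValues(subtractFloor(const)), rep(0, 100))

  # 20,000 points whose lowest 2,000 average 5: every value drops by 5
  set.seed(8)
  base <- c(rep(5, 2000), runif(18000, 6, 50))
  prof <- MetageneProfile(-10000:9999, sample(base), 10L)
  fl <- subtractFloor(prof)
  expect_equal(profileValues(fl), pmax(profileValues(prof) - 5, 0))

  # profile whose lowest decile is exactly zero is unchanged
  tail0 <- MetageneProfile(1:100, c(rep(0, 10), rep(2, 90)), 1L)
  expect_equal(profileValues(subtractFloor(tail0)),
               c(rep(0, 10), rep(2, 90)))
})

test_that("area normalization gives unit area and fixed operation order", {
  p <- MetageneProfile(1:50, runif(50, 1, 4), 1L)
  expect_equal(sum(profileValues(areaNormalize(p))), 1)
  p2 <- MetageneProfile(1:50, 7 * profileValues(p), 1L)
  expect_equal(profileValues(areaNormalize(p)),
               profileValues(areaNormalize(p2)))
  expect_error(areaNormalize(MetageneProfile(1:10, rep(0, 10), 1L)), "area")

  # floor-then-normalize differs from normalize-then-floor
  q <- MetageneProfile(1:100, c(rep(1, 50), rep(11, 50)), 1L)
  a <- profileValues(areaNormalize(subtractFloor(q)))
  b <- profileValues(subtractFloor(areaNormalize(q)))
  expect_false(isTRUE(all.equal(a, b)))
})

test_that("combined profiles sum position-wise", {
  p <- areaNormalize(MetageneProfile(1:20, runif(20, 0.1, 1), 5L))
  expect_equal(profileValues(combineProfiles(list(p))), profileValues(p))
  three <- combineProfiles(list(p, p, p))
  expect_equal(profileValues(three), 3 * profileValues(p))
  expect_equal(sum(profileValues(three)), 3)
  q <- MetageneProfile(1:21, runif(21), 1L)
  expect_error(combineProfiles(list(p, q)), "offsets")
})

test_that("heatmap rows follow the ranking track, ties by gene id", {
  sl <- 20000
  # gene1 strong, gene2 weak in the rank track
  rankFr <- GRanges("chr1", IRanges(c(5000, 5050, 5100, 15000), width = 100))
  seqlengths(rankFr) <- c(chr1 = sl)
  rankTr <- baseCoverage(rankFr)
  otherTr <- baseCoverage(rankFr[4])
  tss <- makeTss(c(5100, 15050), "+", gene = c("g1", "g2"), seqlen = sl)
  hm <- heatmapMatrix(list(rank = rankTr, other = otherTr), tss, "rank",
                      halfWindow = 500)
  expect_equal(rownames(hm$rank), c("g1", "g2"))
  expect_equal(rownames(hm$other), c("g1", "g2"))
  expect_equal(dim(hm$rank), c(2L, 1000L))

  # tie in rank sums -> stable order by gene id
  tie <- makeTss(c(5100, 5100), "+", gene = c("zz", "aa"), seqlen = sl)
  hmTie <- heatmapMatrix(list(rank = rankTr), tie, "rank", 500)
  expect_equal(rownames(hmTie$rank), c("aa", "zz"))

  # ranking is invariant to RPM scaling of the rank track
  rpm <- normalizeRpm(methods::initialize(rankTr, totalReads = 4))
  hmRpm <- heatmapMatrix(list(rank = rpm), tss, "rank", 500)
  expect_equal(rownames(hmRpm$rank), rownames(hm$rank))

  expect_error(heatmapMatrix(list(a = rankTr), tss, "nope", 500), "unknown")
})

test_that("planted factor offsets are recovered in the right order", {
  g <- generateGenome(genomeSpec(1, 4e5, 0.45, seed = 15))
  tss <- makeTss(seq(20000, 380000, by = 9000),
                 rep_len(c("+", "-"), 41), seqlen = 4e5)
  offs <- c(polii = 83, myc = -20, max = -35)
  rec <- vapply(names(offs), function(nm) {
    pr <- factorProfile(nm, offs[[nm]], 40, readsPerTss = 500L,
                        backgroundReads = 1000L)
    rd <- simulateChipReads(tss, pr, g, seed = 100 + offs[[nm]])
    tr <- baseCoverage(extendReads(rd), totalReads = length(rd))
    p <- metageneProfile(tr, tss, 4000)
    profileOffsets(p)[which.max(profileValues(p))]
  }, numeric(1))
  expect_lt(max(abs(rec - offs)), 15)
  expect_true(rec[["max"]] < rec[["myc"]] &&
              rec[["myc"]] < 0 && 0 < rec[["polii"]])
})
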