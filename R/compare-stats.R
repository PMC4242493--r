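#' Sample fixed-width windows from accessible DNA
#'
#' Draws \code{n} windows of width \code{width}, fully inside the supplied
#' accessible intervals, uniformly over all eligible start positions
#' (with replacement).
#'
#' @param accessible \code{GRanges} of accessible (e.g. DNase I sensitive)
#'   intervals.
#' @param n number of windows.
#' @param width window width in bp.
#' @param seed RNG seed.
#' @return \code{GRanges} of sampled windows.
#' @export
sampleAccessibleWindows <- function(accessible, n = 30000L, width = 100L,
                                    seed = 1L) {
  wints <- GenomicRanges::width(accessible)
  elig <- wints - width + 1L
  ok <- which(elig >= 1L)
  if (!length(ok))
    stop("accessible span too small for the requested window width",
         call. = FALSE)
  .with_seed(seed, {
    pick <- sample(ok, n, replace = TRUE, prob = elig[ok])
    off <- floor(runif(n) * elig[pick])
    GenomicRanges::GRanges(GenomicRanges::seqnames(accessible)[pick],
      IRanges::IRanges(GenomicRanges::start(accessible)[pick] + off,
                       width = width))
  })
}

#' Score regions by their best 8-mer in vitro occupancy
#'
#' Applies the \code{\link{best8merInWindow}} scan to the center of each
#' region (for width-1 peak summits: the summit), in one vectorized pass.
#'
#' @param regions \code{GRanges} of regions or peak summits; a
#'   \code{height} metadata column, if present, is carried through.
#' @param genome \code{DNAStringSet}.
#' @param table an \code{\linkS4class{EightMerTable}}.
#' @param halfWidth scan half-width in bp around each region center.
#' @return data.frame with columns \code{chrom}, \code{center},
#'   \code{height} (NA when absent) and \code{occupancy}.
#' @export
scoreRegions <- function(regions, genome, table, halfWidth = 50L) {
  stopifnot(is(regions, "GRanges"))
  sl <- .seq_lengths(genome)
  chrom <- as.character(GenomicRanges::seqnames(regions))
  center <- (GenomicRanges::start(regions) + GenomicRanges::end(regions)) %/% 2L
  s <- pmax(center - halfWidth, 1L)
  e <- pmin(center + halfWidth - 1L, sl[chrom])
  if (any(e - s + 1L < 8L))
    stop("window shorter than 8 bases", call. = FALSE)
  occ <- rep(NA_real_, length(regions))
  tb <- kmerTable(table)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    wins <- as.character(Biostrings::DNAStringSet(
      Biostrings::Views(genome[[ch]], s[i], e[i])))
    nk <- nchar(wins) - 7L
    winIdx <- rep(seq_along(wins), nk)
    starts <- unlist(lapply(nk, seq_len))
    kmers <- substring(wins[winIdx], starts, starts + 7L)
    valid <- grepl("^[ACGT]{8}$", kmers)
    kocc <- rep(NA_real_, length(kmers))
    if (any(valid))
      kocc[valid] <- tb$occupancy[match(.canonical_kmer(kmers[valid]),
                                        tb$kmer)]
    best <- tapply(kocc, winIdx, function(x)
      if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
    occ[i[as.integer(names(best))]] <- as.numeric(best)
  }
  h <- S4Vectors::mcols(regions)$height
  data.frame(chrom = chrom, center = center,
             height = if (is.null(h)) NA_real_ else h,
             occupancy = occ, stringsAsFactors = FALSE)
}

#' Fraction of scores below a cutoff
#'
#' @param scores numeric vector (non-empty).
#' @param cutoff threshold; values strictly below count.
#' @return \code{count(score < cutoff) / n}.
#' @export
fractionBelow <- function(scores, cutoff = 0.2) {
  scores <- scores[!is.na(scores)]
  if (!length(scores)) stop("no scores", call. = FALSE)
  mean(scores < cutoff)
}

#' ROC curve and AUC for a score separating two labeled sets
#'
#' Sweeps the distinct pooled scores as cutoffs (equal scores are one
#' cutoff), computing at each the true positive rate on
#' \code{scoresPos} and false positive rate on \code{scoresNeg} for the
#' rule score >= cutoff; AUC is the trapezoidal area, equal to the
#' all-pairs probability that a positive outscores a negative (ties count
#' one half).
#'
#' @param scoresPos,scoresNeg numeric scores of the positive and negative
#'   class (both non-empty).
#' @return list with \code{cutoffs}, \code{fpr}, \code{tpr} (monotone
#'   non-decreasing, from (0,0) to (1,1)) and \code{auc}.
#' @export
rocCurve <- function(scoresPos, scoresNeg) {
  stopifnot(length(scoresPos) > 0, length(scoresNeg) > 0)
  nP <- length(scoresPos); nN <- length(scoresNeg)
  all <- c(scoresPos, scoresNeg)
  lab <- rep(c(1L, 0L), c(nP, nN))
  o <- order(all, decreasing = TRUE)
  s <- all[o]; lab <- lab[o]
  last <- c(diff(s) != 0, TRUE)     # last index of each distinct score
  tp <- cumsum(lab)[last]
  fp <- cumsum(1L - lab)[last]
  tpr <- c(0, tp / nP)
  fpr <- c(0, fp / nN)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(cutoffs = c(Inf, s[last]), fpr = fpr, tpr = tpr, auc = auc)
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Thin wrapper over \code{stats::wilcox.test} (unpaired, two-sided):
#' exact for small tie-free samples, normal approximation with tie
#' correction otherwise.
#'
#' @param x,y numeric samples.
#' @return list with \code{statistic} (W) and \code{p.value}.
#' @export
wilcoxonRankSum <- function(x, y) {
  res <- suppressWarnings(stats::wilcox.test(x, y, paired = FALSE,
                                             alternative = "two.sided"))
  p <- res$p.value
  if (is.nan(p)) p <- 1  # degenerate: all pooled values tie (zero variance)
  list(statistic = unname(res$statistic), p.value = p)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks, with the p-value from the asymptotic
#' t approximation (appropriate in the presence of ties).
#'
#' @param x,y numeric vectors (length >= 3).
#' @return list with \code{rho} and \code{p.value}.
#' @export
spearmanCor <- function(x, y) {
  stopifnot(length(x) >= 3, length(x) == length(y))
  res <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                          exact = FALSE))
  list(rho = unname(res$estimate), p.value = res$p.value)
}

#' Fisher's exact test for feature enrichment in regions
#'
#' Builds the 2x2 table {query windows, background windows} x {contains at
#' least one feature site, none} and applies the two-sided hypergeometric
#' exact test (summing tables no more probable than the observed one).
#'
#' @param regionsA \code{GRanges} of query windows (e.g. peak windows).
#' @param featureSites \code{GRanges} of feature sites (e.g. CACGTG
#'   matches).
#' @param backgroundWindows \code{GRanges} of background windows of the
#'   same width.
#' @return list with \code{table} (2x2 matrix), \code{odds} and
#'   \code{p.value}.
#' @export
fisherOverlap <- function(regionsA, featureSites, backgroundWindows) {
  a1 <- sum(GenomicRanges::countOverlaps(regionsA, featureSites) > 0)
  a0 <- length(regionsA) - a1
  b1 <- sum(GenomicRanges::countOverlaps(backgroundWindows,
                                         featureSites) > 0)
  b0 <- length(backgroundWindows) - b1
  m <- matrix(c(a1, a0, b1, b0), nrow = 2,
              dimnames = list(c("with_feature", "without"),
                              c("regions", "background")))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    return(list(table = m, odds = NA_real_, p.value = 1))
  ft <- stats::fisher.test(m)
  list(table = m, odds = unname(ft$estimate), p.value = ft$p.value)
}

#' Boxplot summaries over log-scaled bins
#'
#' Groups observations into \code{nBins} equal-width bins in
#' \code{log(height)} and summarizes \code{values} per bin the way R's
#' default boxplot does: type-7 (linear interpolation) quartiles, median,
#' whiskers at the most extreme points within 1.5 x IQR beyond the box,
#' outliers listed.
#'
#' @param heights positive numeric vector defining the binning.
#' @param values numeric vector summarized per bin (defaults to
#'   \code{heights}).
#' @param nBins number of log-spaced bins.
#' @return data.frame, one row per non-empty bin, with columns \code{bin},
#'   \code{lo}, \code{hi} (height range), \code{n}, \code{q1},
#'   \code{median}, \code{q3}, \code{whiskerLo}, \code{whiskerHi} and an
#'   \code{outliers} list column.
#' @export
logBinSummary <- function(heights, values = heights, nBins = 10L) {
  stopifnot(all(heights > 0), length(heights) == length(values))
  lg <- log(heights)
  if (max(lg) == min(lg)) {
    br <- c(min(lg) - 0.5, max(lg) + 0.5)
  } else {
    br <- seq(min(lg), max(lg), length.out = nBins + 1L)
  }
  bin <- cut(lg, br, include.lowest = TRUE, labels = FALSE)
  rows <- lapply(sort(unique(bin)), function(b) {
    v <- values[bin == b]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    inlo <- v[v >= q[1] - 1.5 * iqr]
    inhi <- v[v <= q[3] + 1.5 * iqr]
    out <- v[v < q[1] - 1.5 * iqr | v > q[3] + 1.5 * iqr]
    data.frame(bin = b, lo = exp(br[b]), hi = exp(br[b + 1L]),
               n = length(v), q1 = q[1], median = q[2], q3 = q[3],
               whiskerLo = min(inlo), whiskerHi = max(inhi),
               outliers = I(list(out)))
  })
  do.call(rbind, rows)
}

#' Where does a gene subset fall within the top expressed genes?
#'
#' Ranks all genes by decreasing expression, restricts to the top
#' \code{topN}, extracts the ranks of the subset genes found there, and
#' measures departure from uniformity with the one-sample
#' Kolmogorov-Smirnov statistic of rank/topN against U(0, 1).
#'
#' @param geneSubset character vector of gene ids.
#' @param expressionTable data.frame with columns \code{gene},
#'   \code{level}.
#' @param topN size of the top-expressed universe.
#' @return list with \code{ranks}, \code{statistic} (KS D) and
#'   \code{p.value}.
#' @export
expressionRankDistribution <- function(geneSubset, expressionTable,
                                       topN = 12000L) {
  tb <- expressionTable[order(-expressionTable$level, expressionTable$gene), ]
  top <- utils::head(tb$gene, topN)
  ranks <- match(geneSubset, top)
  ranks <- sort(ranks[!is.na(ranks)])
  if (!length(ranks))
    stop("no subset gene found among the top expressed genes", call. = FALSE)
  u <- ranks / min(topN, nrow(tb))
  ks <- suppressWarnings(stats::ks.test(u, "punif"))
  list(ranks = ranks, statistic = unname(ks$statistic),
       p.value = ks$p.value)
}
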