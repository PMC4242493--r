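#' Extend single-end reads to fragment intervals
#'
#' A plus-strand read whose 5' end is stored at \code{s} becomes the
#' fragment \code{[s, s+L-1]}; a minus-strand read stored at \code{s}
#' extends leftward to \code{[s-L, s-1]} (1-based closed; equivalently
#' \code{[s, s+L)} and \code{[s-L, s)} in 0-based half-open coordinates).
#' Fragments are clipped to the chromosome when seqlengths are available.
#'
#' @param reads width-1 stranded \code{GRanges} of read 5'-end positions.
#' @param fragmentLength fragment length L in bp (> 0).
#' @return unstranded \code{GRanges} of fragment intervals.
#' @export
extendReads <- function(reads, fragmentLength = 200L) {
  stopifnot(fragmentLength > 0)
  L <- as.integer(fragmentLength)
  s <- GenomicRanges::start(reads)
  minus <- as.character(GenomicRanges::strand(reads)) == "-"
  fs <- ifelse(minus, s - L, s)
  fe <- ifelse(minus, s - 1L, s + L - 1L)
  sl <- GenomeInfoDb::seqlengths(reads)
  chrom <- as.character(GenomicRanges::seqnames(reads))
  fs <- pmax(fs, 1L)
  if (!any(is.na(sl))) fe <- pmin(fe, sl[chrom])
  keep <- fs <= fe
  gr <- GenomicRanges::GRanges(chrom[keep],
                               IRanges::IRanges(fs[keep], fe[keep]))
  GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(reads)
  if (!any(is.na(sl))) GenomeInfoDb::seqlengths(gr) <- sl
  gr
}

#' Bin fragment coverage
#'
#' Bins tile each chromosome from coordinate 0 in steps of \code{binWidth};
#' a bin's value is the number of fragments overlapping it (read-count
#' semantics, not a per-base mean).
#'
#' @param fragments \code{GRanges} of extended fragments (seqlengths set).
#' @param binWidth bin width in bp (>= 1).
#' @param totalReads read count stored in the track; defaults to the number
#'   of fragments.
#' @return a \code{\linkS4class{CoverageTrack}}.
#' @export
binCoverage <- function(fragments, binWidth = 25L,
                        totalReads = length(fragments)) {
  stopifnot(binWidth >= 1)
  w <- as.integer(binWidth)
  sl <- GenomeInfoDb::seqlengths(fragments)
  if (any(is.na(sl)))
    stop("fragments must carry seqlengths", call. = FALSE)
  nbins <- ceiling(sl / w)
  vals <- methods::as(stats::setNames(
    lapply(names(sl), function(chrom) {
      f <- fragments[GenomicRanges::seqnames(fragments) == chrom]
      if (length(f) == 0L)
        return(S4Vectors::Rle(0L, nbins[[chrom]]))
      b1 <- (GenomicRanges::start(f) - 1L) %/% w + 1L
      b2 <- (GenomicRanges::end(f) - 1L) %/% w + 1L
      IRanges::coverage(IRanges::IRanges(b1, b2), width = nbins[[chrom]])
    }), names(sl)), "RleList")
  CoverageTrack(vals, binWidth = w, totalReads = totalReads)
}

#' Base-resolution fragment coverage
#'
#' Equivalent to \code{binCoverage} at width 1: the value at a base is the
#' number of fragments covering it.
#'
#' @inheritParams binCoverage
#' @return a \code{\linkS4class{CoverageTrack}} with \code{binWidth = 1}.
#' @export
baseCoverage <- function(fragments, totalReads = length(fragments)) {
  sl <- GenomeInfoDb::seqlengths(fragments)
  if (any(is.na(sl)))
    stop("fragments must carry seqlengths", call. = FALSE)
  cov <- GenomicRanges::coverage(fragments)
  CoverageTrack(cov, binWidth = 1L, totalReads = totalReads)
}

#' Scale a track to reads per million
#'
#' @param track a \code{\linkS4class{CoverageTrack}} with
#'   \code{totalReads > 0}.
#' @return the track with values multiplied by \code{1e6 / totalReads} and
#'   the normalized flag set.
#' @export
normalizeRpm <- function(track) {
  stopifnot(is(track, "CoverageTrack"))
  tr <- totalReads(track)
  if (is.na(tr) || tr <= 0)
    stop("cannot normalize a track with zero or unknown total reads",
         call. = FALSE)
  methods::initialize(track, values = trackValues(track) * (1e6 / tr),
                      normalized = TRUE)
}

#' Differential occupancy track
#'
#' Each input is scaled so its total reads equal one million, then
#' subtracted bin-wise (\code{a - b}).  Tracks must share chromosomes and
#' bin width.
#'
#' @param a,b \code{\linkS4class{CoverageTrack}}s on the same genome and
#'   binning.
#' @return a \code{\linkS4class{DifferenceTrack}} (values may be negative).
#' @export
differenceTrack <- function(a, b) {
  stopifnot(is(a, "CoverageTrack"), is(b, "CoverageTrack"))
  if (binWidth(a) != binWidth(b) ||
      !identical(names(trackValues(a)), names(trackValues(b))) ||
      !identical(lengths(trackValues(a)), lengths(trackValues(b))))
    stop("tracks must share chromosomes, lengths and bin width",
         call. = FALSE)
  va <- if (isNormalized(a)) trackValues(a)
        else trackValues(a) * (1e6 / totalReads(a))
  vb <- if (isNormalized(b)) trackValues(b)
        else trackValues(b) * (1e6 / totalReads(b))
  DifferenceTrack(va - vb, binWidth = binWidth(a))
}
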