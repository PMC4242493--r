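#' Greedy summit peak calling with contributing-read heights
#'
#' Reads are extended to fragments and piled into base-resolution coverage.
#' Repeatedly, the genome-wide coverage maximum is taken as a summit (first
#' maximal plateau, midpoint; deterministic and independent of read input
#' order), the peak height is the number of fragments overlapping the
#' window summit +/- \code{fragmentLength/2} — contributing reads, not the
#' coverage value at the summit — those fragments are removed from the
#' pile, and the search repeats until the remaining coverage maximum falls
#' below \code{minHeight}.  Since every fragment covering the summit also
#' overlaps the window, each emitted peak has height >= \code{minHeight},
#' and each fragment contributes to at most one peak.
#'
#' @param reads width-1 stranded \code{GRanges} of read positions with
#'   seqlengths set.
#' @param minHeight minimum contributing-read count for a reported peak.
#' @param fragmentLength fragment extension in bp; also sets the
#'   contribution window (summit +/- \code{fragmentLength/2}).
#' @return \code{GRanges} of width-1 summits with a \code{height} metadata
#'   column, sorted by position.
#' @export
callPeaks <- function(reads, minHeight = 30L, fragmentLength = 200L) {
  frags <- extendReads(reads, fragmentLength)
  sl <- GenomeInfoDb::seqlengths(frags)
  half <- as.integer(fragmentLength) %/% 2L
  cov <- GenomicRanges::coverage(frags)
  fchrom <- as.character(GenomicRanges::seqnames(frags))
  fstart <- GenomicRanges::start(frags)
  fend <- GenomicRanges::end(frags)
  alive <- !logical(length(frags))
  chromMax <- vapply(cov, function(v) if (length(v)) max(v) else 0,
                     numeric(1))
  outChrom <- character(0); outPos <- integer(0); outH <- integer(0)
  repeat {
    M <- max(chromMax)
    if (M < minHeight) break
    chrom <- names(chromMax)[which(chromMax == M)[1]]
    v <- cov[[chrom]]
    rv <- S4Vectors::runValue(v); rl <- S4Vectors::runLength(v)
    r <- which(rv == M)[1]
    ends <- cumsum(rl)
    summit <- as.integer((ends[r] - rl[r] + 1L + ends[r]) %/% 2L)
    wlo <- summit - half; whi <- summit + half
    idx <- which(alive & fchrom == chrom & fstart <= whi & fend >= wlo)
    h <- length(idx)
    if (h < minHeight) break  # cannot occur while M >= minHeight
    outChrom <- c(outChrom, chrom)
    outPos <- c(outPos, summit)
    outH <- c(outH, h)
    alive[idx] <- FALSE
    removed <- IRanges::coverage(IRanges::IRanges(fstart[idx], fend[idx]),
                                 width = length(v))
    cov[[chrom]] <- v - removed
    chromMax[[chrom]] <- max(cov[[chrom]])
  }
  gr <- GenomicRanges::GRanges(outChrom,
                               IRanges::IRanges(outPos, width = 1L))
  S4Vectors::mcols(gr)$height <- outH
  GenomeInfoDb::seqlevels(gr) <- names(sl)
  GenomeInfoDb::seqlengths(gr) <- sl
  sort(gr)
}

#' Sequences flanking peak summits
#'
#' @param peaks width-1 \code{GRanges} of summits.
#' @param genome \code{DNAStringSet}.
#' @param flank bases retrieved on each side; the window is
#'   \code{[summit - flank, summit + flank)}, clipped at chromosome ends.
#' @return a \code{DNAStringSet}, one (uppercase) sequence per peak.
#' @export
peakSequences <- function(peaks, genome, flank = 50L) {
  sl <- .seq_lengths(genome)
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  if (any(!chrom %in% names(sl)))
    stop("peak on chromosome absent from genome", call. = FALSE)
  pos <- GenomicRanges::start(peaks)
  s <- pmax(pos - flank, 1L)
  e <- pmin(pos + flank - 1L, sl[chrom])
  seqs <- Biostrings::DNAStringSet(vapply(seq_along(peaks), function(i)
    toupper(as.character(Biostrings::subseq(genome[[chrom[i]]],
                                            s[i], e[i]))), character(1)))
  names(seqs) <- sprintf("%s:%d", chrom, pos)
  seqs
}

# greedy peak calling on an arbitrary-valued track: summit = first maximal
# plateau midpoint, height = track value there, window zeroed, repeat
.call_track_peaks <- function(track, minValue, window = 200L) {
  w <- binWidth(track)
  halfBins <- as.integer(ceiling(window / 2 / w))
  vals <- trackValues(track)
  chromMax <- vapply(vals, function(v) if (length(v)) max(v) else -Inf,
                     numeric(1))
  outChrom <- character(0); outPos <- integer(0); outH <- numeric(0)
  repeat {
    M <- max(chromMax)
    if (M < minValue) break
    chrom <- names(chromMax)[which(chromMax == M)[1]]
    v <- vals[[chrom]]
    rv <- S4Vectors::runValue(v); rl <- S4Vectors::runLength(v)
    r <- which(rv == M)[1]
    ends <- cumsum(rl)
    binMid <- as.integer((ends[r] - rl[r] + 1L + ends[r]) %/% 2L)
    pos <- (binMid - 1L) * w + (w + 1L) %/% 2L
    i1 <- max(binMid - halfBins, 1L); i2 <- min(binMid + halfBins, length(v))
    v[i1:i2] <- 0
    vals[[chrom]] <- v
    chromMax[[chrom]] <- max(v)
    outChrom <- c(outChrom, chrom)
    outPos <- c(outPos, pos)
    outH <- c(outH, M)
  }
  gr <- GenomicRanges::GRanges(outChrom, IRanges::IRanges(outPos, width = 1L))
  S4Vectors::mcols(gr)$height <- outH
  GenomeInfoDb::seqlevels(gr) <- names(vals)
  sort(gr)
}

#' Sites with more Max than Myc signal
#'
#' Both tracks are scaled to one million total reads and subtracted
#' (Max - Myc); peaks are then called greedily on the difference track,
#' with heights equal to the difference values (read identity is lost after
#' subtraction).  One peak set is returned per threshold; because the
#' greedy sweep is threshold-independent, peak sets at higher thresholds
#' are nested inside those at lower thresholds.
#'
#' @param maxTrack,mycTrack \code{\linkS4class{CoverageTrack}}s on the same
#'   genome and binning (typically 25-bp bins).
#' @param thresholds numeric vector of minimum difference values.
#' @param fragmentLength window (bp) blanked around each called summit.
#' @return named list (one element per threshold) of width-1 summit
#'   \code{GRanges} with difference-value heights.
#' @export
extraMaxPeaks <- function(maxTrack, mycTrack, thresholds = c(0.5, 1.0),
                          fragmentLength = 200L) {
  stopifnot(length(thresholds) >= 1L, all(thresholds > 0))
  d <- differenceTrack(maxTrack, mycTrack)
  all <- .call_track_peaks(d, min(thresholds), window = fragmentLength)
  out <- lapply(thresholds, function(t)
    all[S4Vectors::mcols(all)$height >= t])
  names(out) <- format(thresholds, trim = TRUE)
  out
}

#' Annotate peaks with the nearest TSS
#'
#' @param peaks width-1 summit \code{GRanges}.
#' @param tss width-1 \code{GRanges} with a \code{gene} column.
#' @param maxDist maximum summit-to-TSS distance in bp (inclusive).
#' @return data.frame with one row per peak: \code{chrom}, \code{summit},
#'   \code{gene} (NA when no TSS is within \code{maxDist}) and
#'   \code{distance}.  Equidistant ties resolve to the upstream (lower
#'   coordinate) TSS.
#' @export
nearestTssAnnotation <- function(peaks, tss, maxDist = 250L) {
  pchrom <- as.character(GenomicRanges::seqnames(peaks))
  ppos <- GenomicRanges::start(peaks)
  tchrom <- as.character(GenomicRanges::seqnames(tss))
  tpos <- GenomicRanges::start(tss)
  genes <- S4Vectors::mcols(tss)$gene
  gene <- rep(NA_character_, length(peaks))
  dist <- rep(NA_integer_, length(peaks))
  for (chrom in unique(pchrom)) {
    ti <- which(tchrom == chrom)
    pi <- which(pchrom == chrom)
    if (!length(ti)) next
    o <- ti[order(tpos[ti])]
    tp <- tpos[o]
    for (i in pi) {
      d <- abs(tp - ppos[i])
      j <- which(d == min(d))[1]  # sorted by position: first = upstream
      if (d[j] <= maxDist) {
        gene[i] <- genes[o[j]]
        dist[i] <- d[j]
      }
    }
  }
  data.frame(chrom = pchrom, summit = ppos, gene = gene, distance = dist,
             stringsAsFactors = FALSE)
}
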