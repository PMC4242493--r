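suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
  library(Biostrings)
})

# width-1 stranded reads with seqlengths, from 1-based 5'-end positions
makeReads <- function(pos, strand = "+", chrom = "chr1", seqlen = 1e5) {
  lv <- unique(chrom)
  gr <- GRanges(rep_len(chrom, length(pos)), IRanges(pos, width = 1L),
                strand = rep_len(strand, length(pos)))
  seqlevels(gr) <- lv
  seqlengths(gr) <- setNames(rep(seqlen, length(lv)), lv)
  gr
}

makeTss <- function(pos, strand = "+", gene = NULL, chrom = "chr1",
                    seqlen = 1e5) {
  lv <- unique(chrom)
  gr <- GRanges(rep_len(chrom, length(pos)), IRanges(pos, width = 1L),
                strand = rep_len(strand, length(pos)))
  mcols(gr)$gene <- if (is.null(gene)) sprintf("g%03d", seq_along(pos))
                    else gene
  seqlevels(gr) <- lv
  seqlengths(gr) <- setNames(rep(seqlen, length(lv)), lv)
  gr
}

# a CoverageTrack from explicit per-chromosome numeric vectors
makeTrack <- function(..., binWidth = 1L, totalReads = NA_real_,
                      normalized = FALSE) {
  vecs <- list(...)
  CoverageTrack(as(lapply(vecs, Rle), "RleList"), binWidth = binWidth,
                totalReads = totalReads, normalized = normalized)
}

# session-cached PBM tables (noisy and noise-free) built from the default
# planted model; building one takes ~2 s so tests share them
.fixture_env <- new.env()
plantedPbmTable <- function(noise = FALSE) {
  key <- if (noise) "noisy" else "clean"
  if (is.null(.fixture_env[[key]])) {
    spec <- if (noise) pbmModelSpec(seed = 42L)
            else pbmModelSpec(noiseCv = 0, seed = 42L)
    .fixture_env[[key]] <- collapseAndNormalize(simulatePbmIntensities(spec))
  }
  .fixture_env[[key]]
}

# brute-force window scanner used as the oracle for best8merInWindow
bruteBest8mer <- function(genome, chrom, center, halfWidth, table) {
  seqc <- as.character(genome[[chrom]])
  s <- max(center - halfWidth, 1L)
  e <- min(center + halfWidth - 1L, nchar(seqc))
  best <- NA_real_
  for (p in s:(e - 7L)) {
    km <- substr(seqc, p, p + 7L)
    occ <- kmerOccupancy(table, km)
    if (!is.na(occ) && (is.na(best) || occ > best)) best <- occ
  }
  best
}
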