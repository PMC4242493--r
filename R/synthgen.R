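#' Synthetic input generators with planted ground truth
#'
#' These generators emulate every input the occupancy-versus-affinity
#' pipeline consumes: a random genome, ChIP-seq reads clustered at
#' factor-specific offsets from TSSs over a uniform background, a PBM 8-mer
#' intensity table with planted core-6-mer preferences and flanking-base
#' modifiers, accessible (nucleosome-free) regions covering a few percent of
#' the genome, and a long-tailed expression table.  All are deterministic
#' for a fixed seed, so planted parameters can be recovered and asserted.
#'
#' @name synthgen
NULL

#' Parameters of a synthetic genome
#'
#' @param nChroms number of chromosomes.
#' @param chromLength chromosome length in bp (> 0).
#' @param gcFraction probability that a base is G or C, in [0, 1].
#' @param seed integer RNG seed.
#' @return a validated parameter list of class \code{"GenomeSpec"}.
#' @export
genomeSpec <- function(nChroms = 1L, chromLength = 2e6, gcFraction = 0.41,
                       seed = 1L) {
  .assert_scalar_num(nChroms, "nChroms", lower = 1)
  if (!is.numeric(chromLength) || length(chromLength) != 1L ||
      is.na(chromLength) || chromLength <= 0)
    stop("invalid genome spec: chromLength must be > 0", call. = FALSE)
  .assert_scalar_num(gcFraction, "gcFraction", lower = 0, upper = 1)
  structure(list(nChroms = as.integer(nChroms),
                 chromLength = as.integer(chromLength),
                 gcFraction = gcFraction, seed = as.integer(seed)),
            class = "GenomeSpec")
}

#' Generate an i.i.d. random genome
#'
#' Bases are drawn independently with the stated GC fraction (C and G
#' equiprobable, likewise A and T).
#'
#' @param spec a \code{\link{genomeSpec}}.
#' @return a named \code{DNAStringSet} (chr1, chr2, ...), FASTA-writable via
#'   \code{Biostrings::writeXStringSet}.
#' @export
generateGenome <- function(spec) {
  stopifnot(inherits(spec, "GenomeSpec"))
  gc <- spec$gcFraction
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  .with_seed(spec$seed, {
    seqs <- vapply(seq_len(spec$nChroms), function(i) {
      paste(sample(c("A", "C", "G", "T"), spec$chromLength,
                   replace = TRUE, prob = probs), collapse = "")
    }, character(1))
    genome <- Biostrings::DNAStringSet(seqs)
    names(genome) <- paste0("chr", seq_len(spec$nChroms))
    genome
  })
}

#' Plant exact motifs into a genome
#'
#' @param genome a \code{DNAStringSet}.
#' @param sites data.frame with columns \code{chrom}, \code{pos} (1-based
#'   start of the planted sequence) and \code{seq}.
#' @return the modified genome; all other bases unchanged.  Overlapping or
#'   out-of-bounds plants are an error.
#' @export
plantMotifs <- function(genome, sites) {
  stopifnot(is(genome, "DNAStringSet"))
  if (is.null(sites) || nrow(as.data.frame(sites)) == 0L) return(genome)
  sites <- as.data.frame(sites)
  stopifnot(all(c("chrom", "pos", "seq") %in% names(sites)))
  sl <- .seq_lengths(genome)
  len <- nchar(sites$seq)
  if (any(!sites$chrom %in% names(sl)))
    stop("unknown chromosome in sites", call. = FALSE)
  if (any(sites$pos < 1L) || any(sites$pos + len - 1L > sl[sites$chrom]))
    stop("planted site out of chromosome bounds", call. = FALSE)
  for (chrom in unique(sites$chrom)) {
    s <- sites[sites$chrom == chrom, ]
    ir <- IRanges::IRanges(s$pos, s$pos + nchar(s$seq) - 1L)
    if (length(ir) > 1L && max(IRanges::coverage(ir)) > 1L)
      stop("overlapping planted sites on ", chrom, call. = FALSE)
    x <- genome[[chrom]]
    for (i in seq_len(nrow(s)))
      Biostrings::subseq(x, s$pos[i], s$pos[i] + nchar(s$seq[i]) - 1L) <-
        Biostrings::DNAString(s$seq[i])
    genome[[chrom]] <- x
  }
  genome
}

#' Parameters of one simulated ChIP-seq factor
#'
#' @param name factor label.
#' @param meanOffset mean binding offset from the TSS in bp, signed;
#'   positive = downstream on the gene's strand.
#' @param sdOffset standard deviation of the binding offset (>= 0).
#' @param readsPerTss reads emitted per TSS.
#' @param backgroundReads reads placed uniformly over the genome.
#' @param fragmentLength sequenced fragment length in bp (> 0).
#' @return a parameter list of class \code{"FactorProfile"}.
#' @export
factorProfile <- function(name, meanOffset, sdOffset = 40,
                          readsPerTss = 100L, backgroundReads = 0L,
                          fragmentLength = 200L) {
  .assert_scalar_num(sdOffset, "sdOffset", lower = 0)
  .assert_scalar_num(fragmentLength, "fragmentLength", lower = 1)
  structure(list(name = name, meanOffset = meanOffset, sdOffset = sdOffset,
                 readsPerTss = as.integer(readsPerTss),
                 backgroundReads = as.integer(backgroundReads),
                 fragmentLength = as.integer(fragmentLength)),
            class = "FactorProfile")
}

#' Simulate ChIP-seq reads around TSSs
#'
#' For each TSS the factor's binding point is drawn from
#' Normal(TSS + strand-adjusted meanOffset, sdOffset); reads are single-end
#' 5' positions, half on each strand, placed so that the
#' \code{fragmentLength} extension is centered on the sampled point
#' (mimicking ChIP fragment symmetry, so pileups summit at the binding
#' point).  Background reads are uniform over the genome.  Draws whose
#' extended fragment would leave the chromosome are redrawn rather than
#' clipped, avoiding edge pileups.
#'
#' @param tss \code{GRanges} of TSS positions (width 1, stranded).
#' @param profile a \code{\link{factorProfile}}.
#' @param genome \code{DNAStringSet} (for chromosome bounds).
#' @param seed RNG seed.
#' @return \code{GRanges} of width-1 read 5'-end positions with strand and
#'   seqlengths set.  A plus-strand read at start \code{s} represents the
#'   fragment \code{[s, s+L-1]}; a minus-strand read the fragment
#'   \code{[s-L, s-1]}.
#' @export
simulateChipReads <- function(tss, profile, genome, seed = 1L) {
  stopifnot(inherits(profile, "FactorProfile"), is(tss, "GRanges"))
  sl <- .seq_lengths(genome)
  L <- profile$fragmentLength
  half <- L %/% 2L
  .with_seed(seed, {
    chroms <- character(0); pos <- integer(0); strands <- character(0)
    if (profile$readsPerTss > 0L && length(tss) > 0L) {
      n <- profile$readsPerTss
      tpos <- GenomicRanges::start(tss)
      tstr <- as.character(GenomicRanges::strand(tss))
      target <- ifelse(tstr == "-", tpos - profile$meanOffset,
                       tpos + profile$meanOffset)
      tchrom <- as.character(GenomicRanges::seqnames(tss))
      centers <- rep(target, each = n) +
        round(rnorm(n * length(tss), 0, profile$sdOffset))
      cchrom <- rep(tchrom, each = n)
      lo <- half + 1L
      hi <- sl[cchrom] - half
      alltarget <- rep(target, each = n)
      bad <- which(centers < lo | centers > hi)
      while (length(bad)) {
        centers[bad] <- alltarget[bad] +
          round(rnorm(length(bad), 0, profile$sdOffset))
        bad <- which(centers < lo | centers > hi)
      }
      str <- rep_len(c("+", "-"), n * length(tss))
      p <- ifelse(str == "+", centers - half, centers + half)
      chroms <- c(chroms, cchrom); pos <- c(pos, as.integer(p))
      strands <- c(strands, str)
    }
    if (profile$backgroundReads > 0L) {
      nb <- profile$backgroundReads
      bchrom <- sample(names(sl), nb, replace = TRUE,
                       prob = sl / sum(sl))
      lo <- half + 1L
      ncenters <- pmax(1, sl[bchrom] - half - lo + 1)  # centers in [lo, len-half]
      centers <- lo + floor(runif(nb) * ncenters)
      str <- rep_len(c("+", "-"), nb)
      p <- ifelse(str == "+", centers - half, centers + half)
      chroms <- c(chroms, bchrom); pos <- c(pos, as.integer(p))
      strands <- c(strands, str)
    }
    gr <- GenomicRanges::GRanges(chroms, IRanges::IRanges(pos, width = 1L),
                                 strand = strands)
    GenomeInfoDb::seqlevels(gr) <- names(sl)
    GenomeInfoDb::seqlengths(gr) <- sl
    sort(gr, ignore.strand = TRUE)
  })
}

#' Parameters of a simulated PBM 8-mer intensity table
#'
#' @param coreEffects named numeric, 6-mer core -> intensity multiplier
#'   (all > 0).
#' @param flankEffects named numeric, two-character flanking-base pattern
#'   (left base then right base immediately outside a contained 6-mer, "N"
#'   when the 6-mer sits at the 8-mer boundary) -> multiplier (> 0).
#' @param baseline baseline fluorescence intensity (> 0).
#' @param noiseCv coefficient of variation of multiplicative lognormal
#'   noise.
#' @param seed RNG seed.
#' @return a parameter list of class \code{"PbmModelSpec"}.  The defaults
#'   plant a canonical E-box hierarchy: CACGTG strongest, eleven weaker
#'   variant cores, and flanking-base modifiers so that CCACGTGG is the
#'   best-bound 8-mer.
#' @export
pbmModelSpec <- function(coreEffects = c(CACGTG = 50, CGCGTG = 18,
                                         CACATG = 15, CACGAG = 12,
                                         CATGCG = 10, AACGTG = 9,
                                         CATGAG = 8, CATATG = 7,
                                         CATGCA = 6.5, CATGCT = 6,
                                         GTGCAC = 5.5, CTCGAG = 5),
                         flankEffects = c(CG = 1.5, GC = 1.35, GG = 1.2,
                                          CC = 1.2, AT = 0.4, TA = 0.3,
                                          AA = 0.5, TT = 0.5),
                         baseline = 100, noiseCv = 0.15, seed = 1L) {
  if (any(coreEffects <= 0) || any(flankEffects <= 0) || baseline <= 0)
    stop("all multipliers and the baseline must be > 0", call. = FALSE)
  if (!all(grepl("^[ACGT]{6}$", names(coreEffects))))
    stop("coreEffects keys must be 6-mers over ACGT", call. = FALSE)
  structure(list(coreEffects = coreEffects, flankEffects = flankEffects,
                 baseline = baseline, noiseCv = noiseCv,
                 seed = as.integer(seed)),
            class = "PbmModelSpec")
}

# deterministic part of the planted PBM model for one 8-mer orientation:
# max over contained 6-mers of core multiplier x flank multiplier
.pbm_det_score <- function(kmers, coreEffects, flankEffects) {
  best <- rep(1, length(kmers))
  for (j in 1:3) {
    core <- substr(kmers, j, j + 5L)
    left <- if (j > 1) substr(kmers, j - 1L, j - 1L) else
      rep("N", length(kmers))
    right <- if (j + 6L <= 8L) substr(kmers, j + 6L, j + 6L) else
      rep("N", length(kmers))
    ce <- coreEffects[core]
    fe <- flankEffects[paste0(left, right)]
    fe[is.na(fe)] <- 1
    sc <- ifelse(is.na(ce), 1, ce * fe)
    best <- pmax(best, sc)
  }
  best
}

#' Simulate a raw PBM 8-mer intensity table
#'
#' Intensity of each reverse-complement-collapsed 8-mer class is
#' \code{baseline * max(core x flank multiplier over contained 6-mers in
#' either orientation) * lognormal(1, noiseCv)}.
#'
#' @param spec a \code{\link{pbmModelSpec}}.
#' @return data.frame with columns \code{kmer} (canonical orientation),
#'   \code{revcomp}, \code{intensity}; one row per collapsed class (32,896
#'   rows).
#' @export
simulatePbmIntensities <- function(spec) {
  stopifnot(inherits(spec, "PbmModelSpec"))
  canon <- enumerateCollapsedKmers(8L)
  rc <- .revcomp_chr(canon)
  det <- pmax(.pbm_det_score(canon, spec$coreEffects, spec$flankEffects),
              .pbm_det_score(rc, spec$coreEffects, spec$flankEffects))
  .with_seed(spec$seed, {
    noise <- if (spec$noiseCv > 0) {
      sdlog <- sqrt(log(1 + spec$noiseCv^2))
      rlnorm(length(canon), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else rep(1, length(canon))
    data.frame(kmer = canon, revcomp = rc,
               intensity = spec$baseline * det * noise,
               stringsAsFactors = FALSE)
  })
}

#' Generate non-overlapping accessible regions
#'
#' Emulates DNase I sensitive / nucleosome-free intervals covering
#' approximately \code{fraction} of the genome, with DHS-like lengths
#' (gamma-distributed around \code{meanWidth}).
#'
#' @param genome \code{DNAStringSet}.
#' @param fraction target covered fraction of the genome, in (0, 1).
#' @param seed RNG seed.
#' @param meanWidth mean interval width in bp.
#' @return sorted, non-overlapping \code{GRanges} (BED-writable).
#' @export
generateAccessibleRegions <- function(genome, fraction = 0.03, seed = 1L,
                                      meanWidth = 600) {
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must be in (0, 1)", call. = FALSE)
  sl <- .seq_lengths(genome)
  .with_seed(seed, {
    out <- lapply(names(sl), function(chrom) {
      len <- sl[[chrom]]
      target <- fraction * len
      n <- max(1L, ceiling(target / meanWidth * 2))
      w <- pmax(100L, round(rgamma(n, shape = 4, scale = meanWidth / 4)))
      s <- 1L + floor(runif(n) * pmax(1, len - w))
      ir <- IRanges::reduce(IRanges::IRanges(s, width = w))
      ir <- IRanges::restrict(ir, 1L, len)
      ord <- sample(length(ir))          # accumulate in random order
      cum <- cumsum(IRanges::width(ir)[ord])
      keep <- ord[seq_len(which(cum >= target)[1])]
      ir <- ir[keep]
      ir <- ir[order(IRanges::start(ir))]
      GenomicRanges::GRanges(chrom, ir)
    })
    gr <- sort(do.call(c, out))
    GenomeInfoDb::seqlevels(gr) <- names(sl)
    GenomeInfoDb::seqlengths(gr) <- sl
    gr
  })
}

#' Generate a long-tailed expression table
#'
#' Log-normal RNA levels spanning several orders of magnitude, emulating an
#' RNA-seq quantification of expressed genes.
#'
#' @param geneIds character vector of gene identifiers (non-empty).
#' @param seed RNG seed.
#' @param meanlog,sdlog log-normal parameters of the level distribution.
#' @return data.frame with columns \code{gene}, \code{level} (all > 0).
#' @export
generateExpressionTable <- function(geneIds, seed = 1L, meanlog = 3,
                                    sdlog = 1.6) {
  if (length(geneIds) == 0L) stop("gene list must be non-empty", call. = FALSE)
  .with_seed(seed, {
    data.frame(gene = as.character(geneIds),
               level = rlnorm(length(geneIds), meanlog, sdlog),
               stringsAsFactors = FALSE)
  })
}
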