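#' Build a curated TSS list
#'
#' Two-step curation of raw transcription start sites, as used upstream of
#' all metagene and heatmap analyses.  Step 1: TSSs of the same gene (same
#' chromosome and strand) whose successive gaps are at most
#' \code{mergeDist} are chained (single linkage) into one cluster,
#' represented by the 5'-most TSS on the gene's strand.  Step 2: any two
#' surviving TSSs, regardless of gene, closer than \code{excludeDist} are
#' both removed, so every remaining metagene window is unambiguous.
#'
#' The result is idempotent and no two output TSSs are closer than
#' \code{excludeDist}.
#'
#' @param tss width-1 stranded \code{GRanges} with a \code{gene} metadata
#'   column.
#' @param mergeDist same-gene merge distance in bp (gap \code{<= mergeDist}
#'   merges).
#' @param excludeDist mutual exclusion distance in bp (distance
#'   \code{< excludeDist} removes both).
#' @return curated \code{GRanges}, sorted by (chromosome, position).
#' @export
buildTssList <- function(tss, mergeDist = 500, excludeDist = 1000) {
  stopifnot(is(tss, "GRanges"), "gene" %in% names(S4Vectors::mcols(tss)))
  if (length(tss) == 0L) return(tss)
  df <- data.frame(gene = S4Vectors::mcols(tss)$gene,
                   chrom = as.character(GenomicRanges::seqnames(tss)),
                   pos = GenomicRanges::start(tss),
                   strand = as.character(GenomicRanges::strand(tss)),
                   stringsAsFactors = FALSE)
  # step 1: same-gene single-linkage chaining within mergeDist
  keyed <- split(df, paste(df$gene, df$chrom, df$strand, sep = "\r"))
  merged <- do.call(rbind, lapply(keyed, function(g) {
    g <- g[order(g$pos), , drop = FALSE]
    cl <- cumsum(c(1, diff(g$pos) > mergeDist))
    do.call(rbind, lapply(split(g, cl), function(cg) {
      rep5 <- if (cg$strand[1] == "-") which.max(cg$pos) else which.min(cg$pos)
      cg[rep5, , drop = FALSE]
    }))
  }))
  merged <- merged[order(merged$chrom, merged$pos, merged$gene), ,
                   drop = FALSE]
  # step 2: mutual removal of any pair closer than excludeDist (any gene)
  keep <- rep(TRUE, nrow(merged))
  for (chrom in unique(merged$chrom)) {
    i <- which(merged$chrom == chrom)
    if (length(i) < 2L) next
    gaps <- diff(merged$pos[i])
    close_ <- gaps < excludeDist
    drop <- unique(c(i[which(close_)], i[which(close_) + 1L]))
    keep[drop] <- FALSE
  }
  merged <- merged[keep, , drop = FALSE]
  gr <- GenomicRanges::GRanges(merged$chrom,
                               IRanges::IRanges(merged$pos, width = 1L),
                               strand = merged$strand)
  S4Vectors::mcols(gr)$gene <- merged$gene
  sl <- GenomeInfoDb::seqlengths(tss)
  if (!any(is.na(sl))) {
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(tss)
    GenomeInfoDb::seqlengths(gr) <- sl
  }
  gr
}
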