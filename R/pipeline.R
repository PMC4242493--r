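#' Pipeline run configuration
#'
#' Bundles every numeric parameter of the occupancy-versus-affinity
#' pipeline with its standard default: 200-bp fragment extension, 25-bp
#' bins, 10-kb metagene and 2-kb heatmap half-windows, minimum peak height
#' 30, 100-bp motif-scan windows, 30,000 random accessible windows, the
#' 0.2 low-affinity occupancy cutoff, top-200 8-mers for core extraction,
#' 500/1,000-bp TSS merge/exclusion distances, difference-track thresholds
#' {0.5, 1.0} and the 250-bp TSS annotation distance.  Demo-scale synthetic
#' genome parameters are included so a run is self-contained.
#'
#' @param seed master RNG seed; every stage seed is derived from it.
#' @param fragmentLength,binWidth,metageneHalfWindow,heatmapHalfWindow,minPeakHeight,peakWindow,nRandomWindows,occupancyCutoff,topN8mers,tssMergeDist,tssExcludeDist,diffThresholds,tssAnnotDist analysis parameters (see Description).
#' @param chromLength,gcFraction,nTss,readsPerTss,backgroundReads synthetic
#'   genome / read-depth parameters for the demo run.
#' @return a named list of class \code{"RunConfig"}.
#' @export
runConfig <- function(seed = 1L,
                      fragmentLength = 200L, binWidth = 25L,
                      metageneHalfWindow = 10000L, heatmapHalfWindow = 2000L,
                      minPeakHeight = 30L, peakWindow = 100L,
                      nRandomWindows = 30000L, occupancyCutoff = 0.2,
                      topN8mers = 200L, tssMergeDist = 500L,
                      tssExcludeDist = 1000L, diffThresholds = c(0.5, 1.0),
                      tssAnnotDist = 250L,
                      chromLength = 2e6, gcFraction = 0.41, nTss = 200L,
                      readsPerTss = 300L, backgroundReads = 5000L) {
  cfg <- list(seed = as.integer(seed), fragmentLength = fragmentLength,
              binWidth = binWidth, metageneHalfWindow = metageneHalfWindow,
              heatmapHalfWindow = heatmapHalfWindow,
              minPeakHeight = minPeakHeight, peakWindow = peakWindow,
              nRandomWindows = nRandomWindows,
              occupancyCutoff = occupancyCutoff, topN8mers = topN8mers,
              tssMergeDist = tssMergeDist, tssExcludeDist = tssExcludeDist,
              diffThresholds = diffThresholds, tssAnnotDist = tssAnnotDist,
              chromLength = chromLength, gcFraction = gcFraction,
              nTss = as.integer(nTss), readsPerTss = as.integer(readsPerTss),
              backgroundReads = as.integer(backgroundReads))
  if (any(vapply(cfg[setdiff(names(cfg), "seed")],
                 function(x) any(x <= 0), logical(1))))
    stop("all configuration parameters must be positive", call. = FALSE)
  structure(cfg, class = "RunConfig")
}

# evenly scattered TSSs with random strands, away from chromosome ends
.demo_tss <- function(sl, nTss, margin, seed) {
  .with_seed(seed, {
    chrom <- names(sl)[1]
    len <- sl[[1]]
    usable <- len - 2 * margin
    pos <- margin + sort(round(usable * (seq_len(nTss) - 0.5) / nTss +
                                 runif(nTss, -usable / (4 * nTss),
                                       usable / (4 * nTss))))
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L),
                                 strand = sample(c("+", "-"), nTss, TRUE))
    S4Vectors::mcols(gr)$gene <- sprintf("g%04d", seq_len(nTss))
    GenomeInfoDb::seqlengths(gr) <- sl
    sort(gr)
  })
}

#' Run the full synthetic-data pipeline
#'
#' Generates a toy genome with TSSs, simulates Pol II / Myc / Max reads at
#' their characteristic offsets (+83 / -20 / -35 bp) plus a CTCF-like
#' intragenic factor, and runs every downstream stage: binned and
#' base-resolution tracks (WIG/bedGraph output), metagene profiles,
#' the pairwise similarity matrix, greedy peak calling, extra-Max
#' difference peaks, PBM simulation and normalization, the core-6-mer
#' genome track, peak-versus-background affinity scoring with ROC and rank
#' statistics, and the expression-rank comparison.  All artifacts are
#' written under \code{outDir} along with a manifest of parameters and
#' file checksums; a fixed seed gives byte-identical output.
#'
#' @param config a \code{\link{runConfig}}.
#' @param outDir output directory (created if needed).
#' @param verbose print stage progress.
#' @return (invisibly) a list of in-memory results: tss, tracks, profiles,
#'   peak sets, similarity matrix, score tables, statistics, manifest path.
#' @export
runPipeline <- function(config = runConfig(), outDir = tempfile("run"),
                        verbose = TRUE) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[", format(Sys.time(), "%H:%M:%S"),
                                            "] ", ...)
  cfg <- config
  sd <- function(k) cfg$seed + k   # derived stage seeds

  say("genome + annotation")
  genome <- generateGenome(genomeSpec(1L, cfg$chromLength, cfg$gcFraction,
                                      seed = sd(1)))
  sl <- .seq_lengths(genome)
  rawTss <- .demo_tss(sl, cfg$nTss, margin = cfg$metageneHalfWindow %/% 2L,
                      seed = sd(2))
  tss <- buildTssList(rawTss, cfg$tssMergeDist, cfg$tssExcludeDist)
  writeTssTable(tss, file.path(outDir, "tss.tsv"))

  say("read simulation (", length(tss), " TSSs )")
  profiles <- list(
    polii = factorProfile("polii", +83, 40, cfg$readsPerTss,
                          cfg$backgroundReads, cfg$fragmentLength),
    myc = factorProfile("myc", -20, 45, cfg$readsPerTss,
                        cfg$backgroundReads, cfg$fragmentLength),
    max = factorProfile("max", -35, 45, cfg$readsPerTss,
                        cfg$backgroundReads, cfg$fragmentLength),
    ctcf = factorProfile("ctcf", +1500, 300, cfg$readsPerTss %/% 2L,
                         cfg$backgroundReads, cfg$fragmentLength))
  reads <- Map(function(p, k) capDuplicates(
    simulateChipReads(tss, p, genome, seed = sd(10 + k)),
    maxPerPosition = 2L), profiles, seq_along(profiles))

  # plant extra-Max loci between genes: Max-only clusters for the
  # difference-track stage
  extraSites <- .with_seed(sd(3), {
    pos <- sort(sample(seq(cfg$metageneHalfWindow,
                           cfg$chromLength - cfg$metageneHalfWindow,
                           by = 5000L), 5L))
    gr <- GenomicRanges::GRanges(names(sl)[1],
                                 IRanges::IRanges(pos, width = 1L),
                                 strand = "+")
    GenomeInfoDb::seqlengths(gr) <- sl
    gr
  })
  extraProfile <- factorProfile("extraMax", 0, 30, cfg$readsPerTss,
                                0L, cfg$fragmentLength)
  reads$max <- sort(c(reads$max,
                      simulateChipReads(extraSites, extraProfile, genome,
                                        seed = sd(4))),
                    ignore.strand = TRUE)
  for (nm in names(reads))
    writeBed(reads[[nm]], file.path(outDir, paste0("reads_", nm, ".bed")))

  say("coverage tracks")
  frags <- lapply(reads, extendReads, fragmentLength = cfg$fragmentLength)
  binned <- Map(function(f, r) binCoverage(f, cfg$binWidth,
                                           totalReads = length(r)),
                frags, reads)
  based <- Map(function(f, r) baseCoverage(f, totalReads = length(r)),
               frags, reads)
  for (nm in names(binned)) {
    writeWig(normalizeRpm(binned[[nm]]),
             file.path(outDir, paste0("track_", nm, ".wig")), name = nm)
    writeBedGraph(normalizeRpm(binned[[nm]]),
                  file.path(outDir, paste0("track_", nm, ".bedgraph")),
                  name = nm)
  }

  say("metagene profiles")
  mg <- lapply(based, function(tr) areaNormalize(subtractFloor(
    metageneProfile(tr, tss, cfg$metageneHalfWindow))))
  mgTab <- data.frame(offset = profileOffsets(mg[[1]]),
                      do.call(cbind, lapply(mg, profileValues)))
  utils::write.table(mgTab, file.path(outDir, "metagene.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  peakOffsets <- vapply(mg, function(p)
    profileOffsets(p)[which.max(profileValues(p))], integer(1))

  say("similarity matrix")
  sim <- similarityMatrix(binned)
  utils::write.table(round(sim, 4), file.path(outDir, "similarity.tsv"),
                     sep = "\t", quote = FALSE)

  say("peak calling")
  peaks <- callPeaks(reads$myc, cfg$minPeakHeight, cfg$fragmentLength)
  writeBed(peaks, file.path(outDir, "peaks_myc.bed"), format = "bed6")
  exm <- extraMaxPeaks(binned$max, binned$myc, cfg$diffThresholds,
                       cfg$fragmentLength)
  for (nm in names(exm))
    writeBed(exm[[nm]], file.path(outDir, paste0("extra_max_", nm, ".bed")),
             format = "bed6")
  annot <- nearestTssAnnotation(exm[[length(exm)]], tss, cfg$tssAnnotDist)
  utils::write.table(annot, file.path(outDir, "extra_max_annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  say("PBM table + affinity track")
  pbm <- collapseAndNormalize(
    simulatePbmIntensities(pbmModelSpec(seed = sd(5))))
  utils::write.table(kmerTable(pbm), file.path(outDir, "pbm_8mers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cores <- topCore6mers(pbm, cfg$topN8mers)
  sixTrack <- genome6merTrack(genome, utils::head(cores$core, 12L), pbm)
  utils::write.table(sixTrack, file.path(outDir, "core6mer_track.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  say("occupancy vs affinity statistics")
  accessible <- generateAccessibleRegions(genome, 0.03, seed = sd(6))
  writeBed(accessible, file.path(outDir, "accessible.bed"), format = "bed3")
  bg <- sampleAccessibleWindows(accessible, cfg$nRandomWindows,
                                cfg$peakWindow, seed = sd(7))
  peakScores <- scoreRegions(peaks, genome, pbm,
                             halfWidth = cfg$peakWindow %/% 2L)
  bgScores <- scoreRegions(bg, genome, pbm,
                           halfWidth = cfg$peakWindow %/% 2L)
  roc <- rocCurve(peakScores$occupancy, bgScores$occupancy)
  wil <- wilcoxonRankSum(peakScores$occupancy, bgScores$occupancy)
  spear <- spearmanCor(peakScores$height, peakScores$occupancy)
  lowAffinity <- fractionBelow(peakScores$occupancy, cfg$occupancyCutoff)
  ebox <- genome6merTrack(genome, "CACGTG", pbm)
  eboxSites <- GenomicRanges::GRanges(ebox$chrom,
                                      IRanges::IRanges(ebox$pos, width = 6L))
  peakWins <- GenomicRanges::resize(peaks, cfg$peakWindow, fix = "center")
  fish <- fisherOverlap(peakWins, eboxSites, bg)
  binsum <- logBinSummary(peakScores$height, peakScores$occupancy, 10L)
  utils::write.table(binsum[, setdiff(names(binsum), "outliers")],
                     file.path(outDir, "logbin_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(fpr = roc$fpr, tpr = roc$tpr),
                     file.path(outDir, "roc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  say("expression comparison")
  expr <- generateExpressionTable(S4Vectors::mcols(tss)$gene, seed = sd(8))
  utils::write.table(expr, file.path(outDir, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  nearGenes <- annot$gene[!is.na(annot$gene)]
  exprRank <- if (length(nearGenes))
    tryCatch(expressionRankDistribution(nearGenes, expr,
                                        topN = nrow(expr)),
             error = function(e) NULL) else NULL

  stats <- data.frame(
    metric = c("auc", "wilcoxon_p", "spearman_rho", "spearman_p",
               "fraction_below_cutoff", "fisher_p",
               paste0("offset_", names(peakOffsets)),
               "n_peaks", paste0("n_extra_max_", names(exm)),
               "expr_ks_stat"),
    value = c(roc$auc, wil$p.value, spear$rho, spear$p.value, lowAffinity,
              fish$p.value, peakOffsets, length(peaks),
              vapply(exm, length, integer(1)),
              if (is.null(exprRank)) NA_real_ else exprRank$statistic))
  utils::write.table(stats, file.path(outDir, "stats.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  say("manifest")
  files <- sort(setdiff(list.files(outDir), "manifest.tsv"))
  manifest <- rbind(
    data.frame(key = paste0("param.", names(unlist(cfg))),
               value = as.character(unlist(cfg))),
    data.frame(key = paste0("md5.", files),
               value = as.character(tools::md5sum(file.path(outDir, files)))))
  utils::write.table(manifest, file.path(outDir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  invisible(list(outDir = outDir, genome = genome, tss = tss, reads = reads,
                 binned = binned, based = based, metagene = mg,
                 peakOffsets = peakOffsets, similarity = sim, peaks = peaks,
                 extraMax = exm, pbm = pbm, cores = cores, roc = roc,
                 wilcoxon = wil, spearman = spear,
                 fractionBelowCutoff = lowAffinity, fisher = fish,
                 logBins = binsum, expression = expr, exprRank = exprRank,
                 stats = stats, manifest = file.path(outDir, "manifest.tsv")))
}
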