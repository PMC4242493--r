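# window of base-resolution signal around one TSS, strand-oriented so that
# positive offsets are downstream; zero-padded at chromosome edges
.tss_window <- function(rleVec, pos, minus, halfWindow) {
  W <- halfWindow
  len <- length(rleVec)
  if (!minus) { s <- pos - W; e <- pos + W - 1L }
  else        { s <- pos - W + 1L; e <- pos + W }
  cs <- max(s, 1L); ce <- min(e, len)
  v <- numeric(2L * W)
  if (cs <= ce)
    v[(cs - s + 1L):(ce - s + 1L)] <- as.numeric(S4Vectors::window(rleVec, cs, ce))
  if (minus) rev(v) else v
}

#' TSS-anchored metagene profile
#'
#' Tabulates base-resolution signal within \code{halfWindow} bases of each
#' TSS (window \code{[-W, +W)}, offset 0 included, \code{+W} excluded, so a
#' 10 kb half-window yields exactly 20,000 data points), orients
#' minus-strand genes so positive offsets are downstream, and averages
#' across genes.  Background subtraction and area normalization are
#' separate steps (\code{\link{subtractFloor}}, \code{\link{areaNormalize}})
#' applied in that order.
#'
#' @param track base-resolution \code{\linkS4class{CoverageTrack}}
#'   (\code{binWidth = 1}).
#' @param tss width-1 stranded \code{GRanges} of curated TSSs (non-empty).
#' @param halfWindow half-window W in bp.
#' @return a \code{\linkS4class{MetageneProfile}} with offsets
#'   \code{-W .. W-1}.
#' @export
metageneProfile <- function(track, tss, halfWindow = 10000L) {
  stopifnot(is(track, "CoverageTrack"))
  if (binWidth(track) != 1L)
    stop("metagene profiles require a base-resolution track", call. = FALSE)
  if (length(tss) == 0L)
    stop("empty TSS list", call. = FALSE)
  W <- as.integer(halfWindow)
  vals <- trackValues(track)
  chrom <- as.character(GenomicRanges::seqnames(tss))
  pos <- GenomicRanges::start(tss)
  minus <- as.character(GenomicRanges::strand(tss)) == "-"
  acc <- numeric(2L * W)
  for (i in seq_along(tss)) {
    if (!chrom[i] %in% names(vals))
      stop("TSS on chromosome absent from track: ", chrom[i], call. = FALSE)
    acc <- acc + .tss_window(vals[[chrom[i]]], pos[i], minus[i], W)
  }
  MetageneProfile(offsets = seq.int(-W, W - 1L), values = acc / length(tss),
                  nGenes = length(tss))
}

#' Subtract the positional floor from a profile
#'
#' The mean of the lowest \code{floor(floorFraction * length)} positional
#' values is subtracted from every position (for the default 10\% on a
#' 20,000-point profile: the lowest 2,000 data points); negatives are
#' clamped to zero so areas stay interpretable.
#'
#' @param profile a \code{\linkS4class{MetageneProfile}} of length >= 10.
#' @param floorFraction fraction of positions defining the floor.
#' @return the floored profile.
#' @export
subtractFloor <- function(profile, floorFraction = 0.1) {
  stopifnot(is(profile, "MetageneProfile"))
  v <- profileValues(profile)
  if (length(v) < 10L)
    stop("profile too short for floor subtraction", call. = FALSE)
  k <- floor(floorFraction * length(v))
  m <- if (k >= 1L) mean(sort(v, partial = k)[seq_len(k)]) else 0
  methods::initialize(profile, values = pmax(v - m, 0))
}

#' Normalize a profile to unit area
#'
#' @param profile a \code{\linkS4class{MetageneProfile}} with positive
#'   total area.
#' @return the profile scaled so its values sum to 1.
#' @export
areaNormalize <- function(profile) {
  stopifnot(is(profile, "MetageneProfile"))
  s <- sum(profileValues(profile))
  if (s <= 0) stop("cannot area-normalize a profile with zero area",
                   call. = FALSE)
  methods::initialize(profile, values = profileValues(profile) / s)
}

#' Sum metagene profiles position-wise
#'
#' Combines already-normalized profiles from several datasets (for
#' instance, several cell types) by summing at each offset.
#'
#' @param profiles list of \code{\linkS4class{MetageneProfile}}s with equal
#'   offsets.
#' @return the combined profile.
#' @export
combineProfiles <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  off <- profileOffsets(profiles[[1]])
  for (p in profiles)
    if (!identical(profileOffsets(p), off))
      stop("profiles must share offsets", call. = FALSE)
  vals <- Reduce(`+`, lapply(profiles, profileValues))
  MetageneProfile(off, vals, sum(vapply(profiles, nGenes, integer(1))))
}

#' Rank-ordered heatmap matrices
#'
#' Builds one genes-by-offsets matrix of base-resolution signal per track,
#' all sharing the row order given by descending window sums of the ranking
#' track (ties broken by gene id for determinism).
#'
#' @param tracks named list of base-resolution
#'   \code{\linkS4class{CoverageTrack}}s.
#' @param tss width-1 stranded \code{GRanges} with a \code{gene} column.
#' @param rankTrack name of the track used for ranking (must be present).
#' @param halfWindow half-window in bp (columns span \code{-W .. W-1}).
#' @return named list of matrices (rownames = gene ids in rank order,
#'   columns = offsets).
#' @export
heatmapMatrix <- function(tracks, tss, rankTrack, halfWindow = 2000L) {
  stopifnot(is.list(tracks), !is.null(names(tracks)))
  if (!rankTrack %in% names(tracks))
    stop("unknown rank track: ", rankTrack, call. = FALSE)
  W <- as.integer(halfWindow)
  genes <- S4Vectors::mcols(tss)$gene
  chrom <- as.character(GenomicRanges::seqnames(tss))
  pos <- GenomicRanges::start(tss)
  minus <- as.character(GenomicRanges::strand(tss)) == "-"
  rows <- function(track) {
    vals <- trackValues(track)
    t(vapply(seq_along(tss), function(i)
      .tss_window(vals[[chrom[i]]], pos[i], minus[i], W),
      numeric(2L * W)))
  }
  rankMat <- rows(tracks[[rankTrack]])
  sums <- rowSums(rankMat)
  ord <- order(-sums, genes)
  lapply(tracks, function(track) {
    m <- if (identical(track, tracks[[rankTrack]])) rankMat else rows(track)
    m <- m[ord, , drop = FALSE]
    dimnames(m) <- list(genes[ord], seq.int(-W, W - 1L))
    m
  })
}
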