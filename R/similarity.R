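#' Background-threshold a track
#'
#' Removes the signal carried by the lowest 95\% of data points — mainly
#' isolated single reads — before genome-wide track comparison.  The
#' positional values with nonzero support are sorted ascending, the value
#' at the \code{quantile} cumulative percentile is subtracted from every
#' position, negatives are clamped to zero, and the remaining signal is
#' scaled to a total of one million (reads per million of the surviving
#' signal).
#'
#' @param track a binned \code{\linkS4class{CoverageTrack}}.
#' @param quantile cumulative fraction of data points treated as
#'   background; 0 leaves values unchanged before scaling.
#' @return the thresholded, normalized track.
#' @export
backgroundThreshold <- function(track, quantile = 0.95) {
  stopifnot(is(track, "CoverageTrack"), quantile >= 0, quantile < 1)
  vals <- trackValues(track)
  pts <- unlist(lapply(vals, function(v) {
    rv <- S4Vectors::runValue(v); rl <- S4Vectors::runLength(v)
    nz <- rv != 0
    rep(rv[nz], rl[nz])
  }), use.names = FALSE)
  thr <- 0
  if (quantile > 0 && length(pts) > 0) {
    pts <- sort(pts)
    thr <- pts[ceiling(quantile * length(pts))]
  }
  out <- methods::as(lapply(vals, function(v) {
    S4Vectors::runValue(v) <- pmax(S4Vectors::runValue(v) - thr, 0)
    v
  }), "RleList")
  tot <- sum(vapply(out, sum, numeric(1)))
  if (tot > 0) out <- out * (1e6 / tot)
  methods::initialize(track, values = out, normalized = TRUE)
}

#' Bounded similarity of two genome-wide tracks
#'
#' The difference between two tracks is quantified as
#' \code{D = sum_i |a_i - b_i|} over all positions; the similarity is
#' \code{1 - D / (sum_i a_i + sum_i b_i)}, which is exactly 1 for identical
#' tracks and exactly 0 for tracks with disjoint support, and lies in
#' [0, 1] for non-negative tracks.  Both inputs should have been
#' background-thresholded and normalized identically
#' (\code{\link{backgroundThreshold}}).
#'
#' @param a,b \code{\linkS4class{CoverageTrack}}s on the same genome and
#'   binning.
#' @return similarity in [0, 1].
#' @export
trackSimilarity <- function(a, b) {
  stopifnot(is(a, "CoverageTrack"), is(b, "CoverageTrack"))
  if (binWidth(a) != binWidth(b) ||
      !identical(names(trackValues(a)), names(trackValues(b))) ||
      !identical(lengths(trackValues(a)), lengths(trackValues(b))))
    stop("tracks must share chromosomes, lengths and bin width",
         call. = FALSE)
  va <- trackValues(a); vb <- trackValues(b)
  D <- sum(vapply(names(va), function(ch) sum(abs(va[[ch]] - vb[[ch]])),
                  numeric(1)))
  S <- sum(vapply(va, sum, numeric(1))) + sum(vapply(vb, sum, numeric(1)))
  if (S == 0)
    stop("similarity undefined: both tracks are all-zero", call. = FALSE)
  min(max(1 - D / S, 0), 1)
}

#' Pairwise similarity matrix of tracks
#'
#' @param tracks named list of at least two
#'   \code{\linkS4class{CoverageTrack}}s.
#' @param quantile background quantile passed to
#'   \code{\link{backgroundThreshold}}; set \code{threshold = FALSE} if the
#'   inputs are already thresholded.
#' @param threshold apply \code{\link{backgroundThreshold}} to each track
#'   first?
#' @return symmetric numeric matrix with unit diagonal.
#' @export
similarityMatrix <- function(tracks, quantile = 0.95, threshold = TRUE) {
  stopifnot(is.list(tracks), length(tracks) >= 2L, !is.null(names(tracks)))
  if (threshold)
    tracks <- lapply(tracks, backgroundThreshold, quantile = quantile)
  n <- length(tracks)
  m <- diag(1, n)
  dimnames(m) <- list(names(tracks), names(tracks))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    s <- trackSimilarity(tracks[[i]], tracks[[j]])
    m[i, j] <- s; m[j, i] <- s
  }
  m
}
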