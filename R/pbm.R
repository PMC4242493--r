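# cache for enumerations that never change within a session
.pkg_cache <- new.env(parent = emptyenv())

#' Enumerate reverse-complement-collapsed k-mers
#'
#' All \code{4^k} k-mers are partitioned into reverse-complement classes
#' and one canonical key (the lexicographically smaller orientation) is
#' returned per class, sorted.  For k = 8 this yields
#' \code{(4^8 + 4^4) / 2 = 32,896} classes, 256 of which are palindromic
#' (self-reverse-complement).
#'
#' @param k k-mer length.
#' @return sorted character vector of canonical k-mers.
#' @export
enumerateCollapsedKmers <- function(k = 8L) {
  key <- paste0("kmers", k)
  if (!is.null(.pkg_cache[[key]])) return(.pkg_cache[[key]])
  kmers <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
  canon <- sort(unique(.canonical_kmer(kmers)))
  .pkg_cache[[key]] <- canon
  canon
}

#' Collapse raw 8-mer intensities and normalize to in vitro occupancies
#'
#' Accepts either per-orientation intensities for all \code{4^8} 8-mers
#' (the two orientations of a class are averaged) or one intensity per
#' collapsed class.  Relative in vitro occupancy is each class intensity
#' divided by the intensity of the highest-ranked 8-mer, so occupancies lie
#' in (0, 1] with the top class at exactly 1.
#'
#' @param raw named numeric vector (8-mer -> intensity, all > 0) or a
#'   data.frame with columns \code{kmer} and \code{intensity}.
#' @return an \code{\linkS4class{EightMerTable}}.
#' @export
collapseAndNormalize <- function(raw) {
  if (is.data.frame(raw)) {
    stopifnot(all(c("kmer", "intensity") %in% names(raw)))
    raw <- stats::setNames(raw$intensity, raw$kmer)
  }
  if (any(raw <= 0) || any(is.na(raw)))
    stop("all intensities must be positive", call. = FALSE)
  canon <- enumerateCollapsedKmers(8L)
  keys <- names(raw)
  if (length(keys) == 4L^8L || !all(keys %in% canon)) {
    # per-orientation table: average the two orientations of each class
    missing <- setdiff(Biostrings::mkAllStrings(c("A", "C", "G", "T"), 8L),
                       keys)
    if (length(missing))
      stop("missing 8-mers: ", paste(utils::head(missing, 5), collapse = ", "),
           if (length(missing) > 5) sprintf(" (and %d more)",
                                            length(missing) - 5) else "",
           call. = FALSE)
    rc <- .revcomp_chr(canon)
    intensity <- (unname(raw[canon]) + unname(raw[rc])) / 2
  } else {
    missing <- setdiff(canon, keys)
    if (length(missing))
      stop("missing 8-mers: ", paste(utils::head(missing, 5), collapse = ", "),
           if (length(missing) > 5) sprintf(" (and %d more)",
                                            length(missing) - 5) else "",
           call. = FALSE)
    intensity <- unname(raw[canon])
  }
  EightMerTable(data.frame(kmer = canon, revcomp = .revcomp_chr(canon),
                           intensity = intensity,
                           occupancy = intensity / max(intensity),
                           stringsAsFactors = FALSE))
}

#' Core 6-mers of the top-ranked 8-mers
#'
#' Extracts the central (core) 6-mer of each of the \code{topN}
#' highest-occupancy 8-mer classes, reverse-complement collapsed (the
#' central 6-mer of an 8-mer's reverse complement is the reverse complement
#' of its central 6-mer, so each class contributes one core), and orders
#' the distinct cores by the occupancy of the best containing 8-mer.
#'
#' @param table an \code{\linkS4class{EightMerTable}}.
#' @param topN number of top 8-mer classes scanned.
#' @return data.frame with columns \code{core} (canonical 6-mer) and
#'   \code{bestOccupancy}, ordered by decreasing \code{bestOccupancy}.
#' @export
topCore6mers <- function(table, topN = 200L) {
  tb <- kmerTable(table)
  tb <- tb[order(-tb$occupancy, tb$kmer), ]
  top <- utils::head(tb, topN)
  core <- .canonical_kmer(substr(top$kmer, 2L, 7L))
  agg <- tapply(top$occupancy, core, max)
  out <- data.frame(core = names(agg), bestOccupancy = as.numeric(agg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$bestOccupancy, out$core), ]
  rownames(out) <- NULL
  out
}

#' Genome track of core 6-mer sites with relative affinity heights
#'
#' Every match of each core 6-mer, on either strand (reverse-complement
#' collapsed, so a palindromic site is reported once), is scored by the in
#' vitro occupancy of the 8-mer obtained by extending the match one base
#' on each side; heights are percent of the best-bound 8-mer.  Matches
#' whose one-base extension leaves the chromosome, or whose 8-mer contains
#' non-ACGT characters, are skipped.
#'
#' @param genome \code{DNAStringSet}.
#' @param cores character vector of core 6-mers (any orientation).
#' @param table an \code{\linkS4class{EightMerTable}}.
#' @return data.frame with columns \code{chrom}, \code{pos} (1-based start
#'   of the 6-mer), \code{core} (canonical) and \code{height} (percent, in
#'   (0, 100]).
#' @export
genome6merTrack <- function(genome, cores, table) {
  stopifnot(is(genome, "DNAStringSet"))
  cores <- unique(.canonical_kmer(toupper(cores)))
  out <- list()
  for (chrom in names(genome)) {
    seqc <- genome[[chrom]]
    len <- length(seqc)
    for (core in cores) {
      pats <- unique(c(core, .revcomp_chr(core)))
      starts <- sort(unique(unlist(lapply(pats, function(p)
        Biostrings::start(Biostrings::matchPattern(p, seqc))))))
      starts <- starts[starts - 1L >= 1L & starts + 6L <= len]
      if (!length(starts)) next
      eight <- as.character(Biostrings::DNAStringSet(
        Biostrings::Views(seqc, starts - 1L, starts + 6L)))
      occ <- kmerOccupancy(table, eight)
      ok <- !is.na(occ)
      if (!any(ok)) next
      out[[length(out) + 1L]] <- data.frame(chrom = chrom,
                                            pos = starts[ok], core = core,
                                            height = 100 * occ[ok],
                                            stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), pos = integer(0),
                      core = character(0), height = numeric(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$pos, res$core), ]
  rownames(res) <- NULL
  res
}

#' Best 8-mer occupancy in a window
#'
#' Scans every 8-mer position fully inside
#' \code{[center - halfWidth, center + halfWidth)} (1-based center; the
#' window is clipped at chromosome ends) on both strands (collapsed) and
#' returns the maximum relative in vitro occupancy.
#'
#' @param genome \code{DNAStringSet}.
#' @param chrom chromosome name.
#' @param center 1-based window center.
#' @param halfWidth half-width in bp (default 50 for a 100-bp window).
#' @param table an \code{\linkS4class{EightMerTable}}.
#' @return maximum occupancy in (0, 1], or \code{NA} if every 8-mer in the
#'   window contains non-ACGT characters.
#' @export
best8merInWindow <- function(genome, chrom, center, halfWidth = 50L, table) {
  stopifnot(is(genome, "DNAStringSet"), chrom %in% names(genome))
  len <- length(genome[[chrom]])
  s <- max(center - halfWidth, 1L)
  e <- min(center + halfWidth - 1L, len)
  n <- e - s + 1L
  if (n < 8L) stop("window shorter than 8 bases", call. = FALSE)
  win <- as.character(Biostrings::subseq(genome[[chrom]], s, e))
  kmers <- substring(win, 1:(n - 7L), 8:n)
  occ <- kmerOccupancy(table, kmers)
  if (all(is.na(occ))) return(NA_real_)
  max(occ, na.rm = TRUE)
}
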