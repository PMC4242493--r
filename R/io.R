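#' Read a BED3/BED6 file
#'
#' All file coordinates are 0-based half-open; the returned \code{GRanges}
#' is 1-based closed (the usual in-memory convention).  Strand defaults to
#' \code{+} when the file has no strand column.  Malformed lines raise a
#' parse error naming the offending line number.
#'
#' @param path file path.
#' @return a \code{GRanges}; BED6 name/score are kept as metadata columns.
#' @export
readBed <- function(path) {
  lines <- readLines(path)
  skip <- grepl("^(track|browser|#)", lines) | lines == ""
  lineno <- which(!skip)
  lines <- lines[!skip]
  if (length(lines) == 0L) return(GenomicRanges::GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop(sprintf("malformed BED line %d: fewer than 3 fields",
                 lineno[which(nf < 3L)[1]]), call. = FALSE)
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  bad <- which(is.na(start0) | is.na(end0) | start0 < 0 | end0 <= start0)
  if (length(bad))
    stop(sprintf("malformed BED line %d: bad coordinates", lineno[bad[1]]),
         call. = FALSE)
  name <- ifelse(nf >= 4L, vapply(fields, function(f)
    if (length(f) >= 4L) f[[4L]] else NA_character_, character(1)), NA)
  score <- ifelse(nf >= 5L, suppressWarnings(as.numeric(vapply(fields,
    function(f) if (length(f) >= 5L) f[[5L]] else NA_character_,
    character(1)))), NA)
  strand <- vapply(fields, function(f)
    if (length(f) >= 6L) f[[6L]] else "+", character(1))
  badstr <- which(!strand %in% c("+", "-", "."))
  if (length(badstr))
    stop(sprintf("malformed BED line %d: bad strand", lineno[badstr[1]]),
         call. = FALSE)
  strand[strand == "."] <- "+"
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start0 + 1, end0),
                               strand = strand)
  if (any(nf >= 4L)) S4Vectors::mcols(gr)$name <- name
  if (any(nf >= 5L)) S4Vectors::mcols(gr)$score <- score
  gr
}

#' Write intervals or reads as BED
#'
#' Width-1 stranded ranges (reads, peak summits) are written as BED6/BED5;
#' plain intervals as BED3.  Coordinates are converted to 0-based half-open.
#'
#' @param gr a \code{GRanges}.
#' @param path output path.
#' @param format "auto" (BED6 when strand or metadata is informative, else
#'   BED3), "bed3" or "bed6".
#' @return \code{path}, invisibly.
#' @export
writeBed <- function(gr, path, format = c("auto", "bed3", "bed6")) {
  format <- match.arg(format)
  strand <- as.character(GenomicRanges::strand(gr))
  hasStrand <- any(strand != "*")
  mc <- S4Vectors::mcols(gr)
  if (format == "auto")
    format <- if (hasStrand || ncol(mc) > 0L) "bed6" else "bed3"
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  if (format == "bed3") {
    df <- data.frame(as.character(GenomicRanges::seqnames(gr)), start0, end0)
  } else {
    name <- if ("name" %in% names(mc)) mc$name else rep(".", length(gr))
    score <- if ("score" %in% names(mc)) mc$score
             else if ("height" %in% names(mc)) mc$height
             else rep(0, length(gr))
    strand[strand == "*"] <- "."
    df <- data.frame(as.character(GenomicRanges::seqnames(gr)), start0, end0,
                     name, score, strand)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a binned track as fixedStep WIG
#'
#' fixedStep blocks with \code{start = bin_start + 1} (WIG is 1-based) and
#' \code{step = span = } bin width; zero bins are omitted (each contiguous
#' nonzero stretch opens a new block).
#'
#' @param track a \code{\linkS4class{CoverageTrack}} with uniform bins.
#' @param path output path.
#' @param name track name for the header line.
#' @return \code{path}, invisibly.
#' @export
writeWig <- function(track, path, name = "track") {
  stopifnot(is(track, "CoverageTrack"))
  w <- binWidth(track)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=wiggle_0 name=\"%s\"", name), con)
  vals <- trackValues(track)
  for (chrom in names(vals)) {
    v <- vals[[chrom]]
    rl <- S4Vectors::runLength(v)
    rv <- S4Vectors::runValue(v)
    ends <- cumsum(rl)
    starts <- ends - rl + 1L
    nz <- rv != 0
    if (!any(nz)) next
    # contiguous stretches of nonzero runs form one fixedStep block each
    blockId <- cumsum(c(TRUE, diff(nz) != 0))
    for (b in unique(blockId[nz])) {
      runs <- which(blockId == b)
      binStart <- starts[runs[1]]
      writeLines(sprintf("fixedStep chrom=%s start=%d step=%d span=%d",
                         chrom, (binStart - 1L) * w + 1L, w, w), con)
      writeLines(format(rep(rv[runs], rl[runs]), trim = TRUE,
                        scientific = FALSE, digits = 10), con)
    }
  }
  invisible(path)
}

#' Write a track as bedGraph
#'
#' 0-based half-open intervals; adjacent equal-valued bins are merged; zero
#' bins omitted.
#'
#' @inheritParams writeWig
#' @return \code{path}, invisibly.
#' @export
writeBedGraph <- function(track, path, name = "track") {
  stopifnot(is(track, "CoverageTrack"))
  w <- binWidth(track)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=\"%s\"", name), con)
  vals <- trackValues(track)
  for (chrom in names(vals)) {
    v <- vals[[chrom]]
    rl <- S4Vectors::runLength(v)
    rv <- S4Vectors::runValue(v)
    ends <- cumsum(rl)
    starts <- ends - rl + 1L
    nz <- which(rv != 0)
    if (!length(nz)) next
    writeLines(sprintf("%s\t%d\t%d\t%s", chrom,
                       (starts[nz] - 1L) * w,
                       ends[nz] * w,
                       format(rv[nz], trim = TRUE, scientific = FALSE,
                              digits = 10)), con)
  }
  invisible(path)
}

#' Cap duplicate reads per genomic position
#'
#' Retains at most \code{maxPerPosition} reads per (chromosome, start,
#' strand), keeping the earliest occurrences so the operation is
#' order-stable.  Strand is part of the key so that opposite-strand stacks
#' are not collapsed.
#'
#' @param reads \code{GRanges} of reads.
#' @param maxPerPosition maximum reads retained per position (>= 1).
#' @return the filtered \code{GRanges}.
#' @export
capDuplicates <- function(reads, maxPerPosition = 2L) {
  stopifnot(maxPerPosition >= 1L)
  if (length(reads) == 0L) return(reads)
  key <- paste(GenomicRanges::seqnames(reads), GenomicRanges::start(reads),
               GenomicRanges::strand(reads))
  occ <- stats::ave(seq_along(key), key, FUN = seq_along)
  reads[occ <= maxPerPosition]
}

#' Read / write a TSS table
#'
#' Tab-separated with header \code{gene, chrom, pos, strand}; \code{pos} is
#' the 0-based TSS coordinate in the file.
#'
#' @param path file path.
#' @return \code{readTssTable}: a width-1 stranded \code{GRanges} with a
#'   \code{gene} metadata column.
#' @export
readTssTable <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$pos + 1, width = 1L),
                               strand = df$strand)
  S4Vectors::mcols(gr)$gene <- df$gene
  gr
}

#' @rdname readTssTable
#' @param tss width-1 stranded \code{GRanges} with a \code{gene} column.
#' @export
writeTssTable <- function(tss, path) {
  df <- data.frame(gene = S4Vectors::mcols(tss)$gene,
                   chrom = as.character(GenomicRanges::seqnames(tss)),
                   pos = GenomicRanges::start(tss) - 1L,
                   strand = as.character(GenomicRanges::strand(tss)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
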