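#' Genome-wide coverage signal
#'
#' A \code{CoverageTrack} holds one numeric signal vector per chromosome as a
#' run-length encoded list, together with the bin width (1 = base
#' resolution), the number of reads the track was built from, and whether the
#' values have been scaled to reads per million.  \code{DifferenceTrack}
#' extends it for subtracted signals, whose values may be negative.
#'
#' @slot values an \code{RleList}, one run-length encoded vector per
#'   chromosome; element \code{i} of chromosome \code{c} is the signal in bin
#'   \code{i}, covering bases \code{[(i-1)*binWidth, i*binWidth)} (0-based).
#' @slot binWidth integer bin width in bp; 1 means base resolution.
#' @slot totalReads number of reads contributing to the track (used for
#'   reads-per-million scaling); may be \code{NA} for derived tracks.
#' @slot normalized logical; \code{TRUE} once values are on a per-million
#'   scale.
#'
#' @aliases DifferenceTrack-class
#' @export
setClass("CoverageTrack",
         representation(values = "RleList",
                        binWidth = "integer",
                        totalReads = "numeric",
                        normalized = "logical"))

#' @rdname CoverageTrack-class
#' @export
setClass("DifferenceTrack", contains = "CoverageTrack")

# note: non-negativity of plain coverage (not difference) tracks is
# enforced in the CoverageTrack() constructor; validObject() coerces
# subclasses to the superclass, so a class-validity check could not tell a
# DifferenceTrack apart
setValidity("CoverageTrack", function(object) {
  msg <- NULL
  if (length(object@binWidth) != 1L || is.na(object@binWidth) ||
      object@binWidth < 1L)
    msg <- c(msg, "binWidth must be a single integer >= 1")
  if (is.null(names(object@values)))
    msg <- c(msg, "values must be a named RleList (chromosome names)")
  if (is.null(msg)) TRUE else msg
})

#' Construct a CoverageTrack
#'
#' @param values named \code{RleList} (or list coercible to one) of
#'   per-chromosome signal vectors.
#' @param binWidth bin width in bp.
#' @param totalReads read count metadata.
#' @param normalized whether values are already reads-per-million scaled.
#' @return a \code{\linkS4class{CoverageTrack}}.
#' @export
CoverageTrack <- function(values, binWidth = 1L, totalReads = NA_real_,
                          normalized = FALSE) {
  if (!is(values, "RleList"))
    values <- methods::as(values, "RleList")
  if (length(values) > 0L &&
      any(vapply(values, function(v) min(min(v), 0), numeric(1)) < 0))
    stop("coverage values must be non-negative (use DifferenceTrack for ",
         "subtracted signals)", call. = FALSE)
  new("CoverageTrack", values = values, binWidth = as.integer(binWidth),
      totalReads = as.numeric(totalReads), normalized = normalized)
}

#' @rdname CoverageTrack
#' @export
DifferenceTrack <- function(values, binWidth = 1L, totalReads = NA_real_,
                            normalized = TRUE) {
  if (!is(values, "RleList"))
    values <- methods::as(values, "RleList")
  new("DifferenceTrack", values = values, binWidth = as.integer(binWidth),
      totalReads = as.numeric(totalReads), normalized = normalized)
}

#' @describeIn CoverageTrack per-chromosome signal as an \code{RleList}
#' @param x,object a \code{CoverageTrack}
#' @export
setGeneric("trackValues", function(x) standardGeneric("trackValues"))
#' @export
setMethod("trackValues", "CoverageTrack", function(x) x@values)

#' @describeIn CoverageTrack bin width in bp
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))
#' @export
setMethod("binWidth", "CoverageTrack", function(x) x@binWidth)

#' @describeIn CoverageTrack read count the track was built from
#' @export
setGeneric("totalReads", function(x) standardGeneric("totalReads"))
#' @export
setMethod("totalReads", "CoverageTrack", function(x) x@totalReads)

#' @describeIn CoverageTrack has the track been scaled to reads per million?
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))
#' @export
setMethod("isNormalized", "CoverageTrack", function(x) x@normalized)

setMethod("show", "CoverageTrack", function(object) {
  cat(class(object), "with", length(object@values), "chromosome(s)\n")
  cat("  bin width:", object@binWidth, "bp",
      if (object@binWidth == 1L) "(base resolution)" else "", "\n")
  cat("  total reads:", format(object@totalReads), "\n")
  cat("  normalized (per million):", object@normalized, "\n")
  for (nm in utils::head(names(object@values), 3)) {
    v <- object@values[[nm]]
    cat(sprintf("  %s: %d bins, max %.4g\n", nm, length(v),
                if (length(v)) max(v) else NA))
  }
  if (length(object@values) > 3) cat("  ...\n")
})

#' TSS-anchored average occupancy profile
#'
#' Average signal as a function of signed distance from the transcription
#' start site, strand-oriented so that positive offsets are downstream.
#'
#' @slot offsets integer offsets in bp, typically \code{-W .. W-1}.
#' @slot values numeric mean signal per offset.
#' @slot nGenes number of genes averaged.
#' @export
setClass("MetageneProfile",
         representation(offsets = "integer", values = "numeric",
                        nGenes = "integer"))

setValidity("MetageneProfile", function(object) {
  if (length(object@offsets) != length(object@values))
    "offsets and values must have equal length"
  else TRUE
})

#' @describeIn MetageneProfile constructor
#' @param offsets,values,nGenes see slots
#' @export
MetageneProfile <- function(offsets, values, nGenes) {
  new("MetageneProfile", offsets = as.integer(offsets),
      values = as.numeric(values), nGenes = as.integer(nGenes))
}

#' @describeIn MetageneProfile offsets in bp
#' @param x,object a \code{MetageneProfile}
#' @export
setGeneric("profileOffsets", function(x) standardGeneric("profileOffsets"))
#' @export
setMethod("profileOffsets", "MetageneProfile", function(x) x@offsets)

#' @describeIn MetageneProfile signal values per offset
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))
#' @export
setMethod("profileValues", "MetageneProfile", function(x) x@values)

#' @describeIn MetageneProfile number of genes averaged
#' @export
setGeneric("nGenes", function(x) standardGeneric("nGenes"))
#' @export
setMethod("nGenes", "MetageneProfile", function(x) x@nGenes)

setMethod("show", "MetageneProfile", function(object) {
  cat("MetageneProfile over", length(object@offsets), "offsets (",
      min(object@offsets), "..", max(object@offsets), "bp ),",
      object@nGenes, "genes\n")
  i <- which.max(object@values)
  cat(sprintf("  peak %.4g at offset %+d bp; area %.4g\n",
              object@values[i], object@offsets[i], sum(object@values)))
})

#' Reverse-complement-collapsed 8-mer affinity table
#'
#' One row per reverse-complement class of 8-mers (32,896 classes: 32,640
#' two-member classes plus 256 palindromes), with the raw PBM fluorescence
#' intensity and the relative in vitro occupancy obtained by dividing by the
#' intensity of the best-bound 8-mer, so occupancies lie in (0, 1] with
#' exactly one class at 1.
#'
#' @slot table \code{data.frame} with columns \code{kmer} (canonical,
#'   lexicographically smaller orientation), \code{revcomp},
#'   \code{intensity}, \code{occupancy}.
#' @export
setClass("EightMerTable", representation(table = "data.frame"))

setValidity("EightMerTable", function(object) {
  tb <- object@table
  msg <- NULL
  need <- c("kmer", "revcomp", "intensity", "occupancy")
  if (!all(need %in% names(tb)))
    return(paste("table must have columns", paste(need, collapse = ", ")))
  if (nrow(tb) != 32896L)
    msg <- c(msg, sprintf("expected 32896 collapsed 8-mer classes, got %d",
                          nrow(tb)))
  if (any(tb$kmer > tb$revcomp))
    msg <- c(msg, "kmer must be the lexicographically smaller orientation")
  if (nrow(tb) && (min(tb$occupancy) <= 0 ||
                   abs(max(tb$occupancy) - 1) > 1e-9))
    msg <- c(msg, "occupancies must lie in (0, 1] with max exactly 1")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn EightMerTable constructor from a complete collapsed table
#' @param table data.frame as described for the \code{table} slot
#' @export
EightMerTable <- function(table) {
  new("EightMerTable", table = as.data.frame(table))
}

#' @describeIn EightMerTable the underlying data.frame
#' @param x,object an \code{EightMerTable}
#' @export
setGeneric("kmerTable", function(x) standardGeneric("kmerTable"))
#' @export
setMethod("kmerTable", "EightMerTable", function(x) x@table)

setMethod("show", "EightMerTable", function(object) {
  tb <- object@table
  top <- tb[which.max(tb$occupancy), ]
  cat("EightMerTable:", nrow(tb), "collapsed 8-mer classes\n")
  cat(sprintf("  top 8-mer: %s (intensity %.4g)\n", top$kmer, top$intensity))
  cat(sprintf("  occupancy range: %.3g .. 1\n", min(tb$occupancy)))
})

#' @describeIn EightMerTable look up relative in vitro occupancy for
#'   arbitrary 8-mers (either orientation); returns NA for k-mers with
#'   non-ACGT characters.
#' @param kmers character vector of 8-mers
#' @export
setGeneric("kmerOccupancy", function(x, kmers) standardGeneric("kmerOccupancy"))
#' @export
setMethod("kmerOccupancy", "EightMerTable", function(x, kmers) {
  ok <- grepl("^[ACGT]{8}$", kmers)
  res <- rep(NA_real_, length(kmers))
  if (any(ok)) {
    canon <- .canonical_kmer(kmers[ok])
    res[ok] <- x@table$occupancy[match(canon, x@table$kmer)]
  }
  res
})
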