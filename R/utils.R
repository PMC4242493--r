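# shared internal helpers

#' @importFrom methods is new validObject slot
#' @importFrom stats rnorm rlnorm rgamma quantile
NULL

# evaluate expr with a locally-set RNG seed, restoring global state afterwards
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(seed)
  }
  force(expr)
}

.assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop(sprintf("'%s' must be a single number in [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  invisible(x)
}

# seqlengths as a plain named numeric, from a DNAStringSet or a GRanges
.seq_lengths <- function(x) {
  if (is(x, "DNAStringSet")) {
    stats::setNames(Biostrings::width(x), names(x))
  } else {
    sl <- GenomeInfoDb::seqlengths(x)
    if (any(is.na(sl)))
      stop("seqlengths must be set on the input ranges", call. = FALSE)
    sl
  }
}

.revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# reverse-complement-collapsed (canonical) form of a character k-mer vector
.canonical_kmer <- function(x) {
  rc <- .revcomp_chr(x)
  ifelse(x <= rc, x, rc)
}
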