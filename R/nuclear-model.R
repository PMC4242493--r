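#' Nuclear occupancy arithmetic
#'
#' Back-of-envelope quantities connecting the copy number of a transcription
#' factor, the volume of a mammalian nucleus, and the amount of accessible
#' (nucleosome-free) DNA: the factor's nuclear concentration, the
#' accessible base pairs per factor molecule, and the expected genomic
#' spacing of the top-affinity k-mers.  Values are returned at full
#' precision; rounding is left to the presentation layer.
#'
#' @name nuclearModel
NULL

#' @describeIn nuclearModel molar concentration of \code{molecules}
#'   molecules in \code{volume} liters: \code{molecules / (avogadro *
#'   volume)}.  A mammalian nucleus is about 4e-13 L.
#' @param molecules molecule count (> 0 where divided by).
#' @param volume nuclear volume in liters (> 0).
#' @param avogadro Avogadro's number.
#' @return \code{molarConcentration}: mol/L.
#' @export
molarConcentration <- function(molecules, volume = 4e-13,
                               avogadro = 6.02214076e23) {
  stopifnot(volume > 0, avogadro > 0)
  molecules / (avogadro * volume)
}

#' @describeIn nuclearModel accessible base pairs per cell:
#'   \code{genomeSize * accessibleFraction * ploidy}.
#' @param genomeSize haploid genome size in bp.
#' @param accessibleFraction fraction of the genome free of histones
#'   (about 0.03).
#' @param ploidy genome copies per cell.
#' @return \code{accessibleBp}: base pairs.
#' @export
accessibleBp <- function(genomeSize = 3e9, accessibleFraction = 0.03,
                         ploidy = 2) {
  stopifnot(genomeSize > 0, accessibleFraction > 0, accessibleFraction <= 1,
            ploidy > 0)
  genomeSize * accessibleFraction * ploidy
}

#' @describeIn nuclearModel accessible DNA per factor molecule:
#'   \code{accessible / molecules}.
#' @param accessible accessible base pairs.
#' @return \code{bpPerMolecule}: base pairs per molecule.
#' @export
bpPerMolecule <- function(accessible, molecules) {
  stopifnot(molecules > 0)
  accessible / molecules
}

#' @describeIn nuclearModel expected spacing between occurrences of any of
#'   the \code{nTop} top k-mers on a uniform-composition single strand:
#'   \code{4^k / nTop}.  (Reverse-complement occurrences are deliberately
#'   not double-counted.)
#' @param k motif length.
#' @param nTop number of top k-mers considered.
#' @return \code{expectedMotifSpacing}: base pairs.
#' @export
expectedMotifSpacing <- function(k = 8, nTop = 16) {
  stopifnot(k >= 1, nTop >= 1, nTop <= 4^k)
  4^k / nTop
}
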