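---
title: "Genome occupancy versus intrinsic DNA-binding affinity: models and methods"
author: "chipaffinity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome occupancy versus intrinsic DNA-binding affinity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipaffinity)
```

## The scientific question

Sequence-specific transcription factors such as the Myc-Max bHLHZip
heterodimer are classically assumed to occupy the genome where their
preferred DNA elements (for Myc-Max, the E-box CACGTG and variants) occur.
An alternative view is that, for factors expressed at high nuclear
concentration with substantial non-specific affinity, occupancy is set
mainly by the transcription machinery and chromatin accessibility, with
intrinsic sequence preference contributing only at the margin.

`chipaffinity` implements the computational side of testing these two
views against each other:

1. build normalized occupancy tracks from aligned ChIP-seq reads;
2. summarize occupancy around transcription start sites (metagene
   profiles, rank-ordered heatmap matrices);
3. quantify genome-wide co-localization of factors with a bounded
   similarity score;
4. call peaks with contributing-read heights and form differential
   (e.g. Max − Myc) occupancy tracks;
5. turn universal protein-binding microarray (PBM) 8-mer intensities into
   relative in vitro occupancies and scan genomes for high-affinity
   sites;
6. ask, with ROC/AUC, rank and Fisher statistics, whether in vitro
   affinity predicts in vivo occupancy against an accessible-chromatin
   background;
7. check the back-of-envelope nuclear arithmetic (factor concentration,
   accessible DNA per molecule, expected spacing of top motifs).

Because the original experiments require large external downloads, the
package ships a synthetic-data generator that emulates every input with
*planted ground truth*, so each stage — and the pipeline end to end — is
testable offline.

## Track building

Reads are single-end 5' positions with strand. A plus-strand read at
position $s$ (0-based) is extended to the fragment $[s, s+L)$ and a
minus-strand read to $[s-L, s)$, with $L = 200$ bp by default,
approximating the sequenced fragment; fragments are clipped at chromosome
ends. Binned tracks (default 25 bp, tiling from coordinate 0) store the
number of fragments overlapping each bin — read-count semantics rather
than per-base means, so a peak's bin value reflects how many fragments
support it. Reads-per-million scaling (`normalizeRpm`) and per-million
difference tracks (`differenceTrack`, each input scaled to $10^6$ total
reads before subtraction) make depths comparable. At most two reads per
(chromosome, start, strand) are kept by `capDuplicates`; strand is part
of the key so opposite-strand stacks at a binding site are not collapsed.

## Metagene profiles and heatmaps

`metageneProfile` tabulates base-resolution signal in a $[-W, +W)$ window
around each TSS ($W = 10^4$ bp, i.e. exactly 20,000 data points), flipping
minus-strand genes so positive offsets are downstream. Two
post-processing steps are deliberately ordered: `subtractFloor` removes
the mean of the lowest 10% of positional values (the profile's baseline;
negatives are clamped to zero so areas stay interpretable), then
`areaNormalize` scales the curve to unit area so datasets of different
depth and enrichment can be overlaid or summed (`combineProfiles`).
Normalizing before flooring gives a different curve, which is why the
order is fixed.

`heatmapMatrix` exports genes-by-offset matrices (default ±2 kb) for a
set of tracks, all sharing one row order: descending window sums of a
designated ranking track (typically Pol II), ties broken by gene id so
the output is deterministic. Image rendering is intentionally out of
scope; matrices are written as TSV.

## The track similarity score

Two background-thresholded, identically normalized tracks $a$ and $b$ are
compared through $D = \sum_i |a_i - b_i|$ and mapped to
$$\mathrm{sim}(a,b) = 1 - \frac{D}{\sum_i a_i + \sum_i b_i},$$
which is exactly 1 for identical tracks, exactly 0 for tracks with
disjoint support, and lies in $[0,1]$ for non-negative tracks. The
$[0,1]$ mapping is this package's reconstruction anchored on those two
boundary cases; published similarity values from other pipelines are
therefore comparable only in their ordering, not digit by digit.
Before comparison, `backgroundThreshold` sorts the nonzero positional
values, subtracts the value at the 95th cumulative percentile (removing
the mass carried by isolated single reads), clamps at zero and rescales
the surviving signal to a total of $10^6$. That rescaling makes the score
invariant to overall depth: $\mathrm{sim}(a, c \cdot a) = 1$ for any
$c > 0$.

## Peak calling

The caller is a deliberately simple greedy scheme honoring two
constraints: the height of a peak is the *number of reads contributing*
to it, not the coverage value at its summit, and peaks below a minimum
height (default 30) are discarded. Iteratively: take the genome-wide
maximum of extended-read coverage; the summit is the midpoint of the
first maximal plateau (deterministic and independent of read input
order); the height is the count of fragments overlapping summit
$\pm L/2$; those fragments are removed from the pile and the search
repeats while the remaining coverage maximum is at least the height
threshold. Every fragment covering a summit also overlaps its window, so
each emitted peak has height ≥ the threshold and each fragment
contributes to at most one peak (so the heights sum to at most the
fragment count).

Differential (extra-Max) peaks run the same greedy sweep on the
difference track, with heights equal to difference values (read identity
is lost after subtraction) and the window around each summit blanked.
Because the sweep itself does not depend on the threshold, peak sets at a
stricter threshold are always nested inside the laxer ones.

## PBM processing and affinity scanning

All $4^8 = 65{,}536$ 8-mers collapse into
$(4^8 + 4^4)/2 = 32{,}896$ reverse-complement classes (256 of them
palindromic); the canonical key is the lexicographically smaller
orientation. `collapseAndNormalize` averages per-orientation intensities
within a class (arithmetic mean; universal-PBM pipelines vary here and
the choice is documented rather than consequential) and divides by the
intensity of the best-bound 8-mer, giving relative in vitro occupancies
in $(0, 1]$ with exactly one class at 1.

`topCore6mers` extracts the central 6-mer of each top-ranked 8-mer class
(collapsed; the central 6-mer of a reverse complement is the reverse
complement of the central 6-mer, so each class contributes one core) and
orders distinct cores by their best containing 8-mer.
`genome6merTrack` then reports every genomic match of the chosen cores,
on either strand, scored by the occupancy of the 8-mer obtained by
extending that particular match one base on each side — the local
affinity of the site, not the global best for the core — as a percent of
the top 8-mer. `best8merInWindow` scans all 8-mer positions fully inside
a window (default 100 bp, clipped at chromosome ends; windows shorter
than 8 bases are an error) and returns the maximum occupancy; windows
containing non-ACGT characters fall back to the valid positions.

## Occupancy-versus-affinity statistics

Peaks and accessible-background windows are scored by
`best8merInWindow`/`scoreRegions`; the background is drawn by
`sampleAccessibleWindows`, uniform over all eligible start positions
inside accessible intervals. The comparison battery is:

* `rocCurve` — unique-threshold sweep with trapezoidal AUC; equal scores
  collapse to one cutoff, so the AUC equals the all-pairs probability
  that a peak outscores a background window (ties count one half);
* `wilcoxonRankSum`, `spearmanCor` — thin wrappers over R's
  `wilcox.test` (unpaired, two-sided; exact for small tie-free samples)
  and `cor.test(method = "spearman", exact = FALSE)` (Pearson on
  mid-ranks, t-approximation p). Identical degenerate samples, where the
  normal approximation is 0/0, are reported as $p = 1$;
* `fisherOverlap` — a 2×2 window-by-feature table with the two-sided
  hypergeometric exact p (minimum-likelihood summation, the convention
  behind `dhyper`-based practice; the source analyses named the function
  without a sidedness, so the common two-sided convention is adopted);
* `logBinSummary` — boxplot statistics over equal-width bins in
  log(height), using type-7 (linear interpolation) quantiles, whiskers at
  the most extreme points within 1.5 × IQR, outliers listed;
* `expressionRankDistribution` — ranks of a gene subset within the top
  expressed genes, with a one-sample Kolmogorov–Smirnov statistic
  against uniformity.

## Nuclear occupancy arithmetic

Four closed-form quantities connect copy number to occupancy: molar
concentration $N/(N_A V)$ with the nuclear volume $V = 4\times10^{-13}$ L
(so 362,000 molecules ≈ 1.5 µM and 13,000 ≈ 54 nM — the unrounded value
behind the conventional "50 nM"); accessible base pairs
$G \cdot f \cdot p$ (3×10⁹ bp × 3% accessible × 2 genome copies
= 1.8×10⁸ bp); accessible DNA per molecule (≈ 500 bp at full
induction); and the expected spacing of the top $n$ 8-mers,
$4^8/n$ (4,096 bp for $n=16$), under a uniform-composition single-strand
occurrence model — reverse-complement hits are deliberately not double
counted, which is what makes the 4,096 figure comparable with the
conventional "every 4,000 bp". All values are returned at full precision;
rounding is left to presentation.

## What the synthetic data emulate — and what they do not

`generateGenome` draws i.i.d. bases at a stated GC fraction (default
0.41, human-like). `simulateChipReads` places, per TSS, binding points
from Normal(TSS + strand-adjusted offset, sd) and emits reads half on
each strand positioned so the 200-bp extension is centered on the
binding point (mimicking ChIP fragment symmetry, so pileups summit at
the binding site); out-of-bounds draws are redrawn rather than clipped to
avoid edge pileups. Default planted offsets follow the promoter
architecture of interest: paused Pol II at +83 bp, Myc at −20, Max at
−35, plus an intragenic CTCF-like factor for similarity contrasts.
Promoter spread defaults (sd 40–45 bp) reflect the envelope of paused
polymerase; planted point-source clusters for the peak-caller checks use
sd 15 bp and ≥100 reads, matching the sharpness at which such datasets
resolve individual sites (25–50 bp).

`simulatePbmIntensities` builds one intensity per collapsed 8-mer class:
baseline × the best core-times-flank multiplier over the contained
6-mers in either orientation × multiplicative lognormal noise (mean 1,
CV 0.15). The default model plants the canonical E-box hierarchy —
CACGTG strongest at 50× baseline, eleven weaker variant cores (18× down
to 5×), and flanking-base modifiers (e.g. C·G flanks 1.5×, T·A flanks
0.3×) so that CCACGTGG is the best-bound 8-mer and poor flanks cost
several-fold, echoing the flank sensitivity seen in real PBM data. The
resulting dynamic range (≈75-fold) is of the same order as measured
tables.

`generateAccessibleRegions` covers ≈3% of the genome with non-overlapping
DHS-like intervals (gamma widths around 600 bp);
`generateExpressionTable` draws log-normal RNA levels (sdlog 1.6)
spanning well over three orders of magnitude for 1,000+ genes.

What the generator does *not* model: sequencing errors, mappability,
paired-end fragments, GC bias, nucleosome positioning, or any coupling
between DNA sequence and simulated read placement. That last omission is
the point of the null: reads are planted at TSSs *irrespective of
sequence*, so affinity-based prediction of occupancy should hover at
chance — and tests assert exactly that (null AUC near 0.5, most peak
windows on low-affinity 8-mers). Conversely, planting high-affinity
8-mers in a known fraction of windows must raise the AUC monotonically.
Passing these tests demonstrates that the machinery measures what it
claims on data with known truth; it does not by itself establish any
property of real chromatin.

## Numerical and design choices

* Coordinates are 1-based closed in memory (the GRanges idiom) and
  0-based half-open in every file format except WIG (1-based, per the
  format); conversion happens only at I/O.
* TSS curation: same-gene starts chain-merge at ≤500 bp (single
  linkage), represented by the 5'-most start on the gene's strand; then
  any two surviving starts closer than 1,000 bp — regardless of gene or
  strand — are both removed. The representative and the mutual-removal
  readings are design choices (the curation rules as usually stated are
  silent on both); the result is idempotent and guarantees unambiguous
  metagene windows.
* Metagene windows are $[-W, +W)$: offset 0 included, $+W$ excluded, so
  the default window has exactly 20,000 points and the floor is the
  lowest 2,000.
* Peak summit ties resolve to the first maximal plateau's midpoint;
  heatmap ties to gene id; nearest-TSS ties to the upstream
  (lower-coordinate) TSS.
* Test and demonstration problem sizes — a 2-Mb toy genome, 200 TSSs,
  10⁵ promoter reads per factor, 2,500-window ROC sets — are chosen so
  the planted parameters are recovered with comfortable statistical
  margin (offsets to ±10 bp, null AUC within ±0.02) while a full run
  stays in the tens of seconds.

## Known limitations

* Differential-track thresholds (0.5 and 1.0 in per-million units) are
  calibrated for production sequencing depths, where a single unmatched
  read contributes ≪ 0.5 after scaling. At demo depths (10⁴ reads) a
  single read already exceeds them, so demo extra-Max lists contain many
  single-read fluctuations besides the planted loci — which still lead
  the list by orders of magnitude in height. Tests therefore assert
  recovery of planted excess and threshold nesting, not list purity.
* The similarity score's mapping to $[0,1]$ is a reconstruction; only
  orderings should be compared across implementations.
* The greedy peak caller has no statistical significance model (no
  Poisson/local-lambda background, no control-track correction); the
  height threshold is an absolute read count.
* `best8merInWindow` treats all-N windows as `NA` rather than an error;
  downstream statistics drop `NA` scores.
* The nuclear model is deliberately first-order: it ignores competition
  between factors, cooperative binding, and the distinction between
  biochemical accessibility and DNase-defined accessibility.

## A minimal run

```{r, eval = FALSE}
cfg <- runConfig(seed = 1, chromLength = 5e5, nTss = 50,
                 readsPerTss = 150, backgroundReads = 2000,
                 nRandomWindows = 2000)
res <- runPipeline(cfg, outDir = "demo_run")
res$similarity          # factor-by-factor similarity matrix
res$peakOffsets         # recovered metagene argmax offsets
res$roc$auc             # affinity-vs-background AUC
res$fractionBelowCutoff # fraction of peaks on low-affinity 8-mers
```

Every artifact (tracks, profiles, peaks, score tables, statistics) is
written under `outDir` together with a manifest of parameters and file
checksums; rerunning the same configuration reproduces the manifest
byte for byte.
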