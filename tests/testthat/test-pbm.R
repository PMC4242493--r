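test_that("reverse-complement collapsing yields the expected class counts", {
  k8 <- enumerateCollapsedKmers(8L)
  expect_length(k8, 32896L)
  # palindromic (self-reverse-complement) classes: 4^4 = 256
  rc <- as.character(reverseComplement(DNAStringSet(k8)))
  expect_equal(sum(k8 == rc), 256L)
  # every class key is the smaller orientation and classes partition 4^8
  expect_true(all(k8 <= rc))
  expect_equal(2L * length(k8) - 256L, 4L^8L)
  # k = 2 analog by exhaustive enumeration: 10 classes
  expect_length(enumerateCollapsedKmers(2L), 10L)
})

test_that("intensity collapsing and normalization anchor the top class at 1", {
  tb <- kmerTable(plantedPbmTable(noise = TRUE))
  expect_equal(max(tb$occupancy), 1.0)
  expect_true(all(tb$occupancy > 0))
  expect_equal(tb$occupancy, tb$intensity / max(tb$intensity))

  # uniform intensities: every occupancy is 1
  canon <- enumerateCollapsedKmers(8L)
  uni <- collapseAndNormalize(setNames(rep(7, length(canon)), canon))
  expect_true(all(kmerTable(uni)$occupancy == 1))

  # per-orientation input: the two orientations of a class are averaged
  all8 <- mkAllStrings(c("A", "C", "G", "T"), 8L)
  raw <- setNames(rep(10, length(all8)), all8)
  raw[["AAAAAAAA"]] <- 30  # its revcomp TTTTTTTT stays 10 -> mean 20
  tab <- kmerTable(collapseAndNormalize(raw))
  expect_equal(tab$intensity[tab$kmer == "AAAAAAAA"], 20)
  expect_equal(max(tab$intensity), 20)

  expect_error(collapseAndNormalize(raw[-1]), "missing")
  expect_error(collapseAndNormalize(setNames(c(-1, raw[-1]), names(raw))),
               "positive")
})

test_that("occupancy lookup is orientation-blind and NA-safe", {
  tb <- plantedPbmTable()
  expect_equal(kmerOccupancy(tb, "CCACGTGG"), 1.0)
  fwd <- kmerOccupancy(tb, "ACGTGGAT")
  expect_equal(kmerOccupancy(tb, "ATCCACGT"), fwd)   # reverse complement
  expect_true(is.na(kmerOccupancy(tb, "ACGTNGAT")))
})

test_that("top core extraction recovers the planted hierarchy", {
  # a single planted core, scanned at depth 1, yields exactly that core
  single <- collapseAndNormalize(simulatePbmIntensities(
    pbmModelSpec(coreEffects = c(CACGTG = 50), flankEffects = c(CG = 1.5),
                 noiseCv = 0)))
  cores1 <- topCore6mers(single, topN = 1L)
  expect_equal(cores1$core, "CACGTG")
  expect_equal(cores1$bestOccupancy, 1.0)

  # every returned core is the central 6-mer of some top-N 8-mer
  tb <- kmerTable(single)
  tb <- tb[order(-tb$occupancy, tb$kmer), ]
  topCentrals <- chipaffinity:::.canonical_kmer(substr(head(tb$kmer, 50L),
                                                       2, 7))
  cores50 <- topCore6mers(single, topN = 50L)
  expect_true(all(cores50$core %in% topCentrals))

  # planted strongest core leads the default table's ranking
  full <- topCore6mers(plantedPbmTable(), topN = 200L)
  expect_equal(full$core[1], "CACGTG")
  expect_equal(full$bestOccupancy[1], 1.0)
})

test_that("core 6-mer genome tracks score each site by its local 8-mer", {
  tb <- plantedPbmTable()
  # genome that is exactly the top 8-mer: one site at full height
  g1 <- DNAStringSet(c(chr1 = "CCACGTGG"))
  tr1 <- genome6merTrack(g1, "CACGTG", tb)
  expect_equal(nrow(tr1), 1L)
  expect_equal(tr1$pos, 2L)
  expect_equal(tr1$height, 100)

  # a minus-strand core is reported once, at the plus-strand position of
  # its reverse complement
  g3 <- DNAStringSet(c(chr1 = "TTCACATGTT"))  # core CACATG; rc CATGTG
  tr3 <- genome6merTrack(g3, "CACATG", tb)
  expect_equal(nrow(tr3), 1L)
  expect_equal(tr3$core, "CACATG")
  tr3rc <- genome6merTrack(g3, "CATGTG", tb)   # same core, other orientation
  expect_equal(tr3rc$pos, tr3$pos)

  # brute-force scan oracle on a random sequence with planted sites
  g <- generateGenome(genomeSpec(1, 1000, 0.5, seed = 23))
  g <- plantMotifs(g, data.frame(chrom = "chr1", pos = c(100, 300, 500),
                                 seq = c("CACGTG", "CACATG", "CATGTG")))
  got <- genome6merTrack(g, c("CACGTG", "CACATG"), tb)
  seqc <- as.character(g[[1]])
  brute <- list()
  for (core in c("CACGTG", "CACATG")) {
    pats <- unique(c(core, as.character(reverseComplement(DNAString(core)))))
    for (p in 2:(1000 - 6)) {
      hex <- substr(seqc, p, p + 5)
      if (hex %in% pats && p + 6 <= 1000) {
        oc <- kmerOccupancy(tb, substr(seqc, p - 1, p + 6))
        brute[[length(brute) + 1]] <-
          data.frame(pos = p, core = chipaffinity:::.canonical_kmer(core),
                     height = 100 * oc)
      }
    }
  }
  brute <- do.call(rbind, brute)
  brute <- brute[order(brute$pos, brute$core), ]
  expect_equal(got$pos, brute$pos)
  expect_equal(got$height, brute$height)
})

test_that("window scanning matches brute force and is strand-symmetric", {
  tb <- plantedPbmTable()
  g <- generateGenome(genomeSpec(1, 5000, 0.45, seed = 27))

  planted <- plantMotifs(g, data.frame(chrom = "chr1", pos = 2000,
                                       seq = "CCACGTGG"))
  expect_equal(best8merInWindow(planted, "chr1", 2004, 50, tb), 1.0)

  polyA <- plantMotifs(g, data.frame(chrom = "chr1", pos = 3000,
                                     seq = strrep("A", 120)))
  expect_equal(best8merInWindow(polyA, "chr1", 3060, 50, tb),
               kmerOccupancy(tb, "AAAAAAAA"))

  set.seed(41)
  for (center in sample(60:4940, 25)) {
    expect_equal(best8merInWindow(g, "chr1", center, 50, tb),
                 bruteBest8mer(g, "chr1", center, 50, tb))
  }

  # invariance under reverse-complementing the genome
  grc <- DNAStringSet(reverseComplement(g[[1]]))
  names(grc) <- "chr1"
  for (center in c(500, 1500, 2500)) {
    expect_equal(best8merInWindow(g, "chr1", center, 50, tb),
                 best8merInWindow(grc, "chr1", 5000 - center + 1, 50, tb))
  }

  expect_error(best8merInWindow(g, "chr1", 3, 2, tb), "shorter than 8")
})
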