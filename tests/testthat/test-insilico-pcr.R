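test_that("an embedded primer is found at its constructed offset", {
  primer <- "GTCGGTAAAACTCGTGCCAGC"
  set.seed(1)
  tmpl <- paste0(rand_dna(73), primer, rand_dna(200 - 73 - nchar(primer)))
  sites <- findBindingSites(primer, tmpl, maxMismatch = 0)
  expect_identical(sites$start, 73L)
  expect_identical(sites$mismatches, 0L)
  expect_false(sites$wraps)
})

test_that("binding sites are nested as the mismatch cap grows", {
  set.seed(2)
  primer <- rand_primer(18)
  for (i in 1:25) {
    tmpl <- rand_dna(300)
    prev <- character(0)
    for (k in 0:3) {
      s <- findBindingSites(primer, tmpl, maxMismatch = k)
      cur <- paste(s$start, s$end)
      expect_true(all(prev %in% cur))
      prev <- cur
    }
  }
})

test_that("a site split across the origin of a circular record is reported once", {
  primer <- "ACGTACGTACGTACGTAAGG"
  set.seed(3)
  body <- rand_dna(180)
  # last 8 primer bases at the sequence start, first 12 at the end
  tmpl <- paste0(substr(primer, 13, 20), body, substr(primer, 1, 12))
  circ <- findBindingSites(primer, tmpl, maxMismatch = 0,
                           topology = "circular")
  expect_identical(nrow(circ), 1L)
  expect_identical(circ$start, nchar(tmpl) - 12L)
  expect_true(circ$wraps)
  # the same scan on a linear molecule finds nothing
  lin <- findBindingSites(primer, tmpl, maxMismatch = 0)
  expect_identical(nrow(lin), 0L)
})

test_that("a primer longer than the reference yields an empty result", {
  s <- findBindingSites(strrep("ACGT", 20), "ACGTACGT", maxMismatch = 3)
  expect_identical(nrow(s), 0L)
})

test_that("a constructed amplicon is recovered with the expected length", {
  pair <- PrimerPair("toy", "12S", "GCCTATATACCGCCGTCG",
                     "GTACACTTACCATGTTACGACTT")
  set.seed(4)
  insert <- rand_dna(150)
  seqs <- paste0(rand_dna(40), forwardSeq(pair), insert,
                 reverseComplementIupac(reverseSeq(pair)), rand_dna(40))
  refs <- toy_refs(seqs)
  hits <- inSilicoPCR(pair, refs, maxMismatch = 0)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$length,
                   nchar(forwardSeq(pair)) + 150L + nchar(reverseSeq(pair)))
  expect_identical(hits$start, 40L)
  expect_identical(hits$orientation, "+")
  # amplicon sequence starts with the forward primer site
  amp <- unname(as.character(ampliconSeqs(hits, refs)))
  expect_identical(substr(amp, 1, 18), forwardSeq(pair))
})

test_that("with two reverse sites only the shorter product is kept per forward site", {
  fwd <- "ACGGATTACGGATTACCA"
  rev <- "TTGGCCAATTGGCCAATG"
  rc <- reverseComplementIupac(rev)
  set.seed(5)
  tmpl <- paste0(rand_dna(30), fwd, rand_dna(100), rc, rand_dna(80), rc,
                 rand_dna(30))
  refs <- toy_refs(tmpl)
  pair <- PrimerPair("toy", "16S", fwd, rev)
  hits <- inSilicoPCR(pair, refs, maxMismatch = 0)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$length, nchar(fwd) + 100L + nchar(rc))
  # the independent enumeration oracle agrees
  orc <- oracle_pcr(fwd, rev, tmpl, 0, 50, 1000)
  expect_identical(canon_hits(hits), canon_hits(orc))
})

test_that("minus-strand products are reported in forward coordinates", {
  fwd <- "ACGGATTACGGATTACCA"
  rev <- "TTGGCCAATTGGCCAATG"
  set.seed(6)
  insert <- rand_dna(120)
  plus_amp <- paste0(fwd, insert, reverseComplementIupac(rev))
  tmpl <- paste0(rand_dna(25),
                 as.character(Biostrings::reverseComplement(
                   Biostrings::DNAString(plus_amp))), rand_dna(25))
  refs <- toy_refs(tmpl)
  pair <- PrimerPair("toy", "16S", fwd, rev)
  hits <- inSilicoPCR(pair, refs, maxMismatch = 0)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$orientation, "-")
  expect_identical(hits$start, 25L)
  expect_identical(hits$length, nchar(plus_amp))
})

test_that("reverse-complementing the reference mirrors hits and sequences", {
  pair <- tankPrimerPanel()[["Ve16S3"]]
  refs <- generateReferenceDb(3, panel = list("Ve16S3" = pair), seed = 8,
                              speciesNames = sprintf("Testfish sp%d", 1:3))
  hits <- inSilicoPCR(pair, refs, maxMismatch = 1)
  flipped <- toy_refs(
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(
      as.character(refs)))), species = refSpecies(refs))
  hits2 <- inSilicoPCR(pair, flipped, maxMismatch = 1)
  expect_identical(nrow(hits), nrow(hits2))
  L <- nchar(as.character(refs))
  # mirrored coordinates: start' = L - end
  m1 <- sort(paste(L[1] - hits$end, hits$length))
  m2 <- sort(paste(hits2$start, hits2$length))
  expect_identical(m1, m2)
  a1 <- sort(unname(as.character(ampliconSeqs(hits, refs))))
  a2 <- sort(unname(as.character(Biostrings::reverseComplement(
    ampliconSeqs(hits2, flipped)))))
  expect_identical(a1, a2)
})

test_that("reported hits reproduce their mismatch counts on re-scan", {
  set.seed(9)
  pair <- PrimerPair("toy", "12S", rand_primer(20), rand_primer(20))
  for (i in 1:20) {
    tmpl <- paste0(rand_dna(20), .mutate_n(forwardSeq(pair), 2),
                   rand_dna(120),
                   oracle_revcomp(.mutate_n(reverseSeq(pair), 2)),
                   rand_dna(20))
    refs <- toy_refs(tmpl)
    hits <- inSilicoPCR(pair, refs, maxMismatch = 3)
    for (k in seq_len(nrow(hits))) {
      amp <- as.character(ampliconSeqs(hits[k, ], refs))
      n <- nchar(amp)
      lf <- nchar(forwardSeq(pair)); lr <- nchar(reverseSeq(pair))
      if (hits$orientation[k] == "+") {
        fw <- substr(amp, 1, lf)
        rw <- oracle_revcomp(substr(amp, n - lr + 1, n))
      } else {
        fw <- oracle_revcomp(substr(amp, n - lf + 1, n))
        rw <- substr(amp, 1, lr)
      }
      expect_identical(countMismatches(forwardSeq(pair), fw),
                       hits$fwd_mm[k])
      expect_identical(countMismatches(reverseSeq(pair), rw),
                       hits$rev_mm[k])
    }
  }
})
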