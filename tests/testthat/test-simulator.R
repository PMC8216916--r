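test_that("generated references amplify exactly once per primer at zero mismatches", {
  panel <- tankPrimerPanel()
  refs <- generateReferenceDb(6, panel = panel, seed = 21)
  expect_identical(length(refs), 6L)
  for (pn in names(panel)) {
    hits <- inSilicoPCR(panel[[pn]], refs, maxMismatch = 0)
    expect_identical(nrow(hits), 6L)
    expect_identical(sort(hits$species), sort(refSpecies(refs)))
    expect_true(all(hits$fwd_mm == 0L & hits$rev_mm == 0L))
  }
})

test_that("between-species barcode identities stay at or below the ceiling", {
  pair <- tankPrimerPanel()[["MiFish-U"]]
  refs <- generateReferenceDb(6, panel = list("MiFish-U" = pair),
                              seed = 22)
  bc <- referenceBarcodes(refs, pair)
  expect_identical(length(bc), 6L)
  # cross-check with the Biostrings aligner as an independent oracle
  for (i in 1:5) for (j in (i + 1):6) {
    aln <- Biostrings::pairwiseAlignment(bc[[i]], bc[[j]])
    pid <- Biostrings::nmatch(aln) /
      (Biostrings::nmatch(aln) + Biostrings::nmismatch(aln) +
         sum(Biostrings::insertion(Biostrings::nindel(aln))[, "WidthSum"]) +
         sum(Biostrings::deletion(Biostrings::nindel(aln))[, "WidthSum"]))
    expect_lte(pid, 0.90)
  }
})

test_that("the same seed reproduces the reference database byte for byte", {
  r1 <- generateReferenceDb(4, seed = 23,
                            speciesNames = sprintf("Testfish sp%d", 1:4))
  r2 <- generateReferenceDb(4, seed = 23,
                            speciesNames = sprintf("Testfish sp%d", 1:4))
  expect_identical(as.character(r1), as.character(r2))
  expect_identical(refSpecies(r1), refSpecies(r2))
})

test_that("skewed abundance draws are positive integers with the lognormal mean", {
  x <- drawSkewedAbundances(50, seed = 24)
  expect_true(all(x >= 1L))
  expect_type(x, "integer")
  big <- drawSkewedAbundances(1e5, meanlog = 1.6, sdlog = 0.8, seed = 25)
  closed_form <- exp(1.6 + 0.8^2 / 2)
  expect_lt(abs(mean(big) / closed_form - 1), 0.02)
  expect_error(drawSkewedAbundances(5, sdlog = -1))
})

test_that("read shares follow biomass shares in the noise-free model", {
  species <- sprintf("Testfish sp%d", 1:2)
  design <- toy_design(species, biomass = c(20, 10))
  prof <- speciesProfiles(species, primers = "MiFish-U")
  cfg <- SimConfig(totalReadsPerSample = 30000, lognormalSigma = 0,
                   errorRate = 0)
  set.seed(26)
  counts <- simulateCounts(design, "MiFish-U", prof, cfg)
  expect_identical(sum(counts), 30000L)
  # exact binomial oracle for the 2:1 ratio
  expect_gt(binom.test(counts[[1]], 30000, 2 / 3)$p.value, 0.01)
})

test_that("negative-control designs yield zero fish reads", {
  species <- sprintf("Testfish sp%d", 1:3)
  nc <- toy_design(species, biomass = c(0, 0, 0), abundance = c(0, 0, 0))
  prof <- speciesProfiles(species, primers = "Ve16S1")
  refs <- generateReferenceDb(3, panel = tankPrimerPanel()["Ve16S1"],
                              seed = 27, speciesNames = species)
  set.seed(27)
  rs <- simulateTankSample(nc, tankPrimerPanel()[["Ve16S1"]], refs, prof,
                           SimConfig(totalReadsPerSample = 1000),
                           replicate = 1, tank = "NC")
  expect_identical(length(rs@mate1), 0L)
  expect_identical(sum(rs@truth), 0L)
})

test_that("a primer that cannot amplify a present species is a configuration error", {
  species <- sprintf("Testfish sp%d", 1:2)
  refs <- ReferenceSet(c(rand_dna(400), rand_dna(400)), species = species,
                       ids = c("R1", "R2"))  # no binding sites at all
  design <- toy_design(species, biomass = c(5, 5))
  prof <- speciesProfiles(species, primers = "MiFish-U")
  set.seed(28)
  expect_error(
    simulateTankSample(design, tankPrimerPanel()[["MiFish-U"]], refs,
                       prof, SimConfig(totalReadsPerSample = 100)),
    "Testfish sp")
})

test_that("sequencing errors are injected at the configured rate", {
  amp <- rand_dna(250)
  reads <- rep(amp, 600)  # 150,000 bases
  set.seed(29)
  mutated <- as.character(eDNAtank:::cpp_mutate_reads(reads, 0.01))
  mm <- vapply(mutated, function(r) eDNAtank:::cpp_hamming(r, amp),
               integer(1))
  rate <- sum(mm) / (250 * 600)
  expect_gt(rate, 0.008)
  expect_lt(rate, 0.012)
})

test_that("truth tables carry one column per sample with configured totals", {
  species <- sprintf("Testfish sp%d", 1:3)
  refs <- generateReferenceDb(3, panel = tankPrimerPanel()["MiFish-U"],
                              seed = 30, speciesNames = species)
  prof <- speciesProfiles(species, primers = "MiFish-U")
  cfg <- SimConfig(totalReadsPerSample = 500)
  pair <- tankPrimerPanel()[["MiFish-U"]]
  set.seed(31)
  readsets <- list()
  for (tk in c("T1", "T2", "T3", "T4")) for (r in 1:3) {
    design <- toy_design(species, biomass = c(10, 20, 30), tank = tk)
    readsets[[length(readsets) + 1L]] <-
      simulateTankSample(design, pair, refs, prof, cfg, r, tk)
  }
  tt <- emitTruthTable(readsets)
  expect_s4_class(tt, "SpeciesSampleTable")
  expect_identical(ncol(tt), 12L)
  expect_true(all(colSums(speciesCounts(tt)) == 500L))
  # single sample: the column equals its truth vector
  one <- emitTruthTable(readsets[1])
  expect_identical(unname(speciesCounts(one)[, 1]),
                   unname(readsets[[1]]@truth[rownames(speciesCounts(one))]))
})

test_that("simulation is deterministic under a fixed seed", {
  species <- sprintf("Testfish sp%d", 1:3)
  refs <- generateReferenceDb(3, panel = tankPrimerPanel()["Ve16S3"],
                              seed = 32, speciesNames = species)
  prof <- speciesProfiles(species, primers = "Ve16S3")
  design <- toy_design(species, biomass = c(1, 2, 3))
  cfg <- SimConfig(totalReadsPerSample = 400)
  pair <- tankPrimerPanel()[["Ve16S3"]]
  set.seed(33); a <- simulateTankSample(design, pair, refs, prof, cfg)
  set.seed(33); b <- simulateTankSample(design, pair, refs, prof, cfg)
  expect_identical(a@mate1, b@mate1)
  expect_identical(a@mate2, b@mate2)
  expect_identical(a@truth, b@truth)
})
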