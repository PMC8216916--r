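make_mates <- function(amp, L = 250, q = 30) {
  w <- min(L, nchar(amp))
  m1 <- substr(amp, 1, w)
  m2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(
    substr(amp, nchar(amp) - w + 1, nchar(amp)))))
  qc <- rawToChar(as.raw(q + 33))
  list(m1 = m1, q1 = strrep(qc, w), m2 = m2, q2 = strrep(qc, w))
}

test_that("error-free mates merge back into the amplicon", {
  set.seed(41)
  for (alen in c(170, 250, 321)) {
    amp <- rand_dna(alen)
    m <- make_mates(amp)
    res <- mergePairs(m$m1, m$q1, m$m2, m$q2)
    expect_identical(res$status, "merged")
    expect_identical(res$seq, amp)
  }
})

test_that("a 9-base true overlap is rejected at the 10-base minimum", {
  set.seed(42)
  amp <- rand_dna(491)  # 2 x 250 mates overlap by exactly 9
  m <- make_mates(amp)
  res <- mergePairs(m$m1, m$q1, m$m2, m$q2)
  expect_identical(res$status, "no_overlap")
  expect_true(is.na(res$seq))
  # one more base of overlap and the pair merges
  amp2 <- rand_dna(490)
  m2 <- make_mates(amp2)
  expect_identical(mergePairs(m2$m1, m2$q1, m2$m2, m2$q2)$status, "merged")
})

test_that("discordant overlap bases take the higher-quality call", {
  set.seed(43)
  amp <- rand_dna(300)
  m <- make_mates(amp)
  # corrupt one mate-1 base inside the overlap and lower its quality
  pos <- 260  # overlap region is bases 51..250 of mate 1? use tail base
  m1c <- m$m1
  old <- substr(m1c, 240, 240)
  substr(m1c, 240, 240) <- setdiff(c("A", "C", "G", "T"), old)[1]
  q1c <- m$q1
  substr(q1c, 240, 240) <- rawToChar(as.raw(2 + 33))
  res <- mergePairs(m1c, q1c, m$m2, m$q2)
  expect_identical(res$status, "merged")
  expect_identical(res$seq, amp)  # mate 2 wins the discordant column
  # and the low mean quality rejection triggers when qualities are poor
  lowq <- strrep(rawToChar(as.raw(10 + 33)), nchar(m$m1))
  res2 <- mergePairs(m$m1, lowq, m$m2, lowq)
  expect_identical(res2$status, "low_quality")
})

test_that("trimming rejects ambiguous, primer-less and short reads", {
  pair <- tankPrimerPanel()[["MiFish-U"]]
  lf <- nchar(forwardSeq(pair)); lr <- nchar(reverseSeq(pair))
  rc <- reverseComplementIupac(reverseSeq(pair))
  set.seed(44)
  core <- rand_dna(150)
  good <- paste0(forwardSeq(pair), core, rc)
  out <- qualityFilterAndTrim(good, pair)
  expect_identical(out$status, "ok")
  expect_identical(out$seq, core)
  # ambiguous base
  withN <- sub("^(.{60}).", "\\1N", good)
  expect_identical(qualityFilterAndTrim(withN, pair)$status, "ambiguous")
  # trimmed length 99 < 100
  short <- paste0(forwardSeq(pair), rand_dna(99), rc)
  expect_identical(qualityFilterAndTrim(short, pair)$status, "short")
  # forward primer with 3 mismatches exceeds the cap of 2
  fwd3 <- .mutate_to_n_mismatches(forwardSeq(pair), 3)
  bad <- paste0(fwd3, core, rc)
  expect_identical(qualityFilterAndTrim(bad, pair)$status, "fwd_primer")
  # 2 mismatches are tolerated
  fwd2 <- .mutate_to_n_mismatches(forwardSeq(pair), 2)
  ok2 <- paste0(fwd2, core, rc)
  expect_identical(qualityFilterAndTrim(ok2, pair)$status, "ok")
})

test_that("greedy clustering groups reads by identity threshold", {
  set.seed(45)
  a <- rand_dna(200)
  expect_identical(nrow(otuCounts(clusterOTUs(rep(a, 20)))), 1L)
  # a second group at ~95% identity opens a second OTU at 0.97
  b <- .mutate_to_n_mismatches(a, 10)
  id_ab <- eDNAtank:::cpp_align_identity(a, b)[["identity"]]
  expect_lt(id_ab, 0.97)
  ot <- clusterOTUs(c(rep(a, 20), rep(b, 10)))
  expect_identical(nrow(otuCounts(ot)), 2L)
  # the abundant sequence is the first centroid
  expect_identical(as.character(otuCentroids(ot)[[1]]), a)
  # reads within 3% of a centroid join it
  a2 <- .mutate_to_n_mismatches(a, 2)
  ot2 <- clusterOTUs(c(rep(a, 20), rep(a2, 5)))
  expect_identical(nrow(otuCounts(ot2)), 1L)
  expect_identical(sum(otuCounts(ot2)), 25L)
})

test_that("error-free reads of six divergent species give six OTUs", {
  pair <- tankPrimerPanel()[["MiFish-U"]]
  refs <- generateReferenceDb(6, panel = list("MiFish-U" = pair),
                              seed = 46)
  bc <- as.character(referenceBarcodes(refs, pair))
  reads <- rep(bc, times = c(30, 25, 20, 15, 12, 11))
  ot <- clusterOTUs(reads)
  expect_identical(nrow(otuCounts(ot)), 6L)
})

test_that("OTU filtering applies the strict <10 rule and conserves counts", {
  counts <- matrix(c(9L, 10L, 50L, 0L, 0L, 12L), 3, 2,
                   dimnames = list(c("OTU_0001", "OTU_0002", "OTU_0003"),
                                   c("s1", "s2")))
  cents <- Biostrings::DNAStringSet(c(OTU_0001 = rand_dna(120),
                                      OTU_0002 = rand_dna(120),
                                      OTU_0003 = rand_dna(120)))
  ot <- new("OTUTable", centroids = cents, counts = counts)
  f <- filterOTUs(ot)
  expect_identical(rownames(otuCounts(f)), c("OTU_0002", "OTU_0003"))
  expect_identical(otuCounts(f), counts[2:3, ])
  # all OTUs at or above 10 -> unchanged
  f2 <- filterOTUs(ot, minTotal = 9)
  expect_identical(otuCounts(f2), counts)
})

test_that("taxonomic assignment routes counts by identity with threshold semantics", {
  pair <- tankPrimerPanel()[["Ve16S1"]]
  refs <- generateReferenceDb(3, panel = list("Ve16S1" = pair), seed = 47,
                              speciesNames = sprintf("Testfish sp%d", 1:3))
  refdb <- referenceBarcodes(refs, pair)
  bc <- as.character(refdb)
  counts <- matrix(c(40L, 30L), 2, 1,
                   dimnames = list(c("OTU_0001", "OTU_0002"), "T1.1.Ve16S1"))
  # OTU 1 is an exact barcode; OTU 2 sits at ~95% identity to everything
  bc <- unname(bc)
  far <- .mutate_to_n_mismatches(bc[1], ceiling(0.05 * nchar(bc[1])))
  ot <- new("OTUTable",
            centroids = Biostrings::DNAStringSet(
              c(OTU_0001 = bc[2], OTU_0002 = far)),
            counts = counts)
  sst <- assignTaxonomy(ot, refdb)
  m <- speciesCounts(sst)
  expect_identical(m["Testfish sp2", 1], 40L)
  expect_identical(m["unassigned", 1], 30L)
  expect_error(assignTaxonomy(ot, Biostrings::DNAStringSet()), "empty")
})

test_that("rarefaction hits the target depth exactly and is idempotent", {
  set.seed(48)
  counts <- matrix(c(100L, 50L, 30L, 20L, 80L, 70L, 40L, 10L), 4, 2,
                   dimnames = list(paste0("sp", 1:4),
                                   c("T1.1.P", "T1.2.P")))
  sst <- SpeciesSampleTable(counts, tank = c("T1", "T1"),
                            replicate = 1:2, primer = "P")
  r <- rarefy(sst, 150, seed = 1)
  expect_true(all(colSums(speciesCounts(r)) == 150L))
  # depth equal to the column total leaves the column unchanged
  r2 <- rarefy(sst, 200, seed = 1)
  expect_identical(speciesCounts(r2), counts)
  expect_error(rarefy(sst, 500), "insufficient")
  # commutes with species-label permutation
  perm <- c(3, 1, 4, 2)
  sstp <- SpeciesSampleTable(counts[perm, ], tank = c("T1", "T1"),
                             replicate = 1:2, primer = "P")
  a <- speciesCounts(rarefy(sst, 120, seed = 9))
  b <- speciesCounts(rarefy(sstp, 120, seed = 9))
  expect_identical(sort(colSums(a)), sort(colSums(b)))
  expect_true(all(colSums(b) == 120L))
})

test_that("accumulation curves match the hypergeometric expectation", {
  counts <- c(500L, 200L, 50L, 10L, 3L, 1L)
  N <- sum(counts)
  curve <- accumulationCurve(counts, c(10, 50, 200, N))
  # at full depth the expectation equals observed richness
  expect_equal(curve$richness[4], 6)
  # non-decreasing and concave
  expect_true(all(diff(curve$richness) >= 0))
  # Monte-Carlo oracle at depth 50
  set.seed(49)
  pool <- rep(seq_along(counts), counts)
  draws <- replicate(1000, length(unique(sample(pool, 50))))
  se <- sd(draws) / sqrt(1000)
  expect_lt(abs(curve$richness[2] - mean(draws)), 2 * se + 1e-9)
  # concavity on an equispaced grid
  grid <- seq(20, 700, by = 20)
  rich <- accumulationCurve(counts, grid)$richness
  expect_true(all(diff(diff(rich)) <= 1e-9))
})

test_that("the end-to-end pipeline is lossless on error-free reads", {
  species <- sprintf("Testfish sp%d", 1:4)
  pair <- tankPrimerPanel()[["MiFish-U"]]
  refs <- generateReferenceDb(4, panel = list("MiFish-U" = pair),
                              seed = 50, speciesNames = species)
  prof <- speciesProfiles(species, primers = "MiFish-U")
  cfg <- SimConfig(totalReadsPerSample = 2000, errorRate = 0)
  set.seed(51)
  readsets <- lapply(1:3, function(r)
    simulateTankSample(toy_design(species, biomass = c(5, 10, 20, 40)),
                       pair, refs, prof, cfg, r, "T1"))
  run <- processRun(readsets, pair, refs, rarefyDepth = NA)
  expect_identical(unname(run$fate[, "raw"]), rep(2000L, 3))
  expect_identical(run$fate[, "clean"], run$fate[, "raw"])
  expect_identical(nrow(otuCounts(run$otus)), 4L)
  truth <- emitTruthTable(readsets)
  m <- speciesCounts(run$assigned)
  expect_identical(m[species, colnames(speciesCounts(truth))],
                   speciesCounts(truth)[species, ])
  expect_true(all(m["unassigned", ] == 0L))
})
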