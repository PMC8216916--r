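test_that("taxonomic coverage counts distinct species with products", {
  pair <- tankPrimerPanel()[["MiFish-U"]]
  empty <- ReferenceSet(Biostrings::DNAStringSet(), species = character(0))
  expect_identical(taxonomicCoverage(pair, empty), 0L)
  refs <- generateReferenceDb(10, panel = list("MiFish-U" = pair),
                              seed = 11,
                              speciesNames = sprintf("Testfish sp%02d", 1:10))
  expect_identical(taxonomicCoverage(pair, refs), 10L)
  # two genomes of one species still count once
  refs2 <- ReferenceSet(
    c(as.character(refs), as.character(refs)[1]),
    species = c(refSpecies(refs), refSpecies(refs)[1]),
    ids = c(names(refs), "DUP001"))
  expect_identical(taxonomicCoverage(pair, refs2), 10L)
})

test_that("ablating binding sites from half the species drops coverage exactly", {
  pair <- tankPrimerPanel()[["Ve16S1"]]
  refs <- generateReferenceDb(8, panel = list("Ve16S1" = pair), seed = 12,
                              speciesNames = sprintf("Testfish sp%02d", 1:8))
  cfg <- MetricsConfig(maxMismatch = 0)
  full <- taxonomicCoverage(pair, refs, cfg)
  expect_identical(full, 8L)
  seqs <- as.character(refs)
  # destroy the forward site in species 1-4 by replacing it with Ns'
  # complement-free junk the primer cannot match
  ablated <- vapply(seq_along(seqs), function(i) {
    if (i <= 4) sub(forwardSeq(pair), strrep("A", nchar(forwardSeq(pair))),
                    seqs[i], fixed = TRUE) else seqs[i]
  }, character(1))
  refs2 <- ReferenceSet(ablated, species = refSpecies(refs),
                        ids = names(refs))
  expect_identical(taxonomicCoverage(pair, refs2, cfg), 4L)
})

test_that("coverage is non-decreasing in the mismatch cap", {
  pair <- tankPrimerPanel()[["AcMDB07"]]
  set.seed(13)
  # degrade half the binding sites so the cap actually matters
  refs <- generateReferenceDb(6, panel = list("AcMDB07" = pair), seed = 13,
                              speciesNames = sprintf("Testfish sp%02d", 1:6))
  seqs <- as.character(refs)
  seqs[1:3] <- vapply(seqs[1:3], function(s)
    sub(forwardSeq(pair), .mutate_n(forwardSeq(pair), 2), s, fixed = TRUE),
    character(1))
  refs <- ReferenceSet(seqs, species = refSpecies(refs), ids = names(refs))
  covs <- vapply(0:3, function(k)
    taxonomicCoverage(pair, refs, MetricsConfig(maxMismatch = k)),
    integer(1))
  expect_true(all(diff(covs) >= 0))
})

test_that("mean barcode length is the arithmetic mean of hit lengths", {
  expect_identical(meanBarcodeLength(data.frame(length = 200L)), 200)
  expect_error(meanBarcodeLength(data.frame(length = integer(0))),
               "undefined")
  set.seed(14)
  lens <- sample(100:400, 50, replace = TRUE)
  expect_equal(meanBarcodeLength(data.frame(length = lens)),
               sum(lens) / 50)
})

test_that("taxonomic resolution matches its definition", {
  # identical barcodes across species -> 0
  bc <- setNames(rep(strrep("ACGT", 25), 3), paste("sp", 1:3))
  expect_equal(taxonomicResolution(bc), 0)
  # two 100-bp barcodes differing at 10 columns -> 10 per 100 bases
  a <- rand_dna(100)
  ch <- strsplit(a, "")[[1]]
  pos <- seq(5, 95, by = 10)
  ch[pos] <- vapply(ch[pos], function(x)
    setdiff(c("A", "C", "G", "T"), x)[1], character(1))
  b <- paste(ch, collapse = "")
  expect_equal(taxonomicResolution(c(sp1 = a, sp2 = b)), 10)
  expect_error(taxonomicResolution(c(sp1 = a)), "fewer than 2")
  # symmetric in species order
  expect_equal(taxonomicResolution(c(sp2 = b, sp1 = a)),
               taxonomicResolution(c(sp1 = a, sp2 = b)))
})

test_that("representative barcodes are deterministic and input-order invariant", {
  pair <- tankPrimerPanel()[["MiFish-U"]]
  refs <- generateReferenceDb(4, panel = list("MiFish-U" = pair), seed = 15,
                              speciesNames = sprintf("Testfish sp%02d", 1:4))
  hits <- inSilicoPCR(pair, refs, maxMismatch = 3)
  r1 <- representativeBarcodes(hits, refs)
  r2 <- representativeBarcodes(hits[sample(nrow(hits)), ], refs)
  expect_identical(as.character(r1), as.character(r2))
})

test_that("success curves follow the penalty model and are monotone", {
  fwd <- "ACGGATTACGGATTACCA"
  rev <- "TTGGCCAATTGGCCAATG"
  pair <- PrimerPair("toy", "16S", fwd, rev)
  rc <- reverseComplementIupac(rev)
  perfect <- paste0(rand_dna(20), fwd, rand_dna(150), rc, rand_dna(20))
  # one internal forward mismatch (multiplier 1 -> penalty 100)
  f1 <- fwd; substr(f1, 3, 3) <- setdiff(c("A","C","G","T"),
                                         substr(fwd, 3, 3))[1]
  t100 <- paste0(rand_dna(20), f1, rand_dna(150), rc, rand_dna(20))
  # one mismatch at the forward 3' terminus (multiplier 32 -> 3200)
  f2 <- fwd; substr(f2, 18, 18) <- setdiff(c("A","C","G","T"),
                                           substr(fwd, 18, 18))[1]
  t3200 <- paste0(rand_dna(20), f2, rand_dna(150), rc, rand_dna(20))
  # no binding at all
  tnone <- rand_dna(250)
  refs <- toy_refs(c(perfect, t100, t3200, tnone))
  cfg <- MetricsConfig(penaltyThresholds = c(0, 99, 100, 3199, 3200))
  curve <- amplificationSuccessCurve(pair, refs, cfg)
  expect_equal(curve$fraction, c(1, 1, 2, 2, 3) / 4)
  expect_true(all(diff(curve$fraction) >= 0))
  # all-perfect references amplify at every threshold including 0
  curve2 <- amplificationSuccessCurve(pair, toy_refs(rep(perfect, 3)), cfg)
  expect_true(all(curve2$fraction == 1))
})

test_that("the screening filter applies coverage and open length window", {
  rep0 <- data.frame(name = c("a", "b", "c", "d"),
                     coverage = c(2500, 2500, 1500, 2500),
                     mean_len = c(200, 400, 200, 150))
  out <- screenPrimers(rep0, MetricsConfig())
  expect_identical(out$selected, c(TRUE, FALSE, FALSE, FALSE))
  # boundary: mean length exactly at the window edge is rejected
  expect_false(screenPrimers(data.frame(coverage = 2500, mean_len = 350),
                             MetricsConfig())$selected)
  expect_false(screenPrimers(data.frame(coverage = 2000, mean_len = 200),
                             MetricsConfig())$selected)
})

test_that("the primer report assembles all statistics per pair", {
  panel <- tankPrimerPanel()
  refs <- generateReferenceDb(5, panel = panel, seed = 16,
                              speciesNames = sprintf("Testfish sp%02d", 1:5))
  # at 0 mismatches each record yields exactly its constructed product
  # (at cap 3 the 16S primers also bind each other's conserved motifs)
  pr <- primerReport(panel, refs,
                     MetricsConfig(maxMismatch = 0, coverageThreshold = 4),
                     successCurves = TRUE)
  expect_identical(nrow(pr$report), 4L)
  expect_identical(pr$report$coverage, rep(5L, 4))
  # every record amplifies perfectly, so the published target lengths
  # are reproduced exactly by construction
  expect_equal(pr$report$mean_len, c(321, 218, 247, 311))
  expect_true(all(pr$report$selected))
  expect_true(all(pr$report$resolution > 0))
  # curves: monotone, and 1 at the top threshold for perfect matches
  for (p in pr$report$name) {
    cv <- pr$curves[pr$curves$primer == p, ]
    expect_true(all(diff(cv$fraction) >= 0))
    expect_equal(cv$fraction[nrow(cv)], 1)
  }
})
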