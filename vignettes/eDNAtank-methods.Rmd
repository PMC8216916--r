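---
title: "Evaluating fish eDNA metabarcoding primers in silico and in simulated tanks"
author: "eDNAtank authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating fish eDNA metabarcoding primers in silico and in simulated tanks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eDNAtank)
```

## The problem

Environmental DNA (eDNA) metabarcoding detects fish communities from a
water sample by amplifying a short mitochondrial marker with "universal"
primers and sequencing the pool. Two questions dominate primer choice:

1. **Screening** — which of the many published primer pairs amplify the
   largest share of the target fauna, at a barcode length that survives
   degraded eDNA yet still discriminates species?
2. **Quantification** — once species are detected, do read counts track
   species biomass, or does primer-specific amplification bias break the
   relationship?

`eDNAtank` implements both stages as a reproducible pipeline. The
packaged primer panel holds 18 published fish primer pairs (COI, cytb,
12S, 16S); the packaged tank designs hold a six-species freshwater
community (goldfish, common carp, mosquitofish, silver carp, pond loach,
stone moroko) in four 100-L tanks crossing high/low density with
even/skewed relative abundance.

## Stage 1: in silico PCR and screening statistics

The engine (`findBindingSites()`, `inSilicoPCR()`) is an **ungapped,
IUPAC-aware sliding-window scan**: a primer binds a window when at most
`maxMismatch` positions (default 3) fail the base-set-intersection test.
A "gap cost of 0" with a mismatch cap is equivalent to capping
substitutions in an ungapped scan, which is how we resolve the ambiguity
in the original tool chain (configurable in principle, but gapped primer
scanning is deliberately out of scope). Template ambiguity codes count
as matches when the sets intersect — conservative towards amplification.
Both strands are scanned; circular mitogenomes are unwrapped across the
origin exactly once, and origin-spanning products carry a
`wraps_origin` flag with `start` kept in `[0, L)`. Per forward binding
site only the **shortest** admissible product is kept, because short
products dominate PCR; distinct forward sites may still contribute
several products per genome.

Screening statistics (`primerReport()`):

* **Taxonomic coverage** — distinct species with at least one product;
  species labels are case-folded and trimmed to the binomial so
  multiple genomes per species count once.
* **Mean barcode length** — primer-inclusive product length. The
  selection filter (`screenPrimers()`) requires coverage **strictly
  above 2,000 species** and mean length **strictly inside (150, 350)
  bp** — the published thresholds, read as an open interval on the
  mean, not a per-hit filter. Scanning itself uses wide 50–1,000 bp
  bounds so the window judges the mean rather than a pre-filtered set.
* **Taxonomic resolution** — mean pairwise bp differences per 100
  aligned bases between one representative barcode per species, using a
  unit-cost global alignment (`100 * edits / columns`). The
  representative is the hit with fewest total mismatches (ties: start
  coordinate, then reference id) — deterministic and input-order
  invariant. Whether the original analysis used one barcode per species
  or averaged all hits is unstated; we chose the single-representative
  reading and document it here.
* **Amplification-success curves** — fraction of references whose best
  (minimum) combined mismatch penalty falls below a sweeping threshold
  (0–15,000). The scoring table behind the published 0–15,000 scale was
  never printed, so `PenaltyModel` is an explicit stand-in: 100 units
  per substitution, with the last five primer positions (the 3' end,
  where extension is most sensitive) up-weighted 2/4/8/16/32. Absolute
  curve values are therefore not comparable to the original; only the
  ordinal behaviour (monotone shape, ranking) is, and nothing
  downstream consumes the absolute scale.

The published headline numbers of this stage (coverage of 2,838
mitogenomes, mean lengths 321/218/247/311 bp, the selection of exactly
AcMDB07/MiFish-U/Ve16S1/Ve16S3) depend on a MitoFish database snapshot
that the package deliberately does not download; `readReferenceFasta()`
accepts any local snapshot should one be available. All in-package
validation runs on synthetic references instead (below), where every
statistic has a constructed ground truth.

## Stage 2: the simulated tank experiment

### What the generator emulates

`generateReferenceDb()` builds one "mitogenome-like" record per species:
for each primer pair, an exact-match realization of the (possibly
degenerate) forward primer and the reverse complement of the reverse
primer flank a species-specific random insert, with random spacers in
between. Insert lengths are chosen so the four screened-in pairs
reproduce their published amplicon lengths (321/218/247/311 bp,
primer-inclusive); inserts are redrawn until all between-species
identities are at or below 0.90, so a 97% clustering threshold cleanly
separates species. A useful emergent property: the 16S pairs bind each
other's conserved motifs at 2–3 mismatches, just as real conserved-region
primers do.

`simulateTankSample()` draws one sample as:

| parameter | default | meaning |
|---|---|---|
| `totalReadsPerSample` | 500,000 | expected reads per library (tests scale this down and say so) |
| `replicatesPerTank` | 3 | replicate water samples per tank |
| `lognormalSigma` | 0.3 | sdlog of replicate-level noise on template weights |
| `errorRate` | 0.005 | i.i.d. per-base substitution rate; Phred qualities are set to match (Q23) |
| `readLength` | 250 | 2 x 250 layout; 2 x 150 available |
| `lognormalMeanlog`, `lognormalSdlog` | 1.6, 0.8 | skewed-abundance draws, giving counts on the scale of the skewed tank designs |

The expected template weight of species *i* is
`biomass_i x shedding_i x efficiency_i,primer x LN(0, sigma)`, and true
counts are multinomial over the read total. This is the simplest
generative model consistent with biomass-driven eDNA shedding and
primer-specific amplification efficiency. Shedding defaults to 1
(no species gives per-gram values, and none were published); two
efficiency presets ship — `"unbiased"` (all 1) and `"paper-like"`
(qualitative tank-heatmap pattern: AcMDB07 down-weights the two carps
and favours silver carp; the 16S pairs down-weight mosquitofish). These
are free simulation parameters, never claimed to match the real tanks.
Mates are the first and last `readLength` bases of the amplicon (mate 2
reverse-complemented), so amplicons shorter than twice the read length
overlap — matching real merge behaviour. A fish-free negative control
yields zero reads. Not emulated: eDNA decay and transport, PCR
chimeras, index hopping, quality-score degradation along the read — so
a green end-to-end test establishes pipeline correctness under clean
assumptions, not robustness to those artefacts.

### The read pipeline

`processRun()` chains the published bioinformatic steps with their
published defaults: merge (longest ungapped overlap ≥ 10 with ≤ 10%
mismatches, higher-quality base wins discordant columns, mean Phred ≥
20), filter/trim (no ambiguous bases, both primers at the read ends
within 2 IUPAC-aware mismatches, trimmed length ≥ 100), greedy centroid
OTU clustering at 97% identity (dereplicate, abundance-descending with
lexicographic tie-break, first-centroid-wins — the documented greedy
algorithm of the standard tools with tie order made explicit), removal
of OTUs with whole-data totals below 10 (exactly 10 is retained),
taxonomic assignment by best semi-global alignment at ≥ 97% identity
and ≥ 100 aligned columns, and rarefaction to the smallest column total
(multivariate hypergeometric, seeded). Two deliberate substitutions:

* **BLAST E-values → identity + minimum alignment length.** With a
  curated six-species barcode database and ≥ 100-bp amplicons, any
  ≥ 97%-identity hit is far below the published E ≤ 1e-5 cutoff; the
  criterion is equivalent here and keeps the pipeline deterministic.
* **Rarefaction depth.** The original standardized to 833,329 reads
  (its smallest sample); we rarefy to the dataset's own minimum column
  total, with 833,329 retained only as the documented original value.
  The original statement that proportions were "identical" before and
  after resampling is treated as what it can only be — an expectation,
  asserted statistically, not exactly.

Numerical notes: clustering identity is `matching columns / alignment
columns` of a unit-cost global alignment; an equal-length Hamming bound
serves as a fast accepting witness and a banded DP with early abandon
decides the rest, so results are exact, not heuristic. Sequence ties
everywhere break lexicographically; sample columns keep their input
order.

### The statistical layer

`fitLme()` fits `log10(reads) ~ covariate + (1 | group)` by REML with
lme4, at three design levels: pooled (6 species x 4 tanks x 3
replicates = 72 points, species random), species-specific (12 points,
tank random) and per-tank (18 points, species random). The slope
p-value is a likelihood-ratio test of ML fits with and without the
slope — chosen over the original Satterthwaite approximation as
implementation-independent; for species-level fits, where the covariate
varies only between the four tanks, the LRT is the more liberal of the
two, which matters when comparing against the original's sparse
species-level significances. Because "r²" is ambiguous for mixed
models, both the squared fitted-observed correlation (used when
comparing to published values) and the marginal R² are reported.
Boundary (singular) fits are flagged, never dropped; when the fitted
random-effect variance is zero the slope provably equals ordinary least
squares, which the tests assert. Zero counts cannot occur in the real
data but can in stress tests; the default pseudocount policy adds 1 to
zero cells only before the log (configurable to `"all"` or a hard
error).

`whitesTTest()` is the permutation form of the two-group comparison:
Welch-studentized difference in means against its label-reshuffle
distribution (exhaustive when feasible, sampled otherwise), with
`p = (1 + #{|t*| >= |t|}) / (1 + B)`. The original publication offers
several variants and the GUI used by the original analysis does not say
which; the studentized permutation form is the canonical two-sided
choice. With 3 vs 3 replicates the minimum attainable p is 3/21 ≈ 0.14,
so tank-level comparisons only become significant with more replicates
— a design fact, not a bug.

`relativeAbundanceMatrix()` reproduces the heatmap matrix: log10 of the
mean standardized reads over the three replicate samples per (tank,
primer), pseudocount policy applied before the log.

## Orchestration and reproducibility

`runEndToEnd()` executes screen → simulate → process → quantify and
writes every report as TSV plus the resolved configuration as JSON.
Every stage derives its RNG stream from the master seed and a fixed
sample index, so identical (config, seed) give identical files; results
are independent of which stages are re-run. `loadRunConfig()` rejects
unknown keys and out-of-range values; every default equals the
published threshold of the corresponding step.

## Known limitations

* The multiplicative shedding model makes read counts *more* faithful
  to biomass than real tank data: pooled biomass regressions are
  essentially always significantly positive, and species-level
  regressions are significant more often than the original observed.
  Constant per-species efficiency biases shift intercepts, not
  within-species slopes, so efficiency dispersion alone cannot
  reproduce the original's species-level failures — that would require
  larger replicate-level noise than the default sdlog of 0.3.
* Screening statistics on the packaged synthetic references validate
  the machinery, not the published MitoFish numbers; those require the
  external database.
* The penalty model behind amplification-success curves is ordinal
  only.
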