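# eDNAtank

Primer evaluation and tank metabarcoding simulation for freshwater-fish
environmental DNA (eDNA).

Choosing a metabarcoding primer pair is the single largest
researcher-controlled source of bias in eDNA fish surveys. `eDNAtank`
implements a two-stage evaluation strategy as a tested, reproducible R
pipeline:

1. **In silico screening.** An IUPAC-aware, ungapped in silico PCR
   engine scans degenerate primer pairs against mitogenome references
   (both strands, circular molecules unwrapped across the origin) and
   computes the four screening statistics per pair: taxonomic coverage
   (species recovered at ≤ 3 mismatches per primer), mean barcode
   length (selected when strictly inside 150–350 bp), taxonomic
   resolution (mean pairwise bp differences per 100 aligned bases), and
   amplification-success curves over a mismatch-penalty threshold
   sweep. The packaged panel holds 18 published fish primer pairs for
   COI, cytb, 12S and 16S; four of them (AcMDB07, MiFish-U, Ve16S1,
   Ve16S3) pass the published screening filter.
2. **A simulated "tank" experiment.** A seeded mock-community generator
   emulates six fish species in four 100-L tanks (even/skewed
   abundance, high/low density; the designs ship as a fixture): the
   expected read weight of species *i* is
   `biomass_i x shedding_i x efficiency_i,primer x LN(0, sigma)`, true
   counts are multinomial (default 500,000 reads/sample, 3 replicate
   water samples per tank, plus a fish-free negative control), and
   paired 2 x 250 bp reads carry i.i.d. substitution errors with
   matching Phred qualities. The read pipeline then mirrors the
   published chain — pair merging (overlap ≥ 10, Phred ≥ 20), quality
   filtering and primer trimming (≤ 2 primer mismatches, length ≥ 100,
   no ambiguous bases), greedy 97% OTU clustering, removal of OTUs with
   whole-data totals < 10, ≥ 97%-identity taxonomic assignment,
   rarefaction to a common depth — and the statistical layer fits
   `log10(reads) ~ biomass (or abundance) + (1 | species or tank)`
   mixed models at the pooled (n = 72), species (n = 12) and tank
   (n = 18) design levels, plus permutation (White-style) t-tests
   between primer pairs.

## Worked example

```r
library(eDNAtank)

cfg <- loadRunConfig()                     # published defaults
cfg$seed <- 42L
cfg$sim$total_reads_per_sample <- 20000L   # scaled-down demo
cfg$screen$coverage_threshold <- 5         # 6 synthetic species, not MitoFish
out <- runEndToEnd(cfg, outdir = "demo_run")

out$screen$report
#>       name coverage mean_len median_len resolution selected
#> 1  AcMDB07        6    321.0      321.0   41.22699     TRUE
#> 2 MiFish-U        6    218.0      218.0   37.91129     TRUE
#> 3   Ve16S1        6    247.0      247.0   39.63425     TRUE
#> 4   Ve16S3        6    346.5      346.5   40.64715     TRUE
```

Coverage is the number of synthetic species each pair amplifies;
`mean_len` reproduces each pair's published amplicon length by
construction (Ve16S3 also picks up Ve16S1's conserved reverse motif at
≤ 3 mismatches, hence its longer secondary product — real conserved
16S primers do the same). `resolution` is high because synthetic
barcode interiors are near-random.

```r
head(out$detection)
#>                       species  tank  primer detected
#> 1           Carassius auratus Tank1 AcMDB07     TRUE
#> 2             Cyprinus carpio Tank1 AcMDB07     TRUE
#> ...
all(out$detection$detected)   # 6 species x 4 tanks x 4 primers
#> [1] TRUE

subset(out$regressions, level == "pooled" & covariate == "biomass")
#>      primer   slope        p r2_corr  n
#> 1   AcMDB07 0.00640 5.46e-07   0.910 72
#> 13 MiFish-U 0.00599 4.88e-05   0.883 72
#> 25   Ve16S1 0.00510 9.39e-06   0.927 72
#> 37   Ve16S3 0.00653 8.16e-08   0.917 72
```

All six species are detected in every tank with every primer, and the
pooled biomass–read regressions are significantly positive: the
simulated world reproduces the qualitative tank findings (detection is
easy; pooled quantification works; per-species quantification is the
fragile part — see the methods vignette). The run directory also holds
the truth tables, the per-sample read-fate accounting
(raw → merged → clean → assigned), the rarefied species x sample
tables, the pairwise primer comparisons and the detection matrix, all
as TSV.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the full two-stage analysis from scratch against the installed
package — synthetic reference generation, screening, tank read
simulation (scaled to 20,000 reads/sample), read processing and the
mixed-model quantification — and writes the machine-readable report to
`--out`. All randomness derives from `--seed`.

## Package layout

* `R/insilico-pcr.R`, `src/core.cpp` — IUPAC matching and the scanning
  engine (C++ hot paths).
* `R/primer-metrics.R` — screening statistics and the selection filter.
* `R/simulate.R` — synthetic references, tank communities, read sets.
* `R/read-pipeline.R` — merge, trim, cluster, assign, rarefy,
  accumulation curves.
* `R/quant-stats.R` — mixed models, permutation tests, heatmap matrix.
* `R/workflow.R` — configuration and the seeded end-to-end driver.
* `inst/extdata/` — the 18-pair primer panel and the four tank designs.
* `vignettes/eDNAtank-methods.Rmd` — model assumptions, parameter
  choices, numerical decisions, limitations.
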