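## Synthetic-data generator: mitogenome-like references carrying real
## primer binding motifs, tank communities, and paired-end amplicon
## reads with the statistical structure the tank analysis assumes
## (biomass-proportional shedding x primer-specific efficiency x
## lognormal replicate noise -> multinomial reads -> per-base error).

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"), I = c("A", "C", "G", "T"))

## One concrete (A/C/G/T) realization of a degenerate primer, so the
## embedded binding site matches the primer exactly.
.concretize <- function(primer) {
  ch <- strsplit(toupper(primer), "")[[1]]
  paste(vapply(ch, function(c) {
    s <- IUPAC_SETS[[c]]
    s[sample.int(length(s), 1L)]
  }, character(1)), collapse = "")
}

.randomDNA <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Published mean amplicon lengths (primer-inclusive) of the four
## screened-in pairs; other primers get a generic 240 bp target.
.AMPLICON_TARGETS <- c("AcMDB07" = 321, "MiFish-U" = 218,
                       "Ve16S1" = 247, "Ve16S3" = 311)

#' Generate a synthetic species reference database
#'
#' Builds one "mitogenome-like" linear reference per species. Each
#' record carries, for every primer pair in \code{panel}, an exact-match
#' forward binding site and a reverse-complemented reverse site flanking
#' a species-specific random insert, separated by random spacers, so
#' every record yields exactly one product per primer at zero
#' mismatches. Insert lengths are chosen so the four screened-in pairs
#' reproduce their published amplicon lengths (321/218/247/311 bp,
#' primer-inclusive). Inserts are redrawn until all between-species
#' identities are at or below \code{maxInsertIdentity}.
#'
#' @param nSpecies Number of species (>= 2).
#' @param panel Named list of \linkS4class{PrimerPair}s (default the
#'   four screened-in pairs).
#' @param seed Optional seed for byte-identical output.
#' @param speciesNames Species labels; defaults to the six tank species
#'   when \code{nSpecies == 6}, otherwise synthetic binomials.
#' @param spacer Spacer length between amplicon loci (bp).
#' @param maxInsertIdentity Ceiling on between-species insert identity
#'   (default 0.90).
#' @return A \linkS4class{ReferenceSet} with one record per species.
#' @export
generateReferenceDb <- function(nSpecies = 6, panel = tankPrimerPanel(),
                                seed = NULL, speciesNames = NULL,
                                spacer = 50, maxInsertIdentity = 0.90) {
  stopifnot(nSpecies >= 2)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(speciesNames)) {
    speciesNames <- if (nSpecies == 6) unique(tankDesigns()$species)
    else sprintf("Simulatus species%02d", seq_len(nSpecies))
  }
  stopifnot(length(speciesNames) == nSpecies)
  targets <- .AMPLICON_TARGETS[names(panel)]
  targets[is.na(targets)] <- 240
  inserts <- list()
  for (p in seq_along(panel)) {
    lf <- nchar(panel[[p]]@forward); lr <- nchar(panel[[p]]@reverse)
    ilen <- max(20L, as.integer(targets[p] - lf - lr))
    ins <- vapply(seq_len(nSpecies), function(i) .randomDNA(ilen),
                  character(1))
    # enforce the inter-species divergence ceiling
    repeat {
      bad <- FALSE
      for (i in seq_len(nSpecies - 1L)) for (j in (i + 1L):nSpecies) {
        id <- cpp_align_identity(ins[i], ins[j])[["identity"]]
        if (id > maxInsertIdentity) { ins[j] <- .randomDNA(ilen); bad <- TRUE }
      }
      if (!bad) break
    }
    inserts[[p]] <- ins
  }
  seqs <- vapply(seq_len(nSpecies), function(i) {
    parts <- c(.randomDNA(spacer))
    for (p in seq_along(panel)) {
      fwd <- .concretize(panel[[p]]@forward)
      rev_rc <- reverseComplementIupac(.concretize(panel[[p]]@reverse))
      parts <- c(parts, fwd, inserts[[p]][i], rev_rc, .randomDNA(spacer))
    }
    paste(parts, collapse = "")
  }, character(1))
  ReferenceSet(seqs, species = speciesNames, topology = "linear",
               ids = sprintf("SYN%03d", seq_len(nSpecies)))
}

#' Species profiles: eDNA shedding and per-primer amplification efficiency
#'
#' The quantification model is multiplicative: the expected template
#' weight of species i in a sample is
#' \code{biomass_i * shedding_i * efficiency_i,primer * lognormal noise}.
#' Shedding defaults to 1 for all species (reads proportional to
#' biomass). Two efficiency presets ship: \code{"unbiased"} (all 1) and
#' \code{"paper-like"} (per-primer species biases qualitatively matching
#' the tank heatmap pattern: the 12S pair AcMDB07 under-amplifies the
#' two carps and favours silver carp, the 16S pairs under-amplify
#' mosquitofish).
#'
#' @param species Character vector of species names.
#' @param primers Character vector of primer names.
#' @param shedding Shedding rates (recycled; named vector allowed).
#' @param preset \code{"unbiased"} or \code{"paper-like"}.
#' @param efficiency Optional explicit species x primer matrix
#'   overriding the preset.
#' @return List with \code{shedding} (named numeric) and
#'   \code{efficiency} (species x primer matrix, values in (0, 1]).
#' @export
speciesProfiles <- function(species, primers = tankPrimerNames(),
                            shedding = 1,
                            preset = c("unbiased", "paper-like"),
                            efficiency = NULL) {
  preset <- match.arg(preset)
  shed <- setNames(rep(shedding, length.out = length(species)), species)
  if (is.null(efficiency)) {
    if (preset == "unbiased") {
      efficiency <- matrix(1, length(species), length(primers),
                           dimnames = list(species, primers))
    } else {
      efficiency <- matrix(0.5, length(species), length(primers),
                           dimnames = list(species, primers))
      tweak <- function(sp, pr, v) {
        i <- match(sp, species); j <- match(pr, primers)
        if (!is.na(i) && !is.na(j)) efficiency[i, j] <<- v
      }
      tweak("Carassius auratus", "AcMDB07", 0.1)
      tweak("Cyprinus carpio", "AcMDB07", 0.1)
      tweak("Hypophthalmichthys molitrix", "AcMDB07", 1.0)
      tweak("Gambusia affinis", "MiFish-U", 1.0)
      tweak("Gambusia affinis", "Ve16S1", 0.15)
      tweak("Gambusia affinis", "Ve16S3", 0.15)
      tweak("Carassius auratus", "Ve16S1", 0.9)
      tweak("Cyprinus carpio", "Ve16S3", 0.9)
      # generic species fall back to a deterministic dispersed grid
      if (!any(species %in% unique(tankDesigns()$species))) {
        grid <- c(0.1, 0.3, 1.0, 0.5, 0.75, 0.2)
        for (i in seq_along(species)) for (j in seq_along(primers))
          efficiency[i, j] <- grid[((i + j) %% length(grid)) + 1L]
      }
    }
  }
  stopifnot(all(efficiency > 0), all(efficiency <= 1),
            identical(rownames(efficiency), species))
  if (any(shed <= 0)) stop("shedding rates must be positive")
  list(shedding = shed, efficiency = efficiency)
}

#' Draw skewed community abundances from a lognormal
#'
#' Emulates the skewed tank designs: lognormal draws (the abundance
#' distribution observed in natural fish assemblages), rounded to
#' integers with a floor of 1 individual.
#'
#' @param nSpecies Number of species.
#' @param meanlog,sdlog Lognormal parameters (defaults 1.6, 0.8).
#' @param seed Optional seed.
#' @return Integer vector of length \code{nSpecies}, all >= 1.
#' @export
drawSkewedAbundances <- function(nSpecies, meanlog = 1.6, sdlog = 0.8,
                                 seed = NULL) {
  stopifnot(nSpecies >= 1, sdlog > 0)
  if (!is.null(seed)) set.seed(seed)
  pmax(1L, as.integer(round(rlnorm(nSpecies, meanlog, sdlog))))
}

#' True read counts for one tank sample
#'
#' Expected template weight of species i:
#' \code{biomass_i * shedding_i * efficiency_i,primer * LN(0, sigma)}
#' (noise drawn independently per species and replicate); true counts
#' are multinomial over the sample's read total. A fish-free design
#' (all biomass zero) yields all-zero counts.
#'
#' @param design data.frame for one tank (\code{species},
#'   \code{biomass_g} columns).
#' @param primer Primer name (column of the efficiency matrix).
#' @param profiles From \code{\link{speciesProfiles}}.
#' @param cfg A \linkS4class{SimConfig}.
#' @return Named integer vector of true reads per species.
#' @export
simulateCounts <- function(design, primer, profiles, cfg = SimConfig()) {
  sp <- design$species
  eff <- profiles$efficiency[sp, primer]
  noise <- if (cfg@lognormalSigma > 0)
    rlnorm(length(sp), 0, cfg@lognormalSigma) else rep(1, length(sp))
  w <- design$biomass_g * profiles$shedding[sp] * eff * noise
  if (all(w == 0)) return(setNames(integer(length(sp)), sp))
  setNames(as.integer(rmultinom(1L, cfg@totalReadsPerSample, w / sum(w))),
           sp)
}

#' Simulate one paired-end tank metabarcoding sample
#'
#' Draws true counts with \code{\link{simulateCounts}}, then emits each
#' read as the species' amplicon for the primer (first and last
#' \code{readLength} bases; mate 2 reverse-complemented; amplicons
#' shorter than twice the read length yield overlapping mates, matching
#' real merge behaviour), applies i.i.d. substitution errors at the
#' configured rate, and attaches Phred qualities consistent with that
#' rate.
#'
#' @param design data.frame for one tank (rows = species).
#' @param pair A \linkS4class{PrimerPair}.
#' @param refs \linkS4class{ReferenceSet} covering all design species.
#' @param profiles From \code{\link{speciesProfiles}}.
#' @param cfg A \linkS4class{SimConfig}.
#' @param replicate Replicate index (metadata only; seed the RNG for
#'   reproducibility).
#' @param tank Tank label; defaults to \code{design$tank[1]}.
#' @return A \linkS4class{ReadSet}.
#' @export
simulateTankSample <- function(design, pair, refs, profiles,
                               cfg = SimConfig(), replicate = 1,
                               tank = NULL) {
  if (is.null(tank)) tank <- as.character(design$tank[1])
  counts <- simulateCounts(design, pair@name, profiles, cfg)
  hits <- inSilicoPCR(pair, refs, maxMismatch = 0)
  amps <- as.character(ampliconSeqs(hits, refs))
  names(amps) <- hits$species
  missing <- setdiff(names(counts)[counts > 0], names(amps))
  if (length(missing))
    stop("primer ", pair@name, " does not amplify the reference of: ",
         paste(missing, collapse = ", "))
  L <- cfg@readLength
  m1 <- character(0); m2 <- character(0)
  for (sp in names(counts)[counts > 0]) {
    amp <- amps[[sp]]
    alen <- nchar(amp)
    w <- min(L, alen)
    a1 <- substr(amp, 1L, w)
    a2 <- as.character(reverseComplement(DNAString(
      substr(amp, alen - w + 1L, alen))))
    m1 <- c(m1, rep(a1, counts[[sp]]))
    m2 <- c(m2, rep(a2, counts[[sp]]))
  }
  if (cfg@errorRate > 0) {
    m1 <- as.character(cpp_mutate_reads(m1, cfg@errorRate))
    m2 <- as.character(cpp_mutate_reads(m2, cfg@errorRate))
  }
  q <- if (cfg@errorRate > 0)
    as.integer(round(-10 * log10(cfg@errorRate))) else 40L
  qc <- rawToChar(as.raw(q + 33L))
  new("ReadSet",
      mate1 = m1, qual1 = strrep(qc, nchar(m1)),
      mate2 = m2, qual2 = strrep(qc, nchar(m2)),
      truth = counts, tank = tank, replicate = as.integer(replicate),
      primer = pair@name)
}

#' Assemble the simulator truth table
#'
#' @param readsets List of \linkS4class{ReadSet} objects sharing one
#'   primer panel.
#' @return A \linkS4class{SpeciesSampleTable} of true counts (one
#'   column per read set; column sums equal the configured totals).
#' @export
emitTruthTable <- function(readsets) {
  species <- sort(unique(unlist(lapply(readsets, function(r)
    names(r@truth)))))
  counts <- vapply(readsets, function(r) {
    v <- setNames(integer(length(species)), species)
    v[names(r@truth)] <- r@truth
    v
  }, integer(length(species)))
  counts <- matrix(counts, nrow = length(species),
                   dimnames = list(species, NULL))
  SpeciesSampleTable(
    counts,
    tank = vapply(readsets, function(r) r@tank, character(1)),
    replicate = vapply(readsets, function(r) r@replicate, integer(1)),
    primer = vapply(readsets, function(r) r@primer, character(1)))
}
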