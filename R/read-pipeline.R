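## The bioinformatic chain applied to each sample: pair merging, quality
## filtering + primer trimming, greedy OTU clustering, OTU abundance
## filtering, taxonomic assignment, rarefaction, accumulation curves.

.revcompChar <- function(x) {
  if (!length(x)) return(character(0))
  as.character(reverseComplement(DNAStringSet(x)))
}

.reverseChar <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverse(BStringSet(x)))
}

#' Merge paired-end mates
#'
#' Finds the longest ungapped overlap of at least \code{minOverlap}
#' bases with a mismatch fraction of at most \code{maxMismatchFrac};
#' discordant overlap bases are resolved to the higher-quality call.
#' Pairs without an admissible overlap, or whose merged read has a mean
#' Phred quality below \code{minPhred}, are rejected (a counted outcome,
#' not an error).
#'
#' @param mate1,mate2 Character vectors of read sequences (mate 2 as
#'   sequenced, i.e. reverse-complemented internally).
#' @param qual1,qual2 Phred+33 quality strings.
#' @param minOverlap Minimum overlap (default 10).
#' @param minPhred Minimum mean Phred score of the merged read
#'   (default 20).
#' @param maxMismatchFrac Maximum mismatch fraction in the overlap
#'   (default 0.1).
#' @return List with \code{seq}, \code{qual} (NA for rejected pairs)
#'   and a \code{status} vector (\code{"merged"}, \code{"no_overlap"},
#'   \code{"low_quality"}).
#' @export
mergePairs <- function(mate1, qual1, mate2, qual2, minOverlap = 10,
                       minPhred = 20, maxMismatchFrac = 0.1) {
  r2 <- .revcompChar(mate2)
  q2 <- .reverseChar(qual2)
  res <- cpp_merge_pairs(mate1, qual1, r2, q2, as.integer(minOverlap),
                         maxMismatchFrac, minPhred)
  status <- c("merged", "no_overlap", "low_quality")[res$status + 1L]
  list(seq = as.character(res$seq), qual = as.character(res$qual),
       status = status)
}

#' Quality filtering and primer trimming of merged reads
#'
#' Both primers must sit at the read ends within
#' \code{maxPrimerMismatch} IUPAC-aware mismatches; they are then
#' removed. Reads containing any ambiguous base, missing either primer,
#' or shorter than \code{minLen} after trimming are rejected.
#'
#' @param seqs Character vector of merged reads.
#' @param pair A \linkS4class{PrimerPair}.
#' @param maxPrimerMismatch Maximum mismatches per primer (default 2).
#' @param minLen Minimum trimmed length (default 100).
#' @return List with \code{seq} (NA for rejects) and \code{status}
#'   (\code{"ok"}, \code{"ambiguous"}, \code{"fwd_primer"},
#'   \code{"rev_primer"}, \code{"short"}).
#' @export
qualityFilterAndTrim <- function(seqs, pair, maxPrimerMismatch = 2,
                                 minLen = 100) {
  rev_rc <- reverseComplementIupac(pair@reverse)
  res <- cpp_trim_primers(seqs, pair@forward, rev_rc,
                          as.integer(maxPrimerMismatch),
                          as.integer(minLen))
  status <- c("ok", "ambiguous", "fwd_primer", "rev_primer",
              "short")[res$status + 1L]
  list(seq = as.character(res$seq), status = status)
}

#' Greedy centroid OTU clustering
#'
#' Dereplicates the reads, sorts unique sequences by abundance
#' (descending, lexicographic tie-break) and assigns each to the first
#' centroid with global alignment identity at or above the threshold
#' (identity = matching columns / alignment columns of a unit-cost
#' global alignment), opening a new centroid otherwise - the documented
#' greedy algorithm of the standard clustering tools, with an explicit
#' deterministic tie order.
#'
#' @param reads Character vector of primer-trimmed reads.
#' @param samples Parallel vector of sample labels.
#' @param identity Identity threshold (default 0.97).
#' @return An \linkS4class{OTUTable}.
#' @export
clusterOTUs <- function(reads, samples = rep("sample1", length(reads)),
                        identity = 0.97) {
  stopifnot(length(reads) == length(samples))
  if (!is.factor(samples)) samples <- factor(samples, unique(samples))
  keep <- !is.na(reads)
  reads <- reads[keep]
  samples <- samples[keep, drop = FALSE]
  if (!length(reads))
    return(new("OTUTable", centroids = DNAStringSet(),
               counts = matrix(integer(0), 0, nlevels(samples),
                               dimnames = list(NULL, levels(samples)))))
  ab <- table(reads)
  uniq <- names(ab)
  ord <- order(-as.integer(ab), uniq)
  uniq <- uniq[ord]
  cl <- cpp_greedy_cluster(uniq, identity)  # 1-based index into uniq
  centroid_of <- uniq[cl]
  otu_ids <- unique(centroid_of)            # first-appearance order
  otu_names <- sprintf("OTU_%04d", seq_along(otu_ids))
  read_centroid <- centroid_of[match(reads, uniq)]
  counts <- table(factor(read_centroid, levels = otu_ids), samples)
  counts <- matrix(as.integer(counts), nrow = length(otu_ids),
                   dimnames = list(otu_names, levels(samples)))
  cents <- DNAStringSet(otu_ids)
  names(cents) <- otu_names
  new("OTUTable", centroids = cents, counts = counts)
}

#' Drop rare OTUs
#'
#' Removes OTUs whose grand total across the whole data set is below
#' \code{minTotal} (strictly: a total of exactly \code{minTotal} is
#' retained). Retained counts are unchanged.
#'
#' @param table An \linkS4class{OTUTable}.
#' @param minTotal Minimum grand total (default 10).
#' @export
filterOTUs <- function(table, minTotal = 10) {
  keep <- rowSums(table@counts) >= minTotal
  new("OTUTable", centroids = table@centroids[keep],
      counts = table@counts[keep, , drop = FALSE])
}

## Alignment columns of a pairwiseAlignment (matches + mismatches +
## gapped columns).
.alignmentColumns <- function(aln) {
  Biostrings::nmatch(aln) + Biostrings::nmismatch(aln) +
    sum(Biostrings::insertion(Biostrings::nindel(aln))[, "WidthSum"]) +
    sum(Biostrings::deletion(Biostrings::nindel(aln))[, "WidthSum"])
}

#' Reference barcodes for taxonomic assignment
#'
#' Extracts one representative amplicon per species for a primer pair
#' and (by default) strips the primer sequences, matching the
#' primer-trimmed reads the pipeline produces.
#'
#' @param refs A \linkS4class{ReferenceSet}.
#' @param pair A \linkS4class{PrimerPair}.
#' @param maxMismatch Mismatch cap for the amplicon search (default 3).
#' @param trimPrimers Strip primer sequences from both ends?
#' @return \code{DNAStringSet} named by species.
#' @export
referenceBarcodes <- function(refs, pair, maxMismatch = 3,
                              trimPrimers = TRUE) {
  hits <- inSilicoPCR(pair, refs, maxMismatch = maxMismatch)
  bc <- representativeBarcodes(hits, refs, normalize = FALSE)
  if (trimPrimers && length(bc)) {
    lf <- nchar(pair@forward); lr <- nchar(pair@reverse)
    bc <- DNAStringSet(substr(as.character(bc), lf + 1L,
                              nchar(as.character(bc)) - lr))
  }
  bc
}

#' Assign OTUs to species
#'
#' Aligns every OTU centroid to every reference barcode (semi-global:
#' global in the centroid, local in the reference). The best hit with
#' identity >= \code{minIdentity} (matching columns over alignment
#' columns) and alignment length >= \code{minAlnLen} assigns the OTU's
#' counts to that species; otherwise they go to \code{"unassigned"}.
#' Ties on identity break by longer alignment, then reference order.
#' This identity + minimum-length criterion replaces a BLAST E-value
#' cutoff: with a curated species-level barcode database and >= 100 bp
#' amplicons, any >= 97\%-identity hit is far below E = 1e-5.
#'
#' @param table An \linkS4class{OTUTable}.
#' @param refdb Species-named \code{DNAStringSet} (e.g. from
#'   \code{\link{referenceBarcodes}}); must be non-empty.
#' @param minIdentity Identity threshold (default 0.97).
#' @param minAlnLen Minimum alignment length (default 100).
#' @param tank,replicate,primer Optional per-sample metadata (parsed
#'   from \code{colnames(otuCounts(table))} as tank.replicate.primer
#'   when omitted).
#' @return A \linkS4class{SpeciesSampleTable} with an
#'   \code{"unassigned"} row.
#' @export
assignTaxonomy <- function(table, refdb, minIdentity = 0.97,
                           minAlnLen = 100, tank = NULL,
                           replicate = NULL, primer = NULL) {
  if (length(refdb) == 0L) stop("reference database is empty")
  counts <- table@counts
  species <- sort(unique(names(refdb)))
  out <- matrix(0L, length(species) + 1L, ncol(counts),
                dimnames = list(c(species, "unassigned"),
                                colnames(counts)))
  nc <- nrow(counts)
  best_sp <- rep(NA_character_, nc)
  best_id <- rep(-1, nc); best_cols <- rep(-1, nc)
  for (r in seq_along(refdb)) {
    # one vectorized call per reference: all centroids at once
    aln <- Biostrings::pairwiseAlignment(table@centroids, refdb[[r]],
                                         type = "global-local")
    nm <- Biostrings::nmatch(aln)
    ind <- Biostrings::nindel(aln)
    cols <- nm + Biostrings::nmismatch(aln) +
      Biostrings::insertion(ind)[, "WidthSum"] +
      Biostrings::deletion(ind)[, "WidthSum"]
    id <- ifelse(cols > 0, nm / cols, 0)
    upd <- cols >= minAlnLen & id >= minIdentity &
      (id > best_id | (id == best_id & cols > best_cols))
    best_sp[upd] <- names(refdb)[r]
    best_id[upd] <- id[upd]; best_cols[upd] <- cols[upd]
  }
  for (k in seq_len(nc)) {
    row <- if (is.na(best_sp[k])) "unassigned" else best_sp[k]
    out[row, ] <- out[row, ] + counts[k, ]
  }
  meta <- .sampleMetaFromNames(colnames(counts), tank, replicate, primer)
  SpeciesSampleTable(out, meta$tank, meta$replicate, meta$primer)
}

.sampleMetaFromNames <- function(nms, tank, replicate, primer) {
  if (!is.null(tank))
    return(list(tank = tank, replicate = replicate, primer = primer))
  parts <- strsplit(nms, ".", fixed = TRUE)
  list(tank = vapply(parts, `[`, character(1), 1L),
       replicate = suppressWarnings(
         as.integer(vapply(parts, `[`, character(1), 2L))),
       primer = vapply(parts, function(p)
         paste(p[-(1:2)], collapse = "."), character(1)))
}

#' Rarefy a species x sample table to a common depth
#'
#' Per column, \code{depth} reads are drawn without replacement
#' (multivariate hypergeometric), so every rarefied column sums exactly
#' to \code{depth}. Deterministic given \code{seed}; idempotent when a
#' column already sits at \code{depth}.
#'
#' @param table A \linkS4class{SpeciesSampleTable}.
#' @param depth Target depth; every column total must be >= depth.
#' @param seed Optional seed.
#' @return The rarefied \linkS4class{SpeciesSampleTable}.
#' @export
rarefy <- function(table, depth, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  counts <- speciesCounts(table)
  tot <- colSums(counts)
  if (any(tot < depth))
    stop("insufficient depth in sample(s): ",
         paste(colnames(counts)[tot < depth], collapse = ", "))
  out <- counts
  for (j in seq_len(ncol(counts))) {
    n <- counts[, j]
    remaining <- sum(n)
    need <- depth
    for (i in seq_along(n)) {
      remaining <- remaining - n[i]
      x <- rhyper(1L, n[i], remaining, need)
      out[i, j] <- x
      need <- need - x
    }
  }
  cd <- colData(table)
  SpeciesSampleTable(out, cd$tank, cd$replicate, cd$primer)
}

#' Expected species accumulation (rarefaction) curve
#'
#' Closed-form hypergeometric expectation of the number of taxa with at
#' least one read in a without-replacement subsample of each depth:
#' \code{E[S(d)] = sum_i (1 - C(N - n_i, d) / C(N, d))}. Non-decreasing
#' and concave along the grid.
#'
#' @param counts Non-negative count vector for one sample.
#' @param depths Depth grid within \code{(0, sum(counts)]}.
#' @return data.frame with \code{depth} and \code{richness}.
#' @export
accumulationCurve <- function(counts, depths) {
  N <- sum(counts)
  stopifnot(all(depths > 0), all(depths <= N))
  n <- counts[counts > 0]
  rich <- vapply(depths, function(d) {
    sum(1 - exp(lchoose(N - n, d) - lchoose(N, d)))
  }, numeric(1))
  data.frame(depth = depths, richness = rich)
}

#' Process one simulated sample through merge, filter and trim
#'
#' @param rs A \linkS4class{ReadSet}.
#' @param pair The matching \linkS4class{PrimerPair}.
#' @param minOverlap,minPhred,maxMismatchFrac Merge parameters.
#' @param maxPrimerMismatch,minLen Trim parameters.
#' @return List with \code{seq} (clean primer-trimmed reads) and
#'   \code{log} (named counts: raw, merged, clean).
#' @export
processReads <- function(rs, pair, minOverlap = 10, minPhred = 20,
                         maxMismatchFrac = 0.1, maxPrimerMismatch = 2,
                         minLen = 100) {
  merged <- mergePairs(rs@mate1, rs@qual1, rs@mate2, rs@qual2,
                       minOverlap, minPhred, maxMismatchFrac)
  ok <- merged$status == "merged"
  trimmed <- qualityFilterAndTrim(merged$seq[ok], pair,
                                  maxPrimerMismatch, minLen)
  clean <- trimmed$seq[trimmed$status == "ok"]
  list(seq = clean,
       log = c(raw = length(rs@mate1), merged = sum(ok),
               clean = length(clean)))
}

#' Run the full pipeline for one primer over a set of samples
#'
#' Merges, filters and trims every sample, clusters the pooled clean
#' reads into OTUs, removes OTUs below the whole-data total threshold,
#' assigns taxonomy against per-species reference barcodes, and
#' rarefies all samples to the smallest column total (the standard
#' standardization step).
#'
#' @param readsets List of \linkS4class{ReadSet}s for ONE primer.
#' @param pair The \linkS4class{PrimerPair}.
#' @param refs \linkS4class{ReferenceSet} for taxonomic assignment.
#' @param otuIdentity,minOtuTotal,assignIdentity,minAlnLen,minOverlap,minPhred,maxMismatchFrac,maxPrimerMismatch,minLen
#'   Pipeline thresholds (defaults: 0.97, 10, 0.97, 100, 10, 20, 0.1,
#'   2, 100).
#' @param rarefyDepth \code{"min"} (smallest column total), a number,
#'   or \code{NA} to skip rarefaction.
#' @param seed Seed for the rarefaction draw.
#' @return List: \code{assigned} (\linkS4class{SpeciesSampleTable}),
#'   \code{rarefied} (or NULL), \code{otus} (filtered
#'   \linkS4class{OTUTable}), \code{fate} (per-sample read-fate
#'   matrix: raw, merged, clean, assigned).
#' @export
processRun <- function(readsets, pair, refs, otuIdentity = 0.97,
                       minOtuTotal = 10, assignIdentity = 0.97,
                       minAlnLen = 100, minOverlap = 10, minPhred = 20,
                       maxMismatchFrac = 0.1, maxPrimerMismatch = 2,
                       minLen = 100, rarefyDepth = "min", seed = 1) {
  stopifnot(length(readsets) > 0)
  labels <- vapply(readsets, function(r)
    paste(r@tank, r@replicate, r@primer, sep = "."), character(1))
  clean <- vector("list", length(readsets))
  fate <- matrix(0L, length(readsets), 4L,
                 dimnames = list(labels,
                                 c("raw", "merged", "clean", "assigned")))
  for (i in seq_along(readsets)) {
    pr <- processReads(readsets[[i]], pair, minOverlap, minPhred,
                       maxMismatchFrac, maxPrimerMismatch, minLen)
    clean[[i]] <- pr$seq
    fate[i, 1:3] <- pr$log
  }
  reads <- unlist(clean)
  samples <- factor(rep(labels, lengths(clean)), levels = labels)
  otus <- clusterOTUs(reads, samples, otuIdentity)
  otus <- filterOTUs(otus, minOtuTotal)
  refdb <- referenceBarcodes(refs, pair)
  assigned <- assignTaxonomy(otus, refdb, assignIdentity, minAlnLen)
  counts <- speciesCounts(assigned)
  fate[, "assigned"] <- as.integer(colSums(
    counts[setdiff(rownames(counts), "unassigned"), colnames(counts),
           drop = FALSE])[labels])
  rarefied <- NULL
  if (!is.na(rarefyDepth)) {
    tot <- colSums(counts)
    pos <- tot > 0  # empty columns (e.g. negative controls) stay zero
    depth <- if (!any(pos)) 0L else if (identical(rarefyDepth, "min"))
      min(tot[pos]) else as.integer(rarefyDepth)
    if (any(pos) && depth > 0) {
      rarefied <- assigned
      sub <- rarefy(assigned[, pos], depth, seed = seed)
      m <- speciesCounts(rarefied)
      m[, pos] <- speciesCounts(sub)
      rarefied <- SpeciesSampleTable(m, colData(assigned)$tank,
                                     colData(assigned)$replicate,
                                     colData(assigned)$primer)
    }
  }
  list(assigned = assigned, rarefied = rarefied, otus = otus,
       fate = fate)
}
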