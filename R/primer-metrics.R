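## Per-primer screening statistics: taxonomic coverage, barcode length,
## taxonomic resolution, amplification-success curves, and the
## coverage + mean-length selection filter.

#' Normalize a species label for species-level counting
#'
#' Case-folds and trims subspecies epithets (everything beyond the first
#' two tokens), so multiple genomes of one species count once.
#'
#' @param x Character vector of species labels.
#' @export
normalizeSpecies <- function(x) {
  toks <- strsplit(trimws(tolower(x)), "\\s+")
  vapply(toks, function(t) paste(head(t, 2L), collapse = " "), character(1))
}

#' Taxonomic coverage of a primer pair
#'
#' Number of distinct species recovered (>= 1 in silico amplification
#' product at the configured mismatch cap) from a reference set.
#'
#' @param pair A \linkS4class{PrimerPair}.
#' @param refs A \linkS4class{ReferenceSet}; empty returns 0.
#' @param cfg A \linkS4class{MetricsConfig}.
#' @return Integer species count.
#' @export
taxonomicCoverage <- function(pair, refs, cfg = MetricsConfig()) {
  if (length(refs) == 0L) return(0L)
  hits <- inSilicoPCR(pair, refs, cfg@maxMismatch,
                      cfg@scanMinLen, cfg@scanMaxLen)
  length(unique(normalizeSpecies(hits$species)))
}

#' Mean barcode (amplicon) length of a primer pair
#'
#' Arithmetic mean of product lengths, primers included.
#'
#' @param hits Non-empty hit table from \code{\link{inSilicoPCR}}.
#' @return Mean length in bp.
#' @export
meanBarcodeLength <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0L)
    stop("mean barcode length is undefined for an empty hit set")
  mean(hits$length)
}

#' Representative barcode per species
#'
#' For resolution statistics each species is represented by one
#' amplicon: the hit with the fewest total mismatches, ties broken by
#' smallest start coordinate, then lexicographically smallest reference
#' id (deterministic and input-order invariant).
#'
#' @param hits Hit table from \code{\link{inSilicoPCR}}.
#' @param refs The matching \linkS4class{ReferenceSet}.
#' @param normalize Normalize species labels (case-fold, drop
#'   subspecies) before picking one representative per species? Set
#'   \code{FALSE} to keep the original labels.
#' @return \code{DNAStringSet} named by species.
#' @export
representativeBarcodes <- function(hits, refs, normalize = TRUE) {
  if (nrow(hits) == 0L) return(DNAStringSet())
  sp <- if (normalize) normalizeSpecies(hits$species) else hits$species
  total_mm <- hits$fwd_mm + hits$rev_mm
  ord <- order(sp, total_mm, hits$start, hits$reference)
  keep <- ord[!duplicated(sp[ord])]
  out <- ampliconSeqs(hits[keep, , drop = FALSE], refs)
  names(out) <- sp[keep]
  out
}

#' Taxonomic resolution of amplified barcodes
#'
#' Average number of bp differences between species per 100 aligned
#' bases: every unordered species pair's representative barcodes are
#' globally aligned with unit substitution and gap costs, scored as
#' \code{100 * edits / alignment columns}, and averaged.
#'
#' @param barcodes \code{DNAStringSet} (or named character), one
#'   representative barcode per species; at least 2 required.
#' @return Mean bp differences per 100 bases.
#' @export
taxonomicResolution <- function(barcodes) {
  seqs <- as.character(barcodes)
  if (length(seqs) < 2L)
    stop("taxonomic resolution is undefined for fewer than 2 species")
  pairs <- combn(length(seqs), 2L)
  vals <- apply(pairs, 2L, function(ij) {
    a <- cpp_align_identity(seqs[ij[1]], seqs[ij[2]])
    100 * a[["edits"]] / a[["columns"]]
  })
  mean(vals)
}

## Penalty of one primer against its binding window, both given 5'->3'
## in primer orientation.
.primerPenalty <- function(primer, window, model) {
  n <- nchar(primer)
  mult <- rep(1, n)
  k <- length(model@threePrimeMultipliers)
  if (k > 0L && n >= k)
    mult[(n - k + 1L):n] <- model@threePrimeMultipliers
  pb <- strsplit(toupper(primer), "")[[1]]
  wb <- strsplit(toupper(window), "")[[1]]
  mm <- !vapply(seq_len(n), function(i) cpp_iupac_match(wb[i], pb[i]),
                logical(1))
  sum(model@basePenalty * mult[mm])
}

## Best (minimum) combined penalty per reference, Inf when the pair
## forms no product at the mismatch cap.
.bestPenalties <- function(pair, refs, cfg) {
  hits <- inSilicoPCR(pair, refs, cfg@maxMismatch,
                      cfg@scanMinLen, cfg@scanMaxLen)
  model <- cfg@penaltyModel
  best <- setNames(rep(Inf, length(refs)), names(refs))
  if (nrow(hits) == 0L) return(best)
  lf <- nchar(pair@forward); lr <- nchar(pair@reverse)
  amps <- as.character(ampliconSeqs(hits, refs))
  for (k in seq_len(nrow(hits))) {
    amp <- amps[k]
    n <- nchar(amp)
    if (hits$orientation[k] == "+") {
      fwd_win <- substr(amp, 1L, lf)
      rev_win <- reverseComplementIupac(substr(amp, n - lr + 1L, n))
    } else {
      fwd_win <- reverseComplementIupac(substr(amp, n - lf + 1L, n))
      rev_win <- substr(amp, 1L, lr)
    }
    pen <- .primerPenalty(pair@forward, fwd_win, model) +
      .primerPenalty(pair@reverse, rev_win, model)
    r <- hits$reference[k]
    if (pen < best[[r]]) best[[r]] <- pen
  }
  best
}

#' Amplification-success curve of a primer pair
#'
#' For each reference the best (minimum) combined mismatch penalty over
#' both primers at their best binding-site pairing is computed under the
#' configured \linkS4class{PenaltyModel}; the curve value at threshold t
#' is the fraction of references with best penalty <= t. References
#' without any product at the mismatch cap never count as amplified.
#' The curve is non-decreasing in t by construction.
#'
#' @inheritParams taxonomicCoverage
#' @return data.frame with \code{threshold} and \code{fraction}.
#' @export
amplificationSuccessCurve <- function(pair, refs, cfg = MetricsConfig()) {
  best <- .bestPenalties(pair, refs, cfg)
  data.frame(threshold = cfg@penaltyThresholds,
             fraction = vapply(cfg@penaltyThresholds,
                               function(t) mean(best <= t), numeric(1)))
}

#' Apply the primer screening filter
#'
#' A primer pair is selected when its species coverage strictly exceeds
#' the coverage threshold AND its mean barcode length lies strictly
#' inside the open length window. Order is preserved from the panel.
#'
#' @param reports data.frame from \code{\link{primerReport}} (columns
#'   \code{coverage} and \code{mean_len}).
#' @param cfg A \linkS4class{MetricsConfig}.
#' @return The input with a logical \code{selected} column (replaced if
#'   present).
#' @export
screenPrimers <- function(reports, cfg = MetricsConfig()) {
  reports$selected <- reports$coverage > cfg@coverageThreshold &
    !is.na(reports$mean_len) &
    reports$mean_len > cfg@lengthWindow[1] &
    reports$mean_len < cfg@lengthWindow[2]
  reports
}

#' Full per-primer screening report
#'
#' Computes, for every pair in a panel, the species coverage, mean and
#' median barcode length, taxonomic resolution and selection status,
#' plus the long-format amplification-success curves.
#'
#' @param panel Named list of \linkS4class{PrimerPair} objects.
#' @param refs A \linkS4class{ReferenceSet}.
#' @param cfg A \linkS4class{MetricsConfig}.
#' @param successCurves Also compute success curves (slower)?
#' @return List with \code{report} (one row per primer: \code{name},
#'   \code{coverage}, \code{mean_len}, \code{median_len},
#'   \code{resolution}, \code{selected}) and \code{curves}
#'   (\code{primer}, \code{threshold}, \code{fraction}; \code{NULL}
#'   unless requested).
#' @export
primerReport <- function(panel, refs, cfg = MetricsConfig(),
                         successCurves = FALSE) {
  rows <- lapply(panel, function(pair) {
    hits <- inSilicoPCR(pair, refs, cfg@maxMismatch,
                        cfg@scanMinLen, cfg@scanMaxLen)
    cov <- length(unique(normalizeSpecies(hits$species)))
    res <- NA_real_
    if (cov >= 2L) {
      reps <- representativeBarcodes(hits, refs)
      res <- taxonomicResolution(reps)
    }
    data.frame(name = pair@name, coverage = cov,
               mean_len = if (nrow(hits)) mean(hits$length) else NA_real_,
               median_len = if (nrow(hits)) median(hits$length) else NA_real_,
               resolution = res)
  })
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  report <- screenPrimers(report, cfg)
  curves <- NULL
  if (successCurves) {
    curves <- do.call(rbind, lapply(panel, function(pair) {
      cv <- amplificationSuccessCurve(pair, refs, cfg)
      cbind(primer = pair@name, cv)
    }))
    rownames(curves) <- NULL
  }
  list(report = report, curves = curves)
}
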