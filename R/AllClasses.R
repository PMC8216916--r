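## Central S4 containers. Sequence data live in Biostrings objects,
## count data in a SummarizedExperiment subclass.

IUPAC_CHARS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "I")

GENE_TARGETS <- c("COI", "cytb", "12S", "16S")

.validIupac <- function(x) {
  all(strsplit(toupper(x), "")[[1]] %in% IUPAC_CHARS)
}

#' PrimerPair: a degenerate metabarcoding primer pair
#'
#' Holds a forward/reverse oligonucleotide pair written 5'->3' in IUPAC
#' codes, its mitochondrial gene target and (optionally) the annealing
#' temperature used in the wet lab.
#'
#' @slot name Short unique label, e.g. \code{"MiFish-U"}.
#' @slot gene One of \code{"COI"}, \code{"cytb"}, \code{"12S"}, \code{"16S"}.
#' @slot forward,reverse IUPAC DNA strings, 5'->3'. Inosine (\code{I})
#'   is accepted and treated as \code{N}.
#' @slot annealingTemp Annealing temperature in degrees C (informational;
#'   \code{NA} when unknown).
#'
#' @examples
#' PrimerPair("MiFish-U", "12S",
#'            "GTCGGTAAAACTCGTGCCAGC", "CATAGTGGGGTATCTAATCCCAGTTTG",
#'            annealingTemp = 58)
#' @export
setClass("PrimerPair",
  representation(name = "character", gene = "character",
                 forward = "character", reverse = "character",
                 annealingTemp = "numeric"),
  prototype(annealingTemp = NA_real_))

setValidity("PrimerPair", function(object) {
  msg <- character(0)
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "name must be a single non-empty string")
  if (length(object@gene) != 1L || !object@gene %in% GENE_TARGETS)
    msg <- c(msg, paste("gene must be one of",
                        paste(GENE_TARGETS, collapse = ", ")))
  for (side in c("forward", "reverse")) {
    s <- slot(object, side)
    if (length(s) != 1L || !nzchar(s))
      msg <- c(msg, paste(side, "sequence must be non-empty"))
    else if (!.validIupac(s))
      msg <- c(msg, paste(side, "sequence contains non-IUPAC characters"))
  }
  if (length(msg)) msg else TRUE
})

#' @param name,gene,forward,reverse,annealingTemp See slot descriptions.
#' @rdname PrimerPair-class
#' @export
PrimerPair <- function(name, gene, forward, reverse,
                       annealingTemp = NA_real_) {
  new("PrimerPair", name = name, gene = gene,
      forward = toupper(forward), reverse = toupper(reverse),
      annealingTemp = as.numeric(annealingTemp))
}

#' @export
setMethod("show", "PrimerPair", function(object) {
  cat("PrimerPair", object@name, sprintf("(%s)\n", object@gene))
  cat("  F 5'-", object@forward, "-3'\n", sep = "")
  cat("  R 5'-", object@reverse, "-3'\n", sep = "")
  if (!is.na(object@annealingTemp))
    cat("  Ta:", object@annealingTemp, "degC\n")
})

#' @rdname PrimerPair-class
#' @param object,x A \code{PrimerPair}.
#' @export
setGeneric("primerName", function(x) standardGeneric("primerName"))
#' @rdname PrimerPair-class
#' @export
setMethod("primerName", "PrimerPair", function(x) x@name)
#' @rdname PrimerPair-class
#' @export
setGeneric("forwardSeq", function(x) standardGeneric("forwardSeq"))
#' @rdname PrimerPair-class
#' @export
setMethod("forwardSeq", "PrimerPair", function(x) x@forward)
#' @rdname PrimerPair-class
#' @export
setGeneric("reverseSeq", function(x) standardGeneric("reverseSeq"))
#' @rdname PrimerPair-class
#' @export
setMethod("reverseSeq", "PrimerPair", function(x) x@reverse)

#' ReferenceSet: species-labelled reference sequences
#'
#' A \link[Biostrings]{DNAStringSet} whose element metadata carry the
#' species label and molecule topology of each record. Names are the
#' accession-like record ids. Circular records (whole mitogenomes) are
#' scanned across the origin by the in silico PCR engine.
#'
#' @slot .Data Inherited from \code{DNAStringSet}; \code{mcols()} must
#'   hold \code{species} (binomial label) and \code{topology}
#'   (\code{"linear"} or \code{"circular"}).
#' @export
setClass("ReferenceSet", contains = "DNAStringSet")

setValidity("ReferenceSet", function(object) {
  msg <- character(0)
  mc <- mcols(object)
  if (is.null(mc) || !all(c("species", "topology") %in% colnames(mc)))
    return("mcols() must contain 'species' and 'topology'")
  if (length(object) && (is.null(names(object)) || anyNA(names(object)) ||
                         !all(nzchar(names(object)))))
    msg <- c(msg, "all records need non-empty ids (names)")
  if (any(duplicated(paste(names(object), mc$species))))
    msg <- c(msg, "(id, species) pairs must be unique")
  if (!all(mc$topology %in% c("linear", "circular")))
    msg <- c(msg, "topology must be 'linear' or 'circular'")
  if (length(object) && any(Biostrings::width(object) < 1L))
    msg <- c(msg, "sequences must be non-empty")
  if (length(msg)) msg else TRUE
})

#' @param seqs A \code{DNAStringSet} or named character vector.
#' @param species Character vector of binomial species labels.
#' @param topology \code{"linear"} or \code{"circular"}, recycled.
#' @param ids Record ids; defaults to \code{names(seqs)}.
#' @rdname ReferenceSet-class
#' @export
ReferenceSet <- function(seqs, species, topology = "linear", ids = NULL) {
  if (!is(seqs, "DNAStringSet")) seqs <- DNAStringSet(seqs)
  if (!is.null(ids)) names(seqs) <- ids
  mcols(seqs) <- DataFrame(species = as.character(species),
                           topology = rep(topology, length.out = length(seqs)))
  new("ReferenceSet", seqs)
}

#' @rdname ReferenceSet-class
#' @param x A \code{ReferenceSet}.
#' @export
setGeneric("refSpecies", function(x) standardGeneric("refSpecies"))
#' @rdname ReferenceSet-class
#' @export
setMethod("refSpecies", "ReferenceSet", function(x) mcols(x)$species)
#' @rdname ReferenceSet-class
#' @export
setGeneric("refTopology", function(x) standardGeneric("refTopology"))
#' @rdname ReferenceSet-class
#' @export
setMethod("refTopology", "ReferenceSet", function(x) mcols(x)$topology)

#' @export
setMethod("show", "ReferenceSet", function(object) {
  cat("ReferenceSet of", length(object), "records,",
      length(unique(mcols(object)$species)), "species\n")
  if (length(object))
    cat("  widths:", paste(range(Biostrings::width(object)),
                           collapse = "-"), "bp\n")
})

#' OTUTable: centroid sequences with per-sample read counts
#'
#' Result of greedy centroid clustering: one centroid sequence per OTU
#' and a non-negative OTU x sample count matrix.
#'
#' @slot centroids \code{DNAStringSet} of centroid sequences, named by
#'   OTU id.
#' @slot counts Integer matrix, rows = OTUs (same order and names as
#'   \code{centroids}), columns = samples.
#' @export
setClass("OTUTable",
  representation(centroids = "DNAStringSet", counts = "matrix"))

setValidity("OTUTable", function(object) {
  msg <- character(0)
  if (length(object@centroids) != nrow(object@counts))
    msg <- c(msg, "one centroid per count row required")
  if (!identical(names(object@centroids), rownames(object@counts)))
    msg <- c(msg, "centroid names must equal count rownames")
  if (length(object@counts) && any(object@counts < 0))
    msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @rdname OTUTable-class
#' @param x,object An \code{OTUTable}.
#' @export
setGeneric("otuCounts", function(x) standardGeneric("otuCounts"))
#' @rdname OTUTable-class
#' @export
setMethod("otuCounts", "OTUTable", function(x) x@counts)
#' @rdname OTUTable-class
#' @export
setGeneric("otuCentroids", function(x) standardGeneric("otuCentroids"))
#' @rdname OTUTable-class
#' @export
setMethod("otuCentroids", "OTUTable", function(x) x@centroids)

#' @export
setMethod("show", "OTUTable", function(object) {
  cat("OTUTable:", nrow(object@counts), "OTUs x",
      ncol(object@counts), "samples,",
      sum(object@counts), "reads\n")
})

#' SpeciesSampleTable: species x sample read counts with tank metadata
#'
#' A \link[SummarizedExperiment]{SummarizedExperiment} with a single
#' \code{counts} assay (rows = species, optionally including an
#' \code{"unassigned"} row) and per-sample \code{tank}, \code{replicate}
#' and \code{primer} columns in \code{colData}.
#'
#' @export
setClass("SpeciesSampleTable", contains = "SummarizedExperiment")

setValidity("SpeciesSampleTable", function(object) {
  msg <- character(0)
  if (!"counts" %in% names(assays(object)))
    return("a 'counts' assay is required")
  if (any(assay(object, "counts") < 0))
    msg <- c(msg, "counts must be non-negative")
  need <- c("tank", "replicate", "primer")
  if (!all(need %in% colnames(colData(object))))
    msg <- c(msg, "colData needs tank, replicate and primer columns")
  if (length(msg)) msg else TRUE
})

#' @param counts Species x sample count matrix (rownames = species).
#' @param tank,replicate,primer Per-sample metadata vectors.
#' @rdname SpeciesSampleTable-class
#' @export
SpeciesSampleTable <- function(counts, tank, replicate, primer) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)))
    colnames(counts) <- paste(tank, replicate, primer, sep = ".")
  se <- SummarizedExperiment(
    assays = list(counts = counts),
    colData = DataFrame(tank = as.character(tank),
                        replicate = as.integer(replicate),
                        primer = as.character(primer),
                        row.names = colnames(counts)))
  new("SpeciesSampleTable", se)
}

#' @rdname SpeciesSampleTable-class
#' @param x A \code{SpeciesSampleTable}.
#' @export
speciesCounts <- function(x) assay(x, "counts")

#' @export
setMethod("show", "SpeciesSampleTable", function(object) {
  cat("SpeciesSampleTable:", nrow(object), "species x",
      ncol(object), "samples\n")
  cat("  primers:", paste(unique(colData(object)$primer), collapse = ", "),
      "\n  tanks:", paste(unique(colData(object)$tank), collapse = ", "),
      "\n")
})

#' RegressionResult: a fitted biomass(or abundance)-read mixed model
#'
#' Summary of one linear mixed-effects fit of log10 read counts on a
#' covariate with a random intercept (species or tank, depending on the
#' design level).
#'
#' @slot primer Primer pair label (or \code{NA}).
#' @slot level \code{"pooled"}, \code{"species:<name>"} or
#'   \code{"tank:<id>"}.
#' @slot covariate \code{"biomass"} or \code{"abundance"}.
#' @slot slope,intercept Fixed effects.
#' @slot slopeP Likelihood-ratio p-value for the slope.
#' @slot r2Corr Squared correlation of fitted and observed responses.
#' @slot r2Marginal Fixed-effect variance over total variance.
#' @slot ranefVariance,residVariance Variance components.
#' @slot n Number of observations.
#' @slot singular \code{TRUE} for a boundary (singular) fit.
#' @export
setClass("RegressionResult",
  representation(primer = "character", level = "character",
                 covariate = "character", slope = "numeric",
                 intercept = "numeric", slopeP = "numeric",
                 r2Corr = "numeric", r2Marginal = "numeric",
                 ranefVariance = "numeric", residVariance = "numeric",
                 n = "integer", singular = "logical"))

setValidity("RegressionResult", function(object) {
  msg <- character(0)
  if (!is.na(object@ranefVariance) && object@ranefVariance < 0)
    msg <- c(msg, "ranefVariance must be >= 0")
  if (!is.na(object@residVariance) && object@residVariance < 0)
    msg <- c(msg, "residVariance must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "RegressionResult", function(object) {
  cat(sprintf(
    "RegressionResult [%s | %s | %s]\n  slope = %.4g (p = %.3g), r2 = %.3f, n = %d%s\n",
    object@primer, object@level, object@covariate, object@slope,
    object@slopeP, object@r2Corr, object@n,
    if (object@singular) ", singular fit" else ""))
})

#' ReadSet: one simulated paired-end amplicon sample
#'
#' In-memory paired reads (with Phred qualities) for one
#' tank/replicate/primer combination, together with the per-species true
#' read counts.
#'
#' @slot mate1,mate2 Character vectors of read sequences.
#' @slot qual1,qual2 Phred+33 quality strings, aligned to the mates.
#' @slot truth Named integer vector of true reads per species.
#' @slot tank,primer Sample labels.
#' @slot replicate Replicate index.
#' @export
setClass("ReadSet",
  representation(mate1 = "character", qual1 = "character",
                 mate2 = "character", qual2 = "character",
                 truth = "integer", tank = "character",
                 replicate = "integer", primer = "character"))

setValidity("ReadSet", function(object) {
  n <- length(object@mate1)
  if (length(object@mate2) != n || length(object@qual1) != n ||
      length(object@qual2) != n)
    return("mate and quality vectors must be parallel")
  if (sum(object@truth) != n)
    return("truth counts must sum to the number of read pairs")
  TRUE
})

#' @export
setMethod("show", "ReadSet", function(object) {
  cat(sprintf("ReadSet %s / rep %d / %s: %d read pairs, %d species\n",
              object@tank, object@replicate, object@primer,
              length(object@mate1), sum(object@truth > 0)))
})
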