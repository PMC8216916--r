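#' Read species-labelled references from a multi-FASTA file
#'
#' Headers are parsed as \code{"id Genus epithet ..."} by default: the
#' first whitespace token is the record id and the next two form the
#' species binomial. Supply \code{speciesFrom} to override - either a
#' regular expression with one capture group applied to the full header,
#' or a function mapping the header to a species label.
#'
#' @param path FASTA file.
#' @param topology \code{"linear"} or \code{"circular"} (recycled).
#' @param speciesFrom \code{NULL}, a regex with one capture group, or a
#'   function of the header string.
#' @return A \linkS4class{ReferenceSet}.
#' @export
readReferenceFasta <- function(path, topology = "linear",
                               speciesFrom = NULL) {
  seqs <- readDNAStringSet(path)
  headers <- names(seqs)
  toks <- strsplit(headers, "\\s+")
  ids <- vapply(toks, `[`, character(1), 1L)
  species <- if (is.null(speciesFrom)) {
    vapply(toks, function(t) paste(t[2:3], collapse = " "), character(1))
  } else if (is.function(speciesFrom)) {
    vapply(headers, speciesFrom, character(1), USE.NAMES = FALSE)
  } else {
    m <- regmatches(headers, regexec(speciesFrom, headers))
    vapply(m, function(g) if (length(g) >= 2L) g[2L] else NA_character_,
           character(1))
  }
  if (anyNA(species) || any(species %in% c("NA NA", "")))
    stop("could not extract a species label from every FASTA header")
  ReferenceSet(seqs, species = species, topology = topology, ids = ids)
}

#' Read a primer panel table
#'
#' Tab-separated with columns \code{name}, \code{gene}, \code{forward},
#' \code{reverse}, \code{annealing_temp}.
#'
#' @param path TSV file.
#' @return Named list of \linkS4class{PrimerPair} objects.
#' @export
readPrimerPanel <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "gene", "forward", "reverse")
  if (!all(need %in% colnames(tab)))
    stop("primer panel needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$name))
    stop("primer names must be unique within a panel")
  ta <- if ("annealing_temp" %in% colnames(tab))
    suppressWarnings(as.numeric(tab$annealing_temp)) else NA_real_
  panel <- lapply(seq_len(nrow(tab)), function(i)
    PrimerPair(tab$name[i], tab$gene[i], tab$forward[i], tab$reverse[i],
               annealingTemp = ta[i]))
  names(panel) <- tab$name
  panel
}

#' The packaged 18-pair fish metabarcoding primer panel
#'
#' The published panel of 18 universal fish primer pairs for COI, cytb,
#' 12S and 16S, as used for the in silico screening. Four of these
#' (AcMDB07, MiFish-U, Ve16S1, Ve16S3) passed screening and carry their
#' wet-lab annealing temperatures.
#'
#' @return Named list of 18 \linkS4class{PrimerPair} objects.
#' @export
fishPrimerPanel <- function() {
  readPrimerPanel(system.file("extdata", "primer_panel.tsv",
                              package = "eDNAtank", mustWork = TRUE))
}

#' Names of the four screened-in primer pairs
#' @export
tankPrimerNames <- function() c("AcMDB07", "MiFish-U", "Ve16S1", "Ve16S3")

#' The four screened-in primer pairs used for the tank experiment
#' @return Named list of 4 \linkS4class{PrimerPair} objects.
#' @export
tankPrimerPanel <- function() fishPrimerPanel()[tankPrimerNames()]

#' The packaged four-tank experimental designs
#'
#' Abundance (individuals) and biomass (g) of the six freshwater fish
#' species in the four 100-L experimental tanks: high/low total density
#' crossed with even/skewed relative abundance.
#'
#' @param negativeControl Also append a fish-free negative-control tank
#'   (\code{"NC"}, all abundance and biomass zero)?
#' @return data.frame with columns \code{tank}, \code{volume_l},
#'   \code{species}, \code{abundance}, \code{biomass_g}.
#' @export
tankDesigns <- function(negativeControl = FALSE) {
  tab <- read.delim(system.file("extdata", "tank_designs.tsv",
                                package = "eDNAtank", mustWork = TRUE),
                    stringsAsFactors = FALSE)
  if (negativeControl) {
    sp <- unique(tab$species)
    tab <- rbind(tab, data.frame(tank = "NC", volume_l = 100,
                                 species = sp, abundance = 0L,
                                 biomass_g = 0))
  }
  tab
}

#' Write amplicon hits as a tab-separated table
#'
#' @param hits data.frame from \code{\link{inSilicoPCR}}.
#' @param path Output file.
#' @export
writeAmpliconTable <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write amplicon sequences as FASTA
#'
#' @param hits data.frame from \code{\link{inSilicoPCR}}.
#' @param refs The matching \linkS4class{ReferenceSet}.
#' @param path Output file.
#' @export
writeAmpliconFasta <- function(hits, refs, path) {
  writeXStringSet(ampliconSeqs(hits, refs), path)
  invisible(path)
}

#' Write a simulated sample as gzipped paired FASTQ files
#'
#' @param rs A \linkS4class{ReadSet}.
#' @param dir Output directory (created if needed).
#' @param prefix File prefix; defaults to tank_rep_primer.
#' @return Character vector of the two file paths.
#' @export
writeReadSet <- function(rs, dir, prefix = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(prefix))
    prefix <- sprintf("%s_rep%d_%s", rs@tank, rs@replicate,
                      gsub("[^A-Za-z0-9]", "", rs@primer))
  paths <- file.path(dir, paste0(prefix, c("_R1.fastq.gz", "_R2.fastq.gz")))
  ids <- sprintf("%s_read%06d", prefix, seq_along(rs@mate1))
  for (m in 1:2) {
    seqs <- DNAStringSet(slot(rs, paste0("mate", m)))
    names(seqs) <- ids
    writeXStringSet(seqs, paths[m], format = "fastq",
                    qualities = BStringSet(slot(rs, paste0("qual", m))),
                    compress = TRUE)
  }
  paths
}

#' Read a paired FASTQ sample back into a ReadSet
#'
#' @param r1,r2 FASTQ(.gz) mate files.
#' @param tank,replicate,primer Sample metadata.
#' @param truth Optional named true counts; defaults to an empty truth
#'   assigning all reads to \code{"unknown"}.
#' @return A \linkS4class{ReadSet}.
#' @export
readReadSet <- function(r1, r2, tank = "NA", replicate = 1L,
                        primer = "NA", truth = NULL) {
  x1 <- readQualityScaledDNAStringSet(r1)
  x2 <- readQualityScaledDNAStringSet(r2)
  if (is.null(truth))
    truth <- c(unknown = length(x1))
  new("ReadSet", mate1 = unname(as.character(x1)),
      qual1 = unname(as.character(quality(x1))),
      mate2 = unname(as.character(x2)),
      qual2 = unname(as.character(quality(x2))),
      truth = setNames(as.integer(truth), names(truth)),
      tank = tank, replicate = as.integer(replicate), primer = primer)
}
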