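#' IUPAC-aware base and window matching
#'
#' Two IUPAC codes match when the base sets they encode intersect;
#' matching is symmetric, and \code{N} (and inosine \code{I}, treated as
#' \code{N}) matches everything. This is the degenerate-primer matching
#' semantics used throughout the in silico PCR engine: ambiguity codes
#' in the template also count as matches when the sets intersect
#' (conservative towards amplification).
#'
#' @param templateBase,primerBase Single IUPAC characters.
#' @return \code{iupacMatch}: logical.
#' @examples
#' iupacMatch("G", "R")  # TRUE,  R = {A, G}
#' iupacMatch("T", "R")  # FALSE
#' @export
iupacMatch <- function(templateBase, primerBase) {
  cpp_iupac_match(toupper(templateBase), toupper(primerBase))
}

#' @param primer,window Equal-length IUPAC strings.
#' @return \code{countMismatches}: integer number of non-matching
#'   positions.
#' @rdname iupacMatch
#' @export
countMismatches <- function(primer, window) {
  cpp_count_mismatches(toupper(primer), toupper(window))
}

#' Reverse complement of an IUPAC string
#'
#' Unlike \code{Biostrings::reverseComplement} this accepts inosine
#' (\code{I}), whose complement is taken as \code{N} (it pairs
#' promiscuously).
#'
#' @param x A single IUPAC DNA string.
#' @export
reverseComplementIupac <- function(x) {
  x <- toupper(x)
  comp <- chartr("ACGTURYSWKMBDHVNI", "TGCAAYRSWMKVHDBNN", x)
  vapply(strsplit(comp, ""), function(ch) paste(rev(ch), collapse = ""),
         character(1))
}
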