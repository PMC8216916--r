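#' Find primer binding sites on a reference sequence
#'
#' Ungapped scan of every window of primer width, keeping windows with at
#' most \code{maxMismatch} IUPAC-aware mismatches (substitutions only; a
#' zero gap cost with a mismatch cap is equivalent to capping
#' substitutions in an ungapped scan). For \code{orientation = "minus"}
#' the primer is reverse-complemented before scanning, so reported
#' coordinates are always on the forward strand. Circular templates are
#' scanned across the origin exactly once: window starts lie in
#' \code{[0, L)} and \code{end} may exceed the sequence length for
#' origin-spanning sites.
#'
#' @param primer IUPAC primer string, 5'->3'.
#' @param subject Reference sequence (character or \code{DNAString}).
#' @param maxMismatch Maximum mismatches (default 3).
#' @param orientation \code{"plus"} (scan the primer as given) or
#'   \code{"minus"} (scan its reverse complement).
#' @param topology \code{"linear"} or \code{"circular"}.
#' @return data.frame with 0-based half-open \code{start}, \code{end},
#'   \code{mismatches}, and \code{wraps} (site spans the origin). A
#'   primer longer than the reference yields an empty result.
#' @examples
#' findBindingSites("ACGT", "TTTACGTTTT", maxMismatch = 0)
#' @export
findBindingSites <- function(primer, subject, maxMismatch = 3,
                             orientation = c("plus", "minus"),
                             topology = c("linear", "circular")) {
  orientation <- match.arg(orientation)
  topology <- match.arg(topology)
  subject <- toupper(as.character(subject))
  primer <- toupper(primer)
  scanned <- if (orientation == "minus") reverseComplementIupac(primer)
             else primer
  L <- nchar(subject)
  plen <- nchar(scanned)
  tmpl <- subject
  if (topology == "circular" && plen > 1L && L >= plen)
    tmpl <- paste0(subject, substr(subject, 1L, plen - 1L))
  res <- cpp_find_sites(scanned, tmpl, as.integer(maxMismatch))
  start <- res$start
  data.frame(start = start, end = start + plen,
             mismatches = res$mismatches,
             wraps = start + plen > L)
}

## Pair left and right binding sites into candidate products; for each
## anchor site (where the forward primer binds) keep the shortest
## admissible product. Lengths are measured primer-inclusive.
.pairSites <- function(left, right, leftLen, rightLen, L, circular,
                       minLen, maxLen, anchor = c("left", "right")) {
  anchor <- match.arg(anchor)
  out <- list()
  if (nrow(left) == 0L || nrow(right) == 0L) return(out)
  anchors <- if (anchor == "left") seq_len(nrow(left)) else seq_len(nrow(right))
  for (a in anchors) {
    cand_len <- numeric(0); cand_i <- integer(0)
    if (anchor == "left") {
      s1 <- left$start[a]
      for (j in seq_len(nrow(right))) {
        s2 <- right$start[j]
        if (s2 >= s1 + leftLen) {
          len <- s2 + rightLen - s1
        } else if (circular) {
          len <- s2 + L + rightLen - s1
          if (len > L) next
        } else next
        if (len >= minLen && len <= maxLen) {
          cand_len <- c(cand_len, len); cand_i <- c(cand_i, j)
        }
      }
      if (length(cand_i)) {
        k <- cand_i[which.min(cand_len)]
        out[[length(out) + 1L]] <- list(
          start = s1, length = min(cand_len),
          left_mm = left$mismatches[a], right_mm = right$mismatches[k])
      }
    } else {
      s2 <- right$start[a]
      for (j in seq_len(nrow(left))) {
        s1 <- left$start[j]
        if (s1 + leftLen <= s2) {
          len <- s2 + rightLen - s1
        } else if (circular) {
          len <- s2 + rightLen - s1 + L
          if (len > L) next
        } else next
        if (len >= minLen && len <= maxLen) {
          cand_len <- c(cand_len, len); cand_i <- c(cand_i, j)
        }
      }
      if (length(cand_i)) {
        k <- cand_i[which.min(cand_len)]
        s1 <- left$start[k]
        start <- if (s1 + leftLen <= s2) s1 else s1  # left coord mod L
        out[[length(out) + 1L]] <- list(
          start = start, length = min(cand_len),
          left_mm = left$mismatches[k], right_mm = right$mismatches[a])
      }
    }
  }
  out
}

#' In silico PCR of a primer pair against reference sequences
#'
#' Pairs forward binding sites with downstream reverse-complemented
#' reverse-primer sites and reports one amplification product per
#' forward site: the shortest product within the length bounds (short
#' products dominate PCR). Both orientations are scanned (the forward
#' primer may bind the minus strand), and all coordinates are reported
#' on the forward strand, 0-based half-open. Product lengths include
#' both primers. Circular references are unwrapped across the origin;
#' origin-spanning products keep \code{start} in \code{[0, L)} with
#' \code{end > L} and \code{wraps_origin = TRUE}.
#'
#' @param pair A \linkS4class{PrimerPair}.
#' @param refs A \linkS4class{ReferenceSet}.
#' @param maxMismatch Maximum mismatches per primer (default 3).
#' @param minLen,maxLen Product length bounds in bp, primer-inclusive
#'   (defaults 50 and 1000: wide, so screening metrics are not
#'   pre-filtered).
#' @return data.frame of amplicon hits: \code{reference},
#'   \code{species}, \code{start}, \code{end}, \code{length},
#'   \code{fwd_mm}, \code{rev_mm}, \code{orientation},
#'   \code{wraps_origin}.
#' @seealso \code{\link{ampliconSeqs}} to extract product sequences.
#' @export
inSilicoPCR <- function(pair, refs, maxMismatch = 3, minLen = 50,
                        maxLen = 1000) {
  stopifnot(is(pair, "PrimerPair"), is(refs, "ReferenceSet"),
            minLen < maxLen, maxMismatch >= 0)
  fwd <- pair@forward; rev <- pair@reverse
  lf <- nchar(fwd); lr <- nchar(rev)
  rows <- list()
  for (i in seq_along(refs)) {
    sq <- as.character(refs[[i]])
    L <- nchar(sq)
    topo <- mcols(refs)$topology[i]
    circ <- topo == "circular"
    fOnPlus <- findBindingSites(fwd, sq, maxMismatch, "plus", topo)
    rRcOnPlus <- findBindingSites(rev, sq, maxMismatch, "minus", topo)
    plus <- .pairSites(fOnPlus, rRcOnPlus, lf, lr, L, circ,
                       minLen, maxLen, anchor = "left")
    rOnPlus <- findBindingSites(rev, sq, maxMismatch, "plus", topo)
    fRcOnPlus <- findBindingSites(fwd, sq, maxMismatch, "minus", topo)
    minus <- .pairSites(rOnPlus, fRcOnPlus, lr, lf, L, circ,
                        minLen, maxLen, anchor = "right")
    mk <- function(h, ori) {
      fm <- if (ori == "+") h$left_mm else h$right_mm
      rm_ <- if (ori == "+") h$right_mm else h$left_mm
      data.frame(reference = names(refs)[i],
                 species = mcols(refs)$species[i],
                 start = as.integer(h$start),
                 end = as.integer(h$start + h$length),
                 length = as.integer(h$length),
                 fwd_mm = as.integer(fm), rev_mm = as.integer(rm_),
                 orientation = ori,
                 wraps_origin = h$start + h$length > L)
    }
    rows <- c(rows, lapply(plus, mk, ori = "+"),
              lapply(minus, mk, ori = "-"))
  }
  if (!length(rows))
    return(data.frame(reference = character(0), species = character(0),
                      start = integer(0), end = integer(0),
                      length = integer(0), fwd_mm = integer(0),
                      rev_mm = integer(0), orientation = character(0),
                      wraps_origin = logical(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$reference, out$start, out$orientation), , drop = FALSE]
}

#' Extract amplicon sequences for in silico PCR hits
#'
#' Returns the forward-strand sequence of each product (minus-strand
#' products are therefore the reverse complement of what would be
#' sequenced). Origin-spanning hits on circular references are stitched
#' across the origin.
#'
#' @param hits data.frame from \code{\link{inSilicoPCR}}.
#' @param refs The \linkS4class{ReferenceSet} the hits came from.
#' @return \code{DNAStringSet} named
#'   \code{reference:start-end(orientation)}.
#' @export
ampliconSeqs <- function(hits, refs) {
  seqs <- character(nrow(hits))
  for (k in seq_len(nrow(hits))) {
    sq <- as.character(refs[[match(hits$reference[k], names(refs))]])
    if (hits$wraps_origin[k]) sq <- paste0(sq, sq)
    seqs[k] <- substr(sq, hits$start[k] + 1L, hits$end[k])
  }
  out <- DNAStringSet(seqs)
  names(out) <- sprintf("%s:%d-%d(%s)", hits$reference, hits$start,
                        hits$end, hits$orientation)
  out
}
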