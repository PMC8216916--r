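## Independent naive oracles and small synthetic fixtures, written
## without reference to the package internals: plain R loops over the
## published IUPAC code table.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"), I = c("A", "C", "G", "T"))

ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                 S = "S", W = "W", K = "M", M = "K", B = "V", D = "H",
                 H = "D", V = "B", N = "N", I = "N")

oracle_match <- function(a, b) {
  length(intersect(ORACLE_IUPAC[[a]], ORACLE_IUPAC[[b]])) > 0
}

oracle_mm <- function(primer, window) {
  p <- strsplit(primer, "")[[1]]
  w <- strsplit(window, "")[[1]]
  stopifnot(length(p) == length(w))
  sum(!mapply(oracle_match, w, p))
}

oracle_revcomp <- function(x) {
  paste(rev(ORACLE_COMP[strsplit(x, "")[[1]]]), collapse = "")
}

## All binding sites of `primer` (already oriented) on the forward
## strand; circular templates are scanned across the origin once.
oracle_sites <- function(primer, tmpl, max_mm, circular = FALSE) {
  L <- nchar(tmpl)
  p <- nchar(primer)
  scan <- if (circular && L >= p) paste0(tmpl, substr(tmpl, 1, p - 1)) else tmpl
  starts <- integer(0); mms <- integer(0)
  if (p <= nchar(scan)) {
    last <- if (circular && L >= p) L - 1 else nchar(scan) - p
    for (s in 0:last) {
      mm <- oracle_mm(primer, substr(scan, s + 1, s + p))
      if (mm <= max_mm) { starts <- c(starts, s); mms <- c(mms, mm) }
    }
  }
  data.frame(start = starts, mm = mms)
}

## Full naive in silico PCR: enumerate all admissible left/right site
## pairs in both orientations, keep the shortest product per
## forward-primer binding site.
oracle_pcr <- function(fwd, rev, tmpl, max_mm, min_len, max_len,
                       circular = FALSE) {
  L <- nchar(tmpl)
  out <- list()
  one_orientation <- function(leftP, rightP, anchor_right, ori) {
    ll <- nchar(leftP); lr <- nchar(rightP)
    left <- oracle_sites(leftP, tmpl, max_mm, circular)
    right <- oracle_sites(oracle_revcomp(rightP), tmpl, max_mm, circular)
    anchors <- if (anchor_right) seq_len(nrow(right)) else seq_len(nrow(left))
    for (a in anchors) {
      best <- NULL
      others <- if (anchor_right) seq_len(nrow(left)) else seq_len(nrow(right))
      for (o in others) {
        s1 <- if (anchor_right) left$start[o] else left$start[a]
        s2 <- if (anchor_right) right$start[a] else right$start[o]
        if (s2 >= s1 + ll) len <- s2 + lr - s1
        else if (circular) {
          len <- s2 + L + lr - s1
          if (len > L) next
        } else next
        if (len < min_len || len > max_len) next
        if (is.null(best) || len < best$length)
          best <- list(start = s1, length = len,
                       left_mm = if (anchor_right) left$mm[o] else left$mm[a],
                       right_mm = if (anchor_right) right$mm[a] else right$mm[o])
      }
      if (!is.null(best))
        out[[length(out) + 1]] <<- data.frame(
          start = best$start, end = best$start + best$length,
          length = best$length,
          fwd_mm = if (ori == "+") best$left_mm else best$right_mm,
          rev_mm = if (ori == "+") best$right_mm else best$left_mm,
          orientation = ori)
    }
  }
  # plus: fwd on the left; minus: fwd (revcomped) on the right
  one_orientation(fwd, rev, anchor_right = FALSE, ori = "+")
  one_orientation(rev, fwd, anchor_right = TRUE, ori = "-")
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), fwd_mm = integer(0),
                      rev_mm = integer(0), orientation = character(0)))
  res <- do.call(rbind, out)
  res[order(res$start, res$end, res$orientation), , drop = FALSE]
}

## canonical sorted form for hit-table comparison
canon_hits <- function(df) {
  df <- df[, c("start", "end", "length", "fwd_mm", "rev_mm",
               "orientation")]
  df <- df[order(df$start, df$end, df$orientation), , drop = FALSE]
  rownames(df) <- NULL
  df
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## random primer with occasional degenerate codes
rand_primer <- function(n, degenerate = TRUE) {
  pool <- c(rep(c("A", "C", "G", "T"), 6),
            if (degenerate) c("R", "Y", "S", "W", "K", "M", "N"))
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

toy_refs <- function(seqs, species = NULL, topology = "linear") {
  if (is.null(species))
    species <- sprintf("Testfish sp%02d", seq_along(seqs))
  ReferenceSet(seqs, species = species, topology = topology,
               ids = sprintf("REF%03d", seq_along(seqs)))
}

## substitute n positions of a (possibly degenerate) string with
## random plain bases
.mutate_n <- function(x, n) {
  ch <- strsplit(x, "")[[1]]
  pos <- sample(length(ch), min(n, length(ch)))
  ch[pos] <- sample(c("A", "C", "G", "T"), length(pos), replace = TRUE)
  paste(ch, collapse = "")
}

## exactly n substitutions at distinct positions, each to a different base
.mutate_to_n_mismatches <- function(x, n) {
  ch <- strsplit(x, "")[[1]]
  pos <- sample(length(ch), n)
  ch[pos] <- vapply(ch[pos], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  paste(ch, collapse = "")
}

## one tank design row-set for quick simulations
toy_design <- function(species, biomass, abundance = NULL,
                       tank = "T1") {
  data.frame(tank = tank, volume_l = 100, species = species,
             abundance = if (is.null(abundance))
               rep(1L, length(species)) else abundance,
             biomass_g = biomass, stringsAsFactors = FALSE)
}
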