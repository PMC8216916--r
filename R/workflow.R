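## Orchestration: configuration with published defaults, seeded
## end-to-end runs (screen -> simulate -> process -> quantify), and the
## detection matrix summarising species recovery.

#' Default run configuration
#'
#' Every threshold default is the published value of the corresponding
#' pipeline step: mismatch cap 3, coverage cutoff 2,000 species,
#' mean-length window (150, 350) bp, penalty grid 0-15,000, merge
#' overlap 10 and Phred 20, minimum read length 100, primer mismatch
#' cap 2, 97\% OTU identity, whole-data OTU total minimum 10, 97\%
#' assignment identity.
#'
#' @return Nested list of stage parameter blocks (\code{seed},
#'   \code{primers}, \code{screen}, \code{sim}, \code{pipeline},
#'   \code{stats}).
#' @export
defaultRunConfig <- function() {
  list(
    seed = 1L,
    primers = tankPrimerNames(),
    screen = list(
      max_mismatch = 3L,
      coverage_threshold = 2000,
      length_window = c(150, 350),
      penalty_thresholds = seq(0, 15000, by = 500),
      success_curves = TRUE),
    sim = list(
      n_species = 6L,
      replicates_per_tank = 3L,
      total_reads_per_sample = 500000L,
      lognormal_sigma = 0.3,
      error_rate = 0.005,
      read_length = 250L,
      lognormal_meanlog = 1.6,
      lognormal_sdlog = 0.8,
      efficiency_preset = "unbiased",
      negative_control = TRUE),
    pipeline = list(
      min_overlap = 10L,
      min_phred = 20,
      max_merge_mismatch_frac = 0.1,
      max_primer_mismatch = 2L,
      min_length = 100L,
      otu_identity = 0.97,
      min_otu_total = 10L,
      assign_identity = 0.97,
      min_alignment_length = 100L,
      rarefy_depth = "min"),
    stats = list(
      pseudocount = 1,
      pseudocount_policy = "zeros",
      permutations = 1000L))
}

.validateConfig <- function(cfg, ref = defaultRunConfig(),
                            path = character(0)) {
  bad <- setdiff(names(cfg), names(ref))
  if (length(bad))
    stop("unknown configuration key(s): ",
         paste(paste(c(path, ""), collapse = "$"), bad,
               sep = "", collapse = ", "))
  for (k in names(cfg)) {
    if (is.list(ref[[k]]))
      .validateConfig(cfg[[k]], ref[[k]], c(path, k))
  }
  chk <- function(val, ok, what) {
    if (!is.null(val) && !ok(val)) stop("invalid configuration value: ", what)
  }
  if (!length(path)) {
    p <- cfg$pipeline
    chk(p$otu_identity, function(x) x > 0 && x <= 1, "pipeline$otu_identity")
    chk(p$assign_identity, function(x) x > 0 && x <= 1,
        "pipeline$assign_identity")
    chk(p$max_merge_mismatch_frac, function(x) x >= 0 && x <= 1,
        "pipeline$max_merge_mismatch_frac")
    chk(cfg$sim$error_rate, function(x) x >= 0 && x < 1, "sim$error_rate")
    chk(cfg$screen$max_mismatch, function(x) x >= 0, "screen$max_mismatch")
    w <- cfg$screen$length_window
    chk(w, function(x) length(x) == 2 && x[1] < x[2],
        "screen$length_window")
  }
  invisible(TRUE)
}

.deepMerge <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]]))
      base[[k]] <- .deepMerge(base[[k]], override[[k]])
    else base[[k]] <- override[[k]]
  }
  base
}

#' Load a run configuration
#'
#' An absent file yields the full defaults; a partial JSON file is
#' deep-merged over them. Unknown keys and out-of-range values raise a
#' validation error.
#'
#' @param path JSON configuration file, or \code{NULL} for defaults.
#' @return Validated nested configuration list.
#' @export
loadRunConfig <- function(path = NULL) {
  cfg <- defaultRunConfig()
  if (!is.null(path)) {
    user <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    .validateConfig(user)
    cfg <- .deepMerge(cfg, user)
  }
  .validateConfig(cfg)
  cfg
}

.sampleSeed <- function(master, i) {
  as.integer((as.numeric(master) + 10007 * i) %% 2147483647)
}

#' Species detection matrix
#'
#' Presence/absence of each species per tank and primer from assigned
#' read counts.
#'
#' @param tables Named list (by primer) of
#'   \linkS4class{SpeciesSampleTable}s of assigned counts.
#' @param allReplicates Require detection in every replicate
#'   (default: any replicate).
#' @return data.frame with \code{species}, \code{tank}, \code{primer},
#'   \code{detected}.
#' @export
detectionMatrix <- function(tables, allReplicates = FALSE) {
  rows <- list()
  for (pn in names(tables)) {
    tab <- tables[[pn]]
    counts <- speciesCounts(tab)
    counts <- counts[setdiff(rownames(counts), "unassigned"), ,
                     drop = FALSE]
    cd <- colData(tab)
    for (tk in unique(cd$tank)) {
      cols <- which(cd$tank == tk)
      det <- if (allReplicates) rowSums(counts[, cols, drop = FALSE] > 0) ==
        length(cols) else rowSums(counts[, cols, drop = FALSE]) > 0
      rows[[length(rows) + 1L]] <- data.frame(
        species = rownames(counts), tank = tk, primer = pn,
        detected = unname(det), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full two-stage analysis end to end
#'
#' Executes screen -> simulate -> process -> quantify on synthetic
#' references and the packaged tank designs, writing all reports to
#' \code{outdir}: the primer screening report, per-primer truth and
#' species x sample tables, read-fate accounting, the regression and
#' pairwise-comparison reports, and the detection matrix. Fully
#' reproducible: identical (config, seed) give identical outputs.
#'
#' @param config From \code{\link{loadRunConfig}}.
#' @param outdir Output directory (created).
#' @param designs Tank design table (default the packaged four tanks).
#' @param quiet Suppress progress messages?
#' @return Invisibly, a list with the in-memory results:
#'   \code{refs}, \code{screen}, \code{truth}, \code{assigned},
#'   \code{rarefied}, \code{fate}, \code{regressions},
#'   \code{comparisons}, \code{detection}.
#' @export
runEndToEnd <- function(config = loadRunConfig(), outdir = tempfile("run"),
                        designs = tankDesigns(), quiet = TRUE) {
  .validateConfig(config)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  t0 <- Sys.time()
  seed <- as.integer(config$seed)
  panel <- fishPrimerPanel()
  if (!all(config$primers %in% names(panel)))
    stop("unknown primer name(s): ",
         paste(setdiff(config$primers, names(panel)), collapse = ", "))
  primers <- panel[config$primers]
  jsonlite::write_json(config, file.path(outdir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  ## stage 1: synthetic references + screening report
  say("[screen] generating references and screening ", length(primers),
      " primer pair(s)")
  species <- unique(designs$species[designs$biomass_g > 0])
  refs <- generateReferenceDb(length(species), panel = primers,
                              seed = .sampleSeed(seed, 0),
                              speciesNames = species)
  mcfg <- MetricsConfig(
    maxMismatch = config$screen$max_mismatch,
    coverageThreshold = config$screen$coverage_threshold,
    lengthWindow = config$screen$length_window,
    penaltyThresholds = config$screen$penalty_thresholds)
  screen <- primerReport(primers, refs, mcfg,
                         successCurves = isTRUE(config$screen$success_curves))
  write.table(screen$report, file.path(outdir, "primer_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(screen$curves))
    write.table(screen$curves, file.path(outdir, "success_curves.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)

  ## stage 2 + 3: simulate and process per primer
  scfg <- SimConfig(
    seed = seed,
    replicatesPerTank = config$sim$replicates_per_tank,
    totalReadsPerSample = config$sim$total_reads_per_sample,
    lognormalSigma = config$sim$lognormal_sigma,
    errorRate = config$sim$error_rate,
    readLength = config$sim$read_length,
    lognormalMeanlog = config$sim$lognormal_meanlog,
    lognormalSdlog = config$sim$lognormal_sdlog)
  profiles <- speciesProfiles(species, names(primers),
                              preset = config$sim$efficiency_preset)
  tanks <- unique(designs$tank)
  if (isTRUE(config$sim$negative_control)) {
    nc <- unique(data.frame(tank = "NC", volume_l = 100,
                            species = species, abundance = 0L,
                            biomass_g = 0))
    designs_all <- rbind(designs, nc)
    tanks <- c(tanks, "NC")
  } else designs_all <- designs
  truth <- assigned <- rarefied <- fate <- list()
  pcfg <- config$pipeline
  si <- 0L
  for (pn in names(primers)) {
    say("[simulate] ", pn)
    readsets <- list()
    for (tk in tanks) for (r in seq_len(scfg@replicatesPerTank)) {
      si <- si + 1L
      set.seed(.sampleSeed(seed, si))
      dsn <- designs_all[designs_all$tank == tk, , drop = FALSE]
      readsets[[length(readsets) + 1L]] <-
        simulateTankSample(dsn, primers[[pn]], refs, profiles, scfg,
                           replicate = r, tank = tk)
    }
    truth[[pn]] <- emitTruthTable(readsets)
    say("[process] ", pn)
    run <- processRun(readsets, primers[[pn]], refs,
                      otuIdentity = pcfg$otu_identity,
                      minOtuTotal = pcfg$min_otu_total,
                      assignIdentity = pcfg$assign_identity,
                      minAlnLen = pcfg$min_alignment_length,
                      minOverlap = pcfg$min_overlap,
                      minPhred = pcfg$min_phred,
                      maxMismatchFrac = pcfg$max_merge_mismatch_frac,
                      maxPrimerMismatch = pcfg$max_primer_mismatch,
                      minLen = pcfg$min_length,
                      rarefyDepth = pcfg$rarefy_depth,
                      seed = .sampleSeed(seed, 900000L + si))
    assigned[[pn]] <- run$assigned
    rarefied[[pn]] <- if (is.null(run$rarefied)) run$assigned else
      run$rarefied
    fate[[pn]] <- run$fate
    for (what in c("truth", "assigned", "rarefied")) {
      tab <- speciesCounts(get(what)[[pn]])
      write.table(cbind(species = rownames(tab), as.data.frame(tab)),
                  file.path(outdir, sprintf("%s_%s.tsv", what,
                                            gsub("[^A-Za-z0-9]", "", pn))),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write.table(cbind(sample = rownames(run$fate),
                      as.data.frame(run$fate)),
                file.path(outdir, sprintf("fate_%s.tsv",
                                          gsub("[^A-Za-z0-9]", "", pn))),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ## stage 4: quantification
  say("[quantify]")
  results <- list()
  comparisons <- list()
  for (pn in names(primers)) {
    tab <- rarefied[[pn]]
    keep <- colData(tab)$tank != "NC"
    qd <- makeQuantDataset(tab[, keep], designs)
    for (cv in c("biomass", "abundance"))
      results[[length(results) + 1L]] <-
        fitLme(qd, cv, "pooled", primer = pn,
               pseudocountPolicy = config$stats$pseudocount_policy,
               pseudocount = config$stats$pseudocount)
    for (sp in species)
      results[[length(results) + 1L]] <-
        fitLme(qd, "biomass", paste0("species:", sp), primer = pn,
               pseudocountPolicy = config$stats$pseudocount_policy,
               pseudocount = config$stats$pseudocount)
    for (tk in unique(designs$tank))
      results[[length(results) + 1L]] <-
        fitLme(qd, "biomass", paste0("tank:", tk), primer = pn,
               pseudocountPolicy = config$stats$pseudocount_policy,
               pseudocount = config$stats$pseudocount)
  }
  report <- regressionReport(results)
  write.table(report, file.path(outdir, "regression_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  pns <- names(primers)
  if (length(pns) >= 2) {
    ci <- 0L
    for (a in seq_len(length(pns) - 1L)) for (b in (a + 1L):length(pns)) {
      for (tk in unique(designs$tank)) for (sp in species) {
        ca <- .replicateCounts(rarefied[[pns[a]]], sp, tk)
        cb <- .replicateCounts(rarefied[[pns[b]]], sp, tk)
        if (length(ca) < 2 || length(cb) < 2) next
        ci <- ci + 1L
        wt <- whitesTTest(ca, cb, config$stats$permutations,
                          seed = .sampleSeed(seed, 800000L + ci))
        comparisons[[length(comparisons) + 1L]] <- data.frame(
          species = sp, tank = tk, primerA = pns[a], primerB = pns[b],
          mean_diff = wt$meanDiff, p = wt$p,
          permutations = wt$permutations,
          significant = wt$p < 0.05, stringsAsFactors = FALSE)
      }
    }
  }
  comp <- if (length(comparisons)) do.call(rbind, comparisons) else
    data.frame()
  if (nrow(comp))
    write.table(comp, file.path(outdir, "comparisons.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

  detection <- detectionMatrix(lapply(assigned, function(tab)
    tab[, colData(tab)$tank != "NC"]))
  write.table(detection, file.path(outdir, "detection_matrix.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  say(sprintf("[done] %.1f s, outputs in %s",
              as.numeric(difftime(Sys.time(), t0, units = "secs")),
              outdir))
  invisible(list(refs = refs, screen = screen, truth = truth,
                 assigned = assigned, rarefied = rarefied, fate = fate,
                 regressions = report, comparisons = comp,
                 detection = detection, outdir = outdir))
}

.replicateCounts <- function(tab, species, tank) {
  counts <- speciesCounts(tab)
  cd <- colData(tab)
  cols <- which(cd$tank == tank)
  if (!species %in% rownames(counts)) return(numeric(0))
  as.numeric(counts[species, cols])
}
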