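## Screening and simulation configuration objects. Defaults are the
## published thresholds of the two-stage evaluation: mismatch cap 3,
## coverage cutoff 2,000 species, open mean-length window (150, 350) bp,
## penalty threshold grid 0..15,000.

#' PenaltyModel: scoring of primer-template mismatches
#'
#' Converts positional primer-template mismatches into a penalty score.
#' Each mismatching position costs \code{basePenalty} times a positional
#' multiplier; the final \code{length(threePrimeMultipliers)} primer
#' positions (towards the 3' terminus, where extension is most
#' sensitive) are up-weighted by the multiplier vector, ordered 5'-most
#' to 3'-terminal. A perfect match scores 0. The published screening
#' inherits an unstated scoring table on a 0-15,000 scale; this model is
#' a configurable stand-in whose ordinal behaviour (curve shape,
#' ranking) is what downstream screening uses.
#'
#' @slot basePenalty Score units per substitution (default 100).
#' @slot threePrimeMultipliers Multipliers for the last k positions
#'   (default \code{c(2, 4, 8, 16, 32)}).
#' @export
setClass("PenaltyModel",
  representation(basePenalty = "numeric",
                 threePrimeMultipliers = "numeric"),
  prototype(basePenalty = 100,
            threePrimeMultipliers = c(2, 4, 8, 16, 32)))

setValidity("PenaltyModel", function(object) {
  if (length(object@basePenalty) != 1L || object@basePenalty <= 0)
    return("basePenalty must be a single positive number")
  if (any(object@threePrimeMultipliers < 1))
    return("threePrimeMultipliers must be >= 1")
  TRUE
})

#' @param basePenalty,threePrimeMultipliers See slots.
#' @rdname PenaltyModel-class
#' @export
PenaltyModel <- function(basePenalty = 100,
                         threePrimeMultipliers = c(2, 4, 8, 16, 32)) {
  new("PenaltyModel", basePenalty = basePenalty,
      threePrimeMultipliers = threePrimeMultipliers)
}

#' MetricsConfig: primer screening parameters
#'
#' @slot maxMismatch Maximum primer-template mismatches per primer
#'   (default 3).
#' @slot coverageThreshold Minimum species count for initial selection
#'   (default 2000; a primer must recover MORE than this).
#' @slot lengthWindow Open interval (lower, upper) in bp applied to the
#'   MEAN barcode length (default 150-350).
#' @slot penaltyThresholds Strictly increasing threshold grid for the
#'   amplification-success curve (default \code{seq(0, 15000, 500)}).
#' @slot penaltyModel A \linkS4class{PenaltyModel}.
#' @slot scanMinLen,scanMaxLen Product length bounds used while
#'   scanning (wide by design, 50-1000 bp, so screening does not
#'   pre-filter what the mean-length window should judge).
#' @export
setClass("MetricsConfig",
  representation(maxMismatch = "integer", coverageThreshold = "numeric",
                 lengthWindow = "numeric", penaltyThresholds = "numeric",
                 penaltyModel = "PenaltyModel",
                 scanMinLen = "integer", scanMaxLen = "integer"),
  prototype(maxMismatch = 3L, coverageThreshold = 2000,
            lengthWindow = c(150, 350),
            penaltyThresholds = seq(0, 15000, by = 500),
            scanMinLen = 50L, scanMaxLen = 1000L))

setValidity("MetricsConfig", function(object) {
  msg <- character(0)
  if (object@maxMismatch < 0) msg <- c(msg, "maxMismatch must be >= 0")
  if (length(object@lengthWindow) != 2L ||
      object@lengthWindow[1] >= object@lengthWindow[2])
    msg <- c(msg, "lengthWindow must be (lower, upper) with lower < upper")
  if (any(diff(object@penaltyThresholds) <= 0))
    msg <- c(msg, "penaltyThresholds must be strictly increasing")
  if (object@scanMinLen >= object@scanMaxLen)
    msg <- c(msg, "scanMinLen must be < scanMaxLen")
  if (length(msg)) msg else TRUE
})

#' @param maxMismatch,coverageThreshold,lengthWindow,penaltyThresholds
#'   See slots.
#' @param penaltyModel A \linkS4class{PenaltyModel}.
#' @param scanMinLen,scanMaxLen Scan-time product length bounds.
#' @rdname MetricsConfig-class
#' @export
MetricsConfig <- function(maxMismatch = 3, coverageThreshold = 2000,
                          lengthWindow = c(150, 350),
                          penaltyThresholds = seq(0, 15000, by = 500),
                          penaltyModel = PenaltyModel(),
                          scanMinLen = 50, scanMaxLen = 1000) {
  new("MetricsConfig", maxMismatch = as.integer(maxMismatch),
      coverageThreshold = coverageThreshold,
      lengthWindow = as.numeric(lengthWindow),
      penaltyThresholds = as.numeric(penaltyThresholds),
      penaltyModel = penaltyModel,
      scanMinLen = as.integer(scanMinLen),
      scanMaxLen = as.integer(scanMaxLen))
}

#' SimConfig: tank read-simulation parameters
#'
#' The defaults emulate the tank experiment: 3 replicate water samples
#' per tank, an expected 500,000 reads per sample, paired-end 2 x 250 bp
#' reads, and a fish-free negative control. Replicate-level biological
#' noise is lognormal on the eDNA template weights; sequencing error is
#' an i.i.d. per-base substitution process with Phred qualities
#' consistent with the error rate.
#'
#' @slot seed Master seed; a fixed seed makes all outputs byte-identical.
#' @slot replicatesPerTank Water samples per tank (default 3).
#' @slot totalReadsPerSample Multinomial read total per sample
#'   (default 500000).
#' @slot lognormalSigma sdlog of the replicate-level lognormal noise on
#'   species template weights (default 0.3).
#' @slot errorRate Per-base substitution probability (default 0.005).
#' @slot readLength Mate length in bp; 250 (HiSeq 2x250) or
#'   150 (NovaSeq 2x150).
#' @slot lognormalMeanlog,lognormalSdlog Parameters of the lognormal
#'   used for skewed abundance draws (defaults 1.6 and 0.8, giving
#'   counts on the scale of the skewed tank designs).
#' @export
setClass("SimConfig",
  representation(seed = "integer", replicatesPerTank = "integer",
                 totalReadsPerSample = "integer",
                 lognormalSigma = "numeric", errorRate = "numeric",
                 readLength = "integer", lognormalMeanlog = "numeric",
                 lognormalSdlog = "numeric"),
  prototype(seed = 1L, replicatesPerTank = 3L,
            totalReadsPerSample = 500000L, lognormalSigma = 0.3,
            errorRate = 0.005, readLength = 250L,
            lognormalMeanlog = 1.6, lognormalSdlog = 0.8))

setValidity("SimConfig", function(object) {
  msg <- character(0)
  if (object@replicatesPerTank < 1L)
    msg <- c(msg, "replicatesPerTank must be >= 1")
  if (object@totalReadsPerSample < 1L)
    msg <- c(msg, "totalReadsPerSample must be >= 1")
  if (object@lognormalSigma < 0) msg <- c(msg, "lognormalSigma must be >= 0")
  if (object@errorRate < 0 || object@errorRate >= 1)
    msg <- c(msg, "errorRate must be in [0, 1)")
  if (!object@readLength %in% c(150L, 250L))
    msg <- c(msg, "readLength must be 150 or 250")
  if (object@lognormalSdlog <= 0)
    msg <- c(msg, "lognormalSdlog must be > 0")
  if (length(msg)) msg else TRUE
})

#' @param seed,replicatesPerTank,totalReadsPerSample,lognormalSigma
#'   See slots.
#' @param errorRate,readLength,lognormalMeanlog,lognormalSdlog See slots.
#' @rdname SimConfig-class
#' @export
SimConfig <- function(seed = 1, replicatesPerTank = 3,
                      totalReadsPerSample = 500000,
                      lognormalSigma = 0.3, errorRate = 0.005,
                      readLength = 250, lognormalMeanlog = 1.6,
                      lognormalSdlog = 0.8) {
  new("SimConfig", seed = as.integer(seed),
      replicatesPerTank = as.integer(replicatesPerTank),
      totalReadsPerSample = as.integer(totalReadsPerSample),
      lognormalSigma = lognormalSigma, errorRate = errorRate,
      readLength = as.integer(readLength),
      lognormalMeanlog = lognormalMeanlog,
      lognormalSdlog = lognormalSdlog)
}
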