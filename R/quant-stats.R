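## Statistical layer: log10 mixed-effects regressions of standardized
## read counts on biomass/abundance at three design levels, a
## permutation (White-style) t-test between primer pairs, and the
## log10 relative-abundance matrix behind the heatmap.

#' Pseudocount policy for log10 transforms
#'
#' Read counts are log10-transformed before model fitting. Real tank
#' data never contained zeros, but synthetic stress tests can; the
#' default policy adds 1 to zero cells only, \code{"all"} adds the
#' pseudocount everywhere, and \code{"error"} refuses zeros.
#'
#' @param x Numeric vector/matrix of counts.
#' @param policy \code{"zeros"}, \code{"all"} or \code{"error"}.
#' @param pc Pseudocount (default 1).
#' @return \code{x} with the policy applied (NOT yet log-transformed).
#' @export
applyPseudocount <- function(x, policy = c("zeros", "all", "error"),
                             pc = 1) {
  policy <- match.arg(policy)
  if (policy == "error" && any(x <= 0))
    stop("non-positive read counts and pseudocount policy is 'error'")
  if (policy == "all") x + pc
  else if (policy == "zeros") ifelse(x <= 0, x + pc, x)
  else x
}

#' Build the long-format quantification dataset
#'
#' Joins a (standardized) species x sample table with a tank design
#' table into one record per (tank, replicate, species, primer):
#' reads, biomass and abundance. With the full tank layout this gives
#' the pooled design of 6 species x 4 tanks x 3 replicates = 72 records
#' per primer.
#'
#' @param table A \linkS4class{SpeciesSampleTable} (the
#'   \code{"unassigned"} row, if present, is dropped).
#' @param design data.frame with \code{tank}, \code{species},
#'   \code{abundance}, \code{biomass_g}.
#' @return data.frame with columns \code{tank}, \code{replicate},
#'   \code{species}, \code{primer}, \code{reads}, \code{biomass},
#'   \code{abundance}.
#' @export
makeQuantDataset <- function(table, design = tankDesigns()) {
  counts <- speciesCounts(table)
  counts <- counts[setdiff(rownames(counts), "unassigned"), ,
                   drop = FALSE]
  cd <- colData(table)
  long <- expand.grid(species = rownames(counts),
                      col = seq_len(ncol(counts)),
                      stringsAsFactors = FALSE)
  out <- data.frame(
    tank = cd$tank[long$col],
    replicate = cd$replicate[long$col],
    species = long$species,
    primer = cd$primer[long$col],
    reads = counts[cbind(match(long$species, rownames(counts)),
                         long$col)],
    stringsAsFactors = FALSE)
  key <- paste(out$tank, out$species)
  dkey <- paste(design$tank, design$species)
  idx <- match(key, dkey)
  out$biomass <- design$biomass_g[idx]
  out$abundance <- design$abundance[idx]
  out[complete.cases(out[, c("biomass", "abundance")]), , drop = FALSE]
}

#' Linear mixed-effects regression of log10 reads on biomass/abundance
#'
#' Fits \code{log10(reads) ~ covariate + (1 | group)} by REML, with the
#' random intercept chosen by design level: species for the pooled and
#' per-tank levels, tank for the species-specific level. The slope
#' p-value comes from a likelihood-ratio test of the ML fit against the
#' slope-free model (implementation-independent; may differ slightly
#' from a Satterthwaite t-test). Both r-squared flavours are returned:
#' the squared correlation of fitted and observed values (used when
#' comparing with published fits) and the marginal R2 (fixed-effect
#' variance over total variance). Singular (boundary) fits are flagged,
#' not dropped.
#'
#' @param data Long-format data from \code{\link{makeQuantDataset}}
#'   (one primer; subset first or pass \code{primer}).
#' @param covariate \code{"biomass"} or \code{"abundance"}.
#' @param level \code{"pooled"}, \code{"species:<name>"} or
#'   \code{"tank:<id>"}.
#' @param primer Optional primer name to subset \code{data}.
#' @param pseudocountPolicy,pseudocount Zero-handling before log10.
#' @return A \linkS4class{RegressionResult}.
#' @export
fitLme <- function(data, covariate = c("biomass", "abundance"),
                   level = "pooled", primer = NULL,
                   pseudocountPolicy = "zeros", pseudocount = 1) {
  covariate <- match.arg(covariate)
  if (!is.null(primer)) data <- data[data$primer == primer, , drop = FALSE]
  if (identical(level, "pooled")) {
    group <- "species"
  } else if (startsWith(level, "species:")) {
    data <- data[data$species == sub("^species:", "", level), ,
                 drop = FALSE]
    group <- "tank"
  } else if (startsWith(level, "tank:")) {
    data <- data[data$tank == sub("^tank:", "", level), , drop = FALSE]
    group <- "species"
  } else stop("level must be 'pooled', 'species:<name>' or 'tank:<id>'")
  if (length(unique(data[[group]])) < 3L)
    stop("need >= 3 grouping units (", group, ") for the random intercept")
  y <- log10(applyPseudocount(data$reads, pseudocountPolicy, pseudocount))
  if (any(!is.finite(y)))
    stop("non-positive responses remain; choose a pseudocount policy")
  df <- data.frame(y = y, x = data[[covariate]], g = data[[group]])
  fml <- y ~ x + (1 | g)
  fit <- suppressMessages(lme4::lmer(fml, data = df, REML = TRUE))
  ml1 <- suppressMessages(lme4::lmer(fml, data = df, REML = FALSE))
  ml0 <- suppressMessages(lme4::lmer(y ~ 1 + (1 | g), data = df,
                                     REML = FALSE))
  lrt <- 2 * (as.numeric(logLik(ml1)) - as.numeric(logLik(ml0)))
  p <- pchisq(max(lrt, 0), df = 1, lower.tail = FALSE)
  fe <- lme4::fixef(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_g <- vc$vcov[vc$grp == "g"]
  var_r <- vc$vcov[vc$grp == "Residual"]
  var_f <- var(fe[["x"]] * df$x)
  new("RegressionResult",
      primer = if (!is.null(primer)) primer else
        if (length(unique(data$primer))) as.character(data$primer[1])
        else NA_character_,
      level = level, covariate = covariate,
      slope = unname(fe[["x"]]), intercept = unname(fe[["(Intercept)"]]),
      slopeP = p,
      r2Corr = cor(fitted(fit), df$y)^2,
      r2Marginal = var_f / (var_f + var_g + var_r),
      ranefVariance = var_g, residVariance = var_r,
      n = nrow(df), singular = lme4::isSingular(fit))
}

#' Wald confidence interval for the fitted slope
#'
#' @param data,covariate,level,primer,pseudocountPolicy,pseudocount As
#'   in \code{\link{fitLme}}.
#' @param levelCI Confidence level (default 0.95).
#' @return Numeric \code{c(lower, upper)}.
#' @export
slopeCI <- function(data, covariate = "biomass", level = "pooled",
                    primer = NULL, levelCI = 0.95,
                    pseudocountPolicy = "zeros", pseudocount = 1) {
  covariate <- match.arg(covariate, c("biomass", "abundance"))
  if (!is.null(primer)) data <- data[data$primer == primer, , drop = FALSE]
  if (identical(level, "pooled")) group <- "species"
  else if (startsWith(level, "species:")) {
    data <- data[data$species == sub("^species:", "", level), ,
                 drop = FALSE]; group <- "tank"
  } else {
    data <- data[data$tank == sub("^tank:", "", level), , drop = FALSE]
    group <- "species"
  }
  y <- log10(applyPseudocount(data$reads, pseudocountPolicy, pseudocount))
  df <- data.frame(y = y, x = data[[covariate]], g = data[[group]])
  fit <- suppressMessages(lme4::lmer(y ~ x + (1 | g), data = df,
                                     REML = TRUE))
  est <- lme4::fixef(fit)[["x"]]
  se <- unname(sqrt(diag(as.matrix(stats::vcov(fit))))[2])
  z <- qnorm(1 - (1 - levelCI) / 2)
  c(lower = est - z * se, upper = est + z * se)
}

#' Permutation t-test for species-level read differences between primers
#'
#' Two-sided non-parametric test of the difference in mean replicate
#' counts between two groups (typically the same species under two
#' primer pairs): the observed Welch-studentized difference in means is
#' compared to its permutation distribution over group-label
#' reshuffles, exhaustive when the number of distinct reshuffles does
#' not exceed \code{permutations}, randomly sampled otherwise.
#' \code{p = (1 + #\{|t*| >= |t|\}) / (1 + B)}.
#'
#' @param countsA,countsB Replicate count vectors (>= 2 each).
#' @param permutations Maximum permutations (default 1000).
#' @param seed Optional seed for the sampled case.
#' @return List: \code{meanDiff} (A - B), \code{statistic}, \code{p},
#'   \code{permutations} used, \code{exhaustive}.
#' @export
whitesTTest <- function(countsA, countsB, permutations = 1000,
                        seed = NULL) {
  stopifnot(length(countsA) >= 2, length(countsB) >= 2)
  if (!is.null(seed)) set.seed(seed)
  tstat <- function(a, b) {
    se <- sqrt(var(a) / length(a) + var(b) / length(b))
    d <- mean(a) - mean(b)
    if (se == 0) {
      if (d == 0) 0 else sign(d) * Inf
    } else d / se
  }
  obs <- tstat(countsA, countsB)
  if (obs == 0 && var(countsA) == 0 && var(countsB) == 0) {
    return(list(meanDiff = 0, statistic = 0, p = 1,
                permutations = 0L, exhaustive = TRUE))
  }
  pool <- c(countsA, countsB)
  na <- length(countsA); n <- length(pool)
  ncomb <- choose(n, na)
  if (ncomb <= permutations) {
    idx <- combn(n, na)
    perm <- apply(idx, 2L, function(i) tstat(pool[i], pool[-i]))
    B <- ncomb
  } else {
    perm <- replicate(permutations, {
      i <- sample.int(n, na)
      tstat(pool[i], pool[-i])
    })
    B <- permutations
  }
  p <- (1 + sum(abs(perm) >= abs(obs))) / (1 + B)
  list(meanDiff = mean(countsA) - mean(countsB), statistic = obs,
       p = min(p, 1), permutations = as.integer(B),
       exhaustive = ncomb <= permutations)
}

#' log10 relative-abundance matrix for heatmap export
#'
#' Cell = log10 of the mean standardized reads over the replicate
#' samples of each (tank, primer), with the pseudocount policy applied
#' before the log. Missing replicates are averaged over what is
#' available, with a warning.
#'
#' @param table A \linkS4class{SpeciesSampleTable} (rarefied;
#'   \code{"unassigned"} dropped).
#' @param expectedReplicates Replicates expected per (tank, primer)
#'   (default 3).
#' @param pseudocountPolicy,pseudocount Zero handling.
#' @return Species x (tank.primer) numeric matrix.
#' @export
relativeAbundanceMatrix <- function(table, expectedReplicates = 3,
                                    pseudocountPolicy = "zeros",
                                    pseudocount = 1) {
  counts <- speciesCounts(table)
  counts <- counts[setdiff(rownames(counts), "unassigned"), ,
                   drop = FALSE]
  cd <- colData(table)
  grp <- paste(cd$tank, cd$primer, sep = ".")
  ug <- unique(grp)
  short <- 0L
  out <- vapply(ug, function(g) {
    cols <- which(grp == g)
    if (length(cols) < expectedReplicates) short <<- short + 1L
    rowMeans(counts[, cols, drop = FALSE])
  }, numeric(nrow(counts)))
  if (short > 0L)
    warning(short, " (tank, primer) group(s) had fewer than ",
            expectedReplicates, " replicates")
  out <- matrix(out, nrow = nrow(counts),
                dimnames = list(rownames(counts), ug))
  log10(applyPseudocount(out, pseudocountPolicy, pseudocount))
}

#' Tabulate regression results
#'
#' @param results List of \linkS4class{RegressionResult} objects.
#' @return data.frame with one row per fit and a stable column order:
#'   primer, level, covariate, slope, intercept, p, r2_corr,
#'   r2_marginal, ranef_var, resid_var, n, singular.
#' @export
regressionReport <- function(results) {
  cols <- c("primer", "level", "covariate", "slope", "intercept", "p",
            "r2_corr", "r2_marginal", "ranef_var", "resid_var", "n",
            "singular")
  if (!length(results)) {
    out <- as.data.frame(setNames(rep(list(logical(0)), length(cols)),
                                  cols))
    return(out)
  }
  out <- do.call(rbind, lapply(results, function(r)
    data.frame(primer = r@primer, level = r@level,
               covariate = r@covariate, slope = r@slope,
               intercept = r@intercept, p = r@slopeP,
               r2_corr = r@r2Corr, r2_marginal = r@r2Marginal,
               ranef_var = r@ranefVariance, resid_var = r@residVariance,
               n = r@n, singular = r@singular,
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
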