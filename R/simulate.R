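#' Scenario configurations for the synthetic generator
#'
#' Builds a [ScenarioConfig-class] with per-scenario defaults. The
#' generator emulates a resequenced region dominated by rare variation:
#' sites are independent (no linkage disequilibrium), genotypes are
#' binomial(2, maf) under Hardy-Weinberg equilibrium, rare-site MAFs are
#' drawn log-uniformly (skewed toward the lower bound, mimicking the
#' rare-heavy site-frequency spectra produced by purifying selection) and
#' disease status follows a logistic model on the causal minor-allele
#' burden, sampled retrospectively to fixed case/control counts.
#'
#' Scenario defaults (per-minor-allele log odds ratios):
#' * `risk_rare`: half of the rare sites causal at log(5); common neutral.
#' * `risk_both`: rare causal at log(3), half of the common sites at
#'   log(1.3).
#' * `risk_common`: common causal at log(2), rare at log(1.2).
#' * `mixed_rare`: as `risk_rare` but half of the causal rare sites are
#'   protective (sign flipped).
#' * `null`: no effects; phenotype independent of genotype.
#'
#' @param name scenario name.
#' @param nCases,nControls retrospective sample sizes (defaults 500/500,
#'   the equal-group setting assumed by the case-control pair
#'   decompositions of SKAT and MDMR).
#' @param nVariants sites per region (default 50).
#' @param rareFraction expected fraction of rare sites (default 0.8).
#' @param rareThreshold MAF boundary for "rare" (default 0.01).
#' @param mafRangeRare,mafRangeCommon MAF ranges of the two site classes.
#' @param causalFractionRare,causalFractionCommon fraction of each class
#'   carrying an effect (scenario-dependent defaults).
#' @param rareEffect,commonEffect per-allele log odds ratios
#'   (scenario-dependent defaults).
#' @param protectiveFraction fraction of causal rare sites made
#'   protective (`mixed_rare` only; default 0.5).
#' @param baselinePrevalence disease probability at zero causal burden
#'   (default 0.1).
#' @param seed base seed for the scenario.
#' @return A [ScenarioConfig-class].
#' @examples
#' scenarioConfig("risk_rare", seed = 1)
#' @export
scenarioConfig <- function(name = c("null", "risk_rare", "risk_both",
                                    "risk_common", "mixed_rare"),
                           nCases = 500L, nControls = 500L,
                           nVariants = 50L, rareFraction = 0.8,
                           rareThreshold = 0.01,
                           mafRangeRare = c(5e-4, 0.01),
                           mafRangeCommon = c(0.01, 0.5),
                           causalFractionRare = NULL,
                           causalFractionCommon = NULL,
                           rareEffect = NULL, commonEffect = NULL,
                           protectiveFraction = NULL,
                           baselinePrevalence = 0.1, seed = 1L) {
  name <- match.arg(name)
  def <- switch(name,
    null        = list(cfr = 0.0, cfc = 0.0, re = 0,      ce = 0,
                       pf = 0),
    risk_rare   = list(cfr = 0.5, cfc = 0.0, re = log(5), ce = 0,
                       pf = 0),
    risk_both   = list(cfr = 0.5, cfc = 0.5, re = log(3), ce = log(1.3),
                       pf = 0),
    risk_common = list(cfr = 0.5, cfc = 0.5, re = log(1.2), ce = log(2),
                       pf = 0),
    mixed_rare  = list(cfr = 0.5, cfc = 0.0, re = log(5), ce = 0,
                       pf = 0.5))
  new("ScenarioConfig", name = name, nCases = as.integer(nCases),
      nControls = as.integer(nControls), nVariants = as.integer(nVariants),
      rareFraction = rareFraction, rareThreshold = rareThreshold,
      mafRangeRare = mafRangeRare, mafRangeCommon = mafRangeCommon,
      causalFractionRare = if (is.null(causalFractionRare)) def$cfr
                           else causalFractionRare,
      causalFractionCommon = if (is.null(causalFractionCommon)) def$cfc
                             else causalFractionCommon,
      rareEffect = if (is.null(rareEffect)) def$re else rareEffect,
      commonEffect = if (is.null(commonEffect)) def$ce else commonEffect,
      protectiveFraction = if (is.null(protectiveFraction)) def$pf
                           else protectiveFraction,
      baselinePrevalence = baselinePrevalence, seed = as.integer(seed))
}

# deterministic per-replicate seed derived from (base seed, replicate id),
# kept inside 32-bit integer range
.replicateSeed <- function(seed, replicateId) {
  as.integer((as.double(seed) * 48271 + as.double(replicateId) * 16807) %%
             2147483647)
}

#' Sample a rare-variant-dominated MAF spectrum
#'
#' Each site is independently rare with probability
#' `config@rareFraction`; rare MAFs are drawn log-uniformly on
#' `mafRangeRare` (density proportional to 1/maf, the rare-skewed shape of
#' neutral-to-deleterious site-frequency spectra), common MAFs uniformly
#' on `mafRangeCommon`.
#'
#' @param L number of sites.
#' @param config a [ScenarioConfig-class].
#' @param seed RNG seed (deterministic spectrum given the seed).
#' @return Numeric vector of L population MAFs.
#' @export
sampleMafSpectrum <- function(L, config, seed = config@seed) {
  stopifnot(L >= 1L)
  set.seed(as.integer(seed))
  rare <- stats::runif(L) < config@rareFraction
  maf <- numeric(L)
  lo <- config@mafRangeRare[1]
  hi <- config@mafRangeRare[2]
  maf[rare] <- exp(stats::runif(sum(rare), log(lo), log(hi)))
  maf[!rare] <- stats::runif(sum(!rare), config@mafRangeCommon[1],
                             config@mafRangeCommon[2])
  maf
}

# per-variant log odds ratios and causal labels for a drawn spectrum
.effectVector <- function(config, maf, seed) {
  set.seed(as.integer(seed) %% 2147483647L)
  L <- length(maf)
  beta <- numeric(L)
  flags <- rep("neutral", L)
  rare <- maf <= config@rareThreshold
  pickCausal <- function(idx, frac) {
    n <- round(length(idx) * frac)
    if (n < 1L) integer(0) else sample(idx, n)
  }
  cr <- pickCausal(which(rare), config@causalFractionRare)
  cc <- pickCausal(which(!rare), config@causalFractionCommon)
  beta[cr] <- config@rareEffect
  beta[cc] <- config@commonEffect
  flags[c(cr, cc)] <- "risk"
  if (config@protectiveFraction > 0 && length(cr)) {
    npro <- round(length(cr) * config@protectiveFraction)
    if (npro >= 1L) {
      pro <- sample(cr, npro)
      beta[pro] <- -beta[pro]
      flags[pro] <- "protective"
    }
  }
  flags[beta == 0] <- "neutral"
  list(beta = beta, flags = flags)
}

#' Generate one synthetic case-control replicate
#'
#' Draws genotypes binomial(2, maf) per site under Hardy-Weinberg
#' equilibrium, assigns disease status from the logistic model
#' `logit P(case) = logit(baselinePrevalence) + sum_l beta_l g_l`, and
#' samples retrospectively (drawing population batches) until the
#' configured numbers of cases and controls are reached. Bit-reproducible
#' given `(config, config@seed, replicateId)`.
#'
#' @param config a [ScenarioConfig-class].
#' @param replicateId replicate number (default 1); distinct replicates
#'   use distinct derived seeds.
#' @param maxDraws cap on the number of individuals sampled before a
#'   sampling-limit error is raised (guards degenerate penetrance
#'   settings).
#' @return A [Replicate-class] with cases first, then controls.
#' @examples
#' rep1 <- generateReplicate(scenarioConfig("null", nCases = 20,
#'                                          nControls = 20, seed = 3))
#' table(phenotypeValues(phenotype(rep1)))
#' @export
generateReplicate <- function(config, replicateId = 1L,
                              maxDraws = 500000L) {
  stopifnot(is(config, "ScenarioConfig"))
  rseed <- .replicateSeed(config@seed, replicateId)
  maf <- sampleMafSpectrum(config@nVariants, config, seed = rseed)
  eff <- .effectVector(config, maf, seed = rseed + 1L)
  set.seed((rseed + 2L) %% 2147483647L)
  L <- config@nVariants
  b0 <- stats::qlogis(config@baselinePrevalence)
  nCa <- config@nCases
  nCo <- config@nControls
  caseRows <- matrix(0, 0, L)
  ctrlRows <- matrix(0, 0, L)
  drawn <- 0L
  batch <- max(2L * (nCa + nCo), 1000L)
  while ((nrow(caseRows) < nCa || nrow(ctrlRows) < nCo) &&
         drawn < maxDraws) {
    Gb <- matrix(stats::rbinom(batch * L, 2L, rep(maf, each = batch)),
                 nrow = batch)
    pr <- stats::plogis(b0 + drop(Gb %*% eff$beta))
    st <- stats::rbinom(batch, 1L, pr)
    drawn <- drawn + batch
    if (nrow(caseRows) < nCa)
      caseRows <- rbind(caseRows,
                        Gb[st == 1L, , drop = FALSE][
                          seq_len(min(sum(st == 1L),
                                      nCa - nrow(caseRows))), ,
                          drop = FALSE])
    if (nrow(ctrlRows) < nCo)
      ctrlRows <- rbind(ctrlRows,
                        Gb[st == 0L, , drop = FALSE][
                          seq_len(min(sum(st == 0L),
                                      nCo - nrow(ctrlRows))), ,
                          drop = FALSE])
  }
  if (nrow(caseRows) < nCa || nrow(ctrlRows) < nCo)
    stop(sprintf(
      "sampling limit reached after %d draws (%d cases, %d controls found): penetrance settings are degenerate",
      drawn, nrow(caseRows), nrow(ctrlRows)))
  G <- rbind(caseRows, ctrlRows)
  rownames(G) <- c(paste0("case", seq_len(nCa)),
                   paste0("ctrl", seq_len(nCo)))
  colnames(G) <- paste0("v", seq_len(L))
  y <- c(rep(1, nCa), rep(-1, nCo))
  gm <- GenotypeMatrix(G)
  new("Replicate", genotypes = gm,
      phenotype = phenotypeVector(y, "plus_minus_one"),
      causalFlags = eff$flags, replicateId = as.integer(replicateId),
      seed = rseed)
}

#' Replicate accessors
#'
#' @param x a [Replicate-class].
#' @return `genotypes`: the [GenotypeMatrix-class]; `phenotype`: the
#'   [PhenotypeVector-class]; `causalFlags`: per-variant causal labels.
#' @name replicate-accessors
NULL

#' @rdname replicate-accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname replicate-accessors
#' @export
setMethod("genotypes", "Replicate", function(x) x@genotypes)

#' @rdname replicate-accessors
#' @export
setGeneric("phenotype", function(x) standardGeneric("phenotype"))

#' @rdname replicate-accessors
#' @export
setMethod("phenotype", "Replicate", function(x) x@phenotype)

#' @rdname replicate-accessors
#' @export
setGeneric("causalFlags", function(x) standardGeneric("causalFlags"))

#' @rdname replicate-accessors
#' @export
setMethod("causalFlags", "Replicate", function(x) x@causalFlags)
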