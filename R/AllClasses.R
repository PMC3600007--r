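#' @import methods
NULL

#' GenotypeMatrix: minor-allele count matrix with per-variant MAF
#'
#' Container for an N x L matrix of minor-allele counts for N individuals at
#' L variant sites, together with the per-variant minor allele frequency
#' (MAF). Raw genotypes are coded 0/1/2 copies of the minor allele; after
#' mean imputation of missing calls or principal-component adjustment
#' (see [projectOut()]) entries may be real-valued, which the `adjusted`
#' flag records.
#'
#' @slot counts numeric matrix, individuals in rows, variants in columns.
#'   Column names are the variant identifiers, row names the sample
#'   identifiers.
#' @slot maf numeric vector of length `ncol(counts)`, each value in
#'   \[0, 0.5\]: the frequency of the minor allele, `sum(counts[, l]) / (2N)`
#'   after minor-allele orientation.
#' @slot adjusted logical scalar; `TRUE` once entries are no longer raw
#'   0/1/2 codes (imputed or stratification-adjusted).
#'
#' @seealso [GenotypeMatrix()] for the validating constructor,
#'   [readGenotypes()] to build one from a VCF or delimited matrix file.
#' @export
setClass("GenotypeMatrix",
  representation(counts = "matrix", maf = "numeric", adjusted = "logical"),
  prototype(counts = matrix(numeric(0), 0, 0), maf = numeric(0),
            adjusted = FALSE))

setValidity("GenotypeMatrix", function(object) {
  msg <- character(0)
  cts <- object@counts
  if (!is.numeric(cts))
    msg <- c(msg, "counts must be a numeric matrix")
  if (length(object@maf) != ncol(cts))
    msg <- c(msg, "maf must have one entry per variant column")
  if (length(object@maf) && (any(!is.finite(object@maf)) ||
      any(object@maf < 0) || any(object@maf > 0.5 + 1e-12)))
    msg <- c(msg, "maf values must lie in [0, 0.5]")
  if (length(object@adjusted) != 1L)
    msg <- c(msg, "adjusted must be a logical scalar")
  if (length(cts) && any(!is.finite(cts)))
    msg <- c(msg, "counts must be finite (impute missing genotypes first)")
  if (isFALSE(object@adjusted) && length(cts) &&
      !all(cts %in% c(0, 1, 2)))
    msg <- c(msg, "raw genotype entries must be in {0, 1, 2}")
  if (length(msg)) msg else TRUE
})

#' PhenotypeVector: case/control or quantitative phenotype
#'
#' Length-N phenotype with an explicit coding. Binary phenotypes are held
#' either as +1 (case) / -1 (control) or 1 (case) / 0 (control); the
#' similarity-based test statistics each expect a particular coding and
#' convert automatically via [recodePhenotype()].
#'
#' @slot values numeric vector of length N.
#' @slot coding one of `"plus_minus_one"`, `"zero_one"`, `"quantitative"`.
#' @export
setClass("PhenotypeVector",
  representation(values = "numeric", coding = "character"),
  prototype(values = numeric(0), coding = "quantitative"))

setValidity("PhenotypeVector", function(object) {
  msg <- character(0)
  cod <- object@coding
  if (length(cod) != 1L ||
      !cod %in% c("plus_minus_one", "zero_one", "quantitative"))
    return("coding must be one of plus_minus_one, zero_one, quantitative")
  v <- object@values
  if (any(!is.finite(v)))
    msg <- c(msg, "phenotype values must be finite")
  if (cod == "plus_minus_one" && length(v) && !all(v %in% c(-1, 1)))
    msg <- c(msg, "plus_minus_one coding requires values in {1, -1}")
  if (cod == "zero_one" && length(v) && !all(v %in% c(0, 1)))
    msg <- c(msg, "zero_one coding requires values in {1, 0}")
  if (length(msg)) msg else TRUE
})

#' SimilarityMatrix: N x N genotype similarity kernel matrix
#'
#' Symmetric positive-semi-definite matrix K with entries s(g_n, g_m) for a
#' similarity kernel s evaluated between the multi-site genotypes of every
#' pair of individuals.
#'
#' @slot values symmetric numeric N x N matrix.
#' @slot kernel kernel name: `"exponential"`, `"ibs"`, `"linear"` or
#'   `"quadratic"`.
#' @slot weighted logical; whether per-variant weights entered the kernel.
#' @export
setClass("SimilarityMatrix",
  representation(values = "matrix", kernel = "character",
                 weighted = "logical"),
  prototype(values = matrix(numeric(0), 0, 0), kernel = "exponential",
            weighted = FALSE))

setValidity("SimilarityMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v))
    return("similarity matrix must be square")
  if (length(v) && max(abs(v - t(v))) > 1e-8 * max(1, max(abs(v))))
    return("similarity matrix must be symmetric")
  TRUE
})

#' PooledGenotype: result of super-locus collapsing
#'
#' Partition of a region into the common-variant block (MAF above the
#' rarity threshold) and a single collapsed pseudo-variant, the
#' super-locus: per individual, `min(2, sum of minor-allele counts over the
#' rare variants)`.
#'
#' @slot common [GenotypeMatrix] of the variants with MAF above `threshold`
#'   (possibly zero columns).
#' @slot superLocus integer-valued length-N vector in \{0, 1, 2\}.
#' @slot threshold rarity threshold on MAF (default 0.01); a variant is
#'   rare iff `maf <= threshold`.
#' @export
setClass("PooledGenotype",
  representation(common = "GenotypeMatrix", superLocus = "numeric",
                 threshold = "numeric"))

setValidity("PooledGenotype", function(object) {
  msg <- character(0)
  if (!all(object@superLocus %in% c(0, 1, 2)))
    msg <- c(msg, "super-locus entries must be in {0, 1, 2}")
  if (length(object@threshold) != 1L || object@threshold <= 0 ||
      object@threshold >= 0.5)
    msg <- c(msg, "threshold must be a single value in (0, 0.5)")
  if (nrow(object@common@counts) &&
      nrow(object@common@counts) != length(object@superLocus))
    msg <- c(msg, "common block and super-locus disagree on N")
  if (length(msg)) msg else TRUE
})

#' TestResult: observed statistic and permutation p-value
#'
#' @slot method one of `"mdmr"`, `"skat"`, `"utest"`, `"kbat"`.
#' @slot statistic observed test statistic.
#' @slot pValue permutation p-value, `(1 + b) / (B + 1)` where b is the
#'   number of permuted statistics at least as large as the observed one;
#'   never smaller than `1/(B + 1)`.
#' @slot nPermutations number of permutations B.
#' @slot seed RNG seed used to generate the permutation stream.
#' @slot settings named list recording pooling, kernel and other options.
#' @export
setClass("TestResult",
  representation(method = "character", statistic = "numeric",
                 pValue = "numeric", nPermutations = "integer",
                 seed = "integer", settings = "list"),
  prototype(settings = list()))

setValidity("TestResult", function(object) {
  msg <- character(0)
  if (!object@method %in% c("mdmr", "skat", "utest", "kbat"))
    msg <- c(msg, "unknown method")
  B <- object@nPermutations
  if (length(object@pValue) == 1L && length(B) == 1L &&
      (object@pValue <= 0 || object@pValue > 1 ||
       object@pValue < 1 / (B + 1) - 1e-12))
    msg <- c(msg, "p-value must lie in [1/(B+1), 1]")
  if (object@method %in% c("utest", "kbat") &&
      length(object@statistic) == 1L && is.finite(object@statistic) &&
      object@statistic < 0)
    msg <- c(msg, "U and KBAT statistics are non-negative by construction")
  if (length(msg)) msg else TRUE
})

#' ScenarioConfig: disease-architecture settings for the synthetic generator
#'
#' Study conditions for one simulated disease scenario. The five scenario
#' names follow the causal architectures compared in the power study:
#' `risk_rare` (risk effects on rare variants only), `risk_both` (moderate
#' rare plus weak common effects), `risk_common` (strong common plus weak
#' rare effects), `mixed_rare` (rare effects of both signs) and `null`
#' (no genotype effect).
#'
#' @slot name scenario name.
#' @slot nCases,nControls retrospective sample sizes (defaults 500/500).
#' @slot nVariants number of variant sites per region (default 50).
#' @slot rareFraction expected fraction of sites with population MAF at or
#'   below `rareThreshold` (default 0.8).
#' @slot rareThreshold rarity boundary on MAF (default 0.01).
#' @slot mafRangeRare,mafRangeCommon MAF ranges for the two site classes;
#'   rare MAFs are drawn log-uniformly (skewed toward the lower bound, as
#'   in site-frequency spectra of purifying selection), common MAFs
#'   uniformly.
#' @slot causalFractionRare,causalFractionCommon fraction of sites of each
#'   class that carry an effect.
#' @slot rareEffect,commonEffect per-minor-allele log odds ratios for
#'   causal sites of each class.
#' @slot protectiveFraction fraction of causal rare sites whose effect sign
#'   is flipped to protective (`mixed_rare` only).
#' @slot baselinePrevalence disease probability for a genotype with no
#'   causal minor alleles.
#' @slot seed base RNG seed; replicate r uses a stream derived from
#'   (seed, r).
#' @export
setClass("ScenarioConfig",
  representation(name = "character", nCases = "integer",
                 nControls = "integer", nVariants = "integer",
                 rareFraction = "numeric", rareThreshold = "numeric",
                 mafRangeRare = "numeric", mafRangeCommon = "numeric",
                 causalFractionRare = "numeric",
                 causalFractionCommon = "numeric",
                 rareEffect = "numeric", commonEffect = "numeric",
                 protectiveFraction = "numeric",
                 baselinePrevalence = "numeric", seed = "integer"))

setValidity("ScenarioConfig", function(object) {
  msg <- character(0)
  if (!object@name %in% c("risk_rare", "risk_both", "risk_common",
                          "mixed_rare", "null"))
    msg <- c(msg, "unknown scenario name")
  if (object@name == "null" &&
      (object@rareEffect != 0 || object@commonEffect != 0))
    msg <- c(msg, "null scenario must have all effects zero")
  if (object@name == "mixed_rare" &&
      (object@protectiveFraction <= 0 || object@protectiveFraction >= 1))
    msg <- c(msg, "mixed_rare requires protectiveFraction in (0, 1)")
  if (object@name %in% c("risk_rare", "risk_both", "risk_common") &&
      (object@rareEffect < 0 || object@commonEffect < 0))
    msg <- c(msg, "risk scenarios require non-negative effects")
  if (object@nCases < 1L || object@nControls < 1L)
    msg <- c(msg, "need at least one case and one control")
  if (object@rareFraction < 0 || object@rareFraction > 1)
    msg <- c(msg, "rareFraction must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Replicate: one simulated genotype/phenotype data set
#'
#' @slot genotypes [GenotypeMatrix] (monomorphic sites retained; analysis
#'   code drops them).
#' @slot phenotype [PhenotypeVector] in +1/-1 coding.
#' @slot causalFlags per-variant `"risk"`, `"protective"` or `"neutral"`.
#' @slot replicateId,seed identifiers making the replicate reproducible.
#' @export
setClass("Replicate",
  representation(genotypes = "GenotypeMatrix",
                 phenotype = "PhenotypeVector",
                 causalFlags = "character", replicateId = "integer",
                 seed = "integer"))

#' PowerCurve: power as a function of significance level
#'
#' @slot alphas significance-level grid (increasing, in (0, 0.05\]).
#' @slot power estimated power at each alpha: the fraction of replicates
#'   with permutation p-value at or below alpha.
#' @slot method,pooling,scenario labels for the curve.
#' @slot nReplicates number of replicates behind the estimates.
#' @export
setClass("PowerCurve",
  representation(alphas = "numeric", power = "numeric",
                 method = "character", pooling = "character",
                 scenario = "character", nReplicates = "integer"))

setValidity("PowerCurve", function(object) {
  msg <- character(0)
  if (length(object@alphas) != length(object@power))
    msg <- c(msg, "alphas and power must have equal length")
  if (is.unsorted(object@alphas, strictly = TRUE))
    msg <- c(msg, "alphas must be strictly increasing")
  if (length(object@power) &&
      (any(object@power < 0) || any(object@power > 1)))
    msg <- c(msg, "power values must lie in [0, 1]")
  if (is.unsorted(object@power))
    msg <- c(msg, "power must be non-decreasing in alpha")
  if (length(msg)) msg else TRUE
})
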