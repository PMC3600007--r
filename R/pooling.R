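#' Beta-density MAF weights
#'
#' Per-variant weights `w_l = Beta(maf_l; b, c)^2`, the Beta(b, c) density
#' evaluated at the variant's MAF, squared. With the default (b, c) =
#' (1, 25) this is `(25 (1 - maf)^24)^2`: strictly decreasing in MAF, so
#' rare variants are up-weighted while common variants retain small but
#' non-zero weight. Parameters are restricted to `0 <= b <= 1`, `c >= 1`,
#' the range over which the weight increases as MAF decreases.
#'
#' @param maf numeric MAF vector, values in \[0, 0.5\].
#' @param b,c Beta density parameters (defaults 1 and 25).
#' @return Non-negative weight vector of the same length.
#' @examples
#' betaWeights(c(0, 0.01, 0.05, 0.5))
#' @export
betaWeights <- function(maf, b = 1, c = 25) {
  if (any(!is.finite(maf)) || any(maf < 0) || any(maf > 0.5))
    stop("MAF values must lie in [0, 0.5]")
  if (b < 0 || b > 1 || c < 1)
    stop("beta weight parameters must satisfy 0 <= b <= 1 and c >= 1")
  stats::dbeta(maf, shape1 = b, shape2 = c)^2
}

#' Collapse rare variants into a super-locus
#'
#' The burden-style pooling strategy: all variants with MAF at or below
#' `threshold` are summed per individual and capped at two copies,
#' `min(2, sum of rare minor-allele counts)`. The collapsed value is
#' treated as a new pseudo-variant (the super-locus); association tests
#' under collapsing run on the common-variant block plus the super-locus.
#'
#' @param g a [GenotypeMatrix-class].
#' @param threshold rarity boundary on MAF (default 0.01, inclusive).
#' @return A [PooledGenotype-class].
#' @examples
#' g <- GenotypeMatrix(matrix(c(1, 0, 0,  1, 0, 0,  1, 0, 0), nrow = 3))
#' collapseRare(g, threshold = 0.2)
#' @export
collapseRare <- function(g, threshold = 0.01) {
  stopifnot(is(g, "GenotypeMatrix"))
  if (g@adjusted)
    stop("collapsing is defined on raw allele counts, not adjusted genotypes")
  rare <- mafs(g) <= threshold
  if (!any(rare)) {
    warning("no variants at or below the MAF threshold; super-locus is all zero")
    super <- numeric(nrow(genotypeCounts(g)))
  } else {
    super <- pmin(2, rowSums(genotypeCounts(g)[, rare, drop = FALSE]))
  }
  new("PooledGenotype", common = g[, !rare], superLocus = as.numeric(super),
      threshold = threshold)
}

#' Restrict a region to its rare variants
#'
#' Drops every variant with MAF strictly above `threshold` (common
#' variants are those with MAF > 1% at the default).
#'
#' @inheritParams collapseRare
#' @return A [GenotypeMatrix-class] with only the rare variants.
#' @export
excludeCommon <- function(g, threshold = 0.01) {
  stopifnot(is(g, "GenotypeMatrix"))
  keep <- mafs(g) <= threshold
  if (!any(keep))
    stop("empty region: no variants at or below the MAF threshold")
  g[, keep]
}

#' Analysis matrix for a pooled region
#'
#' Internal composition used by [runTest()] and the simulation engine:
#' under `"weighting"` all variants enter with their Beta-density weights;
#' under `"collapsing"` the unweighted kernel is built on the common block
#' plus the super-locus; `"none"` uses all variants unweighted.
#'
#' @return list(X = numeric matrix, weights = numeric or NULL).
#' @noRd
.poolForAnalysis <- function(g, pooling, threshold = 0.01, b = 1, c = 25) {
  switch(pooling,
    weighting = list(X = genotypeCounts(g),
                     weights = betaWeights(mafs(g), b, c)),
    collapsing = {
      pooled <- collapseRare(g, threshold)
      X <- cbind(genotypeCounts(pooled@common),
                 super_locus = pooled@superLocus)
      list(X = X, weights = NULL)
    },
    none = list(X = genotypeCounts(g), weights = NULL),
    stop(sprintf("unknown pooling strategy '%s'", pooling)))
}
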