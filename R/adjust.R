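#' Principal components of a genotype matrix
#'
#' Top-k left singular vectors of the column-standardised genotype matrix.
#' Columns are centered at twice the MAF and scaled by
#' `sqrt(2 maf (1 - maf))` (the binomial standard deviation used by the
#' Eigenstrat convention) before the decomposition; monomorphic columns
#' are skipped. Used to project population structure out of genotypes,
#' phenotypes and covariates.
#'
#' @param g a [GenotypeMatrix-class] or numeric matrix.
#' @param k number of components (default 10). If the standardised matrix
#'   has rank below k the result is truncated with a warning.
#' @return N x k matrix R with orthonormal columns (`R'R = I`).
#' @export
pcaComponents <- function(g, k = 10L) {
  X <- if (is(g, "GenotypeMatrix")) genotypeCounts(g) else as.matrix(g)
  k <- as.integer(k)
  if (k == 0L)
    return(matrix(numeric(0), nrow(X), 0L))
  if (nrow(X) <= k)
    stop("need more individuals than components")
  p <- colMeans(X) / 2
  keep <- p > 0 & p < 1
  X <- X[, keep, drop = FALSE]
  p <- p[keep]
  Xs <- sweep(sweep(X, 2L, 2 * p), 2L, sqrt(2 * p * (1 - p)), `/`)
  sv <- svd(Xs, nu = min(k, min(dim(Xs))), nv = 0)
  tolr <- max(dim(Xs)) * .Machine$double.eps * sv$d[1L]
  rk <- sum(sv$d > tolr)
  if (rk < k) {
    warning(sprintf("rank %d below requested %d components; truncating",
                    rk, k))
    k <- rk
  }
  sv$u[, seq_len(k), drop = FALSE]
}

#' Project the column space of R out of a matrix or vector
#'
#' Returns `x - R R' x`, the residual of x after removing its projection
#' onto the principal-component axes. Idempotent and norm-non-increasing.
#'
#' @param x numeric vector or matrix with N rows.
#' @param R N x k matrix with orthonormal columns from [pcaComponents()].
#' @return Same shape as `x`.
#' @export
projectOut <- function(x, R) {
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1L) else as.matrix(x)
  if (nrow(xm) != nrow(R))
    stop(sprintf("row mismatch: x has %d rows, R has %d",
                 nrow(xm), nrow(R)))
  if (ncol(R) == 0L)
    return(x)
  out <- xm - R %*% crossprod(R, xm)
  if (vec) drop(out) else out
}

#' Regress adjusted covariates out of an adjusted phenotype
#'
#' Ordinary least squares of the phenotype on an intercept plus the
#' covariate columns; returns the residuals. The design matrix must be
#' full rank, otherwise an error names the collinear column.
#'
#' @param pheno numeric length-N phenotype (already PC-adjusted).
#' @param covariates N x p numeric matrix of PC-adjusted covariates.
#' @return Length-N residual vector, orthogonal to the intercept and to
#'   every covariate column.
#' @export
regressOutCovariates <- function(pheno, covariates) {
  covariates <- as.matrix(covariates)
  stopifnot(length(pheno) == nrow(covariates))
  # constant columns alias the intercept and carry no information
  const <- apply(covariates, 2L, function(x) max(x) == min(x))
  covariates <- covariates[, !const, drop = FALSE]
  X <- cbind(`(Intercept)` = 1, covariates)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop(sprintf("rank-deficient design: collinear column(s) %s",
                 paste(aliased, collapse = ", ")))
  }
  as.numeric(qr.resid(qx, as.numeric(pheno)))
}

#' Dichotomize residuals into cases and controls
#'
#' The `ceiling(topFraction * N)` largest residuals become cases, the
#' rest controls. Ties at the cutoff are broken by stable index order
#' (earlier individuals first), with a warning so the arbitrary split is
#' visible.
#'
#' @param residuals numeric vector (finite).
#' @param topFraction fraction declared cases (default 0.30, the upper
#'   30 percent of the observed distribution).
#' @return A [PhenotypeVector-class] in +1/-1 coding.
#' @export
dichotomize <- function(residuals, topFraction = 0.30) {
  stopifnot(all(is.finite(residuals)),
            topFraction > 0, topFraction < 1)
  N <- length(residuals)
  nCase <- ceiling(topFraction * N)
  ord <- order(residuals, decreasing = TRUE)   # stable for ties
  cutoff <- residuals[ord[nCase]]
  if (nCase < N && sum(residuals == cutoff) > 1L &&
      residuals[ord[nCase + 1L]] == cutoff)
    warning("ties at the dichotomization cutoff broken by index order")
  y <- rep(-1, N)
  y[ord[seq_len(nCase)]] <- 1
  phenotypeVector(y, "plus_minus_one")
}

#' Full stratification-and-covariate adjustment pipeline
#'
#' Reproduces the standard exome-workshop adjustment: compute k genotype
#' principal components R; project them out of genotypes, phenotype and
#' covariates (`x - R R' x`); regress the adjusted covariates out of the
#' adjusted phenotype by OLS; dichotomize the residuals so the top
#' `topFraction` are cases.
#'
#' @param g a [GenotypeMatrix-class] (raw counts).
#' @param pheno numeric length-N phenotype (quantitative or binary).
#' @param covariates N x p numeric matrix (e.g. age, sex, smoking).
#' @param k number of principal components (default 10).
#' @param topFraction case fraction for dichotomization (default 0.30).
#' @return List with `genotypes` (adjusted, real-valued
#'   [GenotypeMatrix-class]), `phenotype` (dichotomized
#'   [PhenotypeVector-class]), `residuals`, and `components` (R).
#' @export
adjustForStratification <- function(g, pheno, covariates, k = 10L,
                                    topFraction = 0.30) {
  stopifnot(is(g, "GenotypeMatrix"))
  R <- pcaComponents(g, k)
  Gadj <- projectOut(genotypeCounts(g), R)
  phAdj <- projectOut(pheno, R)
  covAdj <- projectOut(as.matrix(covariates), R)
  res <- regressOutCovariates(phAdj, covAdj)
  gAdj <- GenotypeMatrix(Gadj, variantIds = variantIds(g),
                         adjusted = TRUE, maf = mafs(g))
  list(genotypes = gAdj, phenotype = dichotomize(res, topFraction),
       residuals = res, components = R)
}
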