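#' Genotype similarity kernels
#'
#' Pairwise similarity functions between two multi-site genotype vectors.
#' The exponential (Gaussian) kernel is the package default: it is a
#' function of the Euclidean distance between genotypes and therefore
#' remains meaningful for real-valued, stratification-adjusted genotypes.
#' The identity-by-state (IBS) kernel is defined on genotype codes only
#' and rejects non-integer input.
#'
#' * `exponentialKernel(gn, gm)` = `exp(-sum_l (g_nl - g_ml)^2)`
#' * `weightedExponentialKernel(gn, gm, w)` =
#'   `exp(-sum_l w_l (g_nl - g_ml)^2 / sum_l w_l)`
#' * `weightedIbsKernel(gn, gm, w)` = `sum_l w_l (2 - |g_nl - g_ml|)`
#' * `linearKernel(gn, gm, w)` = `sum_l w_l g_nl g_ml`
#' * `quadraticKernel(gn, gm, w)` = `(1 + sum_l w_l g_nl g_ml)^2`
#'
#' @param gn,gm numeric genotype vectors of equal length L.
#' @param w non-negative weights of length L (default: all 1).
#' @return A single numeric similarity value; exponential kernels lie in
#'   (0, 1\] with value 1 iff the genotypes coincide.
#' @name kernels
NULL

.checkPair <- function(gn, gm) {
  if (length(gn) != length(gm))
    stop(sprintf("genotype length mismatch: %d vs %d",
                 length(gn), length(gm)))
  if (length(gn) < 1L)
    stop("genotype vectors must have length >= 1")
}

#' @rdname kernels
#' @export
exponentialKernel <- function(gn, gm) {
  .checkPair(gn, gm)
  exp(-sum((gn - gm)^2))
}

#' @rdname kernels
#' @export
weightedExponentialKernel <- function(gn, gm, w) {
  .checkPair(gn, gm)
  .checkWeights(w, length(gn))
  exp(-sum(w * (gn - gm)^2) / sum(w))
}

#' @rdname kernels
#' @export
weightedIbsKernel <- function(gn, gm, w = rep(1, length(gn))) {
  .checkPair(gn, gm)
  .checkWeights(w, length(gn), allowZeroSum = TRUE)
  if (!all(c(gn, gm) %in% c(0, 1, 2)))
    stop("the IBS kernel is defined on genotype codes {0,1,2} only")
  sum(w * (2 - abs(gn - gm)))
}

#' @rdname kernels
#' @export
linearKernel <- function(gn, gm, w = rep(1, length(gn))) {
  .checkPair(gn, gm)
  .checkWeights(w, length(gn), allowZeroSum = TRUE)
  sum(w * gn * gm)
}

#' @rdname kernels
#' @export
quadraticKernel <- function(gn, gm, w = rep(1, length(gn))) {
  (1 + linearKernel(gn, gm, w))^2
}

.checkWeights <- function(w, L, allowZeroSum = FALSE) {
  if (length(w) != L)
    stop(sprintf("weight length mismatch: %d weights for %d variants",
                 length(w), L))
  if (any(w < 0) || any(!is.finite(w)))
    stop("weights must be finite and non-negative")
  if (!allowZeroSum && sum(w) <= 0)
    stop("degenerate weights: sum of weights must be positive")
  invisible(TRUE)
}

.kernelNames <- c("exponential", "ibs", "linear", "quadratic")

# Full-matrix kernel evaluation on an N x L count matrix. The exponential
# kernels go through the squared-distance expansion
#   d2(n, m) = r_n + r_m - 2 S_nm,  S = X diag(w) X',  r = diag(S),
# one crossprod instead of N^2 pair loops.
.kernelMatrix <- function(X, kernel, w = NULL) {
  X <- as.matrix(X)
  N <- nrow(X)
  L <- ncol(X)
  if (L < 1L)
    stop("empty region: no variants to build a similarity matrix from")
  weighted <- !is.null(w)
  if (kernel == "ibs" && !all(X %in% c(0, 1, 2)))
    stop("the IBS kernel is defined on genotype codes {0,1,2} only")
  if (kernel %in% c("exponential")) {
    if (weighted) {
      .checkWeights(w, L)
      Xw <- sweep(X, 2L, sqrt(w / sum(w)), `*`)
    } else {
      Xw <- X
    }
    S <- tcrossprod(Xw)
    r <- diag(S)
    d2 <- pmax(outer(r, r, `+`) - 2 * S, 0)
    K <- exp(-d2)
    diag(K) <- 1
  } else if (kernel %in% c("linear", "quadratic")) {
    if (weighted) .checkWeights(w, L, allowZeroSum = TRUE)
    Xw <- if (weighted) sweep(X, 2L, sqrt(w), `*`) else X
    K <- tcrossprod(Xw)
    if (kernel == "quadratic") K <- (1 + K)^2
  } else if (kernel == "ibs") {
    if (weighted) .checkWeights(w, L, allowZeroSum = TRUE)
    ww <- if (weighted) w else rep(1, L)
    K <- matrix(2 * sum(ww), N, N)
    for (l in seq_len(L)) {
      K <- K - ww[l] * abs(outer(X[, l], X[, l], `-`))
    }
  } else {
    stop(sprintf("unknown kernel '%s'", kernel))
  }
  (K + t(K)) / 2
}

#' Build the N x N similarity matrix for a region
#'
#' Evaluates the chosen kernel between every pair of individuals and
#' checks the result is symmetric positive semi-definite (the smallest
#' eigenvalue may not fall below `-tol` times the largest).
#'
#' @param g a [GenotypeMatrix-class] or numeric count matrix.
#' @param kernel `"exponential"` (default), `"ibs"`, `"linear"` or
#'   `"quadratic"`.
#' @param weights optional per-variant weights, e.g. from [betaWeights()];
#'   supply them iff a weighted kernel is wanted.
#' @param checkPsd run the eigenvalue PSD check (default `TRUE`; the bulk
#'   simulation engine skips it because the exponential kernel is PSD by
#'   construction and an eigendecomposition per replicate would dominate
#'   runtime).
#' @param tol relative eigenvalue tolerance for the PSD check.
#' @return A [SimilarityMatrix-class].
#' @examples
#' g <- GenotypeMatrix(matrix(c(0, 1, 2, 0, 0, 1), nrow = 3))
#' buildSimilarityMatrix(g, "exponential")
#' @export
buildSimilarityMatrix <- function(g, kernel = "exponential",
                                  weights = NULL, checkPsd = TRUE,
                                  tol = 1e-8) {
  kernel <- match.arg(kernel, .kernelNames)
  X <- if (is(g, "GenotypeMatrix")) genotypeCounts(g) else as.matrix(g)
  if (!is.null(weights) && is(g, "GenotypeMatrix") && g@adjusted &&
      kernel == "ibs")
    stop("the IBS kernel cannot be applied to adjusted genotypes")
  K <- .kernelMatrix(X, kernel, weights)
  if (checkPsd) {
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    lmax <- max(abs(ev))
    if (lmax > 0 && min(ev) < -tol * lmax)
      stop(sprintf(
        "kernel matrix is not positive semi-definite (min eigenvalue %.3g of %.3g)",
        min(ev), lmax))
  }
  new("SimilarityMatrix", values = K, kernel = kernel,
      weighted = !is.null(weights))
}

#' Per-variant (single-SNP) similarity matrices
#'
#' One L-element list of N x N similarity matrices, each computed from a
#' single genotype column; consumed by the KBAT statistic, which pools
#' across variants at the statistic level rather than inside the kernel.
#'
#' @inheritParams buildSimilarityMatrix
#' @return List of L [SimilarityMatrix-class] objects.
#' @export
perSnpSimilarity <- function(g, kernel = "exponential", checkPsd = FALSE) {
  kernel <- match.arg(kernel, .kernelNames)
  X <- if (is(g, "GenotypeMatrix")) genotypeCounts(g) else as.matrix(g)
  lapply(seq_len(ncol(X)), function(l)
    buildSimilarityMatrix(X[, l, drop = FALSE], kernel,
                          checkPsd = checkPsd))
}
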