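# Vectorized permutation engine.
#
# All four statistics are linear-algebra functionals of the similarity
# matrix and the (permuted) label vector, so the B permutations are
# evaluated as matrix products instead of a loop over permutations:
#
#   SKAT    T_b = yc_b' K yc_b / 8            (yc in +-1 coding, centered)
#   MDMR    uses tr(HGH) = y'Gy / N and tr((I-H)G(I-H)) = tr(G) - y'Gy/N
#           (H = yy'/N is a rank-1 projection, H and I-H idempotent),
#           with y'Gy = (Cy)' A (Cy), A = -(1-K)^2 / 2
#   U-test  within-group pair sums expand in the case indicator
#           a = (y+1)/2:  a'Ka = (y'Ky + 2 1'Ky + 1'K1)/4
#   KBAT    a single-variant kernel takes one value per ordered pair of
#           genotype levels, so per-variant pair sums reduce to quadratic
#           forms in the k-vector of per-level case counts (k <= 3 for raw
#           genotypes), computed for all permutations in one k x N matmul.
#
# The per-definition functions in statistics.R are the readable reference;
# tests assert exact agreement between the two routes.

.permEngine <- function(g, yPM, pooling = "none", kernel = "exponential",
                        B = 1000L, seed = 1L,
                        methods = c("mdmr", "skat", "utest", "kbat"),
                        threshold = 0.01, betaParams = c(1, 25),
                        weightExponent = 1, P = NULL,
                        keepPermutationStats = FALSE) {
  stopifnot(is(g, "GenotypeMatrix"))
  methods <- match.arg(methods, several.ok = TRUE)
  poly <- mafs(g) > 0
  if (!all(poly)) {
    if (!any(poly))
      stop("all variants are monomorphic")
    g <- g[, poly]
  }
  pool <- .poolForAnalysis(g, pooling, threshold,
                           b = betaParams[1], c = betaParams[2])
  X <- pool$X
  w <- pool$weights
  if (!is.null(w) && weightExponent != 1)
    w <- w^weightExponent
  if (!is.null(w) && weightExponent == 0)
    w <- rep(1, length(w))
  N <- length(yPM)
  stopifnot(nrow(X) == N, all(yPM %in% c(-1, 1)))
  nA <- sum(yPM == 1)
  nU <- N - nA
  B <- as.integer(B)
  if (is.null(P))
    P <- permutationIndexMatrix(N, B, seed)
  Ymat <- cbind(yPM, matrix(yPM[P], N, ncol(P)))
  nCol <- ncol(Ymat)
  m <- mean(yPM)                      # constant across permutations
  Yc <- Ymat - m
  out <- list()

  needK <- any(c("mdmr", "skat", "utest") %in% methods)
  if (needK) {
    K <- .kernelMatrix(X, kernel, w)
    if (any(c("skat", "utest") %in% methods)) {
      qK <- colSums(Yc * (K %*% Yc))
      if ("skat" %in% methods)
        out$skat <- qK / 8
      if ("utest" %in% methods) {
        if (nA < 2L || nU < 2L)
          stop("insufficient pairs: need at least two cases and two controls")
        k1 <- rowSums(K)
        S <- sum(K)
        dg <- diag(K)
        t2 <- as.vector(crossprod(k1, Yc))
        uKu <- qK + 2 * m * t2 + m^2 * S
        oneKu <- t2 + m * S
        dgu <- as.vector(crossprod(dg, Yc)) + m * sum(dg)
        caseDg <- (dgu + sum(dg)) / 2
        ctrlDg <- sum(dg) - caseDg
        sumCase <- ((uKu + 2 * oneKu + S) / 4 - caseDg) / 2
        sumCtrl <- ((uKu - 2 * oneKu + S) / 4 - ctrlDg) / 2
        U1 <- sumCase / (nA * (nA - 1))
        U0 <- sumCtrl / (nU * (nU - 1))
        out$utest <- (U1 - U0)^2
      }
    }
    if ("mdmr" %in% methods) {
      A <- -((1 - K)^2) / 2
      trG <- sum(diag(A)) - sum(A) / N
      qA <- colSums(Yc * (A %*% Yc))
      num <- qA / N
      den <- trG - num
      if (den[1L] <= .Machine$double.eps^0.5 * max(1, abs(num[1L])))
        stop("degenerate geometry: residual trace is not positive")
      out$mdmr <- num / den
    }
  }

  if ("kbat" %in% methods) {
    if (nA < 2L || nU < 2L)
      stop("insufficient pairs: need at least two cases and two controls")
    kw <- if (is.null(w)) rep(1, ncol(X)) else w
    pA <- nA * (nA - 1) / 2
    pU <- nU * (nU - 1) / 2
    CaseInd <- (Ymat + 1) / 2
    totBss <- totWss <- numeric(nCol)
    for (l in seq_len(ncol(X))) {
      gl <- X[, l]
      lev <- sort(unique(gl))
      # a constant site still enters WSS: with the printed denominator
      # N(N-1) the within-group mean is half the pair average, so
      # (K - U)^2 does not vanish even for an all-equal similarity block
      M <- .levelKernel(lev, kernel)
      Z <- matrix(0, N, length(lev))
      Z[cbind(seq_len(N), match(gl, lev))] <- 1
      tot <- colSums(Z)
      CA <- crossprod(Z, CaseInd)           # per-level case counts
      CU <- tot - CA
      dM <- diag(M)
      M2 <- M * M
      dM2 <- dM^2
      S1 <- (colSums(CA * (M %*% CA)) - as.vector(crossprod(dM, CA))) / 2
      Q1 <- (colSums(CA * (M2 %*% CA)) - as.vector(crossprod(dM2, CA))) / 2
      S0 <- (colSums(CU * (M %*% CU)) - as.vector(crossprod(dM, CU))) / 2
      Q0 <- (colSums(CU * (M2 %*% CU)) - as.vector(crossprod(dM2, CU))) / 2
      U1 <- S1 / (nA * (nA - 1))
      U0 <- S0 / (nU * (nU - 1))
      Ul <- (U1 + U0) / 2
      wss <- (Q1 - 2 * U1 * S1 + pA * U1^2) +
             (Q0 - 2 * U0 * S0 + pU * U0^2)
      bss <- pA * (Ul - U1)^2 + pU * (Ul - U0)^2
      totWss <- totWss + kw[l] * wss
      totBss <- totBss + kw[l] * bss
    }
    if (totWss[1L] <= 0)
      stop("degenerate similarity: total within-group sum of squares is zero")
    out$kbat <- totBss / pmax(totWss, .Machine$double.xmin)
  }

  out <- lapply(out, unname)
  observed <- lapply(out, `[`, 1L)
  pValue <- lapply(out, function(s)
    (1 + sum(s[-1L] >= s[1L])) / (length(s[-1L]) + 1))
  res <- list(observed = observed, pValue = pValue,
              nPermutations = ncol(P), seed = as.integer(seed))
  if (keepPermutationStats)
    res$statistics <- out
  res
}

# kernel evaluated on the distinct genotype levels of one variant
.levelKernel <- function(lev, kernel) {
  switch(kernel,
    exponential = exp(-outer(lev, lev, `-`)^2),
    ibs = {
      if (!all(lev %in% c(0, 1, 2)))
        stop("the IBS kernel is defined on genotype codes {0,1,2} only")
      2 - abs(outer(lev, lev, `-`))
    },
    linear = outer(lev, lev),
    quadratic = (1 + outer(lev, lev))^2,
    stop(sprintf("unknown kernel '%s'", kernel)))
}

#' Run all four similarity-based tests with shared permutations
#'
#' Computes MDMR, SKAT, U-test and KBAT statistics and their permutation
#' p-values from a single seeded permutation stream, so the four methods
#' (and, when called repeatedly with the same `seed` or an explicit
#' permutation matrix, different pooling strategies) are compared on
#' paired permutations.
#'
#' @inheritParams runTest
#' @param methods subset of `c("mdmr", "skat", "utest", "kbat")`.
#' @param permutations optional precomputed permutation index matrix from
#'   [permutationIndexMatrix()]; overrides `seed` for the label stream.
#' @return A data.frame with one row per method: `method`, `statistic`,
#'   `p.value`, `n.permutations`, `pooling`, `kernel`, `seed`.
#' @examples
#' g <- GenotypeMatrix(matrix(rbinom(200, 2, 0.1), nrow = 20))
#' y <- rep(c(1, -1), each = 10)
#' similarityTestSuite(g, y, pooling = "weighting", B = 99, seed = 7)
#' @export
similarityTestSuite <- function(g, y,
                                pooling = c("weighting", "collapsing",
                                            "none"),
                                kernel = "exponential", B = 1000L,
                                seed = 1L,
                                methods = c("mdmr", "skat", "utest",
                                            "kbat"),
                                threshold = 0.01, betaParams = c(1, 25),
                                permutations = NULL) {
  pooling <- match.arg(pooling)
  yv <- .asPlusMinus(y)
  res <- .permEngine(g, yv, pooling = pooling, kernel = kernel, B = B,
                     seed = seed, methods = methods,
                     threshold = threshold, betaParams = betaParams,
                     P = permutations)
  mm <- names(res$observed)
  data.frame(method = mm,
             statistic = unlist(res$observed, use.names = FALSE),
             p.value = unlist(res$pValue, use.names = FALSE),
             n.permutations = res$nPermutations,
             pooling = pooling, kernel = kernel, seed = res$seed,
             row.names = NULL)
}
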