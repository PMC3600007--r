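#' Multivariate distance matrix regression (MDMR) statistic
#'
#' Pseudo-F-like ratio regressing the similarity structure on the
#' phenotype: with phenotype projection `H = Y (Y'Y)^-1 Y'` (Y in +1/-1
#' coding, no intercept), dissimilarities `d_ij = 1 - K_ij`, the matrix
#' `A = {-d_ij^2 / 2}` and its Gower double-centering `G = C A C` with
#' `C = I - 11'/N`, the statistic is
#' `tr(H G H) / tr((I - H) G (I - H))`. Large values indicate association.
#'
#' @param K a [SimilarityMatrix-class] or plain symmetric matrix.
#' @param y a [PhenotypeVector-class] (any binary coding; converted) or a
#'   numeric vector in +1/-1 coding.
#' @return The MDMR statistic (finite; an error is raised when the
#'   residual trace is not positive, e.g. for a constant similarity
#'   matrix where all individuals are identical).
#' @export
mdmrStatistic <- function(K, y) {
  K <- similarityValues(K)
  y <- .asPlusMinus(y)
  N <- length(y)
  stopifnot(nrow(K) == N)
  D <- 1 - K
  A <- -(D^2) / 2
  Cm <- diag(N) - matrix(1 / N, N, N)
  G <- Cm %*% A %*% Cm
  H <- tcrossprod(y) / sum(y^2)
  num <- sum(diag(H %*% G %*% H))
  IH <- diag(N) - H
  den <- sum(diag(IH %*% G %*% IH))
  if (den <= .Machine$double.eps^0.5 * max(1, abs(num)))
    stop("degenerate geometry: residual trace is not positive")
  num / den
}

#' Sequence kernel association test (SKAT) statistic
#'
#' Quadratic form of the centered case indicator in the kernel:
#' `T = (Y - Ybar)' K (Y - Ybar) / 2` with Y coded 1 for cases and 0 for
#' controls and `Ybar` the case fraction. The all-case or all-control
#' phenotype gives exactly 0 (flagged with a message).
#'
#' @inheritParams mdmrStatistic
#' @param y phenotype in 1/0 coding (a [PhenotypeVector-class] is
#'   converted automatically).
#' @return The SKAT statistic.
#' @export
skatStatistic <- function(K, y) {
  K <- similarityValues(K)
  y <- .asZeroOne(y)
  stopifnot(nrow(K) == length(y))
  if (all(y == 1) || all(y == 0))
    message("degenerate phenotype (single group): SKAT statistic is 0")
  yc <- y - mean(y)
  drop(crossprod(yc, K %*% yc)) / 2
}

#' Multi-site U-test statistic
#'
#' Squared difference of the within-group average similarities:
#' `U1` sums the similarity over unordered case pairs divided by
#' `NA (NA - 1)`, `U0` analogously over control pairs, and
#' `U = (U1 - U0)^2`.
#'
#' @inheritParams mdmrStatistic
#' @return Non-negative U statistic.
#' @export
uTestStatistic <- function(K, y) {
  K <- similarityValues(K)
  y <- .asPlusMinus(y)
  stopifnot(nrow(K) == length(y))
  nA <- sum(y == 1)
  nU <- sum(y == -1)
  if (nA < 2L || nU < 2L)
    stop("insufficient pairs: need at least two cases and two controls")
  ca <- which(y == 1)
  co <- which(y == -1)
  U1 <- .pairSum(K, ca) / (nA * (nA - 1))
  U0 <- .pairSum(K, co) / (nU * (nU - 1))
  (U1 - U0)^2
}

# sum of K[n, m] over unordered pairs n < m within index set
.pairSum <- function(K, idx) {
  S <- K[idx, idx, drop = FALSE]
  (sum(S) - sum(diag(S))) / 2
}

#' Kernel-based association test (KBAT) statistic
#'
#' Analysis-of-variance-style ratio over single-variant similarity
#' matrices. For variant l let `U_l1`, `U_l0` be the within-group average
#' similarities (as in [uTestStatistic()]) and `U_l = (U_l1 + U_l0)/2`;
#' with pair counts `P_A = NA(NA-1)/2`, `P_U = NU(NU-1)/2`,
#' `WSS_l = sum_case-pairs (K_l - U_l1)^2 + sum_control-pairs (K_l - U_l0)^2`,
#' `BSS_l = P_A (U_l - U_l1)^2 + P_U (U_l - U_l0)^2`,
#' and the statistic is `sum_l w_l BSS_l / sum_l w_l WSS_l` (weights all 1
#' for the unweighted form; with equal weights the weighted statistic
#' reduces to the unweighted one exactly).
#'
#' @param Ks list of per-variant similarity matrices, as returned by
#'   [perSnpSimilarity()].
#' @inheritParams mdmrStatistic
#' @param weights optional per-variant weights (KBAT incorporates weights
#'   at the statistic level, not inside the kernel).
#' @return Non-negative KBAT statistic.
#' @export
kbatStatistic <- function(Ks, y, weights = NULL) {
  if (is(Ks, "SimilarityMatrix") || is.matrix(Ks)) Ks <- list(Ks)
  y <- .asPlusMinus(y)
  L <- length(Ks)
  w <- if (is.null(weights)) rep(1, L) else weights
  .checkWeights(w, L)
  nA <- sum(y == 1)
  nU <- sum(y == -1)
  if (nA < 2L || nU < 2L)
    stop("insufficient pairs: need at least two cases and two controls")
  ca <- which(y == 1)
  co <- which(y == -1)
  pA <- nA * (nA - 1) / 2
  pU <- nU * (nU - 1) / 2
  bss <- wss <- numeric(L)
  for (l in seq_len(L)) {
    Kl <- similarityValues(Ks[[l]])
    U1 <- .pairSum(Kl, ca) / (nA * (nA - 1))
    U0 <- .pairSum(Kl, co) / (nU * (nU - 1))
    Ul <- (U1 + U0) / 2
    Sa <- Kl[ca, ca][upper.tri(Kl[ca, ca])]
    Su <- Kl[co, co][upper.tri(Kl[co, co])]
    wss[l] <- sum((Sa - U1)^2) + sum((Su - U0)^2)
    bss[l] <- pA * (Ul - U1)^2 + pU * (Ul - U0)^2
  }
  den <- sum(w * wss)
  if (den <= 0)
    stop("degenerate similarity: total within-group sum of squares is zero")
  sum(w * bss) / den
}

.asPlusMinus <- function(y) {
  if (is(y, "PhenotypeVector"))
    return(recodePhenotype(y, "plus_minus_one")@values)
  y <- as.numeric(y)
  if (all(y %in% c(0, 1))) y <- 2 * y - 1
  if (!all(y %in% c(-1, 1)))
    stop("phenotype must be binary (+1/-1 or 1/0 coding)")
  y
}

.asZeroOne <- function(y) {
  if (is(y, "PhenotypeVector"))
    return(recodePhenotype(y, "zero_one")@values)
  y <- as.numeric(y)
  if (all(y %in% c(-1, 1)) && !all(y %in% c(0, 1))) y <- (y + 1) / 2
  if (!all(y %in% c(0, 1)))
    stop("phenotype must be binary (+1/-1 or 1/0 coding)")
  y
}

#' Permutation index matrix
#'
#' The seeded permutation stream shared by all methods (and, in the power
#' harness, by both pooling strategies) within one run, so that method
#' comparisons are paired.
#'
#' @param N number of individuals.
#' @param B number of permutations.
#' @param seed RNG seed.
#' @return Integer N x B matrix; column b is a uniformly random
#'   permutation of `1:N`.
#' @export
permutationIndexMatrix <- function(N, B, seed) {
  set.seed(as.integer(seed))
  vapply(seq_len(B), function(b) sample.int(N), integer(N))
}

#' Permutation p-value for an arbitrary statistic
#'
#' Permutes the phenotype labels uniformly at random B times, holding the
#' similarity structure fixed, and applies the add-one tail estimator
#' `p = (1 + #{permuted >= observed}) / (B + 1)` (ties count toward the
#' tail, and p can never be exactly zero).
#'
#' @param statFn function of a phenotype vector returning the test
#'   statistic; must be deterministic given its argument.
#' @param y phenotype ([PhenotypeVector-class] or numeric vector); its
#'   values are permuted.
#' @param B number of permutations (default 1000).
#' @param seed RNG seed (recorded in the result).
#' @param method label stored in the result (default `"skat"` has no
#'   effect on the computation).
#' @return A [TestResult-class].
#' @examples
#' K <- buildSimilarityMatrix(GenotypeMatrix(matrix(rbinom(40, 2, .3), 8)))
#' y <- phenotypeVector(rep(c(1, -1), each = 4))
#' permutationPvalue(function(yy) skatStatistic(K, yy), y, B = 99, seed = 1)
#' @export
permutationPvalue <- function(statFn, y, B = 1000L, seed = 1L,
                              method = "skat") {
  yv <- if (is(y, "PhenotypeVector")) y@values else as.numeric(y)
  B <- as.integer(B)
  stopifnot(B >= 1L)
  obs <- statFn(yv)
  P <- permutationIndexMatrix(length(yv), B, seed)
  perm <- vapply(seq_len(B), function(b) statFn(yv[P[, b]]), numeric(1))
  p <- (1 + sum(perm >= obs)) / (B + 1)
  new("TestResult", method = method, statistic = obs, pValue = p,
      nPermutations = B, seed = as.integer(seed), settings = list())
}

#' Run one similarity-based association test end to end
#'
#' Applies the pooling strategy, builds the similarity structure, computes
#' the statistic and its permutation p-value. For MDMR, SKAT and the
#' U-test the weights enter through the weighted kernel; for KBAT the
#' per-variant matrices are unweighted and the weights enter the statistic
#' (the weighted form KBAT_W).
#'
#' @param method `"mdmr"`, `"skat"`, `"utest"` or `"kbat"`.
#' @param g a [GenotypeMatrix-class].
#' @param y phenotype ([PhenotypeVector-class] or binary vector).
#' @param pooling `"weighting"`, `"collapsing"` or `"none"`.
#' @param kernel kernel name (default `"exponential"`).
#' @param B number of permutations (default 1000).
#' @param seed RNG seed.
#' @param threshold rarity threshold for collapsing (default 0.01).
#' @param betaParams Beta-density weight parameters c(b, c).
#' @return A [TestResult-class].
#' @export
runTest <- function(method = c("mdmr", "skat", "utest", "kbat"), g, y,
                    pooling = c("weighting", "collapsing", "none"),
                    kernel = "exponential", B = 1000L, seed = 1L,
                    threshold = 0.01, betaParams = c(1, 25)) {
  method <- match.arg(method)
  pooling <- match.arg(pooling)
  stopifnot(is(g, "GenotypeMatrix"))
  yv <- .asPlusMinus(y)
  res <- .permEngine(g, yv, pooling = pooling, kernel = kernel, B = B,
                     seed = seed, methods = method,
                     threshold = threshold, betaParams = betaParams)
  new("TestResult", method = method,
      statistic = res$observed[[method]],
      pValue = res$pValue[[method]], nPermutations = as.integer(B),
      seed = as.integer(seed),
      settings = list(pooling = pooling, kernel = kernel,
                      threshold = threshold, betaParams = betaParams,
                      weightedKbat = (method == "kbat" &&
                                      pooling == "weighting")))
}
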