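test_that("pairwise kernels match their analytic values", {
  expect_equal(exponentialKernel(c(0, 1, 2), c(0, 1, 2)), 1)
  expect_equal(exponentialKernel(c(0, 1), c(0, 0)), exp(-1))
  expect_equal(exponentialKernel(c(2, 0), c(0, 0)), exp(-4))
  expect_equal(weightedExponentialKernel(c(1, 0), c(0, 0), c(1, 1)),
               exp(-1 / 2))
  expect_equal(weightedExponentialKernel(c(1, 0), c(0, 0), c(3, 1)),
               exp(-3 / 4))
  expect_equal(weightedIbsKernel(c(0, 1), c(1, 1), c(1, 2)), 5)
  expect_equal(weightedIbsKernel(0, 2, 1), 0)
  expect_equal(weightedIbsKernel(c(1, 2), c(1, 2), c(2, 3)), 10)
  expect_equal(linearKernel(c(1, 2), c(2, 0), c(1, 1)), 2)
  expect_equal(linearKernel(c(0, 0), c(2, 1)), 0)
  expect_equal(quadraticKernel(c(0, 0), c(2, 1)), 1)
})

test_that("kernel contracts are enforced", {
  expect_error(exponentialKernel(c(0, 1), c(0, 1, 2)), "mismatch")
  expect_error(weightedExponentialKernel(c(0, 1), c(0, 0), c(0, 0)),
               "degenerate weights")
  expect_error(weightedExponentialKernel(c(0, 1), c(0, 0), c(-1, 2)),
               "non-negative")
  expect_error(weightedIbsKernel(c(0.5, 1), c(0, 1), c(1, 1)),
               "genotype codes")
  expect_error(buildSimilarityMatrix(matrix(0.5, 2, 1), kernel = "ibs"),
               "genotype codes")
})

test_that("equal weights reduce the weighted kernel to 1/L-scaled distances", {
  set.seed(3)
  for (i in 1:20) {
    L <- sample(2:8, 1)
    gn <- rbinom(L, 2, 0.3)
    gm <- rbinom(L, 2, 0.3)
    cw <- runif(1, 0.1, 10)
    expect_equal(weightedExponentialKernel(gn, gm, rep(cw, L)),
                 exp(-sum((gn - gm)^2) / L), tolerance = 1e-12)
  }
})

test_that("kernel values are symmetric in the two genotypes", {
  set.seed(4)
  for (i in 1:20) {
    L <- sample(1:6, 1)
    gn <- rbinom(L, 2, 0.4)
    gm <- rbinom(L, 2, 0.4)
    w <- runif(L, 0.1, 5)
    expect_identical(weightedExponentialKernel(gn, gm, w),
                     weightedExponentialKernel(gm, gn, w))
    expect_identical(weightedIbsKernel(gn, gm, w),
                     weightedIbsKernel(gm, gn, w))
  }
})

test_that("similarity matrices match the brute-force pair loop", {
  set.seed(5)
  g <- randomGenotypeMatrix(9, 4)
  X <- genotypeCounts(g)
  w <- betaWeights(mafs(g))
  for (kern in c("exponential", "ibs", "linear", "quadratic")) {
    Kw <- similarityValues(
      buildSimilarityMatrix(g, kern, weights = w, checkPsd = FALSE))
    expect_equal(Kw, oracleKernelMatrix(X, kern, w), tolerance = 1e-12)
    Ku <- similarityValues(
      buildSimilarityMatrix(g, kern, checkPsd = FALSE))
    expect_equal(Ku, oracleKernelMatrix(X, kern), tolerance = 1e-12)
  }
})

test_that("exponential kernel matrices are positive semi-definite", {
  set.seed(6)
  for (i in 1:100) {
    N <- sample(3:12, 1)
    L <- sample(1:8, 1)
    X <- matrix(rnorm(N * L), N)  # real-valued input: adjusted genotypes
    K <- similarityValues(
      buildSimilarityMatrix(X, "exponential", checkPsd = TRUE))
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8 * max(abs(ev)))
    expect_equal(unname(diag(K)), rep(1, N))
    expect_true(all(K > 0 & K <= 1 + 1e-12))
  }
})

test_that("trivial similarity matrices take their closed forms", {
  expect_equal(similarityValues(
    buildSimilarityMatrix(matrix(1, 1, 1), "exponential")),
    matrix(1, 1, 1))
  g <- GenotypeMatrix(rbind(c(0, 1), c(0, 1), c(1, 1)))
  K <- similarityValues(buildSimilarityMatrix(g))
  expect_equal(K[1, 2], 1)   # identical individuals
  expect_equal(K[1, 3], exp(-1))
})

test_that("per-variant matrices agree with single-column evaluation", {
  set.seed(7)
  g <- randomGenotypeMatrix(8, 3)
  Ks <- perSnpSimilarity(g)
  expect_length(Ks, 3)
  for (l in 1:3)
    expect_equal(similarityValues(Ks[[l]]),
                 similarityValues(buildSimilarityMatrix(
                   genotypeCounts(g)[, l, drop = FALSE])))
  # monomorphic column: every pair identical -> all-ones matrix
  K1 <- perSnpSimilarity(matrix(1, 4, 1))[[1]]
  expect_equal(similarityValues(K1), matrix(1, 4, 4))
  # column (0,1,2): off-diagonals e^-1, e^-4, e^-1
  K2 <- similarityValues(perSnpSimilarity(matrix(c(0, 1, 2), 3))[[1]])
  expect_equal(K2[lower.tri(K2)], c(exp(-1), exp(-4), exp(-1)))
})
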