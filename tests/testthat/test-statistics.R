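# Four-individual worked instances used throughout: a brute-force matrix
# oracle fixes the expected values, frozen here after independent
# evaluation.
microY <- c(1, 1, -1, -1)
microK <- local({
  K <- diag(4)
  K[1, 2] <- K[2, 1] <- 1   # the single case pair fully similar
  K
})

test_that("worked micro-examples match the brute-force oracle", {
  # identity kernel, balanced labels
  expect_equal(mdmrStatistic(diag(4), microY), oracleMdmr(diag(4), microY),
               tolerance = 1e-12)
  expect_equal(mdmrStatistic(diag(4), microY), 0.5, tolerance = 1e-12)
  expect_equal(skatStatistic(diag(4), c(1, 1, 0, 0)),
               oracleSkat(diag(4), c(1, 1, 0, 0)), tolerance = 1e-12)
  expect_equal(skatStatistic(diag(4), c(1, 1, 0, 0)), 0.5,
               tolerance = 1e-12)
  # case-pair similarity 1, control-pair similarity 0
  expect_equal(uTestStatistic(microK, microY),
               oracleUtest(microK, microY), tolerance = 1e-12)
  expect_equal(uTestStatistic(microK, microY), 0.25, tolerance = 1e-12)
  expect_equal(kbatStatistic(list(microK), microY),
               oracleKbat(list(microK), microY), tolerance = 1e-12)
  expect_equal(kbatStatistic(list(microK), microY), 0.5,
               tolerance = 1e-12)
})

test_that("statistic degeneracies raise the documented errors", {
  expect_error(mdmrStatistic(matrix(1, 4, 4), microY),
               "degenerate geometry")
  expect_error(uTestStatistic(diag(4), c(1, 1, 1, -1)),
               "insufficient pairs")
  expect_error(kbatStatistic(list(diag(4)), c(1, -1, -1, -1)),
               "insufficient pairs")
  expect_message(s <- skatStatistic(diag(4), c(1, 1, 1, 1)),
                 "single group")
  expect_equal(s, 0)
  # constant kernel, balanced labels: centered phenotype annihilates K
  expect_equal(suppressMessages(
    skatStatistic(matrix(1, 4, 4), c(1, 1, 0, 0))), 0)
})

test_that("statistics are invariant under joint relabeling of individuals", {
  set.seed(21)
  for (i in 1:10) {
    N <- 10
    g <- randomGenotypeMatrix(N, 5)
    y <- balancedPheno(N)
    K <- similarityValues(buildSimilarityMatrix(g, checkPsd = FALSE))
    perm <- sample(N)
    Kp <- K[perm, perm]
    yp <- y[perm]
    expect_equal(mdmrStatistic(Kp, yp), mdmrStatistic(K, y),
                 tolerance = 1e-12)
    expect_equal(skatStatistic(Kp, yp), skatStatistic(K, y),
                 tolerance = 1e-12)
    expect_equal(uTestStatistic(Kp, yp), uTestStatistic(K, y),
                 tolerance = 1e-12)
    Ks <- perSnpSimilarity(g)
    Ksp <- lapply(Ks, function(k) similarityValues(k)[perm, perm])
    expect_equal(kbatStatistic(Ksp, yp), kbatStatistic(Ks, y),
                 tolerance = 1e-12)
  }
})

test_that("U and KBAT are symmetric under a global case/control swap", {
  set.seed(22)
  g <- randomGenotypeMatrix(12, 4)
  y <- balancedPheno(12)
  K <- similarityValues(buildSimilarityMatrix(g, checkPsd = FALSE))
  expect_equal(uTestStatistic(K, -y), uTestStatistic(K, y))
  Ks <- perSnpSimilarity(g)
  expect_equal(kbatStatistic(Ks, -y), kbatStatistic(Ks, y))
})

test_that("equal weights leave KBAT unchanged", {
  set.seed(23)
  g <- randomGenotypeMatrix(10, 6)
  y <- balancedPheno(10)
  Ks <- perSnpSimilarity(g)
  expect_equal(kbatStatistic(Ks, y, weights = rep(3.7, 6)),
               kbatStatistic(Ks, y), tolerance = 1e-12)
})

test_that("permutation p-values obey the add-one tail estimator", {
  # a quantitative label vector makes the identity arrangement the unique
  # maximizer (rearrangement inequality), so no permutation ties it
  yq <- 1:8
  fn <- function(yy) sum(yy * (1:8))
  r <- permutationPvalue(fn, yq, B = 200, seed = 1)
  expect_equal(r@pValue, 1 / 201)
  y <- balancedPheno(8)
  # constant statistic: every permutation ties
  r2 <- permutationPvalue(function(yy) 1, y, B = 50, seed = 1)
  expect_equal(r2@pValue, 1)
  # determinism
  K <- similarityValues(buildSimilarityMatrix(randomGenotypeMatrix(8, 3),
                                              checkPsd = FALSE))
  p1 <- permutationPvalue(function(yy) skatStatistic(K, yy), y,
                          B = 99, seed = 42)
  p2 <- permutationPvalue(function(yy) skatStatistic(K, yy), y,
                          B = 99, seed = 42)
  expect_identical(p1@pValue, p2@pValue)
  expect_gte(p1@pValue, 1 / 100)
})

test_that("the vectorized engine reproduces the per-definition statistics", {
  set.seed(24)
  for (i in 1:8) {
    N <- 14
    g <- randomGenotypeMatrix(N, 6, mafRange = c(0.05, 0.45))
    y <- balancedPheno(N)
    for (pool in c("weighting", "none", "collapsing")) {
      w <- if (pool == "weighting") betaWeights(mafs(g)) else NULL
      X <- suppressWarnings(simpool:::.poolForAnalysis(g, pool)$X)
      K <- buildSimilarityMatrix(X, weights = w, checkPsd = FALSE)
      Ks <- perSnpSimilarity(X)
      eng <- suppressWarnings(
        simpool:::.permEngine(g, y, pooling = pool, B = 3, seed = i))
      expect_equal(eng$observed$mdmr, mdmrStatistic(K, y),
                   tolerance = 1e-10)
      expect_equal(eng$observed$skat, skatStatistic(K, y),
                   tolerance = 1e-10)
      expect_equal(eng$observed$utest, uTestStatistic(K, y),
                   tolerance = 1e-10)
      expect_equal(eng$observed$kbat, kbatStatistic(Ks, y, weights = w),
                   tolerance = 1e-10)
    }
  }
})

test_that("engine p-values equal the generic permutation path", {
  set.seed(25)
  g <- randomGenotypeMatrix(16, 5)
  y <- balancedPheno(16)
  w <- betaWeights(mafs(g))
  K <- buildSimilarityMatrix(g, weights = w, checkPsd = FALSE)
  eng <- simpool:::.permEngine(g, y, pooling = "weighting", B = 199,
                               seed = 77)
  generic <- permutationPvalue(function(yy) skatStatistic(K, yy), y,
                               B = 199, seed = 77)
  expect_equal(eng$pValue$skat, generic@pValue)
  genericM <- permutationPvalue(function(yy) mdmrStatistic(K, yy), y,
                                B = 199, seed = 77)
  expect_equal(eng$pValue$mdmr, genericM@pValue)
})

test_that("SKAT and MDMR reduce to case-control dissimilarity sums", {
  # balanced design decomposition: the SKAT statistic is affine
  # (increasing, slope 1/2 in this parameterisation) in the sum of
  # case-control pair dissimilarities, and MDMR is an increasing rational
  # function of the sum of their squares -- so permutation rankings are
  # shared with the dissimilarity oracles
  set.seed(26)
  for (i in 1:15) {
    N <- 2 * sample(4:10, 1)
    g <- randomGenotypeMatrix(N, 5)
    K <- similarityValues(
      buildSimilarityMatrix(g, weights = betaWeights(mafs(g)),
                            checkPsd = FALSE))
    ys <- replicate(12, balancedPheno(N), simplify = FALSE)
    skat <- vapply(ys, function(y) skatStatistic(K, y), numeric(1))
    cc1 <- vapply(ys, function(y) ccDissimSum(K, y), numeric(1))
    # T = (sum(K) - 4 * sum_cc K)/8 and cc1 = (N/2)^2 - sum_cc K
    expect_equal(skat, (sum(K) - 4 * ((N / 2)^2 - cc1)) / 8,
                 tolerance = 1e-9)
    mdmr <- vapply(ys, function(y) mdmrStatistic(K, y), numeric(1))
    cc2 <- vapply(ys, function(y) ccDissimSum(K, y, squared = TRUE),
                  numeric(1))
    A <- -((1 - K)^2) / 2
    trG <- sum(diag(A)) - sum(A) / N
    num <- (sum(A) + 2 * cc2) / N
    expect_equal(mdmr, num / (trG - num), tolerance = 1e-9)
  }
})

test_that("runTest composes pooling, kernel and permutation deterministically", {
  set.seed(27)
  g <- randomGenotypeMatrix(20, 8, mafRange = c(0.05, 0.3))
  y <- phenotypeVector(balancedPheno(20))
  r1 <- runTest("skat", g, y, pooling = "weighting", B = 99, seed = 5)
  r2 <- runTest("skat", g, y, pooling = "weighting", B = 99, seed = 5)
  expect_identical(r1@statistic, r2@statistic)
  expect_identical(r1@pValue, r2@pValue)
  expect_true(r1@pValue >= 1 / 100 && r1@pValue <= 1)
  # single-variant region: all four tests runnable without pooling
  g1 <- GenotypeMatrix(matrix(rbinom(20, 2, 0.3), 20))
  for (m in c("mdmr", "skat", "utest", "kbat")) {
    r <- runTest(m, g1, y, pooling = "none", B = 49, seed = 2)
    expect_s4_class(r, "TestResult")
    expect_true(r@pValue > 0 && r@pValue <= 1)
  }
  # collapsing with every variant rare: tests run on the super-locus alone
  cts <- vapply(rep(0.008, 10),
                function(p) rbinom(200, 2, p), numeric(200))
  cts[1, 1] <- 1  # guard monomorphic
  gr <- GenotypeMatrix(cts)
  yr <- phenotypeVector(balancedPheno(200))
  rr <- runTest("skat", gr, yr, pooling = "collapsing", B = 49, seed = 3)
  expect_s4_class(rr, "TestResult")
})
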