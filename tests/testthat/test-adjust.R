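# two-population fixture: a block of variants with a strong allele
# frequency difference between the first and second half of the sample
twoPopFixture <- function(N = 200, L = 30, shift = 0.3, seed = 31) {
  set.seed(seed)
  half <- N / 2
  p1 <- runif(L, 0.1, 0.3)
  p2 <- pmin(p1 + shift, 0.49)
  cts <- rbind(
    vapply(p1, function(p) rbinom(half, 2, p), numeric(half)),
    vapply(p2, function(p) rbinom(half, 2, p), numeric(half)))
  GenotypeMatrix(cts)
}
popLabels <- function(g) rep(c(1, 2), each = nrow(genotypeCounts(g)) / 2)

test_that("principal components are orthonormal and detect structure", {
  g <- twoPopFixture()
  R <- pcaComponents(g, k = 5)
  expect_equal(crossprod(R), diag(5), tolerance = 1e-10)
  # the leading component separates the two populations (sign-invariant)
  pop <- popLabels(g)
  expect_gt(abs(mean(R[pop == 1, 1]) - mean(R[pop == 2, 1])),
            2 * (sd(R[pop == 1, 1]) + sd(R[pop == 2, 1])))
  # k = 0: empty matrix, projection becomes the identity
  R0 <- pcaComponents(g, k = 0)
  expect_equal(ncol(R0), 0L)
  x <- rnorm(200)
  expect_identical(projectOut(x, R0), x)
})

test_that("rank-deficient input truncates with a warning", {
  cts <- cbind(c(0, 1, 2, 1, 0, 2), c(0, 1, 2, 1, 0, 2))
  expect_warning(R <- pcaComponents(GenotypeMatrix(cts), k = 4),
                 "truncating")
  expect_lte(ncol(R), 2L)
})

test_that("projectOut is an orthogonal projection", {
  g <- twoPopFixture(seed = 32)
  R <- pcaComponents(g, k = 4)
  x <- rnorm(200)
  once <- projectOut(x, R)
  expect_equal(projectOut(once, R), once, tolerance = 1e-10)  # idempotent
  expect_lte(sum(once^2), sum(x^2) + 1e-12)  # norm-non-increasing
  # an R column projects to (numerically) zero
  expect_equal(max(abs(projectOut(R[, 2], R))), 0, tolerance = 1e-10)
  # a vector already orthogonal to R is unchanged
  ortho <- once
  expect_equal(projectOut(ortho, R), ortho, tolerance = 1e-12)
  expect_error(projectOut(rnorm(10), R), "row mismatch")
})

test_that("covariate regression returns orthogonal OLS residuals", {
  set.seed(33)
  N <- 80
  E <- matrix(rnorm(3 * N), N, dimnames = list(NULL, c("age", "sex",
                                                       "smoke")))
  ph <- 2 + E %*% c(0.5, -1, 0.2) + rnorm(N)
  res <- regressOutCovariates(ph, E)
  expect_equal(sum(res), 0, tolerance = 1e-8)
  for (j in 1:3)
    expect_equal(sum(res * E[, j]), 0, tolerance = 1e-8)
  # exact linear combination: residuals vanish
  exact <- drop(1 + E %*% c(1, 2, 3))
  expect_equal(max(abs(regressOutCovariates(exact, E))), 0,
               tolerance = 1e-8)
  # collinear design is rejected with the offending column named
  E2 <- cbind(E, dup = E[, 1])
  expect_error(regressOutCovariates(ph, E2), "dup")
})

test_that("zero covariates leave the centered phenotype", {
  ph <- c(3, 5, 7, 9)
  expect_equal(regressOutCovariates(ph, matrix(0, 4, 1)), ph - 6)
})

test_that("dichotomization declares the top fraction cases", {
  res <- c(5, 1, 9, 3, 7, 2, 8, 4, 6, 0)
  y <- dichotomize(res, 0.3)
  expect_equal(nCases(y), 3)
  expect_equal(which(phenotypeValues(y) == 1), c(3, 5, 7))
  # ties at the cutoff: stable index order with a warning
  expect_warning(yt <- dichotomize(rep(1, 10), 0.3), "ties")
  expect_equal(which(phenotypeValues(yt) == 1), 1:3)
  expect_equal(nCases(dichotomize(rnorm(10))), 3)  # default 30%
})

test_that("PC adjustment removes the between-population genotype shift", {
  g <- twoPopFixture(seed = 34)
  pop <- popLabels(g)
  R <- pcaComponents(g, k = 10)
  Gadj <- projectOut(genotypeCounts(g), R)
  raw <- genotypeCounts(g)
  rawDiff <- colMeans(raw[pop == 1, ]) - colMeans(raw[pop == 2, ])
  adjDiff <- colMeans(Gadj[pop == 1, ]) - colMeans(Gadj[pop == 2, ])
  # the between-population mean shift along the structured axis shrinks
  # by at least 90% in norm
  expect_lt(sqrt(sum(adjDiff^2) / sum(rawDiff^2)), 0.1)
})

test_that("the full adjustment pipeline composes", {
  g <- twoPopFixture(seed = 35)
  set.seed(35)
  covars <- matrix(rnorm(3 * 200), 200,
                   dimnames = list(NULL, c("age", "sex", "smoke")))
  pheno <- rnorm(200) + 0.5 * covars[, 1]
  adj <- adjustForStratification(g, pheno, covars, k = 5,
                                 topFraction = 0.3)
  expect_s4_class(adj$genotypes, "GenotypeMatrix")
  expect_true(adj$genotypes@adjusted)
  expect_equal(nCases(adj$phenotype), ceiling(0.3 * 200))
  # residuals orthogonal to the components and the adjusted covariates
  expect_equal(max(abs(crossprod(adj$components, adj$residuals))), 0,
               tolerance = 1e-8)
  covAdj <- projectOut(covars, adj$components)
  expect_equal(max(abs(crossprod(covAdj, adj$residuals))), 0,
               tolerance = 1e-6)
})
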