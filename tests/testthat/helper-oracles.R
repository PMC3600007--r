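# Brute-force oracles, kept deliberately independent of the package's
# vectorized implementations: explicit pair loops and dense matrix algebra
# straight from the definitions.

oracleKernelMatrix <- function(X, kernel = "exponential", w = NULL) {
  N <- nrow(X)
  L <- ncol(X)
  if (is.null(w)) wU <- rep(1, L)
  K <- matrix(0, N, N)
  for (n in seq_len(N)) {
    for (m in seq_len(N)) {
      a <- X[n, ]
      b <- X[m, ]
      K[n, m] <- switch(kernel,
        exponential = if (is.null(w)) exp(-sum((a - b)^2))
                      else exp(-sum(w * (a - b)^2) / sum(w)),
        ibs = sum((if (is.null(w)) wU else w) * (2 - abs(a - b))),
        linear = sum((if (is.null(w)) wU else w) * a * b),
        quadratic = (1 + sum((if (is.null(w)) wU else w) * a * b))^2)
    }
  }
  K
}

oracleMdmr <- function(K, y) {
  N <- length(y)
  Y <- matrix(y, ncol = 1)
  H <- Y %*% solve(t(Y) %*% Y) %*% t(Y)
  D <- matrix(1, N, N) - K
  A <- -(D^2) / 2
  C <- diag(N) - matrix(1, N, N) / N
  G <- C %*% A %*% C
  IH <- diag(N) - H
  sum(diag(H %*% G %*% H)) / sum(diag(IH %*% G %*% IH))
}

oracleSkat <- function(K, y01) {
  yc <- y01 - mean(y01)
  as.numeric(t(yc) %*% K %*% yc) / 2
}

oracleUtest <- function(K, y) {
  ca <- which(y == 1)
  co <- which(y == -1)
  nA <- length(ca)
  nU <- length(co)
  s1 <- 0
  for (i in seq_along(ca)) for (j in seq_along(ca))
    if (i < j) s1 <- s1 + K[ca[i], ca[j]]
  s0 <- 0
  for (i in seq_along(co)) for (j in seq_along(co))
    if (i < j) s0 <- s0 + K[co[i], co[j]]
  (s1 / (nA * (nA - 1)) - s0 / (nU * (nU - 1)))^2
}

oracleKbat <- function(Ks, y, w = NULL) {
  ca <- which(y == 1)
  co <- which(y == -1)
  nA <- length(ca)
  nU <- length(co)
  if (is.null(w)) w <- rep(1, length(Ks))
  bssTot <- wssTot <- 0
  for (l in seq_along(Ks)) {
    K <- Ks[[l]]
    s1 <- s0 <- 0
    p1 <- p0 <- numeric(0)
    for (i in seq_along(ca)) for (j in seq_along(ca))
      if (i < j) p1 <- c(p1, K[ca[i], ca[j]])
    for (i in seq_along(co)) for (j in seq_along(co))
      if (i < j) p0 <- c(p0, K[co[i], co[j]])
    U1 <- sum(p1) / (nA * (nA - 1))
    U0 <- sum(p0) / (nU * (nU - 1))
    Ul <- (U1 + U0) / 2
    wss <- sum((p1 - U1)^2) + sum((p0 - U0)^2)
    bss <- nA * (nA - 1) / 2 * (Ul - U1)^2 +
           nU * (nU - 1) / 2 * (Ul - U0)^2
    bssTot <- bssTot + w[l] * bss
    wssTot <- wssTot + w[l] * wss
  }
  bssTot / wssTot
}

# sum of case-control pair dissimilarities (and squares), computed in a
# swap-stable form: the across-group sum is total minus the two
# within-group blocks
ccDissimSum <- function(K, y, squared = FALSE) {
  ca <- which(y == 1)
  co <- which(y == -1)
  D <- 1 - K
  if (squared) D <- D^2
  # group the two within-blocks so a global case/control swap gives a
  # bitwise-identical value (float addition commutes but does not
  # associate)
  (sum(D) - (sum(D[ca, ca]) + sum(D[co, co]))) / 2
}

randomGenotypeMatrix <- function(N, L, mafRange = c(0.05, 0.4)) {
  p <- runif(L, mafRange[1], mafRange[2])
  cts <- vapply(p, function(pp) rbinom(N, 2, pp), numeric(N))
  # guard against monomorphic draws in tiny instances
  for (l in seq_len(L)) {
    if (length(unique(cts[, l])) == 1L)
      cts[seq_len(2), l] <- c(0, 1)
  }
  GenotypeMatrix(cts)
}

balancedPheno <- function(N) sample(rep(c(1, -1), each = N / 2))

writeToyVcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", sep = "\t"),
    paste("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("1", "200", "rs2", "C", "T", ".", "PASS", ".", "GT",
          "1/1", "1/1", "0/1", sep = "\t")), path)
  path
}
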