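# simpool

Similarity-based rare-variant association tests with the two standard
rare-variant pooling strategies, permutation inference, and a simulation
harness for comparing them.

## The problem

Single-variant association tests have essentially no power for rare
variants (minor allele frequency, MAF, at or below 1%), so region-based
tests pool information across the variants of a gene or region. One
family of such tests works on an N x N *genotype similarity matrix*
`K = {s(g_n, g_m)}`, where `g_n` is the multi-site genotype (minor-allele
counts) of individual n and `s` is a positive-semi-definite kernel. This
package implements the four members of that family most used in practice,
for case/control phenotypes with permutation significance:

* **MDMR** — multivariate distance matrix regression: with phenotype
  projection `H = Y(Y'Y)^-1 Y'` (Y in +1/-1 coding), dissimilarities
  `d_ij = 1 - K_ij`, `A = {-d_ij^2/2}` and Gower centering `G = CAC`
  (`C = I - 11'/N`), the statistic is `tr(HGH) / tr((I-H)G(I-H))`.
* **SKAT** — sequence kernel association test:
  `T = (Y - Ybar)' K (Y - Ybar) / 2` with Y coded 1/0.
* **U-test** — squared difference of within-group average similarities,
  `U = (U1 - U0)^2`.
* **KBAT** — kernel-based association test: the ratio of between- to
  within-group sums of squares of pairwise similarities accumulated over
  per-variant similarity matrices, `sum_l w_l BSS_l / sum_l w_l WSS_l`.

The default kernel is the exponential (Gaussian) kernel
`s(g_n, g_m) = exp(-sum_l (g_nl - g_ml)^2)`; weighted IBS, linear and
quadratic kernels are also provided.

Two ways of pooling rare variants are supported and compared:

* **Weighting** — every variant enters the kernel with weight
  `w_l = Beta(maf_l; 1, 25)^2` (squared Beta density), which up-weights
  rare variants smoothly:
  `s_w(g_n, g_m) = exp(-sum_l w_l (g_nl - g_ml)^2 / sum_l w_l)`.
  For KBAT the weights enter the statistic instead (KBAT_W).
* **Collapsing** — rare variants (MAF <= 0.01) are summed per individual
  into a *super-locus* `min(2, sum of rare minor-allele counts)`, which
  joins the common variants as a new pseudo-variant.

Significance is assessed by permuting case/control labels (1000
permutations by default) with the add-one estimator
`p = (1 + #{permuted >= observed}) / (B + 1)`. A stratification module
implements the Eigenstrat-style adjustment used for structured samples:
project ten genotype principal components out of genotypes, phenotypes
and covariates, residualise on the covariates by OLS, and dichotomize the
residuals (upper 30% become cases).

## Worked example

Simulate one region where half of the rare variants carry risk (per-allele
odds ratio 5), then test it both ways:

```r
library(simpool)

cfg  <- scenarioConfig("risk_rare", nCases = 100, nControls = 100,
                       nVariants = 30, seed = 42)
rep1 <- generateReplicate(cfg)
g    <- genotypes(rep1)
g
#> GenotypeMatrix: 200 individuals x 30 variants
#>   MAF range [0, 0.4825]; 17 rare at MAF <= 0.01

similarityTestSuite(g, phenotype(rep1), pooling = "weighting",
                    B = 1000, seed = 42)
#>   method     statistic     p.value n.permutations   pooling      kernel seed
#> 1   skat  1.3167239610 0.008991009           1000 weighting exponential   42
#> 2  utest  0.0001258964 0.005994006           1000 weighting exponential   42
#> 3   mdmr -0.0066228040 0.991008991           1000 weighting exponential   42
#> 4   kbat  0.0001801624 0.024975025           1000 weighting exponential   42

similarityTestSuite(g, phenotype(rep1), pooling = "collapsing",
                    B = 1000, seed = 42)
#>   method    statistic    p.value n.permutations    pooling      kernel seed
#> 1   skat 2.379243e+01 0.58741259           1000 collapsing exponential   42
#> 2  utest 1.497470e-05 0.05394605           1000 collapsing exponential   42
#> 3   mdmr 4.801172e-03 0.61638362           1000 collapsing exponential   42
#> 4   kbat 4.817420e-04 0.11688312           1000 collapsing exponential   42
```

With a strong rare-variant signal, Beta-MAF weighting finds the
association (SKAT p = 0.009, U-test p = 0.006, KBAT p = 0.025) while
collapsing the same variants into a super-locus dilutes it past
detection. MDMR is the known exception under weighting: its
squared-dissimilarity geometry concentrates on pairs differing by several
rare alleles and it loses power (p = 0.99) — use `weightExponentSweep()`
to trace that behaviour.

The binomial-normal 99% confidence band for an empirical type-I error
estimated from 200 replicates at nominal 0.05:

```r
round(type1ErrorCI(0.05, 200), 4)
#>  lower  upper
#> 0.0103 0.0897
```

A thin command-line wrapper is installed at
`system.file("scripts", "simpool", package = "simpool")` with subcommands
`simulate`, `test`, `power` and `adjust`, each writing a JSON manifest
alongside its output.

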