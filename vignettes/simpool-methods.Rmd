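---
title: "Similarity-based rare-variant tests and pooling strategies: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Similarity-based rare-variant tests and pooling strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(simpool)
```

# The statistical model

An association study supplies `N` individuals (`NA` cases, `NU`
controls) genotyped at `L` variant sites in one region. Genotypes are
minor-allele counts `g_nl` in {0, 1, 2}; after mean imputation of missing
calls or stratification adjustment they may be real-valued. The central
object is the similarity matrix `K` with entries `s(g_n, g_m)` for a
symmetric positive-semi-definite kernel `s`. The package's default is the
exponential kernel

    s(g_n, g_m) = exp(-sum_l (g_nl - g_ml)^2),

chosen because it is a function of the Euclidean distance between
multi-site genotypes and therefore stays meaningful for the real-valued
genotypes produced by principal-component adjustment. The
identity-by-state kernel `sum_l w_l (2 - |g_nl - g_ml|)` is provided for
sensitivity analyses but, being defined on genotype codes, rejects
non-integer input. Weighted linear and quadratic kernels round out the
set.

## The four statistics

All four tests reject for large values and take their significance from
the same permutation stream.

**MDMR.** Regression of the dissimilarity geometry on the phenotype:
`H = Y(Y'Y)^-1 Y'` with `Y` the +1/-1 phenotype column (no intercept);
`D = 11' - K`; `A = {-d_ij^2 / 2}`; `G = C A C` with
`C = I - 11'/N`; statistic `tr(HGH) / tr((I-H)G(I-H))`. We read the
centering as the standard Gower double-centering — `C` applied on both
sides — and exploit that `H` and `I - H` are idempotent projections, so
`tr(HGH) = y'Gy / N` and the denominator is `tr(G) - y'Gy / N` for
balanced or unbalanced designs alike. A constant similarity matrix makes
both traces vanish; that degenerate geometry raises an error rather than
returning 0/0.

**SKAT.** `T = (Y - Ybar)' K (Y - Ybar) / 2` with `Y` in 1/0 coding.
The all-case (or all-control) phenotype gives exactly zero and is
flagged. Significance is by permutation only; the asymptotic mixture of
chi-squares is out of scope since every comparison in the package is
permutation-based anyway.

**U-test.** `U1` is the sum of similarities over unordered case pairs
divided by `NA(NA-1)`, `U0` its control analogue, and `U = (U1 - U0)^2`.
The printed denominator `NA(NA-1)` (rather than the pair count
`NA(NA-1)/2`) makes `U1` half the pair average; we keep it exactly as
printed because any consistent rescaling cancels from permutation
p-values. The pair sums run over `n < m`: the printed index range
includes the diagonal, but self-similarity carries no case/control
information and is excluded.

**KBAT.** For each variant `l`, `U_l1` and `U_l0` are the within-group
average similarities from the single-variant matrix `K_l`,
`U_l = (U_l1 + U_l0)/2`, and

    WSS_l = sum_case-pairs (K_l - U_l1)^2 + sum_control-pairs (K_l - U_l0)^2
    BSS_l = NA(NA-1)/2 (U_l - U_l1)^2 + NU(NU-1)/2 (U_l - U_l0)^2,

with the statistic `sum_l w_l BSS_l / sum_l w_l WSS_l`. The `BSS`
coefficients are the pair-group sizes; with equal weights the weighted
statistic reduces to the unweighted one exactly, which the tests assert.
One consequence of the printed `U_l1` convention worth knowing: a
*constant* variant (for example an all-zero super-locus) still
contributes `WSS_l > 0`, because the within-group "mean" is half the
pair average. The implementation honours this so that the fast engine
and the literal definition agree to machine precision.

## Pooling strategies

Rarity means `maf <= 0.01` (boundary inclusive); common means
`maf > 0.01`. The same threshold constant drives both definitions.

*Weighting* gives every variant the squared Beta density weight
`w_l = Beta(maf_l; 1, 25)^2 = (25 (1 - maf_l)^24)^2`, strictly
decreasing in MAF (625 at MAF 0, about 386 at 0.01, essentially zero at
0.5). Parameters `(b, c)` are configurable within `0 <= b <= 1`,
`c >= 1`, the range in which rare variants are up-weighted. For MDMR,
SKAT and the U-test the weights enter the kernel, normalised inside the
exponent by `sum w_l`; for KBAT they enter the statistic (KBAT_W), since
that test never forms a multi-site kernel.

*Collapsing* sums the rare minor-allele counts per individual and caps at
two: `min(2, sum_{l: maf_l <= 0.01} g_nl)`, a super-locus treated as one
new unweighted pseudo-variant alongside the common variants. The two
strategies are mutually exclusive by design — the super-locus never
receives a Beta weight — because the comparison between them is the
package's point.

Monomorphic variants (MAF 0) are dropped before analysis with a warning
in the file readers and silently in the bulk simulation engine: they
carry no similarity information, and the Beta weight at MAF 0 is the
maximum of the weight function, which would let uninformative sites
dominate a weighted kernel. Missing genotypes are mean-imputed per
variant (the kernels then see real values); the count of imputed calls is
messaged.

# Permutation inference

`p = (1 + #{permuted statistic >= observed}) / (B + 1)` with `B = 1000`
by default: the add-one estimator never returns zero and ties count
toward the tail. All four statistics — and, in the power harness, both
pooling strategies — share one seeded permutation stream per replicate,
so method and strategy comparisons are paired and reproducible
bit-for-bit from the seed.

The engine evaluates all `B` permutations by linear algebra rather than a
loop: SKAT and MDMR are quadratic forms in the (centered) label matrix
against `K` and `A`; the U-test expands its within-group pair sums in the
case indicator `a = (y + 1)/2`; and KBAT exploits that a single-variant
kernel takes one value per ordered pair of genotype *levels*, reducing
per-variant pair sums to quadratic forms in the per-level case counts — a
`k x B` computation with `k <= 3` for raw genotypes. The readable
per-definition functions remain the reference implementation, and the
test suite asserts exact agreement between the two routes on random
instances across all pooling strategies and kernels.

On balanced designs the SKAT statistic is an increasing affine function
of the summed case-control pair dissimilarities, and MDMR an increasing
rational function of the summed *squared* case-control dissimilarities.
The suite verifies both identities and, on 200 random balanced instances,
that the permutation p-values of SKAT and MDMR equal those of the two
dissimilarity-sum oracles exactly. This decomposition also explains
MDMR's behaviour under weighting: squaring emphasises pairs that differ
by two or more rare alleles, so up-weighting very rare variants can move
the observed statistic *below* its permutation distribution.
`weightExponentSweep()` traces this by re-analysing a batch with weights
`w_l^p` for `p` from 0 to 1; `p = 0` is the uniform-weight analysis
(identical to the unweighted kernel after the `1/L` rescaling that the
weight normalisation implies — a rescaling the kernel tests pin down
exactly), `p = 1` the full Beta weighting.

# Positive semi-definiteness

`buildSimilarityMatrix()` checks PSD by eigendecomposition with relative
tolerance `1e-8` on the smallest eigenvalue and raises on failure. The
bulk engine skips this check: the exponential kernel is PSD for any real
input (Gaussian kernel property, property-tested on 100 random inputs),
and an `O(N^3)` decomposition per replicate would dominate the whole
simulation. Squared distances are clamped at zero before exponentiation
and the diagonal is set to one exactly, so kernel entries lie in (0, 1].

# Stratification adjustment

For structured samples the package reproduces the standard
exome-workshop pipeline: columns standardised to mean `2p` and variance
`2p(1-p)` (the Eigenstrat convention; only the convention is borrowed —
the decomposition is an ordinary SVD), top `k = 10` components `R`,
projection `x - RR'x` applied to genotypes, phenotypes and covariates,
OLS residualisation of the adjusted phenotype on an intercept plus the
adjusted covariates, and dichotomization of the residuals with the top
30% as cases. The projection of the genotype matrix is `G - RR'G`
(projecting each *column* of `G`), ties at the dichotomization cutoff are
broken by stable index order with a warning, and `ceiling(0.3 N)`
guarantees at least the stated case fraction. Constant covariate columns
(which alias the intercept) are dropped; genuinely collinear columns
raise an error naming the offender. The binary trait follows the same
adjust-residualise-dichotomize path as the quantitative traits.

# The synthetic generator

The generator stands in for a forward population-genetics simulation that
is out of scope here; it is a deliberately simple stand-in and is
labelled as such. What it emulates: a resequenced region dominated by
rare variation and four causal architectures plus a null. What it does
not emulate: linkage disequilibrium (sites are independent by default),
demographic history, selection at linked sites, genotyping error and
site-discovery ascertainment. Passing tests therefore demonstrate the
statistical machinery and the direction of the pooling-strategy
contrasts, not absolute power on real sequence data.

Concretely, per replicate:

* each site is rare with probability 0.8; rare MAFs are log-uniform on
  `[5e-4, 0.01]` (density proportional to `1/maf`, the rare-skewed shape
  of site-frequency spectra under purifying selection; the lower bound
  keeps the expected minor-allele count near one in 1000 individuals),
  common MAFs uniform on `(0.01, 0.5)`;
* genotypes are binomial(2, maf) under Hardy-Weinberg equilibrium;
* disease follows `logit P = logit(0.1) + sum_l beta_l g_nl`, sampled
  retrospectively in batches until 500 cases and 500 controls are found
  (defaults; a draw cap turns degenerate penetrance settings into an
  error rather than a hang);
* scenario effects (per minor allele, chosen once as round odds-ratio
  values that give the architectures their intended character at these
  sample sizes): `risk_rare` — half the rare sites at log OR `log(5)`;
  `risk_both` — rare `log(3)` plus half the common sites at `log(1.3)`;
  `risk_common` — common `log(2)`, rare `log(1.2)`; `mixed_rare` — as
  `risk_rare` with half the causal rare sites sign-flipped to
  protective; `null` — all zero.

Replicates are reproducible from `(config, seed, replicate id)` via a
Lehmer-style derived seed kept inside 32-bit range.

# Study conditions used by the acceptance checks

The calibration and comparison runs use 200 replicates of 500 cases /
500 controls x 50 variants at `B = 1000` permutations — 200 replicates
matches the replicate count of the reference exome data set whose 99%
type-I error band (0.01, 0.09) the analytic interval reproduces, and the
binomial band is what the empirical type-I error of every test-by-pooling
combination is held to. The qualitative contrasts checked at `alpha =
0.05` are: weighting at least as powerful as collapsing for SKAT, KBAT
and the U-test under `risk_rare` and `mixed_rare` (collapsing annihilates
opposing effect signs; weighting does not); collapsing at least as
powerful for all four tests under `risk_common` (Beta weights nearly
silence common-variant signal); and weighted-MDMR power non-increasing in
the weight exponent on a `risk_rare` batch (100 replicates). Orderings
are asserted with a two-standard-error one-sided slack on the paired
binomial estimates. The exponent sweep and all orderings use the paired
permutation stream to cut Monte-Carlo variance.

# Numerical and interface conventions

* Phenotype codings (+1/-1 for MDMR, U-test, KBAT; 1/0 for SKAT) are
  converted automatically; `PhenotypeVector` validates its coding.
* VCF input accepts biallelic SNVs and indels, ignores phase, rejects
  multi-allelic records, and recodes sites where ALT is the major allele
  as `2 - count` so MAFs never exceed one half.
* The alpha grid `{0.001, 0.002, 0.005, 0.01, 0.02, 0.05}` is bounded
  below by the resolution of a 1000-permutation p-value.
* Confidence-interval bounds are reported rounded to two significant
  figures (the raw values travel alongside).
* The normal-approximation interval for 1000 replicates evaluates to
  (0.032, 0.068) at 99% confidence; the package reports what the formula
  gives.
* All CLI outputs carry a JSON manifest (command, options, seed, input
  digests, version) sufficient to regenerate them.

# Known limitations

* No linkage disequilibrium in the default generator (an optional
  block-correlation mode was considered and rejected to keep the null
  exchangeable and the study conditions transparent); real regions have
  correlated sites, which changes absolute power.
* No asymptotic p-values: everything is permutation-based, so
  genome-wide significance levels would need prohibitively many
  permutations; the package targets region-level analysis.
* No covariate-adjusted score-test variants: covariates are handled by
  the projection/residualisation pipeline, not inside the statistics.
* Absolute power values depend on the generator's effect sizes and are
  not comparable to published tables from forward simulations or real
  exome data; only the directional contrasts are.
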