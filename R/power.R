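#' Default significance-level grid
#'
#' `{0.001, 0.002, 0.005, 0.01, 0.02, 0.05}`: bounded below by the
#' resolution of a 1000-permutation p-value.
#'
#' @return Numeric vector of significance levels.
#' @export
defaultAlphaGrid <- function() c(0.001, 0.002, 0.005, 0.01, 0.02, 0.05)

#' Estimate a power curve from per-replicate p-values
#'
#' `power(alpha) = #\{p <= alpha\} / n`, the fraction of replicates
#' rejecting at each significance level. All p-values must come from the
#' same method, pooling strategy and scenario.
#'
#' @param pvalues numeric vector of permutation p-values, one per
#'   replicate.
#' @param alphas increasing significance grid (default
#'   [defaultAlphaGrid()]).
#' @param method,pooling,scenario labels stored in the curve.
#' @return A [PowerCurve-class].
#' @export
estimatePower <- function(pvalues, alphas = defaultAlphaGrid(),
                          method = "", pooling = "", scenario = "") {
  if (length(pvalues) == 0L)
    stop("empty input: no p-values")
  pw <- vapply(alphas, function(a) mean(pvalues <= a), numeric(1))
  new("PowerCurve", alphas = alphas, power = pw, method = method,
      pooling = pooling, scenario = scenario,
      nReplicates = length(pvalues))
}

#' Maximum absolute power difference between two pooling strategies
#'
#' `max_alpha |power_w(alpha) - power_c(alpha)|` over a shared
#' significance grid; the summary used to quantify how much the choice of
#' pooling strategy matters for a given test and scenario.
#'
#' @param curveW,curveC two [PowerCurve-class] objects on identical alpha
#'   grids.
#' @return A value in \[0, 1\].
#' @export
maxAbsPowerDifference <- function(curveW, curveC) {
  if (length(curveW@alphas) != length(curveC@alphas) ||
      any(curveW@alphas != curveC@alphas))
    stop("power curves are on different significance grids")
  max(abs(curveW@power - curveC@power))
}

#' Binomial-normal confidence interval for an empirical type-I error
#'
#' The estimate of the type-I error over n replicates is a binomial
#' proportion; the two-sided normal-approximation interval at the given
#' confidence is `nominal +/- z * sqrt(nominal (1 - nominal) / n)`,
#' clipped to \[0, 1\]. With nominal 0.05, 200 replicates and 99%
#' confidence this gives approximately (0.01, 0.09).
#'
#' @param nominal nominal significance level (e.g. 0.05).
#' @param nReplicates number of replicates behind the estimate.
#' @param confidence confidence level (default 0.99).
#' @return Named vector `c(lower, upper)` with attribute `"reported"`
#'   holding the bounds rounded to two significant figures.
#' @examples
#' type1ErrorCI(0.05, 200)
#' @export
type1ErrorCI <- function(nominal, nReplicates, confidence = 0.99) {
  stopifnot(nominal > 0, nominal < 1, nReplicates >= 1)
  z <- stats::qnorm((1 + confidence) / 2)
  half <- z * sqrt(nominal * (1 - nominal) / nReplicates)
  ci <- c(lower = max(0, nominal - half), upper = min(1, nominal + half))
  attr(ci, "reported") <- signif(ci, 2)
  ci
}

#' Run a power (or type-I error) study over simulated replicates
#'
#' Generates `nReplicates` data sets from the scenario, analyses each with
#' every requested method under every requested pooling strategy, and
#' tabulates p-values. Within a replicate all methods and pooling
#' strategies share one permutation stream, so comparisons are paired.
#' Under the `"null"` scenario the rejection fraction at the nominal
#' level is the empirical type-I error.
#'
#' @param config a [ScenarioConfig-class].
#' @param nReplicates number of replicates (default 200).
#' @param methods methods to run.
#' @param poolings pooling strategies to compare.
#' @param B permutations per test (default 1000).
#' @param alphas significance grid for the returned curves.
#' @param kernel kernel name.
#' @param verbose print a progress line every 50 replicates.
#' @return List with `pvalues` (long data.frame: replicate, method,
#'   pooling, p.value), `curves` (list of [PowerCurve-class], named
#'   `method.pooling`), and `power` (data.frame on the alpha grid).
#' @export
powerStudy <- function(config, nReplicates = 200L,
                       methods = c("mdmr", "skat", "utest", "kbat"),
                       poolings = c("weighting", "collapsing"),
                       B = 1000L, alphas = defaultAlphaGrid(),
                       kernel = "exponential", verbose = FALSE) {
  stopifnot(is(config, "ScenarioConfig"))
  rows <- vector("list", nReplicates * length(poolings))
  k <- 0L
  for (r in seq_len(nReplicates)) {
    rep_r <- generateReplicate(config, r)
    yv <- phenotypeValues(phenotype(rep_r))
    P <- permutationIndexMatrix(length(yv), B,
                                .replicateSeed(config@seed + 7L, r))
    for (pool in poolings) {
      res <- .permEngine(genotypes(rep_r), yv, pooling = pool,
                         kernel = kernel, B = B, methods = methods,
                         P = P)
      k <- k + 1L
      rows[[k]] <- data.frame(replicate = r,
                              method = names(res$pValue),
                              pooling = pool,
                              p.value = unlist(res$pValue,
                                               use.names = FALSE))
    }
    if (verbose && r %% 50L == 0L)
      message(sprintf("scenario %s: %d/%d replicates done",
                      config@name, r, nReplicates))
  }
  pv <- do.call(rbind, rows)
  curves <- list()
  for (m in unique(pv$method)) {
    for (pool in poolings) {
      sel <- pv$method == m & pv$pooling == pool
      curves[[paste(m, pool, sep = ".")]] <-
        estimatePower(pv$p.value[sel], alphas, method = m,
                      pooling = pool, scenario = config@name)
    }
  }
  tab <- do.call(rbind, lapply(curves, function(cu)
    data.frame(scenario = cu@scenario, method = cu@method,
               pooling = cu@pooling, alpha = cu@alphas,
               power = cu@power, n.replicates = cu@nReplicates)))
  rownames(tab) <- NULL
  list(pvalues = pv, curves = curves, power = tab)
}

#' Power of weighted MDMR as the weight exponent varies
#'
#' Re-analyses a batch of replicates from one scenario with modified
#' weights `w_l^p` for each exponent p in `pGrid`: p = 1 is the
#' Beta-density weighting used throughout, p = 0 the uniform-weight
#' (unweighted) analysis, intermediate p interpolates the strength of
#' rare-variant up-weighting. Within a replicate all exponents share the
#' permutation stream.
#'
#' @param config a [ScenarioConfig-class] (typically `risk_rare`).
#' @param pGrid exponents to evaluate; must contain 0 and 1.
#' @param nReplicates replicates per exponent (default 100).
#' @param B permutations (default 1000).
#' @param alpha significance level for the reported power (default 0.05).
#' @param method statistic to sweep (default `"mdmr"`).
#' @return data.frame with columns `p`, `power`, `n.replicates`.
#' @export
weightExponentSweep <- function(config, pGrid = c(0, 0.5, 1),
                                nReplicates = 100L, B = 1000L,
                                alpha = 0.05, method = "mdmr") {
  if (!any(pGrid == 0) || !any(pGrid == 1))
    stop("pGrid must include 0 (unweighted) and 1 (beta weights)")
  hits <- numeric(length(pGrid))
  for (r in seq_len(nReplicates)) {
    rep_r <- generateReplicate(config, r)
    yv <- phenotypeValues(phenotype(rep_r))
    P <- permutationIndexMatrix(length(yv), B,
                                .replicateSeed(config@seed + 7L, r))
    for (i in seq_along(pGrid)) {
      res <- .permEngine(genotypes(rep_r), yv, pooling = "weighting",
                         B = B, methods = method, P = P,
                         weightExponent = pGrid[i])
      hits[i] <- hits[i] + (res$pValue[[method]] <= alpha)
    }
  }
  data.frame(p = pGrid, power = hits / nReplicates,
             n.replicates = nReplicates)
}
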