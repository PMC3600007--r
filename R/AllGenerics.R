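#' Accessors for the core classes
#'
#' Small accessor generics in the Bioconductor style: use these rather than
#' reaching into slots.
#'
#' @param x an object of the documented class.
#' @return `genotypeCounts`: the numeric count matrix; `variantIds`:
#'   character vector of variant labels; `mafs`: numeric MAF vector;
#'   `similarityValues`: the plain N x N kernel matrix; `phenotypeValues`:
#'   numeric phenotype vector; `nCases`/`nControls`: integer group sizes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genotypeCounts", function(x) standardGeneric("genotypeCounts"))

#' @rdname accessors
#' @export
setGeneric("variantIds", function(x) standardGeneric("variantIds"))

#' @rdname accessors
#' @export
setGeneric("mafs", function(x) standardGeneric("mafs"))

#' @rdname accessors
#' @export
setGeneric("similarityValues",
           function(x) standardGeneric("similarityValues"))

#' @rdname accessors
#' @export
setGeneric("phenotypeValues",
           function(x) standardGeneric("phenotypeValues"))

#' @rdname accessors
#' @export
setGeneric("nCases", function(x) standardGeneric("nCases"))

#' @rdname accessors
#' @export
setGeneric("nControls", function(x) standardGeneric("nControls"))

#' @rdname accessors
#' @export
setMethod("genotypeCounts", "GenotypeMatrix", function(x) x@counts)

#' @rdname accessors
#' @export
setMethod("variantIds", "GenotypeMatrix",
          function(x) colnames(x@counts))

#' @rdname accessors
#' @export
setMethod("mafs", "GenotypeMatrix", function(x) x@maf)

#' @rdname accessors
#' @export
setMethod("similarityValues", "SimilarityMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("similarityValues", "matrix", function(x) x)

#' @rdname accessors
#' @export
setMethod("phenotypeValues", "PhenotypeVector", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("nCases", "PhenotypeVector", function(x) {
  if (x@coding == "quantitative")
    stop("nCases is undefined for a quantitative phenotype")
  sum(x@values == 1)  # cases are coded 1 in both binary codings
})

#' @rdname accessors
#' @export
setMethod("nControls", "PhenotypeVector", function(x) {
  if (x@coding == "quantitative")
    stop("nControls is undefined for a quantitative phenotype")
  sum(x@values == if (x@coding == "zero_one") 0 else -1)
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d individuals x %d variants%s\n",
              nrow(object@counts), ncol(object@counts),
              if (object@adjusted) " (adjusted, real-valued)" else ""))
  if (length(object@maf))
    cat(sprintf("  MAF range [%.4g, %.4g]; %d rare at MAF <= 0.01\n",
                min(object@maf), max(object@maf),
                sum(object@maf <= 0.01)))
})

setMethod("show", "PhenotypeVector", function(object) {
  if (object@coding == "quantitative") {
    cat(sprintf("PhenotypeVector: %d quantitative values\n",
                length(object@values)))
  } else {
    cat(sprintf("PhenotypeVector (%s): %d cases / %d controls\n",
                object@coding, nCases(object), nControls(object)))
  }
})

setMethod("show", "SimilarityMatrix", function(object) {
  cat(sprintf("SimilarityMatrix: %d x %d, kernel = %s%s\n",
              nrow(object@values), ncol(object@values), object@kernel,
              if (object@weighted) " (weighted)" else ""))
})

setMethod("show", "PooledGenotype", function(object) {
  cat(sprintf(
    "PooledGenotype: %d common variants + super-locus (threshold %.3g)\n",
    ncol(object@common@counts), object@threshold))
  tb <- table(factor(object@superLocus, levels = 0:2))
  cat(sprintf("  super-locus counts 0/1/2: %s\n",
              paste(tb, collapse = "/")))
})

setMethod("show", "TestResult", function(object) {
  cat(sprintf("TestResult: %s statistic = %.6g, p = %.4g (B = %d)\n",
              toupper(object@method), object@statistic, object@pValue,
              object@nPermutations))
})

setMethod("show", "ScenarioConfig", function(object) {
  cat(sprintf(
    "ScenarioConfig '%s': %d cases / %d controls, %d variants\n",
    object@name, object@nCases, object@nControls, object@nVariants))
  cat(sprintf("  rare fraction %.2f (MAF <= %.3g), effects rare %.3g / common %.3g\n",
              object@rareFraction, object@rareThreshold,
              object@rareEffect, object@commonEffect))
})

setMethod("show", "PowerCurve", function(object) {
  cat(sprintf("PowerCurve: %s / %s / %s over %d replicates\n",
              object@scenario, object@method, object@pooling,
              object@nReplicates))
  print(stats::setNames(object@power, format(object@alphas)))
})
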