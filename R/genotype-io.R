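#' Construct a GenotypeMatrix
#'
#' Validating constructor. Raw input (entries in \{0, 1, 2\}, possibly with
#' `NA` for missing calls) is mean-imputed per variant and oriented to the
#' minor allele: any column whose coded-allele frequency exceeds 0.5 is
#' recoded as `2 - count`, so that `mafs(x)` always refers to the less
#' common allele.
#'
#' @param counts numeric matrix, individuals in rows, variants in columns.
#' @param variantIds optional character vector of column labels; defaults
#'   to existing column names or `v1, v2, ...`.
#' @param adjusted set `TRUE` for real-valued (stratification-adjusted)
#'   matrices; orientation and the \{0,1,2\} entry check are then skipped
#'   and `maf` must be supplied.
#' @param maf optional per-variant MAF; computed from `counts` when `NULL`.
#' @param orient orient columns to the minor allele (default `TRUE` for
#'   raw input).
#' @return A [GenotypeMatrix-class] object.
#' @examples
#' g <- GenotypeMatrix(matrix(c(0, 1, 2, 0, 0, 1), nrow = 3))
#' mafs(g)
#' @export
GenotypeMatrix <- function(counts, variantIds = NULL, adjusted = FALSE,
                           maf = NULL, orient = !adjusted) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(variantIds))
    variantIds <- colnames(counts)
  if (is.null(variantIds))
    variantIds <- paste0("v", seq_len(ncol(counts)))
  colnames(counts) <- variantIds
  if (nrow(counts) == 0L)
    stop("empty input: no individuals")
  if (!adjusted) {
    bad <- which(!(counts %in% c(0, 1, 2) | is.na(counts)))
    if (length(bad)) {
      rc <- arrayInd(bad[1L], dim(counts))
      stop(sprintf(
        "invalid genotype entry %s at individual %d, variant '%s': raw counts must be 0, 1, 2 or missing",
        format(counts[bad[1L]]), rc[1L], variantIds[rc[2L]]))
    }
    nmiss <- sum(is.na(counts))
    if (nmiss > 0L) {
      message(sprintf("mean-imputed %d missing genotype call(s)", nmiss))
      for (l in seq_len(ncol(counts))) {
        miss <- is.na(counts[, l])
        if (any(miss)) {
          mu <- mean(counts[!miss, l])
          if (!is.finite(mu)) mu <- 0
          counts[miss, l] <- mu
        }
      }
      adjusted <- TRUE  # imputed entries are real-valued
    }
    if (orient) {
      af <- colMeans(counts) / 2
      flip <- af > 0.5
      if (any(flip))
        counts[, flip] <- 2 - counts[, flip]
    }
  }
  if (is.null(maf)) {
    maf <- colMeans(counts) / 2
    maf <- pmin(pmax(maf, 0), 0.5)
  }
  new("GenotypeMatrix", counts = counts, maf = as.numeric(maf),
      adjusted = adjusted)
}

#' Construct a PhenotypeVector
#'
#' @param values numeric phenotype values.
#' @param coding `"auto"` (infer from the values), `"plus_minus_one"`,
#'   `"zero_one"` or `"quantitative"`.
#' @return A [PhenotypeVector-class] object.
#' @export
phenotypeVector <- function(values,
                            coding = c("auto", "plus_minus_one",
                                       "zero_one", "quantitative")) {
  coding <- match.arg(coding)
  values <- as.numeric(values)
  if (coding == "auto") {
    coding <- if (all(values %in% c(-1, 1))) "plus_minus_one"
      else if (all(values %in% c(0, 1))) "zero_one"
      else "quantitative"
  }
  new("PhenotypeVector", values = values, coding = coding)
}

#' Convert a binary phenotype between codings
#'
#' @param y a [PhenotypeVector-class] with binary coding.
#' @param coding target coding, `"plus_minus_one"` or `"zero_one"`.
#' @return A [PhenotypeVector-class] in the requested coding.
#' @export
recodePhenotype <- function(y, coding = c("plus_minus_one", "zero_one")) {
  coding <- match.arg(coding)
  stopifnot(is(y, "PhenotypeVector"))
  if (y@coding == "quantitative")
    stop("cannot recode a quantitative phenotype to a binary coding")
  if (y@coding == coding) return(y)
  v <- if (coding == "zero_one") (y@values + 1) / 2 else 2 * y@values - 1
  new("PhenotypeVector", values = v, coding = coding)
}

#' Per-variant minor allele frequency
#'
#' `maf_l = sum_n(g_nl) / (2N)` on counts oriented to the minor allele.
#'
#' @param g a [GenotypeMatrix-class] or numeric count matrix.
#' @return Numeric vector of length L with values in \[0, 0.5\].
#' @export
computeMaf <- function(g) {
  cts <- if (is(g, "GenotypeMatrix")) genotypeCounts(g) else as.matrix(g)
  if (nrow(cts) == 0L)
    stop("empty input: no individuals")
  colMeans(cts) / 2
}

#' Read genotypes from a VCF or delimited count matrix
#'
#' Builds a [GenotypeMatrix-class] from either a VCF 4.x file (biallelic
#' records only; genotype phase is ignored) or a plain delimited matrix
#' with one header row of variant identifiers and one leading column of
#' sample identifiers. Counts are oriented to the minor allele: at sites
#' where the VCF ALT allele is the major allele the column is recoded as
#' `2 - count`. Missing genotypes are mean-imputed per variant (with a
#' message). Monomorphic variants carry no similarity information and the
#' Beta-density weight at MAF 0 is maximal, so they are dropped by default
#' with a warning.
#'
#' @param path path to the input file.
#' @param format `"auto"` (by extension), `"vcf"` or `"matrix"`.
#' @param dropMonomorphic drop variants with MAF 0 (default `TRUE`).
#' @return A [GenotypeMatrix-class].
#' @export
readGenotypes <- function(path, format = c("auto", "vcf", "matrix"),
                          dropMonomorphic = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "matrix"
  }
  g <- if (format == "vcf") .readVcfCounts(path) else .readMatrixCounts(path)
  g <- GenotypeMatrix(g$counts, variantIds = g$ids)
  if (dropMonomorphic && any(mafs(g) == 0)) {
    nmono <- sum(mafs(g) == 0)
    warning(sprintf("dropped %d monomorphic variant(s) (MAF = 0)", nmono))
    keep <- mafs(g) > 0
    if (!any(keep))
      stop("all variants are monomorphic")
    g <- g[, keep]
  }
  g
}

.readVcfCounts <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi))
    stop(sprintf("multi-allelic record(s) not supported: %s",
                 paste(fix[multi, "ID"], collapse = ", ")))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt))
    stop("VCF has no GT genotype field")
  # count ALT alleles; '|' and '/' separators both accepted (phase ignored)
  cnt <- apply(gt, c(1, 2), function(x) {
    if (is.na(x) || x %in% c(".", "./.", ".|.")) return(NA_real_)
    al <- strsplit(x, "[/|]")[[1L]]
    if (any(al == ".")) return(NA_real_)
    if (!all(al %in% c("0", "1")))
      stop(sprintf("allele index outside {0,1} in genotype '%s'", x))
    sum(al == "1")
  })
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], ":", fix[noid, "POS"])
  list(counts = t(cnt), ids = ids)
}

.readMatrixCounts <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                      check.names = FALSE),
    error = function(e) stop(sprintf("malformed matrix file %s: %s",
                                     path, conditionMessage(e))))
  m <- as.matrix(tab)
  if (!is.numeric(m)) {
    badcol <- which(!vapply(tab, is.numeric, logical(1)))[1L]
    badrow <- which(is.na(suppressWarnings(as.numeric(tab[[badcol]]))))[1L]
    stop(sprintf("malformed matrix file %s: non-numeric entry at line %d, column '%s'",
                 path, badrow + 1L, colnames(tab)[badcol]))
  }
  list(counts = m, ids = colnames(m))
}

#' Write a GenotypeMatrix to the delimited matrix format
#'
#' Tab-delimited, one header row of variant identifiers and one leading
#' column of sample identifiers; round-trips exactly through
#' [readGenotypes()] for raw integer counts.
#'
#' @param g a [GenotypeMatrix-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGenotypeMatrix <- function(g, path) {
  stopifnot(is(g, "GenotypeMatrix"))
  cts <- genotypeCounts(g)
  ids <- rownames(cts)
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(cts)))
  df <- data.frame(sample = ids, cts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Subset a GenotypeMatrix by individuals or variants
#'
#' MAFs are carried over for retained variants (not recomputed, so a
#' sample subset keeps the full-sample frequencies; rebuild with
#' [GenotypeMatrix()] to re-estimate).
#'
#' @param x a [GenotypeMatrix-class].
#' @param i,j individual and variant indices.
#' @param ... ignored.
#' @param drop ignored (always `FALSE`).
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@counts))
  if (missing(j)) j <- seq_len(ncol(x@counts))
  jj <- seq_len(ncol(x@counts))[if (is.logical(j)) which(j) else j]
  new("GenotypeMatrix", counts = x@counts[i, jj, drop = FALSE],
      maf = x@maf[jj], adjusted = x@adjusted)
})
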