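#' @import methods
NULL

#' Mapped, stage-labelled diploid SSR genotypes
#'
#' Central data container of the package. Holds, for `n` individuals typed at
#' `L` codominant microsatellite loci, the two allele codes per locus (as two
#' integer matrices, `NA` for missing calls -- a call is either complete or
#' fully missing, half-calls are rejected), together with per-individual
#' metadata: a unique `id`, an ontogenetic `stage` label (free text; the
#' conventional labels are `"reproductive"`, `"immature"`, `"young"`,
#' `"seedling"`) and planar map coordinates `x`, `y` in meters.
#'
#' @slot info data.frame with columns `id`, `stage`, `x`, `y` (one row per
#'   individual; ids unique, coordinates finite).
#' @slot loci character vector of locus names (ordered).
#' @slot allele1,allele2 integer matrices (`n x L`, rows named by id, columns
#'   by locus) of positive allele codes; `NA` marks a missing call and must
#'   agree between the two matrices.
#'
#' @seealso [readGenotypes()], [alleleFrequencies()], [simulatePopulation()]
#' @export
setClass("GenotypeDataset",
  representation(
    info    = "data.frame",
    loci    = "character",
    allele1 = "matrix",
    allele2 = "matrix"
  )
)

setValidity("GenotypeDataset", function(object) {
  msg <- character()
  info <- object@info
  if (!all(c("id", "stage", "x", "y") %in% names(info)))
    msg <- c(msg, "info must have columns id, stage, x, y")
  else {
    if (anyDuplicated(info$id)) msg <- c(msg, "individual ids must be unique")
    if (!all(is.finite(info$x)) || !all(is.finite(info$y)))
      msg <- c(msg, "coordinates must be finite")
  }
  if (length(object@loci) < 1L) msg <- c(msg, "at least one locus required")
  if (nrow(info) < 2L) msg <- c(msg, "at least two individuals required")
  a1 <- object@allele1; a2 <- object@allele2
  if (!identical(dim(a1), dim(a2)))
    msg <- c(msg, "allele matrices must have identical dimensions")
  else {
    if (nrow(a1) != nrow(info) || ncol(a1) != length(object@loci))
      msg <- c(msg, "allele matrices must be n individuals x n loci")
    if (!identical(is.na(a1), is.na(a2)))
      msg <- c(msg, "half-calls not allowed: allele1/allele2 missingness must agree")
    if (any(a1 <= 0L, na.rm = TRUE) || any(a2 <= 0L, na.rm = TRUE))
      msg <- c(msg, "allele codes must be positive integers")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeDataset
#'
#' @param info data.frame with columns `id`, `stage`, `x`, `y`.
#' @param loci character vector of locus names.
#' @param allele1,allele2 integer matrices (individuals x loci) of allele
#'   codes, `NA` for missing calls.
#' @return A [GenotypeDataset-class] object.
#' @export
GenotypeDataset <- function(info, loci, allele1, allele2) {
  info$id <- as.character(info$id)
  info$stage <- as.character(info$stage)
  storage.mode(allele1) <- "integer"
  storage.mode(allele2) <- "integer"
  dimnames(allele1) <- dimnames(allele2) <- list(info$id, loci)
  new("GenotypeDataset", info = info, loci = as.character(loci),
      allele1 = allele1, allele2 = allele2)
}

setMethod("show", "GenotypeDataset", function(object) {
  st <- table(object@info$stage)
  cat("GenotypeDataset:", nrow(object@info), "individuals,",
      length(object@loci), "loci\n")
  cat("  stages:", paste(sprintf("%s (%d)", names(st), st), collapse = ", "), "\n")
  miss <- mean(is.na(object@allele1))
  cat(sprintf("  missing calls: %.1f%%\n", 100 * miss))
})

#' Per-locus allele frequency table
#'
#' Relative allele frequencies per locus computed from non-missing calls,
#' together with the gene count (2 x genotyped individuals) and the number of
#' genotyped individuals per locus. Reference frequencies for the coancestry
#' and parentage likelihood machinery.
#'
#' @slot freqs named list, one element per locus: named numeric vector of
#'   relative frequencies (names are allele codes), each summing to 1.
#' @slot geneCounts named integer vector: gene copies counted per locus.
#' @slot sampleSizes named integer vector: genotyped individuals per locus.
#' @export
setClass("AlleleFrequencyTable",
  representation(
    freqs       = "list",
    geneCounts  = "integer",
    sampleSizes = "integer"
  )
)

setValidity("AlleleFrequencyTable", function(object) {
  msg <- character()
  for (l in names(object@freqs)) {
    p <- object@freqs[[l]]
    if (abs(sum(p) - 1) > 1e-9)
      msg <- c(msg, sprintf("frequencies at locus %s do not sum to 1", l))
    if (any(p <= 0) || any(p > 1))
      msg <- c(msg, sprintf("frequencies at locus %s outside (0, 1]", l))
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "AlleleFrequencyTable", function(object) {
  k <- vapply(object@freqs, length, 1L)
  cat("AlleleFrequencyTable:", length(object@freqs), "loci,",
      sum(k), "alleles (", min(k), "-", max(k), "per locus )\n")
})

#' Pairwise Loiselle coancestry matrix
#'
#' Symmetric matrix of multilocus pairwise coancestry (kinship) coefficients
#' \eqn{\theta_{ij}} estimated with the Loiselle et al. (1995) estimator,
#' relative to the reference allele frequencies of the analysed group. The
#' diagonal is `NA` and excluded from all downstream means.
#'
#' @slot theta symmetric numeric matrix (diagonal `NA`; an off-diagonal `NA`
#'   marks a pair with no shared typed polymorphic locus), row/col names are
#'   ids.
#' @slot stage character label of the analysed group.
#' @slot lociWeights numeric vector of per-locus polymorphism weights
#'   \eqn{\sum_a \bar p_a (1 - \bar p_a)} actually used.
#' @export
setClass("CoancestryMatrix",
  representation(
    theta       = "matrix",
    stage       = "character",
    lociWeights = "numeric"
  )
)

setValidity("CoancestryMatrix", function(object) {
  th <- object@theta
  off <- th[upper.tri(th)]
  msg <- character()
  if (nrow(th) != ncol(th)) msg <- c(msg, "theta must be square")
  if (any(is.nan(off) | is.infinite(off)))
    msg <- c(msg, "off-diagonal theta must be finite or NA")
  if (max(abs(th - t(th)), na.rm = TRUE) > 1e-12)
    msg <- c(msg, "theta must be symmetric")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CoancestryMatrix", function(object) {
  off <- object@theta[upper.tri(object@theta)]
  cat("CoancestryMatrix (", object@stage, "): ", nrow(object@theta),
      " individuals, mean theta = ", signif(mean(off, na.rm = TRUE), 3),
      "\n", sep = "")
})

#' Exponential-power dispersal kernel parameters
#'
#' Two-parameter isotropic dispersal density with scale `a` (meters) and shape
#' `b` (dimensionless): `b < 1` fat-tailed, `b = 1` exponential, `b = 2`
#' Gaussian. The derived mean dispersal distance is
#' \eqn{\delta = a\,\Gamma(3/b)/\Gamma(2/b)}.
#'
#' @slot a positive numeric scale, meters.
#' @slot b positive numeric shape.
#' @seealso [expPowerPdf()], [kernelMeanDistance()], [sampleKernel()]
#' @export
setClass("KernelParams", representation(a = "numeric", b = "numeric"))

setValidity("KernelParams", function(object) {
  if (length(object@a) != 1L || length(object@b) != 1L)
    return("a and b must be scalars")
  if (!is.finite(object@a) || object@a <= 0) return("a must be > 0")
  if (!is.finite(object@b) || object@b <= 0) return("b must be > 0")
  TRUE
})

#' @param a scale parameter (m), > 0.
#' @param b shape parameter, > 0.
#' @return A [KernelParams-class] object.
#' @rdname KernelParams-class
#' @export
KernelParams <- function(a, b) new("KernelParams", a = as.numeric(a), b = as.numeric(b))

setMethod("show", "KernelParams", function(object) {
  cat(sprintf("KernelParams: a = %.4g m, b = %.4g (mean distance %.4g m)\n",
              object@a, object@b, kernelMeanDistance(object)))
})
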