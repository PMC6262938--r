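#' Accessors for GenotypeDataset and friends
#'
#' Small accessor generics: number of individuals/loci, locus names, stage
#' labels, coordinates, and the two allele-call matrices.
#'
#' @param x a [GenotypeDataset-class] (or, where noted, another class).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))
#' @rdname accessors
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))
#' @rdname accessors
#' @export
setGeneric("lociNames", function(x) standardGeneric("lociNames"))
#' @rdname accessors
#' @export
setGeneric("stages", function(x) standardGeneric("stages"))
#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
#' @rdname accessors
#' @export
setGeneric("alleleCalls", function(x) standardGeneric("alleleCalls"))
#' @rdname accessors
#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))
#' @rdname accessors
#' @export
setGeneric("thetaMatrix", function(x) standardGeneric("thetaMatrix"))

#' @rdname accessors
setMethod("nIndividuals", "GenotypeDataset", function(x) nrow(x@info))
#' @rdname accessors
setMethod("nLoci", "GenotypeDataset", function(x) length(x@loci))
#' @rdname accessors
setMethod("lociNames", "GenotypeDataset", function(x) x@loci)
#' @rdname accessors
setMethod("stages", "GenotypeDataset", function(x) x@info$stage)
#' @rdname accessors
setMethod("coords", "GenotypeDataset", function(x)
  as.matrix(x@info[, c("x", "y")]))
#' @rdname accessors
setMethod("alleleCalls", "GenotypeDataset", function(x)
  list(allele1 = x@allele1, allele2 = x@allele2))
#' @rdname accessors
setMethod("individualIds", "GenotypeDataset", function(x) x@info$id)
#' @rdname accessors
setMethod("thetaMatrix", "CoancestryMatrix", function(x) x@theta)

#' Subset a GenotypeDataset by individual
#'
#' @param x a [GenotypeDataset-class].
#' @param i integer, logical or character (id) index of individuals to keep.
#' @param j,...,drop ignored.
#' @return A [GenotypeDataset-class] with the selected individuals.
#' @export
setMethod("[", "GenotypeDataset", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@info$id)
  info <- x@info[i, , drop = FALSE]
  rownames(info) <- NULL
  GenotypeDataset(info, x@loci,
                  x@allele1[i, , drop = FALSE],
                  x@allele2[i, , drop = FALSE])
})

#' Subset a GenotypeDataset to one or more ontogenetic stages
#'
#' @param x a [GenotypeDataset-class].
#' @param stage character vector of stage labels to keep.
#' @return A [GenotypeDataset-class].
#' @export
subsetStage <- function(x, stage) {
  keep <- x@info$stage %in% stage
  if (!any(keep)) stop("no individuals in stage(s): ",
                       paste(stage, collapse = ", "))
  x[which(keep)]
}
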