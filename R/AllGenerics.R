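# Generics and accessors.

#' @name accessors
#' @title Accessors for dsmlink objects
#' @description Slot accessors for the package's S4 classes; user code should
#'   prefer these over direct slot access.
#' @param x an object.
#' @return the requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("alleles", function(x) standardGeneric("alleles"))
#' @rdname accessors
#' @export
setMethod("alleles", "HaplotypePanel", function(x) x@alleles)

#' @rdname accessors
#' @export
setGeneric("variantIds", function(x) standardGeneric("variantIds"))
#' @rdname accessors
#' @export
setMethod("variantIds", "HaplotypePanel", function(x) x@variantIds)
#' @rdname accessors
#' @export
setMethod("variantIds", "EQTLMap", function(x) x@variantIds)

#' @rdname accessors
#' @export
setGeneric("physicalPos", function(x) standardGeneric("physicalPos"))
#' @rdname accessors
#' @export
setMethod("physicalPos", "HaplotypePanel", function(x) x@positions)

#' @rdname accessors
#' @export
setGeneric("geneticPos", function(x) standardGeneric("geneticPos"))
#' @rdname accessors
#' @export
setMethod("geneticPos", "HaplotypePanel", function(x) x@geneticPos)

#' @rdname accessors
#' @export
setGeneric("nHaplotypes", function(x) standardGeneric("nHaplotypes"))
#' @rdname accessors
#' @export
setMethod("nHaplotypes", "HaplotypePanel", function(x) nrow(x@alleles))

#' @rdname accessors
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))
#' @rdname accessors
#' @export
setMethod("nVariants", "HaplotypePanel", function(x) ncol(x@alleles))

#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setMethod("sampleId", "GenotypeProfile", function(x) x@sampleId)
#' @rdname accessors
#' @export
setMethod("sampleId", "ExpressionProfile", function(x) x@sampleId)

#' @rdname accessors
#' @export
setGeneric("maternal", function(x) standardGeneric("maternal"))
#' @rdname accessors
#' @export
setMethod("maternal", "GenotypeProfile", function(x) x@maternal)

#' @rdname accessors
#' @export
setGeneric("paternal", function(x) standardGeneric("paternal"))
#' @rdname accessors
#' @export
setMethod("paternal", "GenotypeProfile", function(x) x@paternal)

#' @rdname accessors
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))
#' @rdname accessors
#' @export
setMethod("dosage", "GenotypeProfile", function(x) x@maternal + x@paternal)

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setMethod("geneIds", "ExpressionProfile", function(x) x@geneIds)

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setMethod("exprValues", "ExpressionProfile",
          function(x) stats::setNames(x@values, x@geneIds))

#' @rdname accessors
#' @export
setGeneric("siteIndex", function(x) standardGeneric("siteIndex"))
#' @rdname accessors
#' @export
setMethod("siteIndex", "EQTLMap", function(x) x@siteIndex)

#' @rdname accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))
#' @rdname accessors
#' @export
setMethod("geneSets", "EQTLMap", function(x) x@geneSets)

#' @rdname accessors
#' @export
setGeneric("scorerName", function(x) standardGeneric("scorerName"))
#' @rdname accessors
#' @export
setMethod("scorerName", "ScoreMatrix", function(x) x@scorer)

#' Score all query-candidate pairs
#'
#' Computes the full matrix of log match scores between query expression
#' profiles and candidate genotype profiles under a trained scorer; dispatch
#' is on the parameter class ([DSMParams-class], [GNBParams-class],
#' [EBLParams-class], or a list of window-wise [DSMParams-class]).
#'
#' @param queries list of [ExpressionProfile-class] (or one profile).
#' @param candidates list of [GenotypeProfile-class] (or one profile).
#' @param params trained scorer parameters.
#' @param ... passed to methods.
#' @return a [ScoreMatrix-class] with one row per query and one column per
#'   candidate; entries are log match scores and are independent of the order
#'   in which profiles are supplied.
#' @export
setGeneric("scoreAll", function(queries, candidates, params, ...)
  standardGeneric("scoreAll"))

#' Pairwise log match score
#'
#' Log match score of one candidate genotype profile for one query expression
#' profile; dispatch on the parameter class.
#'
#' @param x a [GenotypeProfile-class].
#' @param e an [ExpressionProfile-class].
#' @param params trained scorer parameters.
#' @param ... passed to methods.
#' @return a single log match score.
#' @export
setGeneric("logScore", function(x, e, params, ...) standardGeneric("logScore"))
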