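#' Accessors for panmut classes
#'
#' @param object a panmut S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("variantCalls", function(object) standardGeneric("variantCalls"))

#' @rdname accessors
#' @export
setMethod("variantCalls", "MutationCohort", function(object) object@calls)

#' @rdname accessors
#' @export
setGeneric("sampleInfo", function(object) standardGeneric("sampleInfo"))

#' @rdname accessors
#' @export
setMethod("sampleInfo", "MutationCohort", function(object) object@samples)

#' @rdname accessors
#' @export
setGeneric("annotatedGenes", function(object) standardGeneric("annotatedGenes"))

#' @rdname accessors
#' @export
setMethod("annotatedGenes", "GenomeAnnotation", function(object) object@genes)

#' @rdname accessors
#' @export
setGeneric("operons", function(object) standardGeneric("operons"))

#' @rdname accessors
#' @export
setMethod("operons", "GenomeAnnotation", function(object) object@operons)

#' @rdname accessors
#' @export
setGeneric("pathways", function(object) standardGeneric("pathways"))

#' @rdname accessors
#' @export
setMethod("pathways", "GenomeAnnotation", function(object) object@pathways)

#' @rdname accessors
#' @export
setGeneric("pssm", function(object) standardGeneric("pssm"))

#' @rdname accessors
#' @export
setMethod("pssm", "ProfileModel", function(object) object@pssm)

#' @rdname accessors
#' @export
setGeneric("coreVariants", function(object) standardGeneric("coreVariants"))

#' @rdname accessors
#' @export
setMethod("coreVariants", "PanGenomePartition", function(object) object@core)

#' Partition sets as a named list
#'
#' @param object a \linkS4class{PanGenomePartition}.
#' @return list with elements core, shared, unique, discarded and fractions.
#' @export
setGeneric("partitionSets", function(object) standardGeneric("partitionSets"))

#' @rdname partitionSets
#' @export
setMethod("partitionSets", "PanGenomePartition", function(object) {
  list(core = object@core, shared = object@shared, unique = object@unique,
       discarded = object@discarded, fractions = object@fractions)
})

wild_type_id <- function(samples) samples$sample_id[samples$role == "wild_type"]

isolate_ids <- function(samples) samples$sample_id[samples$role == "isolate"]

population_ids <- function(samples) {
  pop <- samples[samples$role == "population", , drop = FALSE]
  pop$sample_id[order(pop$stage_index)]
}
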