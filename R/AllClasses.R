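#' @importFrom methods new validObject is setClass setGeneric setMethod
#'   setValidity show slot
NULL

VALID_ROLES <- c("wild_type", "population", "isolate")
VALID_FLAGS <- c("hc", "fp", "ise", "sv")
VALID_CLASSES <- c("snp", "indel", "structural")

#' MutationCohort: a resequenced ALE cohort
#'
#' Container for one adaptive-laboratory-evolution sequencing cohort: the
#' sample sheet (one wild-type ancestor, serially sampled intermediate
#' populations, endpoint single-colony isolates) and the per-sample variant
#' observations reported by the upstream caller.
#'
#' The \code{samples} slot is a data.frame with columns \code{sample_id},
#' \code{role} (\code{wild_type}/\code{population}/\code{isolate}),
#' \code{stage_index} (ordinal position in the serial-transfer history;
#' wild type is 0, isolates carry the final population stage) and
#' \code{stage_label} (free text, e.g. a hydrolysate concentration).
#'
#' The \code{calls} slot is a data.frame with one row per (variant, sample)
#' observation: \code{variant_id} (\code{chrom:pos:ref>alt}),
#' \code{sample_id}, \code{position} (1-based on the reference),
#' \code{ref_allele} / \code{alt_allele} (bases, or \code{"-"} for the empty
#' side of an indel), \code{caller_class} (\code{snp}/\code{indel}/
#' \code{structural}), \code{confidence_flag} (\code{hc}/\code{fp}/
#' \code{ise}/\code{sv}) and \code{allele_frequency} (in [0,1] for
#' population observations; \code{NA} for wild-type and isolate
#' observations, which are treated as fixed).
#'
#' @slot samples data.frame, the sample sheet.
#' @slot calls data.frame, the variant observations.
#' @export
setClass("MutationCohort",
  representation(samples = "data.frame", calls = "data.frame"))

setValidity("MutationCohort", function(object) {
  s <- object@samples
  v <- object@calls
  msgs <- character()
  need_s <- c("sample_id", "role", "stage_index", "stage_label")
  if (!all(need_s %in% names(s)))
    return(paste("sample sheet must have columns:",
                 paste(need_s, collapse = ", ")))
  if (anyDuplicated(s$sample_id))
    msgs <- c(msgs, "duplicated sample_id in sample sheet")
  if (!all(s$role %in% VALID_ROLES))
    msgs <- c(msgs, "role must be wild_type, population or isolate")
  if (sum(s$role == "wild_type") != 1)
    msgs <- c(msgs, "exactly one wild_type sample is required")
  pop <- s[s$role == "population", , drop = FALSE]
  if (nrow(pop) > 1) {
    ord <- pop$stage_index[order(pop$stage_index)]
    if (any(diff(ord) <= 0))
      msgs <- c(msgs, "population stage_index must be strictly increasing")
  }
  if (nrow(pop) > 0 && any(s$stage_index[s$role == "isolate"] !=
                           max(pop$stage_index)))
    msgs <- c(msgs, "isolate stage_index must equal final population stage")
  if (any(s$stage_index < 0)) msgs <- c(msgs, "stage_index must be >= 0")
  need_v <- c("variant_id", "sample_id", "position", "ref_allele",
              "alt_allele", "caller_class", "confidence_flag",
              "allele_frequency")
  if (!all(need_v %in% names(v)))
    return(paste("calls must have columns:", paste(need_v, collapse = ", ")))
  if (nrow(v) > 0) {
    if (!all(v$sample_id %in% s$sample_id))
      msgs <- c(msgs, "calls reference unknown sample_ids")
    if (any(v$position < 1)) msgs <- c(msgs, "position must be >= 1")
    if (any(v$ref_allele == v$alt_allele))
      msgs <- c(msgs, "ref_allele must differ from alt_allele")
    if (!all(v$caller_class %in% VALID_CLASSES))
      msgs <- c(msgs, "caller_class must be snp, indel or structural")
    if (!all(v$confidence_flag %in% VALID_FLAGS))
      msgs <- c(msgs, "confidence_flag must be one of hc, fp, ise, sv")
    af <- v$allele_frequency
    if (any(!is.na(af) & (af < 0 | af > 1)))
      msgs <- c(msgs, "allele_frequency must lie in [0, 1]")
    role_of <- stats::setNames(s$role, s$sample_id)
    bad <- is.na(af) & !(role_of[v$sample_id] %in% c("wild_type", "isolate"))
    if (any(bad))
      msgs <- c(msgs,
        "population observations must carry an allele_frequency")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a MutationCohort
#'
#' @param calls data.frame of variant observations (see
#'   \linkS4class{MutationCohort}).  Missing \code{allele_frequency} column
#'   is filled with \code{NA}.
#' @param samples data.frame sample sheet.
#' @return A validated \linkS4class{MutationCohort}.
#' @export
#' @examples
#' samples <- data.frame(sample_id = c("WT", "P1", "I1"),
#'                       role = c("wild_type", "population", "isolate"),
#'                       stage_index = c(0L, 1L, 1L),
#'                       stage_label = c("ancestor", "5%", "isolate"))
#' calls <- data.frame(variant_id = "chr:100:A>G", sample_id = "I1",
#'                     position = 100L, ref_allele = "A", alt_allele = "G",
#'                     caller_class = "snp", confidence_flag = "hc",
#'                     allele_frequency = NA_real_)
#' MutationCohort(calls, samples)
MutationCohort <- function(calls, samples) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  calls <- as.data.frame(calls, stringsAsFactors = FALSE)
  if (!"allele_frequency" %in% names(calls) && nrow(calls) >= 0)
    calls$allele_frequency <- rep(NA_real_, nrow(calls))
  if (nrow(calls) == 0)
    calls <- empty_calls()
  samples$stage_index <- as.integer(samples$stage_index)
  calls$position <- as.integer(calls$position)
  calls$allele_frequency <- as.numeric(calls$allele_frequency)
  new("MutationCohort", samples = samples, calls = calls)
}

empty_calls <- function() {
  data.frame(variant_id = character(), sample_id = character(),
             position = integer(), ref_allele = character(),
             alt_allele = character(), caller_class = character(),
             confidence_flag = character(),
             allele_frequency = numeric(), stringsAsFactors = FALSE)
}

#' GenomeAnnotation: genes, operons and pathway membership
#'
#' @slot genes A \link[GenomicRanges]{GRanges} of CDS features carrying
#'   \code{locus_tag} and \code{product} metadata columns, sorted by start.
#' @slot operons Named list; each element an ordered character vector of
#'   locus_tags forming one transcription unit.
#' @slot pathways Named list; each element a character vector (set) of
#'   locus_tags sharing one pathway.
#' @slot referenceLength Integer length of the reference sequence.
#' @export
setClass("GenomeAnnotation",
  representation(genes = "GRanges", operons = "list", pathways = "list",
                 referenceLength = "integer"))

setValidity("GenomeAnnotation", function(object) {
  g <- object@genes
  msgs <- character()
  if (!"locus_tag" %in% names(S4Vectors::mcols(g)))
    return("genes must carry a locus_tag metadata column")
  lt <- g$locus_tag
  if (anyDuplicated(lt)) msgs <- c(msgs, "duplicated locus_tag")
  if (length(g) && (min(GenomicRanges::start(g)) < 1 ||
                    max(GenomicRanges::end(g)) > object@referenceLength))
    msgs <- c(msgs, "gene intervals must lie within [1, referenceLength]")
  for (nm in names(object@operons))
    if (!all(object@operons[[nm]] %in% lt))
      msgs <- c(msgs, sprintf("operon '%s' references unknown locus_tag", nm))
  for (nm in names(object@pathways))
    if (!all(object@pathways[[nm]] %in% lt))
      msgs <- c(msgs, sprintf("pathway '%s' references unknown locus_tag", nm))
  if (length(msgs)) msgs else TRUE
})

#' Construct a GenomeAnnotation
#'
#' @param genes GRanges with \code{locus_tag} (and optionally
#'   \code{product}) metadata columns.
#' @param operons named list of locus_tag vectors (default none).
#' @param pathways named list of locus_tag vectors (default none).
#' @param referenceLength reference sequence length in bp; defaults to the
#'   largest gene end coordinate.
#' @return A validated \linkS4class{GenomeAnnotation} with genes sorted by
#'   start coordinate.
#' @export
GenomeAnnotation <- function(genes, operons = list(), pathways = list(),
                             referenceLength = NULL) {
  if (!"product" %in% names(S4Vectors::mcols(genes)))
    genes$product <- rep(NA_character_, length(genes))
  genes <- genes[order(GenomicRanges::start(genes))]
  if (is.null(referenceLength))
    referenceLength <- if (length(genes)) max(GenomicRanges::end(genes)) else 0L
  new("GenomeAnnotation", genes = genes, operons = operons,
      pathways = pathways, referenceLength = as.integer(referenceLength))
}

#' ProfileModel: a protein-domain position-specific scoring matrix
#'
#' Per-position, per-residue scores over a protein-family domain.  The
#' difference between the mutant and reference residue scores at the
#' substituted position predicts a potential gain (positive) or loss
#' (negative) of protein function.
#'
#' @slot modelId Model identifier.
#' @slot domainLocus Locus tag of the protein the domain maps onto.
#' @slot proteinStart,proteinEnd 1-based span of the domain on the protein.
#' @slot pssm Numeric matrix, domain positions x 20 standard residues
#'   (columns named by one-letter code).
#' @export
setClass("ProfileModel",
  representation(modelId = "character", domainLocus = "character",
                 proteinStart = "integer", proteinEnd = "integer",
                 pssm = "matrix"))

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

setValidity("ProfileModel", function(object) {
  msgs <- character()
  len <- object@proteinEnd - object@proteinStart + 1L
  if (nrow(object@pssm) != len)
    msgs <- c(msgs, "pssm rows must equal proteinEnd - proteinStart + 1")
  if (!identical(sort(colnames(object@pssm)), AA20))
    msgs <- c(msgs, "pssm must score all 20 standard residues")
  if (any(!is.finite(object@pssm)))
    msgs <- c(msgs, "pssm scores must be finite")
  if (length(msgs)) msgs else TRUE
})

#' Construct a ProfileModel
#'
#' @param pssm numeric matrix (positions x residues), columns named by
#'   one-letter amino-acid code; columns are reordered to the standard
#'   alphabet.
#' @param modelId,domainLocus identifiers.
#' @param proteinStart 1-based position of the first domain column on the
#'   protein (default 1).
#' @return A validated \linkS4class{ProfileModel}.
#' @export
ProfileModel <- function(pssm, modelId = "model", domainLocus = NA_character_,
                         proteinStart = 1L) {
  pssm <- as.matrix(pssm)
  pssm <- pssm[, AA20, drop = FALSE]
  rownames(pssm) <- NULL
  proteinStart <- as.integer(proteinStart)
  new("ProfileModel", modelId = modelId, domainLocus = domainLocus,
      proteinStart = proteinStart,
      proteinEnd = proteinStart + nrow(pssm) - 1L, pssm = pssm)
}

#' PanGenomePartition: the four-way mutation partition
#'
#' Disjoint sets of high-confidence variant ids: \code{core} (present in
#' every isolate), \code{shared} (in two or more but not all isolates),
#' \code{unique} (in exactly one isolate) and \code{discarded} (seen in at
#' least one population sample but in no isolate).
#'
#' @slot core,shared,unique,discarded Character vectors of variant ids.
#' @slot fractions Named numeric, each set's fraction of the total.
#' @export
setClass("PanGenomePartition",
  representation(core = "character", shared = "character",
                 unique = "character", discarded = "character",
                 fractions = "numeric"))

setValidity("PanGenomePartition", function(object) {
  sets <- list(object@core, object@shared, object@unique, object@discarded)
  all_ids <- unlist(sets)
  if (anyDuplicated(all_ids))
    return("partition sets must be disjoint")
  TRUE
})

setMethod("show", "MutationCohort", function(object) {
  s <- object@samples
  cat(sprintf("MutationCohort: %d samples (%d wild_type, %d population, %d isolate)\n",
              nrow(s), sum(s$role == "wild_type"),
              sum(s$role == "population"), sum(s$role == "isolate")))
  cat(sprintf("  %d observations of %d distinct variants\n",
              nrow(object@calls), length(unique(object@calls$variant_id))))
})

setMethod("show", "GenomeAnnotation", function(object) {
  cat(sprintf("GenomeAnnotation: %d genes, %d operons, %d pathways on a %d bp reference\n",
              length(object@genes), length(object@operons),
              length(object@pathways), object@referenceLength))
})

setMethod("show", "ProfileModel", function(object) {
  cat(sprintf("ProfileModel %s (%s): %d domain positions spanning protein %d-%d\n",
              object@modelId, object@domainLocus, nrow(object@pssm),
              object@proteinStart, object@proteinEnd))
})

setMethod("show", "PanGenomePartition", function(object) {
  n <- length(object@core) + length(object@shared) + length(object@unique) +
    length(object@discarded)
  cat(sprintf("PanGenomePartition of %d variants:\n", n))
  cat(sprintf("  core %d (%.0f%%), shared %d (%.0f%%), unique %d (%.0f%%), discarded %d (%.0f%%)\n",
              length(object@core), 100 * object@fractions["core"],
              length(object@shared), 100 * object@fractions["shared"],
              length(object@unique), 100 * object@fractions["unique"],
              length(object@discarded), 100 * object@fractions["discarded"]))
})
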