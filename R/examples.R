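#' Worked example: the hotspot landscape of a hydrolysate-tolerant
#' C. thermocellum cohort
#'
#' Loads the bundled mutation-to-gene assignments of a published
#' Populus-hydrolysate-tolerant \emph{Clostridium thermocellum}
#' directed-evolution cohort: 24 high-confidence mutations over 18 genes,
#' their core-set membership, the eight-gene ATP-synthase transcription
#' unit and the pathway groupings that tie the mutated genes together.
#' Running \code{\link{callHotspots}} on this input reproduces the
#' cohort's eight mutational hotspots.
#'
#' @return list with \code{effects} (variant-to-gene effect table),
#'   \code{annotation} (a \linkS4class{GenomeAnnotation} carrying the
#'   operon and pathway membership) and \code{core} (core variant ids).
#' @export
#' @examples
#' ex <- hotspotExampleData()
#' hs <- callHotspots(ex$effects, ex$annotation, ex$core)
#' nrow(hs)            # 8 hotspots
#' sum(hs$n_mutations) # 24 member mutations
hotspotExampleData <- function() {
  path <- function(f) system.file("extdata", f, package = "panmut",
                                  mustWork = TRUE)
  var <- utils::read.delim(path("cthe_hotspot_variants.tsv"),
                           stringsAsFactors = FALSE)
  operon <- read_membership(path("cthe_hotspot_operons.tsv"))
  pathway <- read_membership(path("cthe_hotspot_pathways.tsv"))
  loci <- sort(unique(c(var$locus_tag, unlist(operon), unlist(pathway))))
  genes <- GenomicRanges::GRanges(
    "chr", IRanges::IRanges(start = seq_along(loci) * 2000L, width = 1000L),
    strand = "+")
  genes$locus_tag <- loci
  annotation <- GenomeAnnotation(genes, operons = operon,
                                 pathways = pathway)
  effects <- data.frame(
    variant_id = var$variant_id,
    effect = ifelse(var$region == "NC", "NONCODING", "NONSYN"),
    locus_tag = ifelse(var$region == "NC", NA_character_, var$locus_tag),
    codon_index = NA_integer_, ref_aa = NA_character_,
    alt_aa = NA_character_,
    assigned_gene = ifelse(var$region == "NC", var$locus_tag,
                           NA_character_),
    stringsAsFactors = FALSE)
  list(effects = effects, annotation = annotation,
       core = var$variant_id[var$core])
}
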