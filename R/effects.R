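#' Classify coding effects of high-confidence mutations
#'
#' Single-nucleotide variants falling inside an annotated CDS are
#' translated (bacterial genetic code, translation table 11) as reference
#' and mutant codons and classified as synonymous (\code{SYN}),
#' non-synonymous (\code{NONSYN}) or stop-introducing (\code{STOP}).  Any
#' insertion or deletion is classified \code{INDEL} regardless of frame
#' (the containing gene, if any, is still recorded so indels participate
#' in hotspot grouping).  Variants outside every CDS are \code{NONCODING}
#' and may be assigned to the nearest downstream translation start within
#' \code{window} bp (see \code{\link{assignNoncoding}}).  Reverse-strand
#' genes are handled on the coding strand: the gene region is
#' reverse-complemented before codon extraction and the substituted base
#' complemented.  A variant overlapping two CDS annotations yields one
#' row per gene.
#'
#' @param cohort a \linkS4class{MutationCohort} (typically the
#'   high-confidence set) — or a calls data.frame with one row per
#'   distinct variant.
#' @param annotation a \linkS4class{GenomeAnnotation}.
#' @param reference a \link[Biostrings]{DNAString} (or single-sequence
#'   \code{DNAStringSet}) matching the annotation coordinates.
#' @param window upstream assignment window in bp for non-coding variants
#'   (default 500).
#' @return data.frame with columns \code{variant_id}, \code{effect}
#'   (\code{SYN}/\code{NONSYN}/\code{STOP}/\code{INDEL}/\code{NONCODING}),
#'   \code{locus_tag}, \code{codon_index}, \code{ref_aa}, \code{alt_aa}
#'   and \code{assigned_gene}; one row per (variant, gene) assignment.
#' @export
classifyEffects <- function(cohort, annotation, reference, window = 500) {
  calls <- if (is(cohort, "MutationCohort")) variantCalls(cohort)
           else as.data.frame(cohort)
  calls <- calls[!duplicated(calls$variant_id), , drop = FALSE]
  reference <- as_dnastring(reference)
  genes <- annotatedGenes(annotation)
  rows <- lapply(seq_len(nrow(calls)), function(i)
    classify_one(calls[i, ], genes, reference, window))
  if (length(rows) == 0) return(empty_effects())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_effects <- function() {
  data.frame(variant_id = character(), effect = character(),
             locus_tag = character(), codon_index = integer(),
             ref_aa = character(), alt_aa = character(),
             assigned_gene = character(), stringsAsFactors = FALSE)
}

as_dnastring <- function(reference) {
  if (is(reference, "DNAStringSet")) reference <- reference[[1]]
  if (!is(reference, "DNAString")) reference <- Biostrings::DNAString(reference)
  reference
}

effect_row <- function(variant_id, effect, locus_tag = NA_character_,
                       codon_index = NA_integer_, ref_aa = NA_character_,
                       alt_aa = NA_character_,
                       assigned_gene = NA_character_) {
  data.frame(variant_id = variant_id, effect = effect,
             locus_tag = locus_tag, codon_index = as.integer(codon_index),
             ref_aa = ref_aa, alt_aa = alt_aa,
             assigned_gene = assigned_gene, stringsAsFactors = FALSE)
}

classify_one <- function(call, genes, reference, window) {
  pos <- call$position
  hit <- which(GenomicRanges::start(genes) <= pos &
                 GenomicRanges::end(genes) >= pos)
  is_indel <- call$caller_class != "snp" ||
    call$ref_allele == "-" || call$alt_allele == "-" ||
    nchar(call$ref_allele) != nchar(call$alt_allele)
  if (is_indel) {
    if (length(hit) == 0)
      return(effect_row(call$variant_id, "INDEL",
                        assigned_gene = nearest_downstream_start(
                          pos, genes, window)))
    return(do.call(rbind, lapply(hit, function(j)
      effect_row(call$variant_id, "INDEL",
                 locus_tag = genes$locus_tag[j]))))
  }
  if (length(hit) == 0)
    return(effect_row(call$variant_id, "NONCODING",
                      assigned_gene = nearest_downstream_start(
                        pos, genes, window)))
  do.call(rbind, lapply(hit, function(j)
    classify_snp_in_cds(call, genes[j], reference)))
}

classify_snp_in_cds <- function(call, gene, reference) {
  pos <- call$position
  start <- GenomicRanges::start(gene)
  end <- GenomicRanges::end(gene)
  strand <- as.character(GenomicRanges::strand(gene))
  ref_base <- as.character(Biostrings::subseq(reference, pos, pos))
  if (ref_base != call$ref_allele)
    stop(sprintf("reference mismatch for %s: reference has %s at %d",
                 call$variant_id, ref_base, pos))
  cds <- Biostrings::subseq(reference, start, end)
  if (strand == "-") cds <- Biostrings::reverseComplement(cds)
  off <- if (strand == "-") end - pos + 1L else pos - start + 1L
  codon_index <- (off - 1L) %/% 3L + 1L
  pos_in_codon <- (off - 1L) %% 3L + 1L
  codon_start <- (codon_index - 1L) * 3L + 1L
  if (codon_start + 2L > length(cds))   # truncated trailing codon
    return(effect_row(call$variant_id, "NONSYN",
                      locus_tag = gene$locus_tag,
                      codon_index = codon_index))
  ref_codon <- Biostrings::subseq(cds, codon_start, codon_start + 2L)
  alt_base <- if (strand == "-")
    as.character(Biostrings::complement(Biostrings::DNAString(call$alt_allele)))
  else call$alt_allele
  alt_codon_chars <- strsplit(as.character(ref_codon), "")[[1]]
  alt_codon_chars[pos_in_codon] <- alt_base
  code <- Biostrings::getGeneticCode("11")
  ref_aa <- as.character(Biostrings::translate(
    ref_codon, genetic.code = code, no.init.codon = TRUE))
  alt_aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(paste(alt_codon_chars, collapse = "")),
    genetic.code = code, no.init.codon = TRUE))
  effect <- if (alt_aa == "*" && ref_aa != "*") "STOP"
  else if (ref_aa == alt_aa) "SYN" else "NONSYN"
  effect_row(call$variant_id, effect, locus_tag = gene$locus_tag,
             codon_index = codon_index, ref_aa = ref_aa, alt_aa = alt_aa)
}

#' Assign a non-coding variant to a downstream gene
#'
#' A mutation outside every CDS may sit in the regulatory region of the
#' gene whose translation start lies downstream of it on that gene's
#' strand.  The variant is assigned to the nearest such start within
#' \code{window} bp; beyond the window no assignment is made.
#'
#' @param position 1-based reference position of the non-coding variant.
#' @param annotation a \linkS4class{GenomeAnnotation}; the position must
#'   not fall inside any CDS.
#' @param window maximum upstream distance in bp (default 500).
#' @return The assigned locus_tag, or \code{NA_character_}.
#' @export
assignNoncoding <- function(position, annotation, window = 500) {
  genes <- annotatedGenes(annotation)
  inside <- any(GenomicRanges::start(genes) <= position &
                  GenomicRanges::end(genes) >= position)
  if (inside)
    stop("position ", position, " lies inside a CDS; not a non-coding variant")
  nearest_downstream_start(position, genes, window)
}

nearest_downstream_start <- function(position, genes, window) {
  if (length(genes) == 0) return(NA_character_)
  strand <- as.character(GenomicRanges::strand(genes))
  start <- GenomicRanges::start(genes)
  end <- GenomicRanges::end(genes)
  # distance from the variant to each gene's translation start, measured
  # upstream of the start on the gene's own strand
  dist <- ifelse(strand == "-", position - end, start - position)
  dist[dist < 1] <- NA
  dist[dist > window] <- NA
  if (all(is.na(dist))) return(NA_character_)
  genes$locus_tag[which.min(dist)]
}

#' Tabulate the distribution of mutation effects
#'
#' @param effects effect data.frame from \code{\link{classifyEffects}};
#'   counted per distinct variant (a variant reported against two genes
#'   counts once, under its first classification).
#' @return list with \code{counts} (named integer over SYN, NONSYN, STOP,
#'   INDEL, NONCODING), \code{fraction_noncoding} and
#'   \code{nonsyn_to_syn_ratio} (\code{Inf} when no synonymous mutations
#'   were observed).
#' @export
tabulateEffects <- function(effects) {
  lev <- c("SYN", "NONSYN", "STOP", "INDEL", "NONCODING")
  eff <- effects$effect[!duplicated(effects$variant_id)]
  counts <- table(factor(eff, levels = lev))
  n <- sum(counts)
  list(counts = stats::setNames(as.integer(counts), lev),
       fraction_noncoding = if (n == 0) 0 else counts[["NONCODING"]] / n,
       nonsyn_to_syn_ratio = if (counts[["SYN"]] == 0) Inf
       else counts[["NONSYN"]] / counts[["SYN"]])
}
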