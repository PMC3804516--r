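#' Build the variant-by-sample presence matrix
#'
#' A variant is present in a sample when an observation exists and either
#' carries no allele frequency (wild-type and isolate calls, treated as
#' fixed) or a frequency at or above \code{threshold}.  Population
#' observations below the threshold are detections only — the mutation was
#' seen in the reads but is not considered established in the population —
#' and score as absent.
#'
#' @param cohort a \linkS4class{MutationCohort}.
#' @param threshold presence threshold in [0,1] (default 0.02, i.e.
#'   sub-2\% detections do not count as presence).
#' @return Logical matrix, variants x samples, with the threshold stored
#'   in \code{attr(, "threshold")}.
#' @export
buildPresence <- function(cohort, threshold = 0.02) {
  if (threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1]")
  calls <- variantCalls(cohort)
  samples <- sampleInfo(cohort)
  ids <- unique(calls$variant_id)
  m <- matrix(FALSE, nrow = length(ids), ncol = nrow(samples),
              dimnames = list(ids, samples$sample_id))
  present <- is.na(calls$allele_frequency) |
    calls$allele_frequency >= threshold
  hit <- calls[present, , drop = FALSE]
  m[cbind(match(hit$variant_id, ids),
          match(hit$sample_id, samples$sample_id))] <- TRUE
  attr(m, "threshold") <- threshold
  m
}

#' Partition mutations into core, shared, unique and discarded sets
#'
#' The pan-genome view of the cohort: \code{core} mutations are present
#' in every single-colony isolate; \code{unique} in exactly one isolate;
#' \code{shared} in two or more but not all isolates; \code{discarded}
#' mutations were seen only in population samples and made it into no
#' isolate.  Fractions are taken over the total number of variants in the
#' presence matrix.
#'
#' @param presence logical presence matrix from
#'   \code{\link{buildPresence}} over high-confidence calls.
#' @param samples sample sheet data.frame.
#' @return A \linkS4class{PanGenomePartition}.
#' @export
partitionPanGenome <- function(presence, samples) {
  iso <- isolate_ids(samples)
  if (length(iso) == 0) stop("partition requires at least one isolate")
  n_iso <- rowSums(presence[, iso, drop = FALSE])
  ids <- rownames(presence)
  core <- ids[n_iso == length(iso)]
  unique_ <- ids[n_iso == 1 & length(iso) > 1]
  if (length(iso) == 1) {
    # with a single isolate "all isolates" and "exactly one" coincide;
    # such variants are core and shared is necessarily empty
    unique_ <- character()
  }
  shared <- ids[n_iso >= 2 & n_iso < length(iso)]
  discarded <- ids[n_iso == 0]
  total <- length(ids)
  fr <- function(x) if (total == 0) 0 else length(x) / total
  new("PanGenomePartition", core = core, shared = shared,
      unique = unique_, discarded = discarded,
      fractions = c(core = fr(core), shared = fr(shared),
                    unique = fr(unique_), discarded = fr(discarded)))
}

#' Longitudinal mutation accumulation across population samples
#'
#' Tracks how many established mutations each serially sampled population
#' carries, the gain between consecutive samples, and — because two
#' populations can carry equal counts of entirely different mutations —
#' the symmetric difference between consecutive mutation sets.
#'
#' @param presence logical presence matrix from
#'   \code{\link{buildPresence}}.
#' @param samples sample sheet data.frame with at least two population
#'   samples under a defined stage ordering.
#' @return list with \code{sample_id} (stage order), \code{cumulative}
#'   (established-mutation count per population), \code{deltas}
#'   (consecutive differences), \code{mean_delta}, \code{sd_delta}
#'   (population standard deviation), \code{max_delta},
#'   \code{max_delta_pair} and \code{symmetric_difference} sizes.
#' @export
longitudinalAccumulation <- function(presence, samples) {
  pops <- population_ids(samples)
  if (length(pops) < 2)
    stop("longitudinal analysis requires at least two population samples")
  counts <- colSums(presence[, pops, drop = FALSE])
  deltas <- diff(counts)
  symdiff <- vapply(seq_len(length(pops) - 1), function(i) {
    a <- presence[, pops[i]]
    b <- presence[, pops[i + 1]]
    sum(xor(a, b))
  }, numeric(1))
  pairs <- paste(pops[-length(pops)], pops[-1], sep = " -> ")
  sd_pop <- sqrt(mean((deltas - mean(deltas))^2))
  list(sample_id = pops,
       cumulative = stats::setNames(as.integer(counts), pops),
       deltas = stats::setNames(as.integer(deltas), pairs),
       mean_delta = mean(deltas), sd_delta = sd_pop,
       max_delta = as.integer(max(deltas)),
       max_delta_pair = pairs[which.max(deltas)],
       symmetric_difference = stats::setNames(as.integer(symdiff), pairs))
}

#' Call mutational hotspots over genes, operons and pathways
#'
#' A hotspot is a group of two or more mutations located within one gene,
#' within one operon, or along one pathway, where at least one member
#' gene carries a mutation from the core set.  Groups are formed at three
#' nested levels and kept maximal: a multi-mutation gene inside a mutated
#' operon is merged into the operon-level group, and pathway grouping
#' only merges genes not already claimed by an operon.  A gene belonging
#' to two pathways may anchor two hotspots, so member sets of
#' pathway-based hotspots may overlap.  \code{grouping_basis} records the
#' widest level actually used: \code{operon} and \code{pathway} bases
#' require at least two distinct mutated genes, otherwise the group falls
#' through to \code{same_gene}.
#'
#' @param effects effect-annotation data.frame from
#'   \code{\link{classifyEffects}}; variants map to genes through
#'   \code{locus_tag} (coding) or \code{assigned_gene} (upstream
#'   non-coding).  Variants mapping to no gene are skipped.
#' @param annotation a \linkS4class{GenomeAnnotation} supplying operon and
#'   pathway membership.
#' @param core character vector of core variant ids; a gene is a core
#'   gene if any of its mutations is core.
#' @return data.frame with one row per hotspot: \code{hotspot_id},
#'   \code{n_mutations}, \code{grouping_basis}, \code{core_anchor},
#'   \code{member_genes} and \code{member_variants} (comma-separated),
#'   ordered by decreasing size.
#' @export
callHotspots <- function(effects, annotation, core) {
  gene_of <- variant_gene_map(effects)
  if (nrow(gene_of) == 0) return(empty_hotspots())
  by_gene <- split(gene_of$variant_id, gene_of$locus_tag)
  mutated <- names(by_gene)
  core_gene <- vapply(by_gene, function(v) any(v %in% core), logical(1))

  groups <- list()
  claimed <- character()  # genes already grouped at the operon level

  for (nm in names(operons(annotation))) {
    members <- intersect(operons(annotation)[[nm]], mutated)
    if (length(members) < 2) next
    groups[[length(groups) + 1L]] <-
      list(genes = members, basis = "operon", label = nm)
    claimed <- union(claimed, members)
  }
  pathway_used <- character()
  for (nm in names(pathways(annotation))) {
    members <- setdiff(intersect(pathways(annotation)[[nm]], mutated),
                       claimed)
    if (length(members) < 2) next
    groups[[length(groups) + 1L]] <-
      list(genes = members, basis = "pathway", label = nm)
    pathway_used <- union(pathway_used, members)
  }
  for (g in setdiff(mutated, union(claimed, pathway_used))) {
    if (length(by_gene[[g]]) < 2) next
    groups[[length(groups) + 1L]] <-
      list(genes = g, basis = "same_gene", label = g)
  }

  rows <- lapply(groups, function(gr) {
    variants <- sort(unique(unlist(by_gene[gr$genes])))
    anchors <- gr$genes[core_gene[gr$genes]]
    if (length(variants) < 2 || length(anchors) == 0) return(NULL)
    data.frame(hotspot_id = gr$label, n_mutations = length(variants),
               grouping_basis = gr$basis, core_anchor = anchors[1],
               member_genes = paste(sort(gr$genes), collapse = ","),
               member_variants = paste(variants, collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(empty_hotspots())
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_mutations, out$hotspot_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_hotspots <- function() {
  data.frame(hotspot_id = character(), n_mutations = integer(),
             grouping_basis = character(), core_anchor = character(),
             member_genes = character(), member_variants = character(),
             stringsAsFactors = FALSE)
}

# one row per (variant, gene) assignment, using the CDS locus for coding
# effects and the upstream-window assignment for non-coding ones
variant_gene_map <- function(effects) {
  locus <- ifelse(!is.na(effects$locus_tag), effects$locus_tag,
                  effects$assigned_gene)
  keep <- !is.na(locus)
  unique(data.frame(variant_id = effects$variant_id[keep],
                    locus_tag = locus[keep], stringsAsFactors = FALSE))
}
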