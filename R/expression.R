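#' Upper-quartile normalisation with log2 transform
#'
#' Each sample's counts are divided by the 75th percentile of that
#' sample's nonzero counts and rescaled by the geometric mean of all
#' per-sample factors, so that post-scaling upper quartiles are equal
#' across samples while the overall count scale is preserved.  A +1
#' pseudocount is added before the log2 transform (zero counts exist in
#' every real matrix).
#'
#' @param se a \link[SummarizedExperiment]{SummarizedExperiment} with a
#'   raw \code{counts} assay; every sample must have a nonzero total.
#' @return The same object with assays \code{uq} (scaled counts) and
#'   \code{log2uq} (log2(scaled + 1)) added, and
#'   \code{metadata()$normalized = TRUE}.
#' @export
normalizeCounts <- function(se) {
  m <- SummarizedExperiment::assay(se, "counts")
  if (any(colSums(m) == 0))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(m)[colSums(m) == 0], collapse = ", "))
  factors <- apply(m, 2, function(x) stats::quantile(x[x > 0], 0.75))
  scaled <- sweep(m, 2, factors, "/") * exp(mean(log(factors)))
  SummarizedExperiment::assay(se, "uq") <- scaled
  SummarizedExperiment::assay(se, "log2uq") <- log2(scaled + 1)
  S4Vectors::metadata(se)$normalized <- TRUE
  se
}

#' Select mutation-linked candidate genes
#'
#' The expression analysis is restricted to genes that can be traced to a
#' mutation: genes that (1) are themselves mutated, (2) lie downstream of
#' a mutation or share an operon with a mutated gene, (3) are another
#' copy (paralog) of a mutated gene, or (4) are under regulatory control
#' of a mutated gene.
#'
#' @param effects effect data.frame from \code{\link{classifyEffects}}.
#' @param annotation a \linkS4class{GenomeAnnotation} (operon membership
#'   drives rule 2).
#' @param paralogMap named list: gene -> character vector of other copies
#'   (rule 3).
#' @param regulonMap named list: regulator gene -> character vector of
#'   target genes (rule 4).
#' @return data.frame with columns \code{locus_tag} and \code{reasons}
#'   (comma-separated subset of \code{mutated},
#'   \code{downstream_or_operon}, \code{paralog_copy},
#'   \code{regulatory_target}).
#' @export
selectCandidateGenes <- function(effects, annotation,
                                 paralogMap = list(), regulonMap = list()) {
  reasons <- list()
  add <- function(genes, why) {
    for (g in genes)
      reasons[[g]] <<- union(reasons[[g]], why)
  }
  mutated_cds <- unique(stats::na.omit(effects$locus_tag))
  add(mutated_cds, "mutated")
  # genes downstream of an upstream non-coding mutation
  add(unique(stats::na.omit(effects$assigned_gene)), "downstream_or_operon")
  for (op in operons(annotation)) {
    hit <- which(op %in% mutated_cds)
    if (length(hit) == 0) next
    # co-members from the first mutated gene onward are downstream of (or
    # share the transcript with) the mutation
    add(setdiff(op, mutated_cds), "downstream_or_operon")
  }
  mutated_any <- names(reasons)[vapply(reasons, function(r)
    "mutated" %in% r, logical(1))]
  for (g in intersect(mutated_any, names(paralogMap)))
    add(setdiff(paralogMap[[g]], mutated_any), "paralog_copy")
  for (g in intersect(mutated_any, names(regulonMap)))
    add(regulonMap[[g]], "regulatory_target")
  if (length(reasons) == 0)
    return(data.frame(locus_tag = character(), reasons = character(),
                      stringsAsFactors = FALSE))
  out <- data.frame(
    locus_tag = names(reasons),
    reasons = vapply(reasons, function(r) paste(sort(r), collapse = ","),
                     character(1)),
    stringsAsFactors = FALSE)
  out <- out[order(out$locus_tag), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-gene ANOVA differential-expression test with dual thresholds
#'
#' For every gene a one-way ANOVA across conditions yields one p-value;
#' Benjamini-Hochberg control at \code{fdr} is applied across genes.  Per
#' contrast against the baseline condition the effect size is the
#' difference of mean log2 expression.  A gene/contrast is significant
#' only when all three conditions hold: it survives the FDR procedure,
#' \code{|log2_diff| > log2Cutoff} and \code{-log10(p) > negLog10Cutoff}
#' (the raw ANOVA p-value; the printed thresholds and the FDR screen are
#' applied jointly).
#'
#' @param se a normalised \code{SummarizedExperiment} from
#'   \code{\link{normalizeCounts}} (assay \code{log2uq}), with colData
#'   columns \code{condition} and \code{replicate}.
#' @param baseline baseline condition name.
#' @param fdr Benjamini-Hochberg false-discovery-rate level (default
#'   0.05).
#' @param log2Cutoff minimum absolute log2 difference (default 1).
#' @param negLog10Cutoff minimum -log10 raw p-value (default 1.714, i.e.
#'   p < 0.0193).
#' @param genes optional subset of locus tags to test (e.g. a candidate
#'   set from \code{\link{selectCandidateGenes}}).
#' @return data.frame with one row per gene x non-baseline condition:
#'   \code{locus_tag}, \code{contrast}, \code{log2_diff}, \code{p_value},
#'   \code{neg_log10_p}, \code{fdr_adjusted_p}, \code{significant}.
#'   Single-replicate designs fall back to contrast-only effect sizes
#'   with \code{NA} p-values and no significance calls.
#' @export
testDifferentialExpression <- function(se, baseline, fdr = 0.05,
                                       log2Cutoff = 1,
                                       negLog10Cutoff = 1.714,
                                       genes = NULL) {
  if (!"log2uq" %in% SummarizedExperiment::assayNames(se))
    se <- normalizeCounts(se)
  m <- SummarizedExperiment::assay(se, "log2uq")
  cond <- as.character(SummarizedExperiment::colData(se)$condition)
  if (!baseline %in% cond) stop("baseline condition not present: ", baseline)
  if (length(unique(cond)) < 2)
    stop("differential expression requires at least two conditions")
  if (!is.null(genes)) m <- m[rownames(m) %in% genes, , drop = FALSE]
  contrasts <- setdiff(unique(cond), baseline)
  f <- factor(cond)
  single_rep <- min(table(f)) < 2
  pvals <- if (single_rep) rep(NA_real_, nrow(m)) else
    apply(m, 1, function(y) {
      if (stats::var(y) == 0) return(1)
      stats::oneway.test(y ~ f, var.equal = TRUE)$p.value
    })
  pvals[is.nan(pvals)] <- 1
  padj <- stats::p.adjust(pvals, method = "BH")
  base_mean <- rowMeans(m[, cond == baseline, drop = FALSE])
  rows <- lapply(contrasts, function(cc) {
    ldiff <- rowMeans(m[, cond == cc, drop = FALSE]) - base_mean
    data.frame(locus_tag = rownames(m),
               contrast = paste(cc, "vs", baseline),
               log2_diff = unname(ldiff), p_value = unname(pvals),
               neg_log10_p = unname(-log10(pvals)),
               fdr_adjusted_p = unname(padj),
               significant = !single_rep & !is.na(pvals) &
                 padj <= fdr & abs(ldiff) > log2Cutoff &
                 -log10(pvals) > negLog10Cutoff,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Hierarchically cluster differentially expressed genes
#'
#' Agglomerative clustering of the genes-by-contrasts log2-difference
#' matrix with Euclidean distance and average linkage.  \code{hclust} is
#' deterministic for a fixed input row order, so repeated runs on the
#' same matrix give identical trees.
#'
#' @param deMatrix numeric matrix, genes x contrasts, of log2
#'   differences (rownames are locus tags).
#' @return list with \code{hclust} (the tree; \code{NULL} for a single
#'   gene), \code{order} (ordered locus tags) and \code{newick} (the
#'   dendrogram in Newick text, via \pkg{ape}).
#' @export
clusterDeGenes <- function(deMatrix) {
  deMatrix <- as.matrix(deMatrix)
  if (nrow(deMatrix) == 1)
    return(list(hclust = NULL, order = rownames(deMatrix),
                newick = sprintf("(%s);", rownames(deMatrix))))
  hc <- stats::hclust(stats::dist(deMatrix, method = "euclidean"),
                      method = "average")
  list(hclust = hc, order = rownames(deMatrix)[hc$order],
       newick = ape::write.tree(ape::as.phylo(hc)))
}
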