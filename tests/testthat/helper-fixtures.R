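# Shared fixtures and independent brute-force oracles.

toy_samples <- function(nPop = 2, nIso = 2) {
  data.frame(
    sample_id = c("WT", paste0("P", seq_len(nPop)),
                  paste0("I", seq_len(nIso))),
    role = c("wild_type", rep("population", nPop), rep("isolate", nIso)),
    stage_index = c(0L, seq_len(nPop), rep(nPop, nIso)),
    stage_label = "x", stringsAsFactors = FALSE)
}

toy_call <- function(variant_id, sample_id, position = 10L, ref = "A",
                     alt = "G", class = "snp", flag = "hc", af = NA_real_) {
  data.frame(variant_id = variant_id, sample_id = sample_id,
             position = as.integer(position), ref_allele = ref,
             alt_allele = alt, caller_class = class,
             confidence_flag = flag, allele_frequency = af,
             stringsAsFactors = FALSE)
}

# A small genome with known codons: gene fwd on + at 10..27 (6 codons),
# gene rev on - at 40..57 whose coding sequence equals gene fwd's.
toy_genome <- function() {
  cds <- "ATGCTTGAAGGCCGTTAA"  # M L E G R *
  ref <- paste0(strrep("T", 9), cds, strrep("A", 12),
                as.character(Biostrings::reverseComplement(
                  Biostrings::DNAString(cds))), strrep("T", 23))
  genes <- GenomicRanges::GRanges(
    "chr", IRanges::IRanges(start = c(10L, 40L), width = 18L),
    strand = c("+", "-"))
  genes$locus_tag <- c("fwd", "rev")
  list(reference = Biostrings::DNAString(ref),
       annotation = GenomeAnnotation(genes, referenceLength = nchar(ref)))
}

# Whole-CDS translation oracle for effect classification: mutate the
# genome, re-extract and translate the full CDS, and diff the proteins.
oracle_effect <- function(position, alt, gene, reference) {
  mutated <- as.character(reference)
  substr(mutated, position, position) <- alt
  extract <- function(seq) {
    cds <- Biostrings::subseq(Biostrings::DNAString(seq),
                              GenomicRanges::start(gene),
                              GenomicRanges::end(gene))
    if (as.character(GenomicRanges::strand(gene)) == "-")
      cds <- Biostrings::reverseComplement(cds)
    as.character(Biostrings::translate(
      cds, genetic.code = Biostrings::getGeneticCode("11"),
      no.init.codon = TRUE))
  }
  before <- extract(as.character(reference))
  after <- extract(mutated)
  diff_at <- which(strsplit(before, "")[[1]] != strsplit(after, "")[[1]])
  if (length(diff_at) == 0) return(list(effect = "SYN"))
  aa <- substr(after, diff_at[1], diff_at[1])
  list(effect = if (aa == "*") "STOP" else "NONSYN",
       codon_index = diff_at[1], alt_aa = aa)
}

# Brute-force Benjamini-Hochberg, straight from the step-up definition.
bh_brute <- function(p) {
  n <- length(p)
  adj <- numeric(n)
  for (i in seq_len(n)) {
    rank_i <- sum(p <= p[i])
    candidates <- vapply(which(p >= p[i]), function(j)
      p[j] * n / sum(p <= p[j]), numeric(1))
    adj[i] <- min(1, min(candidates))
  }
  # resolve ties like the step-up procedure: equal p get equal adj
  adj
}

# Brute-force pan-genome partition by per-variant loops.
partition_brute <- function(presence, samples) {
  iso <- samples$sample_id[samples$role == "isolate"]
  out <- list(core = character(), shared = character(),
              unique = character(), discarded = character())
  for (v in rownames(presence)) {
    k <- sum(vapply(iso, function(s) presence[v, s], logical(1)))
    cls <- if (k == length(iso)) "core"
    else if (k == 0) "discarded"
    else if (k == 1) "unique" else "shared"
    out[[cls]] <- c(out[[cls]], v)
  }
  out
}

# Brute-force hotspot enumeration, written directly from the rule:
# candidate groups at operon, pathway (excluding operon-claimed genes)
# and single-gene level; keep maximal groups with >= 2 mutations and a
# core-mutation gene.
hotspot_brute <- function(effects, annotation, core) {
  locus <- ifelse(!is.na(effects$locus_tag), effects$locus_tag,
                  effects$assigned_gene)
  keep <- !is.na(locus)
  pairs <- unique(data.frame(v = effects$variant_id[keep],
                             g = locus[keep], stringsAsFactors = FALSE))
  variants_of <- function(genes) sort(unique(pairs$v[pairs$g %in% genes]))
  gene_is_core <- function(g) any(pairs$v[pairs$g == g] %in% core)
  mutated <- unique(pairs$g)
  groups <- list()
  operon_claimed <- character()
  for (op in panmut::operons(annotation)) {
    genes <- intersect(op, mutated)
    if (length(genes) >= 2) {
      groups[[length(groups) + 1]] <- list(genes = sort(genes),
                                           basis = "operon")
      operon_claimed <- union(operon_claimed, genes)
    }
  }
  pathway_claimed <- character()
  for (pw in panmut::pathways(annotation)) {
    genes <- setdiff(intersect(pw, mutated), operon_claimed)
    if (length(genes) >= 2) {
      groups[[length(groups) + 1]] <- list(genes = sort(genes),
                                           basis = "pathway")
      pathway_claimed <- union(pathway_claimed, genes)
    }
  }
  for (g in setdiff(mutated, union(operon_claimed, pathway_claimed)))
    if (length(unique(pairs$v[pairs$g == g])) >= 2)
      groups[[length(groups) + 1]] <- list(genes = g, basis = "same_gene")
  kept <- Filter(function(gr) {
    length(variants_of(gr$genes)) >= 2 && any(vapply(gr$genes,
                                                     gene_is_core,
                                                     logical(1)))
  }, groups)
  sets <- lapply(kept, function(gr)
    list(genes = gr$genes, basis = gr$basis,
         variants = variants_of(gr$genes)))
  sets[order(vapply(sets, function(s) paste(s$genes, collapse = ","),
                    character(1)))]
}

# small generator config used in property loops
small_config <- function(seed, ...) {
  args <- utils::modifyList(
    list(seed = seed, genomeLength = 200000L, nGenes = 150L,
         nOperons = 10L, nPathways = 8L), list(...))
  do.call(cohortConfig, args)
}

hotspots_as_sets <- function(hs) {
  sets <- lapply(seq_len(nrow(hs)), function(i)
    list(genes = sort(strsplit(hs$member_genes[i], ",")[[1]]),
         basis = hs$grouping_basis[i],
         variants = sort(strsplit(hs$member_variants[i], ",")[[1]])))
  sets[order(vapply(sets, function(s) paste(s$genes, collapse = ","),
                    character(1)))]
}
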