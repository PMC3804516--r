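#' Read a flat key = value pipeline configuration file
#'
#' One \code{key = value} pair per line; \code{#} starts a comment.
#' Values parse to numeric when possible.  Defaults mirror the
#' pipeline's analysis parameters: presence threshold 0.02, upstream
#' window 500 bp, FDR 0.05, |log2 difference| > 1, -log10(p) > 1.714,
#' ANCOVA alpha 0.05.
#'
#' @param path config file path (optional; \code{NULL} gives defaults).
#' @param overrides named list merged over the file values.
#' @return named list of configuration values.
#' @export
readPipelineConfig <- function(path = NULL, overrides = list()) {
  config <- list(presence_threshold = 0.02, upstream_window = 500,
                 fdr = 0.05, log2_cutoff = 1, neglog10_cutoff = 1.714,
                 ancova_form = "main_effect", ancova_alpha = 0.05,
                 baseline = "WT_0", seed = 1L, outdir = "panmut_out")
  if (!is.null(path)) {
    lines <- readLines(path)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines[grepl("=", lines, fixed = TRUE)])
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1])
      val <- trimws(paste(kv[-1], collapse = "="))
      val <- gsub('^"|"$', "", val)
      num <- suppressWarnings(as.numeric(val))
      config[[key]] <- if (!is.na(num)) num else val
    }
  }
  utils::modifyList(config, overrides)
}

pipeline_stages <- c("simulate", "filter", "annotate", "pangenome",
                     "longitudinal", "hotspots", "score", "expression",
                     "growth", "report")

#' Run one pipeline stage, or all of them in dependency order
#'
#' Thin orchestration over the package's analysis functions.  Each stage
#' reads its inputs from the paths named in \code{config} (or the
#' outputs a previous stage wrote under \code{config$outdir}) and writes
#' its own TSV outputs there.  \code{"all"} runs every applicable stage
#' in dependency order.  Reruns with identical configuration and inputs
#' produce identical outputs; stochastic stages consume
#' \code{config$seed}.
#'
#' @param stage one of \code{simulate}, \code{filter}, \code{annotate},
#'   \code{pangenome}, \code{longitudinal}, \code{hotspots},
#'   \code{score}, \code{expression}, \code{growth}, \code{report} or
#'   \code{all}.
#' @param config configuration list from
#'   \code{\link{readPipelineConfig}}.
#' @return The configuration list (with paths the stage added),
#'   invisibly.
#' @export
runPipeline <- function(stage = "all", config = readPipelineConfig()) {
  stage <- match.arg(stage, c(pipeline_stages, "all"))
  outdir <- config$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  log_line <- function(...) {
    msg <- sprintf("[panmut %s] %s", format(Sys.time(), "%H:%M:%S"),
                   sprintf(...))
    message(msg)
  }
  stages <- if (stage == "all") pipeline_stages else stage
  for (st in stages) {
    if (stage == "all" && st == "simulate" &&
        !is.null(config$variant_table) && file.exists(config$variant_table)) {
      next  # inputs supplied; nothing to simulate
    }
    log_line("stage %s (seed=%s, threshold=%s, fdr=%s)", st,
             config$seed, config$presence_threshold, config$fdr)
    config <- switch(st,
      simulate = stage_simulate(config),
      filter = stage_filter(config),
      annotate = stage_annotate(config),
      pangenome = stage_pangenome(config),
      longitudinal = stage_longitudinal(config),
      hotspots = stage_hotspots(config),
      score = stage_score(config),
      expression = stage_expression(config),
      growth = stage_growth(config),
      report = stage_report(config))
  }
  invisible(config)
}

need_input <- function(config, key) {
  path <- config[[key]]
  if (is.null(path) || !file.exists(path))
    stop("missing input for key '", key, "'",
         if (!is.null(path)) paste0(": ", path) else "")
  path
}

load_cohort <- function(config) {
  samples <- readSampleSheet(need_input(config, "sample_sheet"))
  readVariantTable(need_input(config, "variant_table"), samples)
}

load_annotation <- function(config) {
  readAnnotation(need_input(config, "gff"),
                 operonPath = config$operons,
                 pathwayPath = config$pathways)
}

out_path <- function(config, f) file.path(config$outdir, f)

stage_simulate <- function(config) {
  cc <- cohortConfig(
    seed = as.integer(config$seed),
    genomeLength = as.integer(config$sim_genome_length %||% 384000L),
    nGenes = as.integer(config$sim_n_genes %||% 300L))
  sim <- simulateCohort(cc)
  config$sample_sheet <- out_path(config, "samples.tsv")
  config$variant_table <- out_path(config, "variants.tsv")
  config$gff <- out_path(config, "annotation.gff3")
  config$operons <- out_path(config, "operons.tsv")
  config$pathways <- out_path(config, "pathways.tsv")
  config$reference <- out_path(config, "reference.fasta")
  writeSampleSheet(sim$cohort, config$sample_sheet)
  writeVariantTable(sim$cohort, config$variant_table)
  writeAnnotation(sim$annotation, config$gff, config$operons,
                  config$pathways)
  ref <- Biostrings::DNAStringSet(sim$reference)
  names(ref) <- "chr"
  Biostrings::writeXStringSet(ref, config$reference)
  utils::write.table(
    data.frame(variant_id = names(sim$truth$labels),
               label = unname(sim$truth$labels)),
    out_path(config, "truth.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  counts <- simulateCounts(seed = as.integer(config$seed) + 1L)
  config$counts <- out_path(config, "counts.tsv")
  config$design <- out_path(config, "design.tsv")
  writeCountsMatrix(counts$se, config$counts, config$design)
  config$candidate_genes <- out_path(config, "candidate_genes.tsv")
  utils::write.table(data.frame(locus_tag = counts$panel),
                     config$candidate_genes, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  config$baseline <- "WT_0"
  growth <- c(
    simulateGrowthCurves(mu = 0.35, lagH = 4, strain = "PM",
                         condition = "0pct",
                         seed = as.integer(config$seed) + 2L)$curves,
    simulateGrowthCurves(mu = 0.25, lagH = 6, strain = "WT",
                         condition = "10pct",
                         seed = as.integer(config$seed) + 3L)$curves)
  config$growth_csv <- out_path(config, "growth.csv")
  writeGrowthCurves(growth, config$growth_csv)
  config
}

stage_filter <- function(config) {
  cohort <- load_cohort(config)
  screened <- screenVariants(cohort,
                             threshold = config$presence_threshold)
  config$hc_variant_table <- out_path(config, "hc_variants.tsv")
  writeVariantTable(screened$cohort, config$hc_variant_table)
  writeFilterSummary(screened$summary,
                     out_path(config, "filter_summary.tsv"))
  config
}

load_hc_cohort <- function(config) {
  samples <- readSampleSheet(need_input(config, "sample_sheet"))
  readVariantTable(need_input(config, "hc_variant_table"), samples)
}

stage_annotate <- function(config) {
  cohort <- load_hc_cohort(config)
  annotation <- load_annotation(config)
  ref <- Biostrings::readDNAStringSet(need_input(config, "reference"))
  effects <- classifyEffects(cohort, annotation, ref,
                             window = config$upstream_window)
  config$effects_table <- out_path(config, "effects.tsv")
  utils::write.table(effects, config$effects_table, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  dist <- tabulateEffects(effects)
  utils::write.table(
    data.frame(effect = names(dist$counts), count = dist$counts),
    out_path(config, "effect_distribution.tsv"), sep = "\t",
    quote = FALSE, row.names = FALSE)
  config
}

stage_pangenome <- function(config) {
  cohort <- load_hc_cohort(config)
  presence <- buildPresence(cohort,
                            threshold = config$presence_threshold)
  partition <- partitionPanGenome(presence, sampleInfo(cohort))
  sets <- partitionSets(partition)
  tab <- data.frame(
    variant_id = c(sets$core, sets$shared, sets$unique, sets$discarded),
    class = rep(c("core", "shared", "unique", "discarded"),
                c(length(sets$core), length(sets$shared),
                  length(sets$unique), length(sets$discarded))))
  config$partition_table <- out_path(config, "partition.tsv")
  utils::write.table(tab[order(tab$class, tab$variant_id), ],
                     config$partition_table, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  config
}

stage_longitudinal <- function(config) {
  cohort <- load_hc_cohort(config)
  presence <- buildPresence(cohort,
                            threshold = config$presence_threshold)
  prof <- longitudinalAccumulation(presence, sampleInfo(cohort))
  tab <- data.frame(sample_id = prof$sample_id,
                    cumulative = prof$cumulative,
                    delta = c(NA, prof$deltas),
                    symmetric_difference = c(NA,
                                             prof$symmetric_difference))
  utils::write.table(tab, out_path(config, "longitudinal.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  config
}

stage_hotspots <- function(config) {
  effects <- utils::read.delim(need_input(config, "effects_table"),
                               stringsAsFactors = FALSE)
  annotation <- load_annotation(config)
  part <- utils::read.delim(need_input(config, "partition_table"),
                            stringsAsFactors = FALSE)
  hs <- callHotspots(effects, annotation,
                     core = part$variant_id[part$class == "core"])
  config$hotspot_table <- out_path(config, "hotspots.tsv")
  utils::write.table(hs, config$hotspot_table, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  config
}

stage_score <- function(config) {
  if (is.null(config$pssm_dir) || !dir.exists(config$pssm_dir)) {
    message("no pssm_dir configured; skipping function-change scoring")
    return(config)
  }
  effects <- utils::read.delim(need_input(config, "effects_table"),
                               stringsAsFactors = FALSE)
  models <- lapply(list.files(config$pssm_dir, pattern = "\\.tsv$",
                              full.names = TRUE), readPssm)
  scores <- scoreEffects(effects, models)
  utils::write.table(scores, out_path(config, "function_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  config
}

stage_expression <- function(config) {
  se <- readCountsMatrix(need_input(config, "counts"),
                         need_input(config, "design"))
  se <- normalizeCounts(se)
  panel <- if (!is.null(config$candidate_genes) &&
               file.exists(config$candidate_genes))
    utils::read.delim(config$candidate_genes,
                      stringsAsFactors = FALSE)$locus_tag
  de <- testDifferentialExpression(
    se, baseline = config$baseline, fdr = config$fdr,
    log2Cutoff = config$log2_cutoff,
    negLog10Cutoff = config$neglog10_cutoff, genes = panel)
  config$de_table <- out_path(config, "de_calls.tsv")
  utils::write.table(de, config$de_table, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sig <- unique(de$locus_tag[de$significant])
  if (length(sig) >= 2) {
    m <- stats::reshape(de[de$locus_tag %in% sig,
                           c("locus_tag", "contrast", "log2_diff")],
                        idvar = "locus_tag", timevar = "contrast",
                        direction = "wide")
    mat <- as.matrix(m[, -1, drop = FALSE])
    rownames(mat) <- m$locus_tag
    cl <- clusterDeGenes(mat)
    writeLines(cl$newick, out_path(config, "de_dendrogram.nwk"))
  }
  config
}

stage_growth <- function(config) {
  curves <- readGrowthCurves(need_input(config, "growth_csv"))
  fits <- fitGrowthRates(curves)
  config$growth_table <- out_path(config, "growth.tsv")
  utils::write.table(fits, config$growth_table, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ids <- names(curves)
  rows <- list()
  if (length(ids) >= 2) {
    for (i in seq_len(length(ids) - 1)) for (j in (i + 1):length(ids)) {
      a <- curves[[ids[i]]]; b <- curves[[ids[j]]]
      a <- a[a$od > 0, ]; b <- b[b$od > 0, ]
      res <- ancovaCompare(list(x = a$time, y = log(a$od)),
                           list(x = b$time, y = log(b$od)),
                           modelForm = config$ancova_form,
                           alpha = config$ancova_alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = paste(ids[i], "vs", ids[j]),
        model_form = res$model_form, coefficient = res$coefficient,
        p_value = res$p_value, significant = res$significant,
        stringsAsFactors = FALSE)
    }
    utils::write.table(do.call(rbind, rows),
                       out_path(config, "ancova.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  config
}

stage_report <- function(config) {
  read_if <- function(key) {
    p <- config[[key]]
    if (!is.null(p) && file.exists(p))
      utils::read.delim(p, stringsAsFactors = FALSE) else NULL
  }
  part_tab <- read_if("partition_table")
  partition <- if (!is.null(part_tab)) {
    by_class <- split(part_tab$variant_id, factor(
      part_tab$class, levels = c("core", "shared", "unique", "discarded")))
    n <- nrow(part_tab)
    new("PanGenomePartition", core = by_class$core,
        shared = by_class$shared, unique = by_class$unique,
        discarded = by_class$discarded,
        fractions = vapply(by_class, function(x)
          if (n == 0) 0 else length(x) / n, numeric(1)))
  }
  writeReport(file.path(config$outdir, "report"), partition = partition,
              hotspots = read_if("hotspot_table"),
              deCalls = read_if("de_table"),
              growthStats = read_if("growth_table"))
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a
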