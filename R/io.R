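#' Read a sample sheet
#'
#' TSV with columns \code{sample_id}, \code{role}, \code{stage_index},
#' \code{stage_label}.
#'
#' @param path file path.
#' @return data.frame sample sheet (validated when combined into a
#'   \linkS4class{MutationCohort}).
#' @export
readSampleSheet <- function(path) {
  s <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "role", "stage_index", "stage_label")
  if (!all(need %in% names(s)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  s$stage_index <- as.integer(s$stage_index)
  s
}

#' Read a per-sample variant table
#'
#' Reads either the package's TSV dialect (header columns
#' \code{sample_id}, \code{position}, \code{ref}, \code{alt},
#' \code{caller_class}, \code{confidence_flag} and optionally
#' \code{allele_frequency} and \code{chrom}) or a minimal VCF (detected by
#' a \code{##fileformat=VCF} first line; per-sample genotype columns, INFO
#' keys \code{CLASS}, \code{CONF}, \code{AF}).
#'
#' @param path file path.
#' @param samples sample sheet data.frame; observations naming unknown
#'   sample_ids are rejected.
#' @return A \linkS4class{MutationCohort}.
#' @export
readVariantTable <- function(path, samples) {
  first <- readLines(path, n = 1L)
  calls <- if (length(first) && startsWith(first, "##fileformat=VCF"))
    parse_minimal_vcf(path) else parse_variant_tsv(path)
  MutationCohort(calls, samples)
}

parse_variant_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("variant table has no header: ", path)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  need <- c("sample_id", "position", "ref", "alt", "caller_class",
            "confidence_flag")
  if (!all(need %in% header))
    stop("variant table must have columns: ", paste(need, collapse = ", "))
  if (length(lines) == 1) return(empty_calls())
  ncol <- length(header)
  # sentinel keeps trailing empty fields that strsplit would drop
  rows <- strsplit(paste0(lines[-1], "\x01"), "\t", fixed = TRUE)
  rows <- lapply(rows, function(r) {
    r[length(r)] <- sub("\x01$", "", r[length(r)])
    r
  })
  lens <- lengths(rows)
  if (any(lens != ncol))
    stop(sprintf("parse error at line %d: expected %d fields, found %d",
                 which(lens != ncol)[1] + 1L, ncol,
                 lens[lens != ncol][1]))
  m <- do.call(rbind, rows)
  colnames(m) <- header
  pos <- suppressWarnings(as.integer(m[, "position"]))
  if (anyNA(pos))
    stop(sprintf("parse error at line %d: non-integer position '%s'",
                 which(is.na(pos))[1] + 1L, m[is.na(pos)[1], "position"]))
  flag <- m[, "confidence_flag"]
  if (!all(flag %in% VALID_FLAGS))
    stop("confidence_flag outside {hc, fp, ise, sv}: ",
         paste(unique(flag[!flag %in% VALID_FLAGS]), collapse = ", "))
  af <- if ("allele_frequency" %in% header) {
    raw <- m[, "allele_frequency"]
    ifelse(raw %in% c("", "NA", "."), NA_real_,
           suppressWarnings(as.numeric(raw)))
  } else rep(NA_real_, nrow(m))
  chrom <- if ("chrom" %in% header) m[, "chrom"] else rep("chr", nrow(m))
  data.frame(
    variant_id = sprintf("%s:%d:%s>%s", chrom, pos, m[, "ref"], m[, "alt"]),
    sample_id = m[, "sample_id"], position = pos,
    ref_allele = m[, "ref"], alt_allele = m[, "alt"],
    caller_class = m[, "caller_class"], confidence_flag = flag,
    allele_frequency = af, stringsAsFactors = FALSE)
}

parse_minimal_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("reading VCF input requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("minimal VCF input requires a GT genotype field")
  ref <- as.character(rr$REF)
  alt <- vapply(seq_along(rr), function(i)
    as.character(rr$ALT[[i]])[1], character(1))
  cls <- if ("CLASS" %in% names(info)) as.character(info$CLASS)
         else rep("snp", length(rr))
  conf <- if ("CONF" %in% names(info)) as.character(info$CONF)
          else rep("hc", length(rr))
  af <- if ("AF" %in% names(info))
    vapply(info$AF, function(x) as.numeric(x)[1], numeric(1))
  else rep(NA_real_, length(rr))
  out <- list()
  for (i in seq_along(rr)) {
    carriers <- colnames(gt)[grepl("1", gt[i, ])]
    if (length(carriers) == 0) next
    out[[length(out) + 1L]] <- data.frame(
      variant_id = sprintf("%s:%d:%s>%s",
                           as.character(GenomicRanges::seqnames(rr)[i]),
                           GenomicRanges::start(rr)[i], ref[i], alt[i]),
      sample_id = carriers,
      position = GenomicRanges::start(rr)[i],
      ref_allele = ref[i], alt_allele = alt[i],
      caller_class = cls[i], confidence_flag = conf[i],
      allele_frequency = af[i], stringsAsFactors = FALSE)
  }
  if (length(out) == 0) return(empty_calls())
  do.call(rbind, out)
}

#' Write a cohort's variant observations as TSV
#'
#' Inverse of \code{\link{readVariantTable}} for the TSV dialect;
#' writing then reading reproduces the in-memory observations.
#'
#' @param cohort a \linkS4class{MutationCohort}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeVariantTable <- function(cohort, path) {
  v <- variantCalls(cohort)
  chrom <- sub(":.*$", "", v$variant_id)
  out <- data.frame(chrom = chrom, sample_id = v$sample_id,
                    position = v$position, ref = v$ref_allele,
                    alt = v$alt_allele, caller_class = v$caller_class,
                    confidence_flag = v$confidence_flag,
                    allele_frequency = v$allele_frequency,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeVariantTable
#' @export
writeSampleSheet <- function(cohort, path) {
  utils::write.table(sampleInfo(cohort), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read genome annotation from GFF3 plus membership tables
#'
#' @param gffPath GFF3 file with gene and/or CDS features carrying
#'   \code{locus_tag} attributes.
#' @param operonPath optional TSV of (\code{group_id}, \code{locus_tag});
#'   row order within a group gives the transcription-unit gene order.
#' @param pathwayPath optional TSV of (\code{group_id}, \code{locus_tag}).
#' @param referenceLength reference length override (bp).
#' @return A \linkS4class{GenomeAnnotation}, genes sorted by start.
#' @export
readAnnotation <- function(gffPath, operonPath = NULL, pathwayPath = NULL,
                           referenceLength = NULL) {
  gr <- rtracklayer::import(gffPath)
  keep <- as.character(gr$type) %in% c("gene", "CDS")
  gr <- gr[keep & !is.na(gr$locus_tag)]
  gr <- gr[!duplicated(gr$locus_tag)]
  genes <- GenomicRanges::granges(gr)
  genes$locus_tag <- gr$locus_tag
  genes$product <- if ("product" %in% names(S4Vectors::mcols(gr)))
    as.character(gr$product) else rep(NA_character_, length(gr))
  GenomeAnnotation(genes,
                   operons = read_membership(operonPath),
                   pathways = read_membership(pathwayPath),
                   referenceLength = referenceLength)
}

read_membership <- function(path) {
  if (is.null(path)) return(list())
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("group_id", "locus_tag") %in% names(tab)))
    stop("membership table must have columns group_id, locus_tag: ", path)
  split(tab$locus_tag, factor(tab$group_id, levels = unique(tab$group_id)))
}

write_membership <- function(groups, path) {
  tab <- data.frame(
    group_id = rep(names(groups), lengths(groups)),
    locus_tag = unlist(groups, use.names = FALSE),
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a GenomeAnnotation back to GFF3 plus membership tables
#'
#' @param annotation a \linkS4class{GenomeAnnotation}.
#' @param gffPath,operonPath,pathwayPath output paths (membership paths
#'   optional).
#' @return \code{gffPath}, invisibly.
#' @export
writeAnnotation <- function(annotation, gffPath, operonPath = NULL,
                            pathwayPath = NULL) {
  g <- annotatedGenes(annotation)
  g$type <- "gene"
  g$source <- "panmut"
  g$ID <- g$locus_tag
  rtracklayer::export(g, gffPath, format = "gff3")
  if (!is.null(operonPath)) write_membership(operons(annotation), operonPath)
  if (!is.null(pathwayPath))
    write_membership(pathways(annotation), pathwayPath)
  invisible(gffPath)
}

#' Read and write profile-model PSSMs
#'
#' TSV with a \code{position} column (1-based within the domain) and one
#' column per one-letter residue code; model metadata is carried in
#' \code{#key=value} comment lines (\code{model_id}, \code{domain_locus},
#' \code{protein_start}).
#'
#' @param path file path.
#' @return \code{readPssm}: a \linkS4class{ProfileModel}.
#' @export
readPssm <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list(model_id = "model", domain_locus = NA_character_,
               protein_start = "1")
  for (ml in meta_lines) {
    kv <- strsplit(sub("^#", "", ml), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  tab <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                           stringsAsFactors = FALSE)
  if (!"position" %in% names(tab)) stop("PSSM must have a position column")
  tab <- tab[order(tab$position), , drop = FALSE]
  m <- as.matrix(tab[, setdiff(names(tab), "position"), drop = FALSE])
  ProfileModel(m, modelId = meta$model_id, domainLocus = meta$domain_locus,
               proteinStart = as.integer(meta$protein_start))
}

#' @rdname readPssm
#' @param model a \linkS4class{ProfileModel}.
#' @export
writePssm <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#model_id=%s", model@modelId),
               sprintf("#domain_locus=%s", model@domainLocus),
               sprintf("#protein_start=%d", model@proteinStart)), con)
  tab <- data.frame(position = seq_len(nrow(model@pssm)), model@pssm,
                    check.names = FALSE)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an aligned protein FASTA
#'
#' @param path aligned FASTA; all sequences must share one width.
#' @return An \link[Biostrings]{AAStringSet} of equal-width rows.
#' @export
readMsa <- function(path) {
  aln <- Biostrings::readAAStringSet(path)
  if (length(aln) == 0) stop("empty alignment: ", path)
  if (length(unique(Biostrings::width(aln))) != 1)
    stop("alignment rows have unequal widths: ", path)
  aln
}

#' Read an RNA-seq raw-count matrix with its design
#'
#' @param countsPath TSV; first column \code{locus_tag}, remaining columns
#'   one per sample.
#' @param designPath TSV with columns \code{sample}, \code{condition},
#'   \code{replicate}.
#' @return A \link[SummarizedExperiment]{SummarizedExperiment} with assay
#'   \code{counts} and colData condition/replicate.
#' @export
readCountsMatrix <- function(countsPath, designPath) {
  tab <- utils::read.delim(countsPath, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (!"locus_tag" %in% names(tab))
    stop("counts table must have a locus_tag column")
  m <- as.matrix(tab[, setdiff(names(tab), "locus_tag"), drop = FALSE])
  rownames(m) <- tab$locus_tag
  design <- utils::read.delim(designPath, stringsAsFactors = FALSE)
  need <- c("sample", "condition", "replicate")
  if (!all(need %in% names(design)))
    stop("design table must have columns: ", paste(need, collapse = ", "))
  if (!setequal(design$sample, colnames(m)))
    stop("design samples do not match counts columns")
  design <- design[match(colnames(m), design$sample), , drop = FALSE]
  if (any(m < 0)) stop("counts must be non-negative")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = m),
    colData = S4Vectors::DataFrame(condition = design$condition,
                                   replicate = as.integer(design$replicate),
                                   row.names = design$sample))
}

#' @rdname readCountsMatrix
#' @param se a SummarizedExperiment with assay \code{counts}.
#' @export
writeCountsMatrix <- function(se, countsPath, designPath) {
  m <- SummarizedExperiment::assay(se, "counts")
  tab <- data.frame(locus_tag = rownames(m), m, check.names = FALSE)
  utils::write.table(tab, countsPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cd <- SummarizedExperiment::colData(se)
  utils::write.table(
    data.frame(sample = rownames(cd), condition = cd$condition,
               replicate = cd$replicate),
    designPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(countsPath)
}

#' Read growth-curve time series from CSV
#'
#' CSV with columns \code{strain}, \code{condition}, optional
#' \code{replicate}, \code{time} (hours), \code{od} (OD600,
#' blank-referenced readings may be slightly negative) and optionally
#' further product/substrate concentration columns in g/L.
#'
#' @param path CSV path.
#' @return Named list of per-(strain, condition, replicate) data.frames
#'   with strictly increasing \code{time}.
#' @export
readGrowthCurves <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("strain", "condition", "time", "od")
  if (!all(need %in% names(tab)))
    stop("growth CSV must have columns: ", paste(need, collapse = ", "))
  key <- if ("replicate" %in% names(tab))
    interaction(tab$strain, tab$condition, tab$replicate, drop = TRUE,
                lex.order = TRUE)
  else interaction(tab$strain, tab$condition, drop = TRUE,
                   lex.order = TRUE)
  curves <- split(tab, key)
  lapply(curves, function(cv) {
    cv <- cv[order(cv$time), , drop = FALSE]
    if (nrow(cv) < 3) stop("growth curve needs at least 3 time points")
    if (any(diff(cv$time) <= 0)) stop("times must be strictly increasing")
    rownames(cv) <- NULL
    cv
  })
}

#' @rdname readGrowthCurves
#' @param curves list of growth-curve data.frames (as returned by
#'   \code{readGrowthCurves} or \code{\link{simulateGrowthCurves}}).
#' @export
writeGrowthCurves <- function(curves, path) {
  tab <- do.call(rbind, c(curves, list(make.row.names = FALSE)))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the end-of-pipeline report
#'
#' Machine-readable TSVs (partition, hotspots, differential-expression
#' calls, growth statistics) plus a human-readable summary.  Re-running on
#' the same inputs is byte-identical: all tables are sorted before writing.
#'
#' @param dir output directory (created if needed).
#' @param partition optional \linkS4class{PanGenomePartition}.
#' @param hotspots optional hotspot data.frame from
#'   \code{\link{callHotspots}}.
#' @param deCalls optional DE-call data.frame from
#'   \code{\link{testDifferentialExpression}}.
#' @param growthStats optional data.frame of growth fits / ANCOVA results.
#' @return \code{dir}, invisibly.
#' @export
writeReport <- function(dir, partition = NULL, hotspots = NULL,
                        deCalls = NULL, growthStats = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  summary_lines <- c("panmut analysis report", "======================")
  if (!is.null(partition)) {
    sets <- partitionSets(partition)
    tab <- data.frame(
      variant_id = c(sets$core, sets$shared, sets$unique, sets$discarded),
      class = rep(c("core", "shared", "unique", "discarded"),
                  c(length(sets$core), length(sets$shared),
                    length(sets$unique), length(sets$discarded))),
      stringsAsFactors = FALSE)
    tab <- tab[order(tab$class, tab$variant_id), , drop = FALSE]
    utils::write.table(tab, file.path(dir, "partition.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    summary_lines <- c(summary_lines, sprintf(
      "Pan-genome partition: %d core, %d shared, %d unique, %d discarded",
      length(sets$core), length(sets$shared), length(sets$unique),
      length(sets$discarded)))
  }
  if (!is.null(hotspots)) {
    hs <- hotspots[order(-hotspots$n_mutations, hotspots$hotspot_id), ,
                   drop = FALSE]
    utils::write.table(hs, file.path(dir, "hotspots.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    summary_lines <- c(summary_lines,
                       sprintf("Hotspots: %d groups covering %d mutations",
                               nrow(hs), sum(hs$n_mutations)))
  }
  if (!is.null(deCalls)) {
    de <- deCalls[order(deCalls$locus_tag, deCalls$contrast), , drop = FALSE]
    utils::write.table(de, file.path(dir, "de_calls.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    summary_lines <- c(summary_lines, sprintf(
      "Differential expression: %d significant calls over %d genes",
      sum(de$significant), length(unique(de$locus_tag))))
  }
  if (!is.null(growthStats)) {
    gs <- growthStats[do.call(order, growthStats), , drop = FALSE]
    utils::write.table(gs, file.path(dir, "growth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    summary_lines <- c(summary_lines,
                       sprintf("Growth statistics: %d rows", nrow(gs)))
  }
  writeLines(summary_lines, file.path(dir, "summary.txt"))
  invisible(dir)
}
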