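#' Configuration for the synthetic-cohort generator
#'
#' Defaults emulate the sequenced study design: one wild-type ancestor,
#' six intermediate population samples and seven endpoint single-colony
#' isolates; mutations accumulating at roughly 5 +/- 3 established
#' mutations between consecutive population samples; 20 ancestor-shared
#' reference artifacts; caller flag noise dominated by false positives;
#' a bacterial-scale reference with most mutations falling in coding
#' sequence.
#'
#' @param seed mandatory integer seed; every draw is reproducible.
#' @param nPopulations,nIsolates cohort design (defaults 6 and 7).
#' @param genomeLength reference length in bp (default 3.84e6, a
#'   Clostridium-scale chromosome).
#' @param nGenes,geneLength annotation density (defaults 3000 genes of
#'   900 bp).
#' @param nOperons,nPathways grouping structure sizes.
#' @param epochGainMean,epochGainSd per-epoch established-mutation gain
#'   distribution (defaults 5 and 3; draws are rounded and truncated at
#'   0).
#' @param pCore probability that a population-borne mutation fixes (ends
#'   up in every isolate) rather than being discarded (default 0.48).
#' @param nUnique,nShared isolate-private mutation counts (defaults 23
#'   and 4, the endpoint burden of the emulated design).
#' @param nSubthreshold how many isolate-private mutations are also
#'   detected in the final population below the presence threshold, at
#'   frequencies drawn uniformly on (0, 0.02) (default 4).
#' @param nWtArtifacts ancestor-shared artifacts present in every sample
#'   including the wild type (default 20).
#' @param flagNoise named integer vector of fp/ise/sv flagged caller
#'   noise variants (default c(fp = 120, ise = 5, sv = 6)).
#' @param codingFraction probability a mutation lands inside a CDS
#'   (default 0.89).
#' @param indelFraction fraction of true mutations that are indels
#'   (default 0.15).
#' @return list of generator settings for \code{\link{simulateCohort}}.
#' @export
cohortConfig <- function(seed,
                         nPopulations = 6L, nIsolates = 7L,
                         genomeLength = 3840000L,
                         nGenes = 3000L, geneLength = 900L,
                         nOperons = 60L, nPathways = 40L,
                         epochGainMean = 5, epochGainSd = 3,
                         pCore = 0.48,
                         nUnique = 23L, nShared = 4L, nSubthreshold = 4L,
                         nWtArtifacts = 20L,
                         flagNoise = c(fp = 120L, ise = 5L, sv = 6L),
                         codingFraction = 0.89,
                         indelFraction = 0.15) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(pCore >= 0, pCore <= 1, codingFraction >= 0,
            codingFraction <= 1, indelFraction >= 0, indelFraction <= 1)
  as.list(environment())
}

#' Generate a complete synthetic study cohort with planted truth
#'
#' Simulates a single dominant lineage under serial transfer: mutations
#' arise per epoch and either fix (appearing in every later population
#' sample and in all isolates: planted core) or segregate in the
#' populations without reaching any isolate (planted discarded).
#' Isolate-private mutations (planted unique/shared) arise at the
#' endpoint, a configurable few of them also detected in the final
#' population below the presence threshold.  Ancestor-shared artifacts
#' and flag-noise variants are planted on top.  All outputs are
#' deterministic functions of \code{config$seed}.
#'
#' @param config a list from \code{\link{cohortConfig}}.
#' @return list with \code{cohort} (a \linkS4class{MutationCohort}),
#'   \code{annotation} (a \linkS4class{GenomeAnnotation}),
#'   \code{reference} (a \link[Biostrings]{DNAString}) and \code{truth}
#'   (list: \code{labels}, a named character vector over variant ids with
#'   values core/shared/unique/discarded/wt_artifact/flag_noise;
#'   \code{epoch_gains}; \code{epoch_of}).
#' @export
simulateCohort <- function(config) {
  set.seed(config$seed)
  ref_chars <- sample(c("A", "C", "G", "T"), config$genomeLength,
                      replace = TRUE)
  reference <- Biostrings::DNAString(paste(ref_chars, collapse = ""))

  annotation <- simulate_annotation(config)
  genes <- annotatedGenes(annotation)
  gene_start <- GenomicRanges::start(genes)
  gene_end <- GenomicRanges::end(genes)

  samples <- data.frame(
    sample_id = c("WT", paste0("P", seq_len(config$nPopulations)),
                  paste0("I", seq_len(config$nIsolates))),
    role = c("wild_type", rep("population", config$nPopulations),
             rep("isolate", config$nIsolates)),
    stage_index = c(0L, seq_len(config$nPopulations),
                    rep(config$nPopulations, config$nIsolates)),
    stage_label = c("ancestor",
                    paste0("transfer epoch ", seq_len(config$nPopulations)),
                    rep("endpoint isolate", config$nIsolates)),
    stringsAsFactors = FALSE)
  pops <- paste0("P", seq_len(config$nPopulations))
  isos <- paste0("I", seq_len(config$nIsolates))

  used <- new.env(parent = emptyenv())
  draw_position <- function(coding) {
    repeat {
      if (coding) {
        g <- sample.int(length(genes), 1)
        pos <- gene_start[g] + sample.int(gene_end[g] - gene_start[g] + 1L,
                                          1) - 1L
      } else {
        pos <- sample.int(config$genomeLength, 1)
        g <- findInterval(pos, gene_start)
        if (g >= 1 && pos <= gene_end[g]) next
      }
      key <- as.character(pos)
      if (is.null(used[[key]])) {
        used[[key]] <- TRUE
        return(pos)
      }
    }
  }
  make_variant <- function(class = NULL) {
    coding <- stats::runif(1) < config$codingFraction
    pos <- draw_position(coding)
    ref <- ref_chars[pos]
    if (is.null(class))
      class <- if (stats::runif(1) < config$indelFraction) "indel" else "snp"
    alt <- if (class == "snp") sample(setdiff(c("A", "C", "G", "T"), ref), 1)
           else "-"
    list(variant_id = sprintf("chr:%d:%s>%s", pos, ref, alt),
         position = pos, ref = ref, alt = alt, class = class)
  }

  rows <- list()
  labels <- character()
  epoch_of <- integer()
  add_obs <- function(v, sample_ids, freqs, flag, class) {
    rows[[length(rows) + 1L]] <<- data.frame(
      variant_id = v$variant_id, sample_id = sample_ids,
      position = v$position, ref_allele = v$ref, alt_allele = v$alt,
      caller_class = class, confidence_flag = flag,
      allele_frequency = freqs, stringsAsFactors = FALSE)
  }

  gains <- pmax(0L, as.integer(round(stats::rnorm(
    config$nPopulations, config$epochGainMean, config$epochGainSd))))
  for (e in seq_len(config$nPopulations)) {
    for (k in seq_len(gains[e])) {
      v <- make_variant()
      fixed <- stats::runif(1) < config$pCore
      later_pops <- pops[e:config$nPopulations]
      if (fixed) {
        add_obs(v, later_pops, rep(1.0, length(later_pops)), "hc", v$class)
        add_obs(v, isos, rep(NA_real_, length(isos)), "hc", v$class)
        labels[v$variant_id] <- "core"
      } else {
        add_obs(v, later_pops,
                stats::runif(length(later_pops), 0.02, 0.5), "hc", v$class)
        labels[v$variant_id] <- "discarded"
      }
      epoch_of[v$variant_id] <- e
    }
  }

  n_private <- config$nUnique + config$nShared
  private_sub <- if (n_private > 0 && config$nSubthreshold > 0)
    sample.int(n_private, min(config$nSubthreshold, n_private))
  else integer()
  for (k in seq_len(n_private)) {
    v <- make_variant()
    if (k <= config$nUnique) {
      carriers <- sample(isos, 1)
      labels[v$variant_id] <- "unique"
    } else {
      carriers <- sample(isos, sample(2:(config$nIsolates - 1), 1))
      labels[v$variant_id] <- "shared"
    }
    add_obs(v, carriers, rep(NA_real_, length(carriers)), "hc", v$class)
    if (k %in% private_sub)
      add_obs(v, pops[config$nPopulations], stats::runif(1, 0, 0.0199),
              "hc", v$class)
    epoch_of[v$variant_id] <- config$nPopulations
  }

  for (k in seq_len(config$nWtArtifacts)) {
    v <- make_variant()
    all_ids <- samples$sample_id
    freqs <- ifelse(samples$role == "population", 1.0, NA_real_)
    add_obs(v, all_ids, freqs, "hc", v$class)
    labels[v$variant_id] <- "wt_artifact"
  }

  for (flag in names(config$flagNoise)) {
    class <- if (flag == "sv") "structural" else "snp"
    for (k in seq_len(config$flagNoise[[flag]])) {
      v <- make_variant(class = class)
      carriers <- sample(samples$sample_id, sample(1:3, 1))
      freqs <- ifelse(samples$role[match(carriers, samples$sample_id)] ==
                        "population", stats::runif(length(carriers), 0.02, 0.5),
                      NA_real_)
      add_obs(v, carriers, freqs, flag, class)
      labels[v$variant_id] <- "flag_noise"
    }
  }

  calls <- do.call(rbind, rows)
  list(cohort = MutationCohort(calls, samples), annotation = annotation,
       reference = reference,
       truth = list(labels = labels, epoch_gains = gains,
                    epoch_of = epoch_of))
}

simulate_annotation <- function(config) {
  spacing <- config$genomeLength %/% config$nGenes
  if (spacing <= config$geneLength)
    stop("infeasible config: genes do not fit the genome ",
         "(genomeLength / nGenes must exceed geneLength)")
  starts <- (seq_len(config$nGenes) - 1L) * spacing + 1L
  genes <- GenomicRanges::GRanges(
    "chr",
    IRanges::IRanges(start = starts, width = config$geneLength),
    strand = sample(c("+", "-"), config$nGenes, replace = TRUE))
  genes$locus_tag <- sprintf("SCT_%04d", seq_len(config$nGenes))
  genes$product <- rep("synthetic protein", config$nGenes)
  operons <- list()
  if (config$nOperons > 0) {
    anchors <- sort(sample.int(config$nGenes - 6L, config$nOperons))
    for (i in seq_along(anchors)) {
      len <- sample(2:6, 1)
      operons[[sprintf("op_%03d", i)]] <-
        genes$locus_tag[anchors[i]:(anchors[i] + len - 1L)]
    }
  }
  pathways <- list()
  if (config$nPathways > 0) {
    for (i in seq_len(config$nPathways))
      pathways[[sprintf("pw_%03d", i)]] <-
        sort(sample(genes$locus_tag, sample(3:8, 1)))
  }
  GenomeAnnotation(genes, operons = operons, pathways = pathways,
                   referenceLength = config$genomeLength)
}

#' Simulate a transcriptome count matrix with a planted candidate panel
#'
#' Gene means are drawn log-normally; counts are negative binomial with a
#' common dispersion.  The matrix emulates the study design the DE stage
#' assumes: normalisation factors are estimated from a transcriptome-wide
#' matrix, while the ANOVA is run on a small mutation-linked candidate
#' panel that is rich in true expression changes.  A candidate panel of
#' \code{panelSize} genes is embedded in a null transcriptome background;
#' \code{deFraction} of the panel has its mean shifted by \code{2^log2fc}
#' in every non-baseline condition.
#'
#' Defaults emulate the emulated study's analysis: a 41-gene candidate
#' panel of which about 60 percent are differentially expressed
#' somewhere, five strain-by-hydrolysate conditions with the wild type
#' in plain medium as baseline, and triplicate fermentations.
#'
#' @param nGenes transcriptome size (default 2000).
#' @param panelSize candidate-panel size (default 41).
#' @param conditions character vector of condition names; the first is
#'   the baseline (default the five strain/medium combinations
#'   WT_0, WT_10, PM_0, PM_10, PM_17.5).
#' @param nReplicates replicates per condition (default 3).
#' @param deFraction fraction of panel genes planted as differentially
#'   expressed (default 0.6).
#' @param log2fc planted log2 fold change (default 2).
#' @param dispersion negative-binomial dispersion (default 0.05; variance
#'   = mu + dispersion * mu^2).
#' @param meanLog,sdLog log-normal parameters of baseline gene means
#'   (defaults log(200) and 1).
#' @param seed mandatory integer seed.
#' @return list with \code{se} (a SummarizedExperiment with assay
#'   \code{counts} and condition/replicate colData), \code{panel}
#'   (candidate locus tags) and \code{truth} (data.frame of
#'   \code{locus_tag}, \code{panel}, \code{de}, \code{log2fc}).
#' @export
simulateCounts <- function(nGenes = 2000, panelSize = 41,
                           conditions = c("WT_0", "WT_10", "PM_0",
                                          "PM_10", "PM_17.5"),
                           nReplicates = 3, deFraction = 0.6, log2fc = 2,
                           dispersion = 0.05, meanLog = log(200), sdLog = 1,
                           seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(panelSize <= nGenes)
  set.seed(seed)
  genes <- sprintf("SCT_%04d", seq_len(nGenes))
  mu <- stats::rlnorm(nGenes, meanLog, sdLog)
  panel <- rep(FALSE, nGenes)
  panel[sample.int(nGenes, panelSize)] <- TRUE
  n_de <- round(deFraction * panelSize)
  de <- rep(FALSE, nGenes)
  if (n_de > 0) de[sample(which(panel), n_de)] <- TRUE
  cond_of <- rep(conditions, each = nReplicates)
  m <- matrix(0, nrow = nGenes, ncol = length(cond_of),
              dimnames = list(genes, sprintf("%s_r%d", cond_of,
                                             rep(seq_len(nReplicates),
                                                 length(conditions)))))
  for (j in seq_along(cond_of)) {
    mu_j <- mu
    if (cond_of[j] != conditions[1])
      mu_j[de] <- mu_j[de] * 2^log2fc
    m[, j] <- stats::rnbinom(nGenes, mu = mu_j, size = 1 / dispersion)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = m),
    colData = S4Vectors::DataFrame(
      condition = cond_of,
      replicate = rep(seq_len(nReplicates), length(conditions)),
      row.names = colnames(m)))
  truth <- data.frame(locus_tag = genes, panel = panel, de = de,
                      log2fc = ifelse(de, log2fc, 0),
                      stringsAsFactors = FALSE)
  list(se = se, panel = genes[panel], truth = truth)
}

#' Simulate lag/exponential/stationary growth curves
#'
#' OD(t) = OD0 during the lag phase, grows exponentially at rate
#' \code{mu} after it, and plateaus at \code{odMax}; Gaussian measurement
#' noise is added.  Substrate utilisation tracks biomass and product
#' concentrations follow the planted yields.
#'
#' @param mu true net growth rate (1/h), > 0.
#' @param lagH lag duration in hours (default 4).
#' @param od0 initial OD600 (default 0.05).
#' @param odMax stationary-phase plateau (default 0.75).
#' @param noiseSd Gaussian OD noise standard deviation (default 0.01).
#' @param yields named numeric of product yields in g product per g
#'   substrate utilised (default c(ethanol = 0.35, acetic_acid = 1)).
#' @param substrateTotal substrate consumed from lag end to plateau, g/L
#'   (default 4.5).
#' @param times sampling times in hours (default 0 to 24 h, hourly).
#' @param nCurves replicate curves (default 1).
#' @param strain,condition labels attached to each curve.
#' @param seed mandatory integer seed.
#' @return list with \code{curves} (named list of data.frames with
#'   columns strain, condition, time, od, substrate_used and one column
#'   per product) and \code{truth} (mu, lag, yields).
#' @export
simulateGrowthCurves <- function(mu, lagH = 4, od0 = 0.05, odMax = 0.75,
                                 noiseSd = 0.01,
                                 yields = c(ethanol = 0.35,
                                            acetic_acid = 1),
                                 substrateTotal = 4.5,
                                 times = seq(0, 24, by = 1), nCurves = 1,
                                 strain = "PM", condition = "0% v/v",
                                 seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (mu <= 0) stop("mu must be positive")
  set.seed(seed)
  curves <- list()
  for (r in seq_len(nCurves)) {
    od_true <- pmin(od0 * exp(mu * pmax(times - lagH, 0)), odMax)
    od <- od_true + stats::rnorm(length(times), 0, noiseSd)
    used <- substrateTotal * (od_true - od0) / (odMax - od0)
    cv <- data.frame(strain = strain, condition = condition,
                     replicate = r, time = times, od = od,
                     substrate_used = used, stringsAsFactors = FALSE)
    for (p in names(yields))
      cv[[p]] <- yields[[p]] * used +
        stats::rnorm(length(times), 0, noiseSd)
    curves[[sprintf("%s.%s.r%d", strain, condition, r)]] <- cv
  }
  list(curves = curves,
       truth = list(mu = mu, lag = lagH, yields = yields))
}
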