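test_that("upper-quartile scaling matches hand arithmetic and equalises quartiles", {
  m <- matrix(c(1, 2, 7,
                2, 4, 14), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = m),
    colData = S4Vectors::DataFrame(condition = c("a", "b"),
                                   replicate = c(1L, 1L),
                                   row.names = c("s1", "s2")))
  norm <- normalizeCounts(se)
  # factors: 75th percentile of nonzero counts = 4.5 and 9 (type-7);
  # geometric mean of factors = sqrt(4.5 * 9)
  gm <- sqrt(4.5 * 9)
  expect_equal(SummarizedExperiment::assay(norm, "uq")[, "s1"],
               m[, "s1"] / 4.5 * gm)
  expect_equal(SummarizedExperiment::assay(norm, "log2uq")["g3", "s2"],
               log2(14 / 9 * gm + 1))
  # sample 2 is an exact 2x rescaling of sample 1: identical normalized cols
  expect_equal(SummarizedExperiment::assay(norm, "uq")[, "s1"],
               SummarizedExperiment::assay(norm, "uq")[, "s2"])

  sc <- simulateCounts(seed = 31)
  uq <- SummarizedExperiment::assay(normalizeCounts(sc$se), "uq")
  q75 <- apply(uq, 2, function(x) quantile(x[x > 0], 0.75))
  expect_equal(max(q75) - min(q75), 0, tolerance = 1e-9)

  zero <- m; zero[, 1] <- 0
  se0 <- se; SummarizedExperiment::assay(se0, "counts") <- zero
  expect_error(normalizeCounts(se0), "all-zero")
})

test_that("normalisation is equivariant to rescaling one raw sample", {
  sc <- simulateCounts(seed = 32)
  m <- SummarizedExperiment::assay(sc$se, "counts")
  m2 <- m; m2[, 3] <- m2[, 3] * 7
  se2 <- sc$se; SummarizedExperiment::assay(se2, "counts") <- m2
  a <- SummarizedExperiment::assay(normalizeCounts(sc$se), "uq")[, 3] /
    exp(mean(log(apply(m, 2, function(x) quantile(x[x > 0], 0.75)))))
  b <- SummarizedExperiment::assay(normalizeCounts(se2), "uq")[, 3] /
    exp(mean(log(apply(m2, 2, function(x) quantile(x[x > 0], 0.75)))))
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("candidate genes gather all four selection reasons", {
  expect_equal(nrow(selectCandidateGenes(panmut:::empty_effects(),
                                         hotspotExampleData()$annotation)),
               0)
  loci <- c("reg", "op2", "par", "t1", "t2", "t3", "other")
  genes <- GenomicRanges::GRanges(
    "chr", IRanges::IRanges(start = seq_along(loci) * 1000L, width = 500L),
    strand = "+")
  genes$locus_tag <- loci
  ann <- GenomeAnnotation(genes, operons = list(op = c("reg", "op2")))
  effects <- data.frame(variant_id = "m1", effect = "NONSYN",
                        locus_tag = "reg", codon_index = 1L,
                        ref_aa = "A", alt_aa = "V",
                        assigned_gene = NA_character_,
                        stringsAsFactors = FALSE)
  out <- selectCandidateGenes(effects, ann,
                              paralogMap = list(reg = "par"),
                              regulonMap = list(reg = c("t1", "t2", "t3")))
  expect_equal(nrow(out), 6)
  reasons <- setNames(out$reasons, out$locus_tag)
  expect_equal(reasons[["reg"]], "mutated")
  expect_equal(reasons[["op2"]], "downstream_or_operon")
  expect_equal(reasons[["par"]], "paralog_copy")
  expect_equal(unname(reasons[c("t1", "t2", "t3")]),
               rep("regulatory_target", 3))
  # an upstream non-coding mutation marks its assigned gene as downstream
  nc <- effects; nc$locus_tag <- NA; nc$assigned_gene <- "other"
  out2 <- selectCandidateGenes(nc, ann)
  expect_equal(out2$reasons[out2$locus_tag == "other"],
               "downstream_or_operon")
})

test_that("identical expression across conditions is never significant", {
  m <- matrix(rep(c(100, 160, 250, 40), 6), nrow = 4, byrow = FALSE,
              dimnames = list(paste0("g", 1:4),
                              paste0("s", 1:6)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = m),
    colData = S4Vectors::DataFrame(
      condition = rep(c("base", "trt"), each = 3),
      replicate = rep(1:3, 2), row.names = colnames(m)))
  de <- testDifferentialExpression(se, baseline = "base")
  expect_equal(de$log2_diff, rep(0, 4))
  expect_false(any(de$significant))
  expect_error(testDifferentialExpression(se, baseline = "nope"),
               "baseline")
})

test_that("planted fold changes are detected with controlled error rates", {
  detected <- logical(0); fp <- 0L; called <- 0L
  for (s in 1:20) {
    sc <- simulateCounts(seed = 500 + s)
    de <- testDifferentialExpression(normalizeCounts(sc$se),
                                     baseline = "WT_0", genes = sc$panel)
    sig <- tapply(de$significant, de$locus_tag, any)
    truth <- setNames(sc$truth$de, sc$truth$locus_tag)[names(sig)]
    detected <- c(detected, sig[truth])
    fp <- fp + sum(sig[!truth])
    called <- called + sum(sig)
  }
  expect_gte(mean(detected), 0.9)
  expect_lte(fp / max(called, 1), 0.05)
})

test_that("under a global null the full significance rule stays rare", {
  frac <- vapply(1:60, function(s) {
    sc <- simulateCounts(nGenes = 300, panelSize = 41, deFraction = 0,
                         seed = 600 + s)
    de <- testDifferentialExpression(normalizeCounts(sc$se),
                                     baseline = "WT_0", genes = sc$panel)
    sig <- tapply(de$significant, de$locus_tag, any)
    mean(sig)
  }, numeric(1))
  expect_lte(mean(frac), 0.07)
})

test_that("BH adjustment agrees with the brute-force step-up definition", {
  set.seed(12)
  for (n in c(1, 5, 20, 100)) {
    p <- runif(n)
    if (n >= 5) p[1:2] <- p[1]  # exercise ties
    expect_equal(p.adjust(p, method = "BH"), bh_brute(p),
                 tolerance = 1e-12)
  }
})

test_that("average-linkage clustering matches a hand trace and is deterministic", {
  # rows on a line: a=0, b=0.4, c=3, d=3.9; average linkage merges
  # (a,b) at 0.4, (c,d) at 0.9, then the pair of pairs at the average of
  # the four cross distances: (3+3.9+2.6+3.5)/4 = 3.25
  m <- matrix(c(0, 0.4, 3, 3.9), ncol = 1,
              dimnames = list(c("a", "b", "c", "d"), "x"))
  cl <- clusterDeGenes(m)
  expect_equal(sort(cl$hclust$height), c(0.4, 0.9, 3.25))
  expect_setequal(cl$order[1:2], c("a", "b"))

  # identical rows merge first at height 0 and sit adjacent in the order
  m2 <- matrix(c(1, 1, 5), ncol = 1, dimnames = list(c("x", "y", "z"), NULL))
  cl2 <- clusterDeGenes(m2)
  expect_equal(min(cl2$hclust$height), 0)
  expect_equal(sort(cl2$hclust$merge[1, ]), c(-2, -1))  # leaves x and y
  expect_equal(abs(diff(match(c("x", "y"), cl2$order))), 1)

  # repeat runs give identical dendrograms; single gene is a trivial tree
  m3 <- matrix(rnorm(12), 4, 3, dimnames = list(paste0("g", 1:4), NULL))
  expect_identical(clusterDeGenes(m3)$newick, clusterDeGenes(m3)$newick)
  expect_equal(clusterDeGenes(m3[1, , drop = FALSE])$order, "g1")
})
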