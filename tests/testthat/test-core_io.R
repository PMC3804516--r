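test_that("variant-table TSV round trip reproduces the cohort exactly", {
  sim <- simulateCohort(small_config(seed = 101))
  vt <- withr::local_tempfile(fileext = ".tsv")
  ss <- withr::local_tempfile(fileext = ".tsv")
  writeVariantTable(sim$cohort, vt)
  writeSampleSheet(sim$cohort, ss)
  back <- readVariantTable(vt, readSampleSheet(ss))
  expect_equal(variantCalls(back), variantCalls(sim$cohort))
  expect_equal(sampleInfo(back), sampleInfo(sim$cohort))
})

test_that("variant-table parsing handles edge rows and rejects bad ones", {
  samples <- toy_samples()
  header <- "sample_id\tposition\tref\talt\tcaller_class\tconfidence_flag\tallele_frequency"
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(header, empty)
  expect_equal(nrow(variantCalls(readVariantTable(empty, samples))), 0)

  three <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(header,
               "WT\t10\tA\tG\tsnp\thc\t",
               "P1\t10\tA\tG\tsnp\tfp\t0.015",
               "I1\t22\tC\t-\tindel\thc\t"), three)
  cohort <- readVariantTable(three, samples)
  calls <- variantCalls(cohort)
  expect_equal(nrow(calls), 3)
  expect_equal(sum(calls$confidence_flag == "fp"), 1)
  # sub-2% population detection parses as a plain frequency
  expect_equal(calls$allele_frequency[calls$sample_id == "P1"], 0.015)

  bad_fields <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(header, "WT\t10\tA\tG\tsnp\thc\t0.1", "WT\t10\tA"),
             bad_fields)
  expect_error(readVariantTable(bad_fields, samples), "line 3")

  bad_flag <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(header, "WT\t10\tA\tG\tsnp\tmaybe\t"), bad_flag)
  expect_error(readVariantTable(bad_flag, samples), "confidence_flag")

  unknown_sample <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(header, "Zed\t10\tA\tG\tsnp\thc\t"), unknown_sample)
  expect_error(readVariantTable(unknown_sample, samples), "sample_id")
})

test_that("a minimal VCF yields one observation per carrier sample", {
  skip_if_not_installed("VariantAnnotation")
  samples <- toy_samples(nPop = 1, nIso = 1)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr,length=1000>",
    '##INFO=<ID=CLASS,Number=1,Type=String,Description="caller class">',
    '##INFO=<ID=CONF,Number=1,Type=String,Description="confidence">',
    '##INFO=<ID=AF,Number=1,Type=Float,Description="population frequency">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tWT\tP1\tI1",
    "chr\t42\t.\tA\tT\t.\t.\tCLASS=snp;CONF=hc;AF=0.3\tGT\t0\t1\t1",
    "chr\t99\t.\tG\tC\t.\t.\tCLASS=snp;CONF=fp\tGT\t0\t0\t1"), vcf)
  cohort <- readVariantTable(vcf, samples)
  calls <- variantCalls(cohort)
  expect_equal(nrow(calls), 3)
  expect_setequal(calls$sample_id[calls$position == 42], c("P1", "I1"))
  expect_equal(unique(calls$confidence_flag[calls$position == 99]), "fp")
})

test_that("annotation GFF3 + membership tables round trip; bad membership rejected", {
  sim <- simulateCohort(small_config(seed = 102))
  gff <- withr::local_tempfile(fileext = ".gff3")
  op <- withr::local_tempfile(fileext = ".tsv")
  pw <- withr::local_tempfile(fileext = ".tsv")
  writeAnnotation(sim$annotation, gff, op, pw)
  back <- readAnnotation(gff, op, pw,
                         referenceLength = sim$annotation@referenceLength)
  expect_equal(annotatedGenes(back)$locus_tag,
               annotatedGenes(sim$annotation)$locus_tag)
  expect_equal(GenomicRanges::start(annotatedGenes(back)),
               GenomicRanges::start(annotatedGenes(sim$annotation)))
  expect_equal(as.character(GenomicRanges::strand(annotatedGenes(back))),
               as.character(GenomicRanges::strand(annotatedGenes(sim$annotation))))
  expect_equal(operons(back), operons(sim$annotation))
  expect_equal(pathways(back), pathways(sim$annotation))
  # a GFF interval of a 300 bp gene spans exactly 300 bases (1-based incl.)
  g1 <- annotatedGenes(back)[1]
  expect_equal(GenomicRanges::width(g1),
               GenomicRanges::end(g1) - GenomicRanges::start(g1) + 1L)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("group_id\tlocus_tag", "op1\tNOT_A_GENE"), bad)
  expect_error(readAnnotation(gff, bad), "unknown locus_tag")
})

test_that("an eight-gene transcription unit loads as one ordered operon", {
  ex <- hotspotExampleData()
  expect_length(operons(ex$annotation), 1)
  expect_equal(operons(ex$annotation)[[1]],
               sprintf("Cthe_26%02d", 2:9))
  # five-gene pathway set loads with size 5
  expect_length(pathways(ex$annotation)$amino_acid_production, 5)
})

test_that("PSSM, counts and growth formats round trip", {
  m <- matrix(rnorm(40), nrow = 2,
              dimnames = list(NULL, sample(panmut:::AA20)))
  model <- ProfileModel(m, modelId = "toy", domainLocus = "SCT_0001",
                        proteinStart = 5L)
  f <- withr::local_tempfile(fileext = ".tsv")
  writePssm(model, f)
  back <- readPssm(f)
  expect_equal(pssm(back), pssm(model), tolerance = 1e-12)
  expect_equal(back@proteinStart, 5L)
  expect_equal(back@domainLocus, "SCT_0001")

  sc <- simulateCounts(nGenes = 20, panelSize = 5, seed = 1)
  cp <- withr::local_tempfile(fileext = ".tsv")
  dp <- withr::local_tempfile(fileext = ".tsv")
  writeCountsMatrix(sc$se, cp, dp)
  se2 <- readCountsMatrix(cp, dp)
  expect_equal(SummarizedExperiment::assay(se2, "counts"),
               SummarizedExperiment::assay(sc$se, "counts"))
  expect_equal(SummarizedExperiment::colData(se2)$condition,
               SummarizedExperiment::colData(sc$se)$condition)

  g <- simulateGrowthCurves(mu = 0.3, nCurves = 2, seed = 2)
  gp <- withr::local_tempfile(fileext = ".csv")
  writeGrowthCurves(g$curves, gp)
  back_curves <- readGrowthCurves(gp)
  expect_length(back_curves, 2)  # one per replicate
  expect_equal(back_curves[[1]]$od, g$curves[[1]]$od, tolerance = 1e-6)
})

test_that("report writing is complete, size-consistent and deterministic", {
  d1 <- withr::local_tempdir()
  writeReport(d1)  # empty analysis still yields a valid report
  expect_true(file.exists(file.path(d1, "summary.txt")))

  sim <- simulateCohort(small_config(seed = 103))
  scr <- screenVariants(sim$cohort)
  pres <- buildPresence(scr$cohort)
  part <- partitionPanGenome(pres, sampleInfo(scr$cohort))
  ex <- hotspotExampleData()
  hs <- callHotspots(ex$effects, ex$annotation, ex$core)
  d2 <- withr::local_tempdir()
  d3 <- withr::local_tempdir()
  writeReport(d2, partition = part, hotspots = hs)
  writeReport(d3, partition = part, hotspots = hs)
  ptab <- read.delim(file.path(d2, "partition.tsv"))
  expect_equal(nrow(ptab), length(unlist(partitionSets(part)[1:4])))
  expect_equal(nrow(read.delim(file.path(d2, "hotspots.tsv"))), nrow(hs))
  for (f in list.files(d2))
    expect_identical(readLines(file.path(d2, f)),
                     readLines(file.path(d3, f)))
})
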