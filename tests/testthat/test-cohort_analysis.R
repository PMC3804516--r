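test_that("presence follows the frequency-threshold rule exactly", {
  samples <- toy_samples(nPop = 1, nIso = 1)
  calls <- rbind(
    toy_call("below", "P1", position = 1, af = 0.015),
    toy_call("at", "P1", position = 2, af = 0.02),
    toy_call("fixed", "I1", position = 3))
  cohort <- MutationCohort(calls, samples)
  pres <- buildPresence(cohort, threshold = 0.02)
  expect_false(pres["below", "P1"])  # detected, not established
  expect_true(pres["at", "P1"])
  expect_true(pres["fixed", "I1"])
  # threshold 0: every observed call is present
  pres0 <- buildPresence(cohort, threshold = 0)
  expect_true(all(pres0[cbind(calls$variant_id, calls$sample_id)]))
  expect_error(buildPresence(cohort, threshold = 1.5), "threshold")

  # random frequency matrix versus elementwise brute force
  set.seed(7)
  samples2 <- toy_samples(nPop = 4, nIso = 2)
  rows <- list()
  for (v in paste0("v", 1:25)) {
    carriers <- sample(samples2$sample_id, sample(1:6, 1))
    roles <- samples2$role[match(carriers, samples2$sample_id)]
    rows[[v]] <- toy_call(v, carriers,
                          position = match(v, paste0("v", 1:25)),
                          af = ifelse(roles == "population",
                                      runif(length(carriers)), NA_real_))
  }
  tab <- do.call(rbind, rows)
  cohort2 <- MutationCohort(tab, samples2)
  pres2 <- buildPresence(cohort2, threshold = 0.3)
  for (i in seq_len(nrow(tab))) {
    expected <- is.na(tab$allele_frequency[i]) ||
      tab$allele_frequency[i] >= 0.3
    expect_equal(unname(pres2[tab$variant_id[i], tab$sample_id[i]]),
                 expected)
  }
})

test_that("the pan-genome partition matches planted truth and brute force", {
  for (seed in 401:405) {
    sim <- simulateCohort(small_config(seed = seed))
    scr <- screenVariants(sim$cohort)
    pres <- buildPresence(scr$cohort)
    part <- partitionPanGenome(pres, sampleInfo(scr$cohort))
    sets <- partitionSets(part)
    truth <- sim$truth$labels
    for (cls in c("core", "shared", "unique", "discarded"))
      expect_setequal(sets[[cls]], names(truth)[truth == cls])
    brute <- partition_brute(pres, sampleInfo(scr$cohort))
    for (cls in names(brute)) expect_setequal(sets[[cls]], brute[[cls]])
    # exhaustive and disjoint
    all_ids <- c(sets$core, sets$shared, sets$unique, sets$discarded)
    expect_equal(sort(all_ids), sort(rownames(pres)))
  }
})

test_that("a one-isolate cohort has no shared class and its variants are core", {
  samples <- toy_samples(nPop = 1, nIso = 1)
  calls <- rbind(toy_call("v1", "I1"),
                 toy_call("v2", "P1", position = 2, af = 0.4))
  pres <- buildPresence(MutationCohort(calls, samples))
  part <- partitionSets(partitionPanGenome(pres, samples))
  expect_equal(part$core, "v1")
  expect_length(part$shared, 0)
  expect_length(part$unique, 0)
  expect_equal(part$discarded, "v2")
  expect_error(partitionPanGenome(
    pres[, "P1", drop = FALSE], samples[samples$role == "population", ]),
    "isolate")
})

test_that("adding an isolate can only shrink or preserve the core set", {
  for (seed in 411:413) {
    sim <- simulateCohort(small_config(seed = seed))
    scr <- screenVariants(sim$cohort)
    samples <- sampleInfo(scr$cohort)
    pres <- buildPresence(scr$cohort)
    drop_iso <- samples[samples$sample_id != "I7", ]
    core_small <- partitionSets(partitionPanGenome(
      pres[, drop_iso$sample_id], drop_iso))$core
    core_full <- partitionSets(partitionPanGenome(pres, samples))$core
    expect_true(all(core_full %in% core_small))
  }
})

test_that("longitudinal profile recovers planted per-epoch gains exactly", {
  cfg <- small_config(seed = 420)
  sim <- simulateCohort(cfg)
  scr <- screenVariants(sim$cohort)
  pres <- buildPresence(scr$cohort)
  prof <- longitudinalAccumulation(pres, sampleInfo(scr$cohort))
  gains <- sim$truth$epoch_gains
  expect_equal(unname(prof$cumulative), cumsum(gains))
  expect_equal(unname(prof$deltas), diff(cumsum(gains)))
  expect_equal(prof$max_delta, max(diff(cumsum(gains))))
  expect_equal(prof$mean_delta, mean(diff(cumsum(gains))))
  # population (not sample) standard deviation
  d <- diff(cumsum(gains))
  expect_equal(prof$sd_delta, sqrt(mean((d - mean(d))^2)))
})

test_that("equal counts with different members show in the symmetric difference", {
  samples <- toy_samples(nPop = 2, nIso = 1)
  calls <- rbind(toy_call("v1", "P1", position = 1, af = 0.5),
                 toy_call("v2", "P2", position = 2, af = 0.5),
                 toy_call("anchor", "I1", position = 3))
  pres <- buildPresence(MutationCohort(calls, samples))
  prof <- longitudinalAccumulation(pres, samples)
  expect_equal(unname(prof$deltas), 0L)
  expect_equal(unname(prof$symmetric_difference), 2L)

  # identical consecutive samples: delta 0 and symmetric difference 0
  calls2 <- rbind(toy_call("v1", "P1", position = 1, af = 0.5),
                  toy_call("v1", "P2", position = 1, af = 0.5),
                  toy_call("anchor", "I1", position = 3))
  prof2 <- longitudinalAccumulation(
    buildPresence(MutationCohort(calls2, samples)), samples)
  expect_equal(unname(prof2$deltas), 0L)
  expect_equal(unname(prof2$symmetric_difference), 0L)
})

test_that("the bundled worked example yields its eight published hotspots", {
  ex <- hotspotExampleData()
  hs <- callHotspots(ex$effects, ex$annotation, ex$core)
  expect_equal(nrow(hs), 8)
  expect_equal(sort(hs$n_mutations, decreasing = TRUE),
               c(5, 5, 4, 2, 2, 2, 2, 2))
  members <- unlist(strsplit(hs$member_variants, ","))
  expect_length(members, 24)
  expect_equal(sum(members %in% ex$core), 14)
  expect_setequal(
    hs$grouping_basis[hs$hotspot_id == "atp_synthase_unit"], "operon")
})

test_that("hotspot edge rules: no partner, no core anchor, no hotspot", {
  ex <- hotspotExampleData()
  # single mutated gene with one mutation and no partners: nothing
  solo <- ex$effects[ex$effects$variant_id == "v_Cthe_2529_1", ]
  expect_equal(nrow(callHotspots(solo, ex$annotation, ex$core)), 0)
  # two mutations in one gene but none core: filtered out
  pair <- ex$effects[ex$effects$variant_id %in%
                       c("v_Cthe_1020_1", "v_Cthe_1020_2"), ]
  expect_equal(nrow(callHotspots(pair, ex$annotation, character())), 0)
  expect_equal(nrow(callHotspots(pair, ex$annotation, "v_Cthe_1020_1")), 1)
})

test_that("hotspot caller equals brute-force enumeration on random cohorts", {
  set.seed(99)
  for (rep in 1:25) {
    n_genes <- sample(6:20, 1)
    loci <- sprintf("g%02d", seq_len(n_genes))
    genes <- GenomicRanges::GRanges(
      "chr", IRanges::IRanges(start = seq_len(n_genes) * 1000L,
                              width = 500L), strand = "+")
    genes$locus_tag <- loci
    operons <- list()
    for (k in seq_len(sample(0:2, 1))) {
      st <- sample(n_genes - 2, 1)
      operons[[paste0("op", k)]] <- loci[st:(st + sample(1:2, 1))]
    }
    pathways <- list()
    for (k in seq_len(sample(0:3, 1)))
      pathways[[paste0("pw", k)]] <- sample(loci, sample(2:5, 1))
    ann <- GenomeAnnotation(genes, operons = operons, pathways = pathways)
    n_mut <- sample(2:30, 1)
    effects <- data.frame(
      variant_id = sprintf("m%02d", seq_len(n_mut)),
      effect = "NONSYN", locus_tag = sample(loci, n_mut, replace = TRUE),
      codon_index = NA_integer_, ref_aa = NA_character_,
      alt_aa = NA_character_, assigned_gene = NA_character_,
      stringsAsFactors = FALSE)
    core <- sample(effects$variant_id,
                   sample(0:min(5, n_mut), 1))
    got <- hotspots_as_sets(callHotspots(effects, ann, core))
    want <- hotspot_brute(effects, ann, core)
    expect_equal(length(got), length(want))
    for (i in seq_along(got)) {
      expect_equal(got[[i]]$genes, want[[i]]$genes)
      expect_equal(got[[i]]$variants, want[[i]]$variants)
      expect_equal(got[[i]]$basis, want[[i]]$basis)
    }
  }
})
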