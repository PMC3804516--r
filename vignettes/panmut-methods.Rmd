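---
title: "Analysing resequenced ALE mutation cohorts with panmut"
author: "panmut authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing resequenced ALE mutation cohorts with panmut}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panmut)
```

## The analysis model

panmut analyses the mutation cohort produced by resequencing an
adaptive laboratory evolution (ALE) experiment.  The cohort design it
assumes — and that its synthetic generator emulates — is one wild-type
ancestor, a series of intermediate population samples taken along the
serial-transfer history, and a set of endpoint single-colony isolates.
The motivating system is a *Clostridium thermocellum* lineage evolved
for tolerance to increasing concentrations of *Populus* hydrolysate,
but nothing in the package is specific to that organism: inputs are a
per-sample variant table, a reference genome with GFF3 annotation,
operon/pathway membership tables, optional protein-domain PSSMs and
alignments, an RNA-seq count matrix with its design, and fermentation
OD time series.

The pipeline proceeds in stages, each exposed as an exported function
and orchestrated by `runPipeline()`:

1.  **High-confidence screening** (`screenVariants()`).  Two screens,
    in a fixed order.  First, variants present in *every* sample
    including the wild type are differences between the parent strain
    and the published reference assembly, not mutations acquired during
    the experiment; they are removed entirely.  Second, calls flagged
    by the upstream caller as false positive (`fp`), sequence-specific
    error (`ise`) or structural variant (`sv`) are dropped, leaving the
    high-confidence set.  Flagged calls remain available in the raw
    object (callers sometimes validate a sample of them), but none of
    the downstream analyses see them.  The order — artifacts first,
    flags second — is a package convention; the two screens commute on
    the variants they jointly touch, which the test suite verifies.
2.  **Effect classification** (`classifyEffects()`).  SNVs inside a CDS
    are translated with the bacterial genetic code (table 11) and
    classified SYN / NONSYN / STOP; any insertion or deletion is a
    single INDEL class regardless of frame, because the downstream
    tabulation does not distinguish frameshifts (frame information is
    recoverable from the alleles).  Reverse-strand genes are handled on
    the coding strand.  Variants outside every CDS are NONCODING and
    may be assigned to the gene whose translation start lies downstream
    within a 500 bp window (nearest start wins).  The window default
    covers the regulatory-region cases seen in real cohorts of this
    kind (tens to a few hundred bp upstream) while excluding intergenic
    deletions kilobases from any gene.
3.  **Cohort analyses** (`buildPresence()`, `partitionPanGenome()`,
    `longitudinalAccumulation()`, `callHotspots()`).  Presence of a
    variant in a sample requires either a fixed observation (wild-type
    and isolate calls carry no frequency and count as fixed) or a
    population allele frequency at or above the 2% threshold;
    sub-threshold observations are recorded as detections but are not
    "established" in the population.  The pan-genome partition is then:
    *core* = present in all isolates, *unique* = exactly one isolate,
    *shared* = two or more but not all, *discarded* = populations only.
    The longitudinal profile reports per-population established-mutation
    counts, consecutive deltas, and symmetric differences between
    consecutive mutation sets, since two populations can carry equal
    counts of different mutations.
4.  **Hotspot calling.**  A hotspot is a group of two or more mutations
    within one gene, one operon, or one pathway, with at least one
    member gene carrying a core mutation.  Groups are maximal: a
    multi-mutation gene inside a mutated operon merges into the operon
    group, and pathway grouping only merges genes not already claimed
    by an operon.  Cross-gene bases (operon, pathway) require at least
    two distinct mutated genes; a lone multi-mutation gene reports the
    `same_gene` basis even if it happens to sit in an operon, because
    the wider level added nothing.  A gene belonging to two pathways
    may anchor two hotspots, so pathway-level member sets may overlap;
    the report preserves the overlap rather than arbitrating it.
5.  **Function-change scoring** (`scoreFunctionChange()`,
    `classifyConservation()`, `buildProfileFromMsa()`).  For a
    non-synonymous substitution inside a profiled domain the score is
    the PSSM delta `pssm[pos, alt] - pssm[pos, ref]`: positive deltas
    suggest a potential gain of function, negative a potential loss.
    Deltas are antisymmetric and additive along substitution chains by
    construction.  Scores are in the native log-odds units of the
    supplied matrix; magnitudes reported by external toolkits use
    unpublished scalings, so only sign and ordering are guaranteed, and
    the package makes no attempt to reproduce third-party magnitudes.
    Protein position is mapped to domain column assuming ungapped
    correspondence from the model's stated start; alignment-based
    mapping is out of scope.  The conservation classifier reports the
    identity fraction of non-gap residues against a reference row:
    1.0 is `very_conserved`, below 0.5 `non_conserved` (the 0.5 floor
    is a package choice; the classification it mirrors was visual),
    anything between `intermediate`.  `buildProfileFromMsa()` exists so
    the scoring stage is testable without external profile downloads:
    match columns (at most 50% gaps) are scored as smoothed log2
    odds against a uniform 1/20 background.
6.  **Mutation-linked expression analysis** (`selectCandidateGenes()`,
    `normalizeCounts()`, `testDifferentialExpression()`,
    `clusterDeGenes()`).  Candidate genes are the union of four rules:
    mutated; downstream of a mutation or in an operon with a mutated
    gene; another copy of a mutated gene; under regulatory control of a
    mutated gene.  Counts are upper-quartile scaled (per-sample 75th
    percentile of nonzero counts, rescaled by the geometric mean of the
    factors) and log2-transformed with a +1 pseudocount — zero counts
    exist, and the transform must be defined there.  Each gene gets a
    one-way ANOVA across conditions; significance demands all three of:
    Benjamini-Hochberg survival at FDR 5% across the tested genes, an
    absolute log2 difference above 1 against the baseline condition,
    and a raw -log10 p above 1.714 (p < 0.0193).  Whether that last
    printed threshold was meant for raw or adjusted p-values is
    ambiguous in the sources this design follows; the package applies
    it to raw p-values and requires the FDR screen separately, the
    conservative reading.  Significant genes are clustered on their
    log2-difference profiles (Euclidean distance, average linkage),
    deterministically for a fixed row order.
7.  **Growth kinetics** (`fitGrowthRate()`, `fitYield()`,
    `ancovaCompare()`).  The net growth rate is the least-squares slope
    of ln(OD) versus time over the exponential window.  Lag end is the
    first reading exceeding (1 + 0.2) x OD(0) *and staying above it*
    — the sustained-rise condition keeps single noisy readings near the
    detection margin from truncating the lag.  The window closes at the
    first reading entering the plateau band (within 5% of the maximum
    OD): with measurement noise the literal argmax can land anywhere
    along a flat stationary plateau, and growth has ended by plateau
    entry, so the fit runs strictly before it.  On noise-free
    capped-exponential curves both rules reduce to the obvious
    endpoints and the fit recovers the true rate exactly.  Non-positive
    (blank-referenced) OD readings never enter the log fit.  Yields are
    slopes of product concentration against substrate utilised.
    Pairwise comparisons use a pooled regression with a 0/1 treatment
    indicator z: the default `main_effect` form `y ~ x + z` tests a
    treatment offset at common slope — the form the emulated analysis
    states, even though the compared quantities are slopes — and the
    `interaction` form `y ~ x + z + x:z` is offered for a direct slope
    comparison; the form used is recorded in the result so the
    discrepancy is visible downstream.  Significance is p < 0.05.

## The synthetic-data generator

Every stage is testable offline because `simulateCohort()`,
`simulateCounts()` and `simulateGrowthCurves()` generate complete study
inputs with planted ground truth, fully deterministic under their
mandatory seeds.

`simulateCohort()` simulates a single dominant lineage with transient
side-lineages rather than full Wright-Fisher dynamics — sufficient to
produce all four partition classes, and anything richer would be out of
proportion to what the cohort analyses consume.  Per transfer epoch,
`round(rnorm(mean = 5, sd = 3))` (truncated at zero) new mutations
arise; each either fixes (frequency 1 from its epoch onward, present in
all isolates: planted *core*) or segregates in the populations at
frequencies uniform on (0.02, 0.5) without reaching any isolate
(planted *discarded*).  Because population-borne mutations persist from
arrival to the final sample, longitudinal deltas equal the planted
epoch gains exactly, which the tests exploit.  Isolate-private
mutations are planted at the endpoint: 23 *unique* (one isolate each)
and 4 *shared* (two to six isolates), of which 4 are also detected in
the final population below the 2% threshold (frequencies uniform on
(0, 0.02)) to exercise the detection-versus-presence rule.  On top of
these, 20 ancestor-shared artifacts (present in every sample including
the wild type) and caller flag noise `c(fp = 120, ise = 5, sv = 6)`
are planted; the noise total matches the scale of flagged calls in the
motivating cohort, and its fp-dominated split is a package calibration
(the source split is not published).  Default cohort geometry is six
populations, seven isolates, a 3.84 Mb reference with 3000 genes of
900 bp — a Clostridium-scale chromosome — with 89% of mutations placed
in coding sequence and 15% indels.

`simulateCounts()` draws log-normal gene means and negative-binomial
counts (dispersion 0.05) for five strain-by-medium conditions in
triplicate, and embeds a 41-gene candidate panel — 60% of it shifted by
2^2 in every non-baseline condition — in a null transcriptome
background.  The split matters: normalisation factors must come from a
transcriptome-scale matrix (upper-quartile scaling computed on a
DE-rich panel alone would absorb the planted fold changes into the
factors), while the ANOVA and FDR run on the panel, which is exactly
how a mutation-linked candidate analysis is structured.

`simulateGrowthCurves()` produces lag / exponential / plateau OD curves
(`OD0 = 0.05`, plateau 0.75, Gaussian noise, default lag 4 h) with
substrate utilisation tracking biomass and product series following the
planted yields.

What the generators deliberately do not emulate: read-level error,
linkage between specific mutations and expression changes, mutation
rate acceleration (mutator phenotypes), non-exponential growth phases,
and product inhibition.  Passing tests therefore demonstrate that the
*analysis logic* is correct on data matching its assumptions, not that
those assumptions hold for any particular real experiment.

## Numerical and design choices

* Coordinates are 1-based inclusive everywhere (GFF3/VCF native); a
  gene annotated 101..400 has length 300.
* Multi-allelic sites are split into separate variant ids; a variant
  overlapping two CDS annotations is reported once per gene.
* A single presence threshold (default 2%) governs both the
  ancestor-shared artifact screen and the cohort analyses; how
  sub-threshold population observations interact with the artifact
  screen is otherwise unspecified, and one parameter keeps the two
  rules consistent.
* With a single isolate, "present in all isolates" and "present in
  exactly one" coincide; such variants are classed core and the shared
  class is empty by construction.
* Variants present in no isolate are classed discarded; in well-formed
  cohorts these are exactly the population-only mutations.
* Core anchoring of hotspots is evaluated at the gene level: a gene is
  a core gene if *any* of its mutations is in the core set (a gene can
  carry one core and one non-core mutation).
* ANOVA p-values for zero-variance genes are set to 1; single-replicate
  designs fall back to contrast-only log2 differences with no
  significance calls.
* `hclust` ties are resolved by input row order; duplicated runs on the
  same matrix give identical trees, which is the determinism the
  dendrogram output promises.

## Problem sizes used by the test suite

The shipped tests and the acceptance script run at sizes chosen to
exercise every code path while completing quickly on one CPU: the
100-cohort partition properties use a 60 kb / 50-gene genome (partition
logic is independent of genome size), single-cohort end-to-end checks
use 200 kb / 150 genes or the full 3.84 Mb default, expression power
uses 200 replications of a 400-gene transcriptome with the 41-gene
panel, growth-rate recovery uses 30 noisy curves, and the null ANCOVA
calibration uses 1000 replicates.

## Worked example

The bundled `hotspotExampleData()` encodes the mutation-to-gene
assignments of the motivating *C. thermocellum* cohort: 24
high-confidence mutations over 18 genes, their core flags, the
eight-gene ATP-synthase transcription unit and four pathway groupings.

```{r hotspots}
ex <- hotspotExampleData()
hs <- callHotspots(ex$effects, ex$annotation, ex$core)
hs[, c("hotspot_id", "n_mutations", "grouping_basis", "core_anchor")]
```

The caller returns eight hotspots with member counts 5, 5, 4, 2, 2, 2,
2, 2 — 24 member mutations in total, 14 of them core — reproducing the
published hotspot landscape of that cohort.

## Known limitations

* Confidence flags are consumed, never recomputed from read evidence.
* The minimal VCF reader covers a small dialect (GT genotypes, INFO
  CLASS/CONF/AF); the TSV variant table is the primary format.
* PSSM magnitudes are toolkit-specific; only sign semantics are
  portable.
* The ANCOVA main-effect form tests an offset, not a slope difference;
  use the interaction form when the slopes themselves are compared.
* Hotspot calling is rule-based, as in the analysis it implements; no
  enrichment statistics are attached.
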