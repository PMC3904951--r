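---
title: "Methods: from amplicon reads to the spatial structure of root-fungal symbiosis"
author: "mycoroot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from amplicon reads to the spatial structure of root-fungal symbiosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycoroot)
```

## The scientific setting

In mixed subtropical forests, ectomycorrhizal (EcM) host trees — here the
fagaceous species — co-occur with many plant species whose symbionts are
arbuscular mycorrhizal (AM) fungi or root endophytes of unknown function.
Grid-based root sampling (terminal root fragments collected every metre,
hosts identified from metadata) combined with fungal ITS metabarcoding
yields, per root sample, a vector of fungal OTU read counts. The questions
the package addresses are: which fungi associate with which host group, how
often multiple fungal functional groups co-occur within a single root
fragment, and whether the community is spatially structured — in particular
whether EcM fungi "spill over" onto non-fagaceous roots growing next to
fagaceous ones.

`mycoroot` implements the full chain: read filtering and OTU construction,
association matrices, guild statistics (G-tests, CLAM host-preference
classification, shared-OTU counts, co-existence profiles) and spatial
statistics (Raup-Crick dissimilarity, Mantel correlograms, adjacency Fisher
tests), plus a synthetic generator that produces grid communities with a
known ground truth so every stage can be validated end to end.

## Read processing and OTU construction

Reads are 3'-trimmed at their last base with Phred quality >= 27 (interior
low-quality bases are retained) and discarded below 150 bp. OTUs are built
in two stages of agglomerative **complete-linkage clustering** on
`1 - identity` distance: reads within each sample at 97% similarity
(denoising: the per-cluster majority-rule consensus replaces its members),
then the within-sample consensi across samples at 95% similarity
(ITS-appropriate; a conserved marker would use 99.8%). Complete linkage
guarantees that every pair inside an OTU meets the similarity cutoff.
Afterwards, singleton OTUs (one read in total) are dropped, OTUs never
reaching 5 reads in any single sample are dropped (an OTU is kept if *any*
sample has >= 5 reads — the literal reading of the rule), and samples with
fewer than 20 high-quality reads are excluded.

Numerical choices worth stating explicitly:

* **Alignment identity.** Global (Needleman-Wunsch) alignment with match 1,
  mismatch 0 and a 0.5 penalty per gap column; identity = matched columns /
  total alignment columns, so gaps count as mismatches. Whether the original
  assembler scored the overlap region only or the full alignment is not
  documented; full-global is used here and stated. Among co-optimal
  alignments the aligner's traceback decides; ties essentially never affect
  the partition at the cutoffs used.
* **Canonical order and tie-breaks.** Sequences are pooled by exact
  identity and sorted by (descending abundance, lexicographic) before
  agglomeration; equal merge distances are resolved toward the smallest
  cluster indices. This makes the partition invariant to input order, which
  the tests verify by permutation.
* **Consensus.** Members are star-aligned to the cluster head; insertions
  relative to the head are ignored, per-column majorities are weighted by
  read abundance, base ties go to the alphabetically first base (no IUPAC
  codes, keeping downstream identity arithmetic on A/C/G/T), and a column is
  deleted only when the gap strictly wins.
* **Two-stage vs single-stage.** With well-separated OTUs (reference
  divergence comfortably above the among-sample radius, sequencing error
  comfortably below the within-sample radius) the two-stage result equals
  direct single-stage clustering, and the tests check this against a
  brute-force oracle. In borderline regimes (reference divergence near the
  clustering radius) the two routes can legitimately differ because
  consensus replaces members between stages; the recovery tests therefore
  use references ~10% apart with 1% sequencing error.
* Chimera screening is treated as an external pass-through (the published
  pipeline used a dedicated tool for it); it is out of scope here.

## Matrices

Presence/absence is scored either by the **strict 5% rule** — an OTU is
present in a sample iff its reads are *strictly more than* 5% of the sample
total, which suppresses low-frequency contaminants without equalizing
depth — or by **rarefaction** to 50 reads (samples below 50 reads dropped,
subsampling without replacement, seeded). The plant x fungus association
matrix counts, per plant species i and OTU j, the samples in which the
association was observed (`A[i,j]`), with proportions `P = A / sum(A)` and
fagaceous / non-fagaceous margins; fagaceous membership is decided by
`host_family == "Fagaceae"`, never by a species list.

## Guild statistics

* **G-test**: `G = 2 * sum(O log(O/E))` with independence expectations, no
  Williams or continuity correction, upper-tail chi-squared p. Calibration
  is verified on 10,000 fixed-margin null tables (type-I error within
  [0.04, 0.06] at alpha 0.05).
* **CLAM classification** labels each OTU fagaceous-specialist,
  non-fagaceous-specialist, generalist or too-rare from its two association
  counts, the group totals, and a supermajority threshold K = 2/3: an OTU
  specializes on a group when its coverage-corrected relative abundance
  there exceeds `K/(1-K)` times the other group's by a one-sided normal
  test at level alpha. Counts below the coverage limit (10) are shrunk by
  the group's estimated sample coverage (1 - singletons/total); zero counts
  enter as 1 (conservative). The too-rare region is bounded by the line
  joining the smallest classifiable count in each group, following the
  published procedure. Defaults: alpha = 0.005 and coverage limit 10, the
  practice recommended with the original test; both are configurable, and
  analyses should report any OTU whose label changes between alpha 0.005
  and 0.05 rather than silently fixing one. The implementation is
  cross-checked in the tests against vegan's independent `clamtest`.
* **Co-existence profiles** flag each root sample for EcM / AM /
  unknown-guild presence and tabulate the eight flag combinations per host
  group.

## Spatial statistics

* **Raup-Crick dissimilarity**: for each sample pair, null assemblages are
  drawn preserving each sample's richness, with OTUs weighted by occurrence
  frequency; the dissimilarity is the fraction of null draws sharing *at
  least* as many OTUs as observed (ties count toward dissimilarity).
  Reported on the [0, 1] probability scale, 999 draws by default, seeded.
  Tests compare against exhaustive enumeration on <= 6-OTU toy communities
  (agreement within +-0.03).
* **Mantel correlogram**: per 1-m distance class, the Mantel correlation
  between the community dissimilarity and the class-membership matrix
  (computed through `vegan::mantel.correlog`), sign-oriented so positive r
  means samples at that distance are more similar. Classes whose upper bound
  exceeds half the maximum inter-sample distance, or with fewer than two
  pairs, are flagged untested. The permutation engine reports the tail
  matching the observed sign; the package doubles it so that p is two-sided
  and uniform under the null (verified by a KS test over replicate null
  runs). Correction is simultaneous Bonferroni over the tested classes, not
  progressive — the study's figure caption says only "after Bonferroni
  correction", so the simpler simultaneous convention was chosen and is
  stated here.
* **Adjacency analysis**: each non-fagaceous sample is classified
  fagaceous-adjacent or not by its grid neighbours; the neighbourhood is
  rook (4-neighbour) by default — the source analysis never defines
  "adjacent", so this is an explicit, recorded configuration choice (Moore
  8-neighbour available) on which replication of the published odds ratio
  depends. Samples with fewer than three data-bearing neighbours are
  excluded. Whether that filter should count only neighbours with *both*
  marker genes recovered is likewise not documented; here "data-bearing"
  means present in the retained sample table. The Fisher exact test reports
  the sample cross-product odds ratio (the convention of the published
  value) with the conditional MLE alongside; p-values are exact and are
  verified against full hypergeometric enumeration for all 2x2 tables with
  N <= 40.

## The synthetic generator

`simulate_community()` emulates the study design: a 30 x 40 grid at 1-m
spacing (1200 positions), spatially clumped hosts with 25.2% fagaceous
samples, three fungal guilds, negative-binomial read depths with mean 98.7
and SD 62.2, and ~2% contaminant reads drawn uniformly from the OTU pool.
Choices the data do not dictate, decided once:

* **Host process.** The source data give only the observed host map, not a
  generating process. Hosts are assigned by thresholding smoothed Gaussian
  random fields (one field for the fagaceous/non-fagaceous split using a
  within-realization rank threshold, so the realized fagaceous fraction hits
  its target; one field per species within each group). The correlation
  scale defaults to 3 m, which reproduces patch sizes of a few metres —
  a stand-in for the forest, not an inference about it.
* **Occupancy model.** Each OTU has lognormally heterogeneous baseline
  occupancy odds (sdlog 1). EcM odds are multiplied by 5 on fagaceous hosts
  and by `1 + 0.5 * n_adjacent_fagaceous` on non-fagaceous hosts (the
  spillover term; the generator's neighbourhood definition is shared with
  the spatial module so recovery tests are self-consistent); AM odds by 40
  on non-fagaceous hosts; unknown-guild OTUs are host-indifferent.
* **Calibration.** With the default 132/58/390 EcM/AM/unknown OTU pool,
  the defaults give ~3.9 detected OTUs per sample after the 5% cutoff
  (study: 3.58), non-fagaceous EcM association share ~13% (study: 11.1%)
  and AM share ~24% (study: 19.2%), fagaceous AM share ~0.6% (study:
  0.8%), and fagaceous EcM share ~49% (study: 56.2%). The fagaceous EcM
  share cannot be matched exactly while keeping the unknown guild
  host-indifferent: the real fagaceous samples are OTU-poor overall
  (a mycelial-mantle effect the generator does not model), which inflates
  their EcM share. The calibration therefore prioritizes overall richness
  and the mycorrhizal contrasts.
* **Depths.** Negative binomial parameterized by mean and SD (size =
  mu^2/(sd^2 - mu)); the printed SD is far above Poisson, hence the
  overdispersed family.
* **Contaminants.** Uniform over the full OTU pool — rare reads are
  attributed to contamination without a mechanistic model, so the simplest
  null is used. Contaminant reads are flagged in the truth object, which is
  how the tests verify that the 5% cutoff removes them in samples deep
  enough to be retained.

What passing tests on this generator do **not** show about real data: no
phylogenetically realistic sequence evolution, no chimeras, no
host-specific richness suppression (the mantle effect above), and no
spatial structure in the unknown guild. Conclusions about statistical
procedures transfer; conclusions about effect sizes in a real forest do
not.

## Problem sizes and determinism

Test and validation runs use deliberately scaled problems: 10 x 10 grids
with a ~70-OTU pool (baseline occupancy scaled up ~8x so per-sample
richness stays realistic) for pipeline smoke tests, 140-sample subsets for
correlograms, 999 null draws for Raup-Crick, 299-499 Mantel permutations,
and 200 replicate 30 x 40 grids for odds-ratio recovery. A single seed
fixes every stochastic stage; the pipeline derives per-stage seeds from the
global one, so re-running any stage on unchanged inputs is bit-for-bit
reproducible.

## Known limitations

* The two-stage clustering is quadratic in the number of unique sequences
  per stage; it is meant for study-scale amplicon sets (10^4-10^5 reads),
  not for modern shotgun-scale data.
* CLAM labels for OTUs with very unbalanced group coverage can be
  alpha-sensitive; the package reports labels at the configured alpha and
  the recommended practice is to flag OTUs that flip between 0.005 and
  0.05.
* Raup-Crick pairs involving empty samples are undefined (`NA`) and must be
  dropped before the correlogram.
* The cross-product odds ratio is infinite for tables with a zero cell; the
  conditional MLE reported alongside is finite and preferable there.

## A worked run

```{r example, eval = FALSE}
cfg <- pipeline_config(grid = grid_spec(30, 40),
                       params = community_params(seed = 1),
                       seed = 1)
res <- run_pipeline(cfg, out_dir = "results")
res$g_tests$guild       # host-group x guild G-test
res$clam                # host-preference classification
res$fisher$EcM          # EcM colonization vs fagaceous adjacency
```
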