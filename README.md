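# mycoroot

Spatially explicit analysis of root-associated fungal communities in mixed
ectomycorrhizal / arbuscular-mycorrhizal forests.

## The problem

In subtropical forests, ectomycorrhizal (EcM) host trees (Fagaceae) grow
intermixed with plants whose symbionts are arbuscular mycorrhizal (AM)
fungi or root endophytes of unknown function. Grid-based root sampling plus
fungal ITS metabarcoding produces, per root sample, fungal OTU read counts
together with the host plant and the sample's grid position. `mycoroot` is
for ecologists who want to go from those reads (or simulated equivalents)
to answers about host preference, functional-group co-existence within
single root fragments, and the fine-scale spatial structure of the
plant–fungal association network — including whether EcM fungi spill over
onto non-fagaceous roots adjacent to fagaceous ones.

## What it computes

* **OTU construction** — quality trimming (3' tails at Phred < 27, reads
  < 150 bp discarded) and two-stage complete-linkage consensus clustering:
  reads within each sample at 97% similarity, within-sample consensi across
  samples at 95%; singleton OTUs, OTUs with < 5 reads in every sample, and
  samples with < 20 reads are removed.
* **Matrices** — presence/absence by the strict "> 5% of sample reads" rule
  or by rarefaction to 50 reads; the plant-species x fungal-OTU association
  matrix `A[i,j]` (number of samples of species *i* where OTU *j* is
  present) with proportions `P[i,j] = A[i,j] / ΣΣA` and fagaceous /
  non-fagaceous margins.
* **Guild statistics** — G-tests (`G = 2 Σ O ln(O/E)`) comparing taxon and
  guild proportions between host groups; CLAM multinomial classification of
  each OTU as fagaceous-specialist / non-fagaceous-specialist / generalist /
  too-rare at supermajority threshold K = 2/3; shared-OTU counts per plant
  species pair; per-root EcM/AM/unknown co-existence profiles.
* **Spatial statistics** — Raup–Crick null-model dissimilarity (richness
  preserved, occurrence-frequency-weighted draws; dissimilarity =
  P(null shared ≥ observed)); Mantel correlograms over 1-m distance classes
  with Bonferroni correction; classification of non-fagaceous samples by
  fagaceous adjacency on the grid (rook neighbourhood, ≥ 3 data-bearing
  neighbours required) and Fisher exact tests of guild colonization vs
  adjacency, reporting the cross-product odds ratio.
* **Synthetic communities** — a seeded generator producing 30 × 40 grids
  with clumped hosts (25.2% fagaceous), guild-structured occupancy with an
  EcM spillover term, negative-binomial read depths (mean 98.7, SD 62.2)
  and flagged contaminant reads, with full ground truth for validation.

## Worked example

```r
library(mycoroot)

com  <- simulate_community(grid_spec(30, 40), community_params(seed = 7))
pres <- presence_by_cutoff(com)                    # strict 5% rule
pf   <- build_plant_fungus_matrix(pres, com$meta)

aggregate_proportions(pf, com$annotation, "guild")[, c(1, 5, 6)]
#>     taxon prop_fagaceous prop_non_fagaceous
#> 3 unknown    0.520714286          0.6082275
#> 2     EcM    0.471428571          0.1256212
#> 1      AM    0.007857143          0.2661513

adj <- classify_adjacency(com$meta)
fisher_adjacency_test(adj, pres, com$annotation, "EcM")
#> Fisher exact test: EcM colonization vs fagaceous adjacency
#>                    colonized not-colonized
#> fagaceous-adjacent        44            38
#> not-adjacent             323           490
#>   odds ratio = 1.76 (conditional MLE 1.76), two-sided p = 0.0181
```

Read: on this synthetic forest, 47% of the fagaceous plant–fungal
associations involve EcM fungi against ~13% on non-fagaceous hosts, AM
fungi are essentially restricted to non-fagaceous hosts, and non-fagaceous
roots next to a fagaceous neighbour carry EcM fungi noticeably more often
(odds ratio 1.76, p = 0.018) — the spillover the generator planted and the
adjacency test recovers. `run_pipeline(pipeline_config(...), out_dir = "...")` runs
every stage end to end and writes TSV/JSON outputs with provenance headers;
`inst/scripts/mycoroot.R` wraps it for the shell.

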