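Package: mycoroot
Title: Spatially Explicit Analysis of Root-Associated Fungal Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing belowground plant-fungal association data from
    grid-based root sampling in mixed ectomycorrhizal/arbuscular-mycorrhizal
    forests. Implements quality filtering and two-stage complete-linkage
    consensus clustering of amplicon reads into OTUs, presence/absence and
    plant-by-fungus association matrices (strict relative-abundance cutoff or
    rarefaction), G-tests on guild and taxon proportions, CLAM multinomial
    host-preference classification, shared-OTU counts, per-root functional-group
    co-existence profiles, Raup-Crick null-model beta-diversity, Mantel
    correlograms with Bonferroni correction, grid adjacency classification with
    Fisher exact tests of proximity effects, and a seeded synthetic
    grid-community generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vegan,
    Biostrings,
    S4Vectors,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
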