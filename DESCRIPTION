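Package: ringminer
Title: Rule-Based Genome-Wide Analysis of RING-Type E3 Ligase Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide characterization of RING-type E3 ubiquitin
    ligase gene families from protein sequences and gene models: detection of
    RING zinc-finger domains with a configurable variable-gap eight-metal-ligand
    consensus and classification into RING-H2, RING-HC, RING-v and RING-G
    subtypes (with RBX and incomplete-domain handling); gene duplication
    classification (singleton, dispersed, proximal, tandem, WGD/segmental) from
    homolog pairs and gene order with collinear block chaining; seed-stage
    expression calls, three-way Venn partitioning, hierarchical clustering with
    uncentered Pearson distance, and differential-expression filtering; Livak
    delta-delta-Ct fold changes and consistency-based candidate screening from
    qRT-PCR Ct tables; rule-based variant effect categorization with impact
    tiers; and Pearson correlation screening against starch-pathway genes.
    Every pipeline stage is exercisable on synthetic inputs with planted ground
    truth produced by the included generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    yaml,
    jsonlite,
    Biostrings,
    BiocGenerics,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
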