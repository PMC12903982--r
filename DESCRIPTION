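Package: svcascade
Title: Structural-Variant-Driven 3D Genome and Methylation Cascade Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrates structural variants (insertions, deletions,
    inversions), topologically associating domain (TAD) and A/B compartment
    annotations, DNA methylation (whole-genome bisulfite cytosine reports),
    direct-RNA m6A/m5C modification tables, and replicate gene expression into
    a gene-level regulatory cascade: window methylation summarisation and
    differentially methylated region (DMR) calling with per-context
    thresholds, detection of acquired methylation regions carried by InDels
    (InDel-AMRs), conserved/differential TAD classification with SV enrichment
    statistics, compartment switch segmentation, gene cascade categories
    (SV-gene, DMG, DPG, InDel-DMG, InDel-AMG) and expression-impact
    comparisons. Ships a synthetic two-accession multi-omics generator with
    planted ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
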