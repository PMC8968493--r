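Package: qtlprior
Title: QTL Mapping and Multi-Layer Candidate Gene Prioritization for
    Biparental RIL Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative trait locus (QTL) analysis in
    recombinant inbred line (RIL) populations and for systematic
    prioritization of candidate genes within QTL support intervals.
    Implements single-marker and composite LOD scans with genome-wide
    permutation thresholds, 1.5/2-LOD drop support intervals, robust-QTL
    consolidation across environments, two-locus epistasis tests,
    gene-action statistics (additive and dominance components) and
    ANOVA-based heritability; classifies sequence variants against gene
    models into consequence terms and impact tiers; computes expression
    and multi-allelic association evidence layers; and combines five
    evidence layers into an indexed 1-10 candidate-gene score.  A
    seed-deterministic forward simulator of biparental selfing
    populations (Haldane map function), gene/variant/expression
    annotation bundles and half-diallel F1 panels provides planted-truth
    data so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    vcfR,
    rtracklayer,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
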