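Package: crossfsv
Title: QTL Mapping and Causal-Variant Fine-Mapping in F2 Intercrosses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: An end-to-end genetic-inference workflow for two-generation
    intercross designs between divergent founder breeds: pedigree-kinship
    mixed-model association by the two-stage GRAMMAR approach, Haley-Knott
    line-cross and half-sib interval mapping with permutation thresholds,
    founder-haplotype-cluster (joint linkage and linkage-disequilibrium)
    scans with LOD-drop support intervals, marker-assisted segregation
    analysis of F1 sires, a four-stage candidate-variant filter cascade
    (biallelic, sire segregation pattern, cross intersection, regulatory
    motif overlap), Bayesian fine-mapping with per-variant posterior
    inclusion probabilities, credible sets and colocalization, and
    population diversity statistics (nucleotide diversity and Tajima's D
    with missing data). Includes a synthetic-data generator that simulates
    phased F2 crosses with a planted pleiotropic regulatory variant, so the
    whole chain is testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
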