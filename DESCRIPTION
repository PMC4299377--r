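Package: boundaryGRN
Title: Gene-Centered Regulatory Network Analysis of Organ-Boundary Translatomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for gene-centered gene-regulatory-network
    studies of Arabidopsis organ-boundary cells. Implements RPKM
    quantification and negative-binomial differential enrichment calling from
    translatome (TRAP-seq) count tables, hypergeometric gene-set and
    list-overlap enrichment with log odds ratios, enumerative IUPAC
    cis-element enrichment over upstream promoter regions, deconvolution of
    pooled yeast one-hybrid screens into validated protein-DNA interactions,
    bipartite network summary statistics and promoter-hub detection, and
    weighted-least-squares modeling of regulatory direction across genotypes
    with regenerative/degenerative edge classification. A seeded synthetic
    data generator emulates each stage's inputs together with the planted
    ground truth used to validate the pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR
Config/testthat/edition: 3
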