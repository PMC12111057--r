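Package: sysgenet
Title: Systems-Genetics Candidate Gene Prioritization for Recombinant
    Inbred Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for systems-genetics candidate-gene prioritization in
    recombinant inbred (RI) mouse panels such as the BXD family.
    Implements expression normalization to the GeneNetwork display scale
    (the 2Z+8 transformation), per-gene strain-variation summaries,
    Pearson correlation screens of a focal gene against transcriptome and
    phenome, mixed-model eQTL mapping with marker-based kinship and
    leave-one-chromosome-out (LOCO) correction, cis/trans eQTL
    classification, hypergeometric over-representation analysis of gene
    sets, protein-protein interaction ego-network degree analysis,
    two-group differential expression with Benjamini-Hochberg FDR, a
    composite 0-5 evidence score for ranking downstream candidate genes,
    and a single-locus phenome-wide association scan.  A synthetic-cohort
    generator with known planted structure (cis effects, co-expressed
    genes, genetically correlated traits, case/control shifts) makes the
    whole pipeline testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
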