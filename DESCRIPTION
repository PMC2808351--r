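Package: stemsig
Title: Quiescent Stem-Cell Signature Meta-Analysis for Replicated
    Two-Color Microarrays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested re-implementation of a meta-analysis pipeline that
    derives a quiescent hematopoietic stem cell (HSC) gene signature from
    replicated two-color cDNA microarray comparisons.  Provides
    probe-to-gene best-match mapping and redundancy collapse, a
    reproducibility-filtered one-class SAM (Significance Analysis of
    Microarrays) differential-expression caller with exhaustive sign-flip
    permutation FDR, hypergeometric pairwise and trinary gene-list overlap
    testing against an explicit detectability-defined universe, Venn
    region counting at clone and gene level, and cross-study signature
    comparison restricted to commonly tested genes.  A seeded
    synthetic-data module generates clone libraries, mapping tables and
    replicate log-ratio matrices with planted Venn overlap structure so
    the whole pipeline is testable without raw array data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
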