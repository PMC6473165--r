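Package: avianpv
Title: Avian Papillomavirus Genome Annotation, Typing, Phylogenetics and
    Prevalence Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational analysis of avian papillomavirus
    (APV) genomes and surveillance data: circular genome I/O and annotation
    with the avian-specific gene layout (E6-E7-E1/E9-E2-NCR-L2-L1-LCR,
    including the GTG alternative L1 start), degenerate-consensus motif
    scanning (E2-binding sites, TATA box, polyadenylation signals, zinc,
    pRb-binding, Walker, furin and trafficking motifs), L1 identity-based
    type/subtype/species/genus demarcation, neighbor-joining phylogenetics
    under Kimura 2-parameter and Tamura-Nei distances with gamma and
    invariant-site corrections, bootstrap and monophyly queries, and
    binomial-GLM prevalence comparisons.  A synthetic-data module generates
    papillomavirus-like genomes, alignments evolved down known cluster
    designs, and cohorts with set prevalences, all with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
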