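Package: milrcurate
Title: Curation and Tiered Re-Annotation of Hairpin-Derived Small RNA Loci in Fungi
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to curate reported fungal microRNA and miRNA-like (mi/milRNA)
    loci. Provides dot-bracket secondary-structure handling with a three-criterion
    hairpin validity test, recovery of precursor hairpins for loci reported with
    only mature sequences, re-assessment of loci against small-RNA sequencing
    evidence (strandedness, expression and duplex-structure rules, plus strict
    plant-style rule sets), classification by structural-RNA homology and genomic
    adjacency, cross-genome conservation filtering of homology hits, and a
    four-tier evidence classification. A synthetic-data generator plants stem-loop
    precursors, gene and transposon annotations, diced reads and orthologous
    hairpins so the whole pipeline can be exercised and benchmarked offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    Rsamtools,
    optparse
Config/testthat/edition: 3
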