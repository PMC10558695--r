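Package: skincat
Title: Skin Microbiome Genome Catalog Construction and Population Genomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a dereplicated species-level genome catalog from
    metagenome-assembled genome bins and profiles its biology: single-copy
    marker based completeness/contamination and quality tiers, fragment-based
    average nucleotide identity (ANI) dereplication with quality-ranked
    representatives, coverage-based species abundance, pileup SNV calling with
    codon-aware synonymous/nonsynonymous classification and depth-corrected
    pN/pS selection-pressure statistics per skin environment, best-match plus
    phylogenetic horizontal gene transfer detection with a recency split,
    KEGG-module completeness scoring, and shared-gene biosynthetic gene
    cluster networks. Ships a seed-deterministic synthetic metagenome
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    igraph,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
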