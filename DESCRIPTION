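Package: ltrscape
Title: Census, Dating and Genomic Distribution of LTR Retrotransposon Loci
Version: 0.1.0
Authors@R:
    person("ltrscape", "maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for a genomic census of LTR retrotransposon families such as
    the mouse VL30 elements. Discovers candidate loci by k-mer seeding against a
    consensus library, classifies loci as full-length, truncated or solo-LTR,
    detects target-site duplications, primer-binding sites, polypurine tracts
    and PSF-binding motifs, dates integrations from LTR-pair divergence under a
    neutral molecular clock, builds Tamura-Nei/neighbor-joining phylogenies with
    column bootstrap, and tests chromosomal and gene-context distribution
    (chi-square insertion model, TSS-distance binning, cluster detection and
    GREAT-style region/gene association). A synthetic-genome simulator plants
    elements with known truth tables so the whole pipeline is testable without
    genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    ape,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    Matrix
Config/testthat/edition: 3
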