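Package: ampliconid
Title: Amplicon Sequencing Toolkit for Meat Species Identification in DNA Mixtures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds multi-species reference panels of mitochondrial 12S/16S rRNA
    amplicon target regions from universal primer pairs by in-silico PCR,
    simulates semiconductor-sequencing (Ion Torrent style) amplicon reads from
    defined DNA pools with substitution and homopolymer-indel errors, and runs
    the downstream identification pipeline: barcode demultiplexing, primer
    trimming, glocal (read-global, reference-local) pairwise alignment with a
    mapping-quality gate, per-region read counting, per-base error-rate
    estimation, replicate correlations and species detection calls.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    S4Vectors,
    Rsamtools,
    graphics,
    jsonlite,
    yaml,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
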