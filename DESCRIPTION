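Package: crasskit
Title: Detection, Classification and Quantification of crAss-Like Phages
    in Synthetic Gut Metagenomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An analysis toolkit for crAss-like phage (Crassvirales)
    discovery in gut metagenomes, driven by a synthetic-community
    generator that plants all ground truth. Implements dual-route
    crAss-like genome identification (signature-protein alignment and
    six-frame profile search), vOTU dereplication at 95% ANI / 85%
    aligned fraction, terminase-large-subunit phylogeny with MRCA-based
    family assignment, alternative genetic-code inference with
    suppressor-tRNA detection, gene-block structure statistics,
    CRISPR-spacer host linkage at one mismatch, coverage-gated RPKM
    quantification, and two-group abundance association with
    Benjamini-Hochberg control.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    ape,
    phangorn,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
SystemRequirements: minimap2 (on PATH, for nucleotide genome alignment)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
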