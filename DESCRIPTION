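Package: tpppscan
Title: Domain Architecture Classification of p25alpha-Family (TPPP-Like) Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Annotation and classification pipeline for p25alpha-domain (TPPP-like)
    proteins. Locates full and partial p25alpha domains and doublecortin (DCX)
    domains with position-specific scoring profiles, scans for the diagnostic
    degenerate motifs (the Rossmann-like GxGxGxxGR block, the L(V)xxxF(Y)xxF
    start anchor, and GGP), and applies rule-based typing into long, short and
    truncated TPPPs, apicortins and multidomain p25alpha proteins. Also provides
    affine-gap global alignment, progressive multiple alignment, percent-identity
    matrices, neighbor-joining trees with bootstrap support, six-frame translation
    of transcriptome contigs, and a synthetic protein-family simulator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    phangorn,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
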