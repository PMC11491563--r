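Package: insilicoPCR
Title: In Silico PCR: Mismatch-Tolerant Primer and Probe Search with
    Amplicon Prediction
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts PCR amplicons from linear, circular and
    bisulfite-converted DNA templates. Primer and probe binding sites are
    located with a k-mer hash seed-and-extend search that tolerates
    mismatches, applies a dedicated 3'-end stringency rule, down-weights
    stable guanine mismatches (G-G, G-T, G-A) and supports IUPAC
    degenerate bases in both primers and templates. Convergent hit pairs
    are assembled into products for standard, inverse (circular),
    multiplex and single-primer inter-repeat (IRAP/ISSR/RAPD-style) PCR,
    with nearest-neighbor melting temperatures and annealing-temperature
    estimates for every duplex. Includes a seeded synthetic-fixture
    generator with planted ground truth and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
biocViews: SequenceMatching, Alignment, Genetics, qPCR
RoxygenNote: 7.3.3
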