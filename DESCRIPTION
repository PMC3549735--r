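Package: metasig
Title: Alignment-Free Comparison of Metagenomic Samples Using k-Tuple
    Sequence Signatures
Version: 0.1.0
Authors@R:
    person("Metasig", "Developers", email = "maintainer@metasig.dev",
           role = c("aut", "cre"))
Description: Compares shotgun metagenomic samples without assembly or
    alignment by summarising each sample's reads as a k-tuple (k-mer)
    count vector and measuring beta-diversity between samples with a
    panel of fourteen dissimilarity measures: the d2-type statistics
    (d2, d2S, d2*) with Markov background models of order 0-3,
    lp-norm distances (Manhattan, Euclidean, Chebyshev) on frequency
    vectors, the CVTree-style composition-vector correlation, and the
    di/tri/tetra-nucleotide relative-abundance odds-ratio measures.
    Includes UPGMA clustering with a Fitch parsimony group test
    (Monte Carlo p-value), principal coordinates analysis with
    gradient correlation scoring, and community simulators that
    generate synthetic genomes, Zipf and perturbed abundance
    profiles, and error-free shotgun reads for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    methods,
    optparse,
    stats,
    tools,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
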