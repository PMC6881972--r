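Package: d2bin
Title: Alignment-Free Metagenome Comparison with GC-Binned Markov Background Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the d2S and d2* alignment-free dissimilarities between
    shotgun metagenomic samples from centralized k-tuple counts, with reads
    first classified into GC-stratified bins by maximum log-likelihood under
    per-bin Markov background models trained on reference genomes. Includes
    UPGMA clustering with rooted triplet distance against a reference
    grouping, principal coordinates analysis with gradient correlation, a
    synthetic community simulator (Zipf abundance profiles with Gaussian
    perturbation, paired-end read sampling with substitution errors), and a
    small command-line interface over the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    ape,
    stats,
    utils,
    methods,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
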