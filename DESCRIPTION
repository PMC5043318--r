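Package: motifcv
Title: Temporal Regularity of Shared Motifs in Birdsong Performances
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying temporal regularity in long birdsong
    performances. Phrases are the atomic unit; many phrase types share
    motifs (notes or stereotyped note groups), and the package measures
    how regularly phrase types and shared motifs recur using a pooled
    coefficient of variation of mean-normalized inter-phrase intervals
    (CV*). Includes a shuffled null, first-order (bigram) Markov syntax
    models, a permuted-Markov rank procedure that estimates how strongly
    a bird's phrase syntax is optimized for motif regularity, and a
    transition-matrix complexity measure. An acoustic front end converts
    recordings to syllable-onset point processes and clusters phrases
    into types by spike-train similarity; a synthetic-data generator
    produces performances, transition matrices and audio renderings with
    controllable structure so the full pipeline is testable without
    field recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    stats,
    utils,
    graphics,
    grDevices,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
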