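Package: squigglecall
Title: Joint Raw and Event Nanopore Basecalling with an Attention
    Sequence-to-Sequence Model
Version: 0.1.0
Authors@R:
    person("squigglecall", "developers", email = "squigglecall@example.org",
           role = c("aut", "cre"))
Description: A compact, fully tested nanopore basecalling pipeline that
    translates raw ionic-current squiggles into nucleotide sequences by
    jointly processing the raw signal and its event segmentation.  Includes
    a pore-model squiggle simulator over reduced-complexity references with
    per-base ground-truth alignment, sliding-window t-statistic event
    detection, a windowed sample/batch preparation pipeline, twin
    bidirectional-LSTM encoders with Luong multiplicative attention and an
    LSTM decoder trained by scheduled sampling with gradient clipping
    (implemented natively, with analytic backpropagation), greedy and beam
    search decoding, Needleman-Wunsch read assembly, and subset/read
    ("BLAST identity") accuracy evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
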