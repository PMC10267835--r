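Package: nctmux
Title: Simulation-Based Design of Multiplexed Nascent Chain Tracking Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to design single-color multiplexed nascent chain tracking
    (NCT) experiments in silico. Simulates codon-dependent TASEP ribosome
    dynamics on epitope-tagged mRNA constructs, renders the resulting
    fluorescent spot intensities into synthetic microscopy video with a
    heterogeneous cell background, Brownian spot motion and controllable
    signal-to-noise ratio, re-quantifies spots with the disk-and-doughnut
    method, and trains a dual-input 1D convolutional classifier on
    min-max-normalized intensity traces and their autocorrelation functions
    to discriminate identically tagged mRNA species. Includes analytic
    sparse-loading calculators for the mean and variance of spot intensity
    and for the critical initiation- and elongation-rate ratios at which two
    constructs become indistinguishable, plus sweep runners for imaging and
    biophysical parameter studies and a two-color multiplexing demonstration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    Biostrings,
    tiff,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
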