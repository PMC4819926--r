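Package: scanlba
Title: Linear Ballistic Accumulator Analysis of Scanner-Environment Effects on Decision-Making
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to decompose scanner-environment effects on perceptual
    decision-making into latent components of the linear ballistic accumulator
    (LBA) model. Provides closed-form LBA distributions and defective race
    likelihoods, declarative experimental designs for three random-dot-motion
    paradigms (probabilistic cueing, speed-accuracy trade-off, motion
    coherence with inter-trial-interval manipulation), enumeration of nested
    model hierarchies, per-participant maximum-likelihood fitting with warm
    starts, AIC-weight model averaging, default-prior Bayes-factor ANOVAs for
    repeated-measures designs, and a trial-level synthetic data generator with
    injectable session effects (motor slowing, response caution, arousal,
    attentional focus).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
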