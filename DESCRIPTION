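Package: replayburst
Title: Replay Decoding, Time-Delay-Embedded HMM States, and Burst
    Statistics for Multichannel Neural Recordings
Version: 0.1.0
Authors@R:
    person("replayburst", "developers", email = "replayburst@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline linking spontaneous replay events to
    transient resting-state-network (RSN) activations in multichannel
    electrophysiological recordings. Provides sparse logistic decoders for
    stimulus reactivation, lagged sequence evidence and a replay
    probability trace, a time-delay-embedded hidden Markov model with
    full-covariance Gaussian observations fit by Baum-Welch EM,
    transition-derived state labeling via classical multidimensional
    scaling, state-conditioned Slepian multitaper power and coherence with
    non-negative matrix factorization frequency modes, replay-evoked
    responses with sign-flip cluster permutation tests, and Fano-factor
    burstiness analysis of event trains with interval-shuffle surrogates.
    Includes a synthetic-data module that generates fixtures with planted
    ground truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
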