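Package: adlHMM
Title: Hybrid Generative/Discriminative Hidden Markov Models for
    Activity Recognition from Binary Home Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Recognises activities of daily living from binary
    state-change sensor streams recorded in a single-resident home.
    Implements time-slice discretization of sensor event streams, the
    raw/change-point/last-sensor feature encodings, a supervised hidden
    Markov model with independent Bernoulli emissions, and hybrid
    HMM/MLP and HMM/SVM models in which discriminative classifier
    posteriors are converted to scaled likelihoods and decoded with the
    Viterbi algorithm. Includes Platt sigmoid calibration for SVM
    decision values, leave-one-day-out evaluation with macro-averaged
    precision, recall and F-measure, paired significance tests, and a
    seeded synthetic smart-home simulator so the whole stack can be
    exercised without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    nnet,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
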