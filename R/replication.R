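#' Hybrid-versus-static replication study on synthetic homes
#'
#' Runs the package's end-to-end comparison on seeded simulated
#' recordings: for each replicate a fresh home is sampled, split into
#' days, and evaluated leave-one-day-out with four models sharing the
#' same fitted emitters per fold — the hybrid HMM/MLP and HMM/SVM
#' (scaled-likelihood Viterbi decoding) and their static sliding-window
#' counterparts (per-slice posterior argmax). Under temporal persistence
#' and sensor noise the hybrid decoders are expected to match or beat the
#' static classifiers in macro F-measure; [pairedTests()] on the
#' per-replicate means quantifies the difference.
#'
#' @param nReplicates number of independently seeded homes.
#' @param config a [simConfig()]; default [replicationConfig()].
#' @param representation feature representation string for [featurize()].
#' @param seed base seed; replicate r uses `seed + r`.
#' @param mlpConfig,svmConfig emitter configurations.
#' @param alpha transition smoothing pseudocount.
#' @return `data.frame` with one row per replicate and columns
#'   `hybrid_mlp`, `static_mlp`, `hybrid_svm`, `static_svm` (mean
#'   leave-one-day-out macro F-measure per replicate).
#' @export
replicationStudy <- function(nReplicates = 20L, config = replicationConfig(),
                             representation = "raw", seed = 1L,
                             mlpConfig = emitterConfig("mlp"),
                             svmConfig = emitterConfig("svm"),
                             alpha = 1) {
  rows <- vector("list", nReplicates)
  for (r in seq_len(nReplicates)) {
    sim <- sampleHome(config, seed = seed + r)
    days <- lapply(splitDays(sim$truth), function(d) {
      list(features = featurize(d, representation), labels = d@labels)
    })
    cn <- sim$truth@classNames
    scores <- .lodoHybridStatic(days, cn, mlpConfig, svmConfig, alpha)
    rows[[r]] <- data.frame(replicate = r, t(scores))
  }
  do.call(rbind, rows)
}

# One LODO pass computing hybrid and static macro F for both emitter
# kinds, fitting each emitter once per fold.
.lodoHybridStatic <- function(days, classNames, mlpConfig, svmConfig,
                              alpha) {
  nD <- length(days)
  f <- matrix(NA_real_, nD, 4,
              dimnames = list(NULL, c("hybrid_mlp", "static_mlp",
                                      "hybrid_svm", "static_svm")))
  for (d in seq_len(nD)) {
    trainDays <- days[-d]
    test <- days[[d]]
    opts <- trainOptions(alpha = alpha)
    mMLP <- trainHybrid(trainDays, mlpConfig, opts, classNames = classNames)
    mSVM <- trainHybrid(trainDays, svmConfig, opts, classNames = classNames)
    for (spec in list(list(m = mMLP, h = "hybrid_mlp", s = "static_mlp"),
                      list(m = mSVM, h = "hybrid_svm", s = "static_svm"))) {
      predH <- predict(spec$m, test$features)
      predS <- predictStatic(spec$m@emitter, test$features)
      f[d, spec$h] <- macroMetrics(
        confusionCounts(test$labels, predH, classNames))["fmeasure"]
      f[d, spec$s] <- macroMetrics(
        confusionCounts(test$labels, predS, classNames))["fmeasure"]
    }
  }
  colMeans(f)
}
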