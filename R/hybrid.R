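#' Hybrid training options
#'
#' By default training is a single supervised pass: the transition
#' structure comes from the labelled data and the emitter is fitted once.
#' With `realign = TRUE` the iterative variant is used: after each emitter
#' fit the training days are re-decoded with the current hybrid model and
#' the emitter is refitted on the decoded labels, until the decoded paths
#' stop changing or `maxIterations` is reached. `reestimateChain` also
#' refreshes `pi`/`trans` from the realigned labels on each iteration.
#'
#' @param maxIterations iteration cap for the realignment loop (>= 1).
#' @param realign enable Viterbi realignment between iterations.
#' @param reestimateChain re-estimate `pi`/`trans` from realigned labels.
#' @param alpha smoothing pseudocount for `pi`/`trans` estimation.
#' @param seed integer seed (also forwarded to the emitter when its config
#'   carries no seed).
#' @return list of class `TrainOptions`.
#' @export
trainOptions <- function(maxIterations = 1L, realign = FALSE,
                         reestimateChain = FALSE, alpha = 1, seed = 1L) {
  stopifnot(maxIterations >= 1L, alpha >= 0)
  structure(list(maxIterations = as.integer(maxIterations),
                 realign = isTRUE(realign),
                 reestimateChain = isTRUE(reestimateChain),
                 alpha = alpha, seed = as.integer(seed)),
            class = "TrainOptions")
}

#' Train a hybrid HMM/classifier model
#'
#' Builds the hybrid generative/discriminative recognizer: `pi` and the
#' transition matrix are estimated from the labelled training days
#' (with smoothing, so every transition keeps nonzero probability), the
#' discriminative emitter is fitted on all training slices, and the class
#' priors for the scaled-likelihood conversion are taken from the final
#' training labels. Each day is an independent sequence: `pi` applies at
#' each day's first slice and no transition is counted across midnight.
#'
#' @param days list of training days, each a `list(features = <T x M
#'   binary matrix>, labels = <length-T labels>)`.
#' @param emitterConfig an [emitterConfig()].
#' @param options a [trainOptions()].
#' @param classNames full ordered class set; defaults to factor levels of
#'   the first day's labels.
#' @return a [HybridModel-class].
#' @seealso [predict,HybridModel-method], [predictStatic()]
#' @export
trainHybrid <- function(days, emitterConfig = adlHMM::emitterConfig(),
                        options = trainOptions(), classNames = NULL) {
  stopifnot(length(days) >= 1L, inherits(options, "TrainOptions"))
  featList <- lapply(days, `[[`, "features")
  labList <- lapply(days, `[[`, "labels")
  cn <- .resolveClasses(labList, classNames)
  labList <- lapply(labList, .asLabelIndex, classNames = cn)
  if (length(unique(unlist(labList))) < 2L) {
    stop("training labels must cover at least two classes", call. = FALSE)
  }

  chain <- estimateSupervised(featList, labList, alpha = options$alpha,
                              classNames = cn)
  allFeat <- do.call(rbind, featList)
  curLabels <- labList
  pi <- chain@pi
  trans <- chain@trans
  emitter <- fitEmitter(allFeat, unlist(curLabels), emitterConfig,
                        classNames = cn)

  if (options$realign) {
    for (iter in seq_len(options$maxIterations)) {
      priors <- estimatePriors(unlist(curLabels), classNames = cn)
      decoded <- lapply(featList, function(fm) {
        em <- scaledLikelihoods(posterior(emitter, fm), priors)
        viterbi(pi, trans, em)
      })
      if (length(unique(unlist(decoded))) < 2L) {
        warning("realignment collapsed to a single class; keeping the ",
                "previous model", call. = FALSE)
        break
      }
      if (identical(decoded, curLabels)) break
      curLabels <- decoded
      if (options$reestimateChain) {
        chain <- estimateSupervised(featList, curLabels,
                                    alpha = options$alpha, classNames = cn)
        pi <- chain@pi
        trans <- chain@trans
      }
      emitter <- fitEmitter(allFeat, unlist(curLabels), emitterConfig,
                            classNames = cn)
    }
  }

  priors <- estimatePriors(unlist(curLabels), classNames = cn)
  new("HybridModel", pi = pi, trans = trans, emitter = emitter,
      priors = unname(priors), classNames = cn,
      options = unclass(options))
}

#' Decode a day with a hybrid model
#'
#' Obtains the emitter's posteriors for every slice, converts them to log
#' scaled likelihoods with the model's class priors, and runs Viterbi over
#' the model's `pi` and transition matrix.
#'
#' @param object a [HybridModel-class].
#' @param feat T x M binary feature matrix with the training columns.
#' @param ... unused.
#' @return integer label sequence of length T.
#' @export
setMethod("predict", "HybridModel", function(object, feat, ...) {
  post <- posterior(object@emitter, feat)
  em <- scaledLikelihoods(post, object@priors)
  viterbi(object@pi, object@trans, em)
})

#' Persist a hybrid model
#'
#' Writes a JSON document with the interpretable parts of the model (`pi`,
#' `trans`, `priors`, class names, feature names, configs) next to an RDS
#' payload holding the fitted emitter object, and reads the pair back.
#'
#' @param model a [HybridModel-class].
#' @param prefix path prefix; `<prefix>.json` and `<prefix>.rds` are
#'   written.
#' @return `writeHybridModel`: the prefix, invisibly; `readHybridModel`:
#'   the model.
#' @export
writeHybridModel <- function(model, prefix) {
  doc <- list(
    pi = model@pi, trans = unname(model@trans), priors = model@priors,
    class_names = model@classNames,
    feature_names = model@emitter@featureNames,
    emitter = model@emitter@config, options = model@options
  )
  jsonlite::write_json(doc, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  saveRDS(model, paste0(prefix, ".rds"))
  invisible(prefix)
}

#' @rdname writeHybridModel
#' @export
readHybridModel <- function(prefix) {
  readRDS(paste0(prefix, ".rds"))
}
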