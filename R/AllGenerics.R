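#' Class posteriors of a fitted emitter
#'
#' @param object a fitted [Emitter-class].
#' @param feat binary feature matrix with the training columns.
#' @return T x Q matrix of posterior probabilities `p(y_t | x_t)`; rows sum
#'   to 1 and every class of the training class set has a column.
#' @export
setGeneric("posterior", function(object, feat) standardGeneric("posterior"))

#' @rdname accessors
#' @export
setGeneric("obsMatrix", function(x) standardGeneric("obsMatrix"))

#' @rdname accessors
#' @export
setGeneric("sensorIds", function(x) standardGeneric("sensorIds"))

#' @rdname accessors
#' @export
setGeneric("sliceLabels", function(x) standardGeneric("sliceLabels"))

#' @rdname accessors
#' @export
setGeneric("classNames", function(x) standardGeneric("classNames"))

#' @rdname accessors
#' @export
setGeneric("startTime", function(x) standardGeneric("startTime"))

#' @rdname accessors
#' @export
setGeneric("sliceDuration", function(x) standardGeneric("sliceDuration"))

#' Accessors for adlHMM objects
#'
#' `obsMatrix` returns the T x N binary observation matrix, `sensorIds` the
#' sensor column names, `sliceLabels` the per-slice integer labels (length 0
#' when absent), `classNames` the activity names, `startTime` the timestamp
#' of the first slice and `sliceDuration` the slice length in seconds.
#'
#' @param x a [SliceData-class], [HMMParams-class] or [HybridModel-class]
#'   object, as applicable.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("obsMatrix", "SliceData", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("sensorIds", "SliceData", function(x) x@sensorIds)

#' @rdname accessors
#' @export
setMethod("sliceLabels", "SliceData", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("classNames", "SliceData", function(x) x@classNames)

#' @rdname accessors
#' @export
setMethod("classNames", "HMMParams", function(x) x@classNames)

#' @rdname accessors
#' @export
setMethod("classNames", "HybridModel", function(x) x@classNames)

#' @rdname accessors
#' @export
setMethod("startTime", "SliceData", function(x) x@t0)

#' @rdname accessors
#' @export
setMethod("sliceDuration", "SliceData", function(x) x@dt)

setMethod("show", "SliceData", function(object) {
  cat(sprintf(
    "SliceData: %d slices x %d sensors, dt = %gs, from %s\n",
    nrow(object@values), ncol(object@values), object@dt,
    .formatStamp(object@t0)
  ))
  if (length(object@labels)) {
    tab <- table(factor(object@classNames[object@labels],
                        levels = object@classNames))
    cat("labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  } else {
    cat("labels: none\n")
  }
})

setMethod("show", "HMMParams", function(object) {
  cat(sprintf(
    "HMMParams: Q = %d states, N = %d Bernoulli features (alpha = %g)\n",
    length(object@pi), ncol(object@mu), object@alpha
  ))
  if (length(object@classNames)) {
    cat("states:", paste(object@classNames, collapse = ", "), "\n")
  }
})

setMethod("show", "MLPEmitter", function(object) {
  cat(sprintf(
    "MLPEmitter: %d -> %d -> %d (softmax), seed %d\n",
    length(object@featureNames), object@config$hiddenUnits,
    length(object@observed), object@config$seed
  ))
})

setMethod("show", "SVMEmitter", function(object) {
  cat(sprintf(
    "SVMEmitter: %d RBF binary subproblems (%s), Platt-calibrated\n",
    length(object@models), object@config$multiclassScheme
  ))
})

setMethod("show", "HybridModel", function(object) {
  cat(sprintf(
    "HybridModel: %s emitter over %d activities\n",
    object@emitter@config$kind, length(object@classNames)
  ))
  cat("activities:", paste(object@classNames, collapse = ", "), "\n")
})
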