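#' Time-slice representation of a binary sensor stream
#'
#' A `SliceData` object holds the discretized form of a recording: a T x N
#' binary matrix whose entry (t, i) is 1 when sensor i fired for at least
#' one second inside slice t (slices are half-open intervals
#' `[t0 + (t-1) dt, t0 + t dt)`), together with the per-slice activity
#' labels. Class index 1 is reserved for the idle/unlabeled class; labels
#' may be absent (length 0) for data awaiting prediction.
#'
#' @slot values T x N numeric matrix with entries in \{0, 1\}.
#' @slot sensorIds character vector of N sensor identifiers, in column order.
#' @slot t0 `POSIXct` start of the first slice.
#' @slot dt slice length in seconds.
#' @slot labels integer vector of length T (or 0) with values in `1..Q`.
#' @slot classNames character vector of the Q activity names; index 1 is the
#'   idle/unlabeled class.
#'
#' @seealso [discretize()], [sliceData()], [splitDays()]
#' @export
setClass("SliceData",
  slots = c(
    values = "matrix",
    sensorIds = "character",
    t0 = "POSIXct",
    dt = "numeric",
    labels = "integer",
    classNames = "character"
  )
)

setValidity("SliceData", function(object) {
  msgs <- character()
  v <- object@values
  if (!is.numeric(v)) msgs <- c(msgs, "values must be a numeric matrix")
  if (nrow(v) < 1L) msgs <- c(msgs, "at least one time slice required")
  if (is.numeric(v) && !all(v == 0 | v == 1)) {
    msgs <- c(msgs, "values must be binary (0/1)")
  }
  if (ncol(v) != length(object@sensorIds)) {
    msgs <- c(msgs, "ncol(values) must equal length(sensorIds)")
  }
  if (any(!nzchar(object@sensorIds))) msgs <- c(msgs, "sensorIds must be non-empty")
  if (anyDuplicated(object@sensorIds)) msgs <- c(msgs, "sensorIds must be unique")
  if (length(object@dt) != 1L || object@dt <= 0) msgs <- c(msgs, "dt must be a positive scalar")
  nl <- length(object@labels)
  if (nl > 0L) {
    if (nl != nrow(v)) msgs <- c(msgs, "labels length must match the number of slices")
    q <- length(object@classNames)
    if (q < 1L) msgs <- c(msgs, "classNames required when labels are present")
    if (any(object@labels < 1L | object@labels > max(q, 1L))) {
      msgs <- c(msgs, "labels must index classNames")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Parameters of a Bernoulli-emission hidden Markov model
#'
#' Holds the full parameterisation of the generative model: initial state
#' probabilities `pi`, the row-stochastic transition matrix `trans`
#' (`trans[i, j] = p(y_t = j | y_{t-1} = i)`), and the Q x N matrix `mu` of
#' Bernoulli means (`mu[i, n] = p(x^n = 1 | y = i)`), assuming the N binary
#' features are conditionally independent given the activity.
#'
#' @slot pi length-Q initial-state probability vector.
#' @slot trans Q x Q row-stochastic transition matrix.
#' @slot mu Q x N matrix of Bernoulli means in `[0, 1]`.
#' @slot classNames character vector of the Q state names.
#' @slot featureNames character vector of the N feature/sensor names.
#' @slot alpha smoothing pseudocount used at estimation time.
#'
#' @seealso [estimateSupervised()], [viterbi()], [bernoulliLogEmissions()]
#' @export
setClass("HMMParams",
  slots = c(
    pi = "numeric",
    trans = "matrix",
    mu = "matrix",
    classNames = "character",
    featureNames = "character",
    alpha = "numeric"
  )
)

setValidity("HMMParams", function(object) {
  msgs <- character()
  q <- length(object@pi)
  if (q < 1L) msgs <- c(msgs, "Q must be >= 1")
  if (abs(sum(object@pi) - 1) > 1e-9) msgs <- c(msgs, "pi must sum to 1")
  if (any(object@pi < 0)) msgs <- c(msgs, "pi must be nonnegative")
  if (!all(dim(object@trans) == c(q, q))) msgs <- c(msgs, "trans must be Q x Q")
  else if (any(abs(rowSums(object@trans) - 1) > 1e-9) || any(object@trans < 0)) {
    msgs <- c(msgs, "trans rows must be probability vectors summing to 1")
  }
  if (nrow(object@mu) != q) msgs <- c(msgs, "mu must have Q rows")
  if (ncol(object@mu) < 1L) msgs <- c(msgs, "N must be >= 1")
  if (any(object@mu < 0 | object@mu > 1)) msgs <- c(msgs, "mu entries must lie in [0, 1]")
  if (length(object@classNames) && length(object@classNames) != q) {
    msgs <- c(msgs, "classNames must have length Q")
  }
  if (length(object@featureNames) && length(object@featureNames) != ncol(object@mu)) {
    msgs <- c(msgs, "featureNames must have length N")
  }
  if (length(msgs)) msgs else TRUE
})

#' Fitted discriminative emitters
#'
#' `Emitter` is the virtual parent of the discriminative posterior
#' estimators used as observation models of the hybrid HMM. `MLPEmitter`
#' wraps a single-hidden-layer perceptron with softmax outputs
#' (via \pkg{nnet}); `SVMEmitter` wraps one RBF-kernel support vector
#' machine per binary subproblem (via \pkg{e1071}) together with the Platt
#' sigmoid calibration of each decision value.
#'
#' Both respond to [posterior()] with a T x Q row-stochastic matrix over
#' the full training class set; classes absent from the training slices
#' receive floored (effectively zero) posterior mass.
#'
#' @slot classNames the Q class names the posteriors are defined over.
#' @slot featureNames training feature columns, checked at prediction time.
#' @slot config the [emitterConfig()] used for fitting.
#' @slot observed integer indices of the classes present in training data.
#'
#' @aliases MLPEmitter-class SVMEmitter-class
#' @seealso [fitEmitter()], [posterior()]
#' @export
setClass("Emitter",
  representation("VIRTUAL",
    classNames = "character",
    featureNames = "character",
    config = "list",
    observed = "integer"
  )
)

#' @rdname Emitter-class
#' @slot fit the fitted `nnet` object.
#' @export
setClass("MLPEmitter", contains = "Emitter", slots = c(fit = "ANY"))

#' @rdname Emitter-class
#' @slot models list of fitted binary `svm` objects (one per subproblem).
#' @slot platt list of Platt sigmoid parameter pairs, one per subproblem.
#' @slot problems list describing each binary subproblem (scheme-dependent).
#' @export
setClass("SVMEmitter", contains = "Emitter",
  slots = c(models = "list", platt = "list", problems = "list"))

#' Hybrid generative/discriminative activity model
#'
#' Combines an HMM over activities (only `pi` and `trans` are used; the
#' temporal structure) with a discriminative emitter whose class posteriors
#' are converted to scaled likelihoods `p(y|x)/p(y)` before Viterbi
#' decoding. `priors` are the class relative frequencies of the training
#' slices used in that conversion.
#'
#' @slot pi length-Q initial-state probabilities.
#' @slot trans Q x Q row-stochastic transition matrix.
#' @slot emitter a fitted [Emitter-class] object.
#' @slot priors length-Q class prior probabilities.
#' @slot classNames the Q activity names.
#' @slot options the [trainOptions()] list used for training.
#'
#' @seealso [trainHybrid()], [predict,HybridModel-method]
#' @export
setClass("HybridModel",
  slots = c(
    pi = "numeric",
    trans = "matrix",
    emitter = "Emitter",
    priors = "numeric",
    classNames = "character",
    options = "list"
  )
)

setValidity("HybridModel", function(object) {
  msgs <- character()
  q <- length(object@classNames)
  if (length(object@pi) != q || abs(sum(object@pi) - 1) > 1e-9) {
    msgs <- c(msgs, "pi must be a length-Q probability vector")
  }
  if (!all(dim(object@trans) == c(q, q)) ||
      any(abs(rowSums(object@trans) - 1) > 1e-9)) {
    msgs <- c(msgs, "trans must be Q x Q row-stochastic")
  }
  if (length(object@priors) != q || abs(sum(object@priors) - 1) > 1e-6 ||
      any(object@priors <= 0)) {
    msgs <- c(msgs, "priors must be strictly positive and sum to 1")
  }
  if (!identical(object@emitter@classNames, object@classNames)) {
    msgs <- c(msgs, "emitter class names must match the model's")
  }
  if (length(msgs)) msgs else TRUE
})
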