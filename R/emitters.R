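#' Emitter configuration
#'
#' Hyperparameters of the discriminative posterior estimators. For the MLP
#' (`kind = "mlp"`): one hidden layer of `hiddenUnits` units (default
#' twice the feature count) with softmax outputs, trained to maximum
#' conditional likelihood with weight decay `decay` for capacity control.
#' For the SVM (`kind = "svm"`): RBF kernel
#' `K(x, y) = exp(-|x - y|^2 / (2 sigma^2))` with `rbfSigma` set by the
#' median heuristic on pairwise training distances when `NULL`, soft-margin
#' cost `cost`, the multiclass problem reduced to binary subproblems by
#' `multiclassScheme`, and each subproblem's decision values calibrated by
#' a Platt sigmoid fitted on a `calibrationFolds`-fold cross-validated
#' decision-value pool (so the sigmoid never sees in-sample, optimistically
#' separated scores).
#'
#' @param kind `"mlp"` or `"svm"`.
#' @param hiddenUnits MLP hidden layer width; `NULL` = 2 x feature count.
#' @param decay MLP weight decay.
#' @param rbfSigma RBF kernel width sigma; `NULL` = median heuristic.
#' @param cost SVM soft-margin cost.
#' @param multiclassScheme `"one_vs_rest"` (default) or `"one_vs_one"`.
#' @param calibrationFolds folds for the Platt calibration pool.
#' @param maxIterations optimizer iteration cap.
#' @param seed integer seed making training deterministic.
#' @return a validated list of class `EmitterConfig`.
#' @export
emitterConfig <- function(kind = c("mlp", "svm"), hiddenUnits = NULL,
                          decay = 0.1, rbfSigma = NULL, cost = 1,
                          multiclassScheme = c("one_vs_rest", "one_vs_one"),
                          calibrationFolds = 3L, maxIterations = 200L,
                          seed = 1L) {
  kind <- match.arg(kind)
  multiclassScheme <- match.arg(multiclassScheme)
  stopifnot(maxIterations >= 1L, cost > 0, calibrationFolds >= 2L,
            is.null(hiddenUnits) || hiddenUnits >= 1L,
            is.null(rbfSigma) || rbfSigma > 0)
  structure(list(kind = kind, hiddenUnits = hiddenUnits, decay = decay,
                 rbfSigma = rbfSigma, cost = cost,
                 multiclassScheme = multiclassScheme,
                 calibrationFolds = as.integer(calibrationFolds),
                 maxIterations = as.integer(maxIterations),
                 seed = as.integer(seed)),
            class = "EmitterConfig")
}

#' Fit a discriminative emitter
#'
#' Trains the classifier that supplies per-slice class posteriors to the
#' hybrid model. Training is deterministic given `config$seed`. Classes
#' absent from the training slices remain part of the class set and get
#' floored posterior mass at prediction time.
#'
#' @param feat T x M binary feature matrix.
#' @param labels factor or integer labels (length T).
#' @param config an [emitterConfig()].
#' @param classNames full ordered class set; defaults to factor levels.
#' @return a fitted [Emitter-class] ([MLPEmitter][Emitter-class] or
#'   [SVMEmitter][Emitter-class]).
#' @export
fitEmitter <- function(feat, labels, config = emitterConfig(),
                       classNames = NULL) {
  stopifnot(inherits(config, "EmitterConfig"), is.matrix(feat))
  if (!.isBinary(feat)) stop("features must be binary", call. = FALSE)
  cn <- .resolveClasses(list(labels), classNames)
  y <- .asLabelIndex(labels, cn)
  stopifnot(length(y) == nrow(feat))
  observed <- sort(unique(y))
  if (length(observed) < 2L) {
    stop("emitter training needs at least two observed classes",
         call. = FALSE)
  }
  fn <- colnames(feat)
  if (is.null(fn)) fn <- paste0("f", seq_len(ncol(feat)))
  colnames(feat) <- fn
  set.seed(config$seed)
  if (config$kind == "mlp") {
    .fitMLP(feat, y, observed, cn, fn, config)
  } else {
    .fitSVM(feat, y, observed, cn, fn, config)
  }
}

.fitMLP <- function(feat, y, observed, cn, fn, config) {
  h <- config$hiddenUnits
  if (is.null(h)) h <- 2L * ncol(feat)
  config$hiddenUnits <- h
  yind <- nnet::class.ind(factor(y, levels = observed))
  nw <- (ncol(feat) + 1L) * h + (h + 1L) * length(observed)
  fit <- nnet::nnet(x = feat, y = yind, size = h, softmax = TRUE,
                    decay = config$decay, maxit = config$maxIterations,
                    MaxNWts = nw + 10L, trace = FALSE)
  new("MLPEmitter", fit = fit, classNames = cn, featureNames = fn,
      config = unclass(config), observed = as.integer(observed))
}

.medianSigma <- function(feat, maxRows = 400L) {
  rows <- if (nrow(feat) > maxRows) {
    sample.int(nrow(feat), maxRows)
  } else {
    seq_len(nrow(feat))
  }
  d <- as.numeric(dist(feat[rows, , drop = FALSE]))
  d <- d[d > 0]
  if (!length(d)) return(1)
  median(d)
}

.fitSVM <- function(feat, y, observed, cn, fn, config) {
  sigma <- config$rbfSigma
  if (is.null(sigma)) sigma <- .medianSigma(feat)
  config$rbfSigma <- sigma
  gamma <- 1 / (2 * sigma^2)
  problems <- if (config$multiclassScheme == "one_vs_rest") {
    lapply(observed, function(i) list(pos = i, neg = setdiff(observed, i)))
  } else {
    prs <- utils::combn(observed, 2L, simplify = FALSE)
    lapply(prs, function(pq) list(pos = pq[1L], neg = pq[2L]))
  }
  folds <- sample(rep_len(seq_len(config$calibrationFolds), length(y)))
  models <- vector("list", length(problems))
  platt <- vector("list", length(problems))
  for (k in seq_along(problems)) {
    pr <- problems[[k]]
    inProblem <- y %in% c(pr$pos, pr$neg)
    xk <- feat[inProblem, , drop = FALSE]
    posk <- y[inProblem] %in% pr$pos
    fk <- folds[inProblem]
    models[[k]] <- .binSVM(xk, posk, gamma, config$cost)
    # Platt pool from cross-validated decision values where feasible
    dv <- rep(NA_real_, length(posk))
    for (f in unique(fk)) {
      tr <- fk != f
      if (length(unique(posk[tr])) < 2L) next
      m <- .binSVM(xk[tr, , drop = FALSE], posk[tr], gamma, config$cost)
      dv[!tr] <- .decisionValues(m, xk[!tr, , drop = FALSE])
    }
    if (anyNA(dv)) dv <- .decisionValues(models[[k]], xk)
    platt[[k]] <- fitPlatt(dv, posk)
  }
  new("SVMEmitter", models = models, platt = platt, problems = problems,
      classNames = cn, featureNames = fn,
      config = unclass(config), observed = as.integer(observed))
}

.binSVM <- function(x, pos, gamma, cost) {
  yb <- factor(ifelse(pos, "pos", "rest"), levels = c("pos", "rest"))
  e1071::svm(x = x, y = yb, kernel = "radial", gamma = gamma, cost = cost,
             scale = FALSE)
}

# Decision values oriented so that larger means more 'pos'.
.decisionValues <- function(model, x) {
  pr <- predict(model, x, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  if (colnames(dv)[1L] == "rest/pos") -dv[, 1L] else dv[, 1L]
}

#' @rdname posterior
#' @export
setMethod("posterior", "MLPEmitter", function(object, feat) {
  .checkFeat(object, feat)
  p <- predict(object@fit, feat)
  if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
  .expandPosterior(p, object@observed, object@classNames)
})

#' @rdname posterior
#' @export
setMethod("posterior", "SVMEmitter", function(object, feat) {
  .checkFeat(object, feat)
  nT <- nrow(feat)
  nObs <- length(object@observed)
  sig <- vapply(seq_along(object@models), function(k) {
    plattProb(object@platt[[k]],
              .decisionValues(object@models[[k]], feat))
  }, numeric(nT))
  sig <- matrix(sig, nrow = nT)
  raw <- matrix(.EPS, nT, nObs)
  if (object@config$multiclassScheme == "one_vs_rest") {
    raw <- pmax(sig, .EPS)
  } else {
    # pairwise coupling: average each class's calibrated pairwise wins
    for (k in seq_along(object@problems)) {
      pr <- object@problems[[k]]
      i <- match(pr$pos, object@observed)
      j <- match(pr$neg, object@observed)
      raw[, i] <- raw[, i] + sig[, k]
      raw[, j] <- raw[, j] + (1 - sig[, k])
    }
    raw <- raw / (nObs - 1L)
  }
  degenerate <- rowSums(raw) <= nObs * .EPS * 1.01
  if (any(degenerate)) {
    warning("all calibrated outputs floored for some slices; using a ",
            "uniform posterior there", call. = FALSE)
    raw[degenerate, ] <- 1
  }
  raw <- raw / rowSums(raw)
  .expandPosterior(raw, object@observed, object@classNames)
})

.checkFeat <- function(object, feat) {
  if (!is.matrix(feat) || ncol(feat) != length(object@featureNames)) {
    stop("feature columns do not match the emitter's training features",
         call. = FALSE)
  }
}

# Embed posteriors over the observed classes into the full class set,
# floor at .EPS and renormalize so rows sum to 1 exactly.
.expandPosterior <- function(p, observed, classNames) {
  q <- length(classNames)
  full <- matrix(.EPS, nrow(p), q, dimnames = list(NULL, classNames))
  full[, observed] <- pmax(p, .EPS)
  full / rowSums(full)
}

#' Class priors from label frequencies
#'
#' Relative frequency of each class among the training slices, floored at
#' 1e-12 for absent classes and renormalized, so the scaled-likelihood
#' conversion never divides by zero.
#'
#' @param labels factor or integer labels.
#' @param classNames full ordered class set; defaults to factor levels.
#' @return named numeric vector of length Q summing to 1.
#' @export
estimatePriors <- function(labels, classNames = NULL) {
  cn <- .resolveClasses(list(labels), classNames)
  y <- .asLabelIndex(labels, cn)
  p <- tabulate(y, nbins = length(cn)) / length(y)
  p <- pmax(p, .EPS)
  p <- p / sum(p)
  names(p) <- cn
  p
}

#' Convert posteriors to log scaled likelihoods
#'
#' By Bayes' rule `p(x|y) = p(y|x) p(x) / p(y)`; since `p(x)` is constant
#' across states at a given slice it can be dropped for decoding, leaving
#' the scaled likelihood `p(y|x) / p(y)`. Returned in log space:
#' `log p(y|x) - log p(y)`, with posteriors floored at 1e-12.
#'
#' @param post T x Q posterior matrix (rows sum to 1).
#' @param priors length-Q strictly positive class priors.
#' @return T x Q matrix of log scaled likelihoods with attribute
#'   `kind = "scaled_likelihood"`.
#' @export
scaledLikelihoods <- function(post, priors) {
  stopifnot(is.matrix(post), ncol(post) == length(priors),
            all(priors > 0))
  em <- log(pmax(post, .EPS)) -
    matrix(log(priors), nrow(post), ncol(post), byrow = TRUE)
  attr(em, "kind") <- "scaled_likelihood"
  em
}

#' Per-slice argmax classification (sliding-window baseline)
#'
#' The static counterpart of the hybrid model: each slice is assigned the
#' class with the highest posterior, independently of its neighbours. Ties
#' go to the lowest class index.
#'
#' @param emitter a fitted [Emitter-class].
#' @param feat T x M binary feature matrix.
#' @return integer label sequence.
#' @export
predictStatic <- function(emitter, feat) {
  max.col(posterior(emitter, feat), ties.method = "first")
}
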