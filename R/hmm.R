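#' Supervised estimation of a Bernoulli-emission HMM
#'
#' With fully labelled slices all parameters have closed-form relative
#' frequency estimators. With pseudocount `alpha`:
#' `pi_i = (#\{y = i\} + alpha) / (T + Q alpha)`; row i of the transition
#' matrix comes from the within-sequence consecutive-pair counts with
#' `alpha` added to each cell; and
#' `mu_in = (#\{y = i, x^n = 1\} + alpha) / (#\{y = i\} + 2 alpha)`.
#' Several recordings (e.g. days) may be passed as lists; transition pairs
#' are then counted within each sequence only, so no transition spans a
#' day boundary.
#'
#' @param feat T x N binary feature matrix, or a list of such matrices.
#' @param labels integer/factor labels of length T, or a list matching
#'   `feat`.
#' @param alpha nonnegative smoothing pseudocount (default 1, Laplace).
#' @param classNames activity names; defaults to factor levels or
#'   `"class1".."classQ"`.
#' @return an [HMMParams-class] object.
#' @examples
#' feat <- matrix(c(1, 1, 0, 0), ncol = 1)
#' estimateSupervised(feat, c(1, 1, 2, 2), alpha = 0,
#'                    classNames = c("A", "B"))
#' @export
estimateSupervised <- function(feat, labels, alpha = 1, classNames = NULL) {
  if (!is.list(feat)) feat <- list(feat)
  if (!is.list(labels)) labels <- list(labels)
  stopifnot(length(feat) == length(labels), alpha >= 0)
  cn <- .resolveClasses(labels, classNames)
  labels <- lapply(labels, .asLabelIndex, classNames = cn)
  q <- length(cn)
  n <- ncol(feat[[1]])
  for (fm in feat) {
    stopifnot(is.matrix(fm), ncol(fm) == n)
    if (!.isBinary(fm)) stop("features must be binary", call. = FALSE)
  }
  nT <- sum(lengths(labels))
  stopifnot(nT == sum(vapply(feat, nrow, integer(1))))

  stateCounts <- tabulate(unlist(labels), nbins = q)
  if (alpha == 0 && any(stateCounts == 0)) {
    stop(sprintf("class(es) never observed with alpha = 0: %s",
                 paste(cn[stateCounts == 0], collapse = ", ")),
         call. = FALSE)
  }
  pi <- (stateCounts + alpha) / (nT + q * alpha)

  pairCounts <- matrix(0, q, q)
  for (y in labels) {
    if (length(y) < 2L) next
    pairCounts <- pairCounts + table(
      factor(y[-length(y)], levels = seq_len(q)),
      factor(y[-1L], levels = seq_len(q))
    )
  }
  pairCounts <- unclass(as.matrix(pairCounts))
  fromCounts <- rowSums(pairCounts)
  if (alpha == 0 && any(fromCounts == 0)) {
    stop(sprintf("no outgoing transitions observed for class(es): %s",
                 paste(cn[fromCounts == 0], collapse = ", ")), call. = FALSE)
  }
  trans <- (pairCounts + alpha) / (fromCounts + q * alpha)

  onCounts <- matrix(0, q, n)
  for (k in seq_along(feat)) {
    for (i in seq_len(q)) {
      rows <- labels[[k]] == i
      if (any(rows)) {
        onCounts[i, ] <- onCounts[i, ] +
          colSums(feat[[k]][rows, , drop = FALSE])
      }
    }
  }
  mu <- (onCounts + alpha) / (stateCounts + 2 * alpha)
  if (alpha == 0) mu[stateCounts == 0, ] <- 0.5  # unreachable (error above)

  fn <- colnames(feat[[1]])
  if (is.null(fn)) fn <- paste0("f", seq_len(n))
  dimnames(trans) <- list(cn, cn)
  dimnames(mu) <- list(cn, fn)
  new("HMMParams", pi = as.numeric(pi), trans = trans, mu = mu,
      classNames = cn, featureNames = fn, alpha = alpha)
}

.resolveClasses <- function(labelsList, classNames) {
  if (!is.null(classNames)) return(as.character(classNames))
  first <- labelsList[[1]]
  if (is.factor(first)) return(levels(first))
  q <- max(unlist(labelsList))
  paste0("class", seq_len(q))
}

.asLabelIndex <- function(labels, classNames) {
  if (is.factor(labels)) {
    idx <- match(as.character(labels), classNames)
    if (anyNA(idx)) stop("labels outside the class set", call. = FALSE)
    return(as.integer(idx))
  }
  labels <- as.integer(labels)
  if (any(labels < 1L | labels > length(classNames))) {
    stop("labels outside the class set", call. = FALSE)
  }
  labels
}

#' Bernoulli log emission scores
#'
#' For each slice t and state i computes
#' `sum_n [ x_t^n log mu_in + (1 - x_t^n) log(1 - mu_in) ]`, the log of the
#' naive-Bayes product of independent Bernoulli densities. `mu` is clamped
#' to `[1e-12, 1 - 1e-12]` before taking logs so contradicting observations
#' yield a large negative score, never `-Inf`.
#'
#' @param params an [HMMParams-class].
#' @param feat T x N binary feature matrix with the training columns.
#' @return T x Q matrix of log scores with attribute `kind = "bernoulli"`.
#' @export
bernoulliLogEmissions <- function(params, feat) {
  stopifnot(is.matrix(feat), ncol(feat) == ncol(params@mu))
  if (!.isBinary(feat)) stop("features must be binary", call. = FALSE)
  mu <- .clamp01(params@mu)
  em <- feat %*% t(log(mu)) + (1 - feat) %*% t(log(1 - mu))
  colnames(em) <- params@classNames
  attr(em, "kind") <- "bernoulli"
  em
}

#' Viterbi decoding
#'
#' Returns the state sequence maximizing
#' `log pi[y1] + em[1, y1] + sum_t ( log trans[y_{t-1}, y_t] + em[t, y_t] )`
#' by dynamic programming in log space. Probabilities in `pi` and `trans`
#' are floored at 1e-12 before logs; ties are broken toward the lowest
#' state index, so decoding is deterministic.
#'
#' @param pi length-Q initial-state probability vector.
#' @param trans Q x Q row-stochastic transition matrix.
#' @param em T x Q matrix of log emission scores (Bernoulli log densities
#'   or log scaled likelihoods).
#' @return integer vector of length T with the decoded state indices.
#' @export
viterbi <- function(pi, trans, em) {
  q <- length(pi)
  stopifnot(ncol(em) == q, all(dim(trans) == c(q, q)))
  nT <- nrow(em)
  logPi <- log(.clamp01(pi))
  logA <- log(.clamp01(trans))
  delta <- logPi + em[1L, ]
  psi <- matrix(0L, nT, q)
  for (t in seq_len(nT)[-1L]) {
    cand <- delta + logA                # [i, j] = delta_i + log a_ij
    best <- apply(cand, 2L, which.max)  # lowest index on ties
    psi[t, ] <- best
    delta <- cand[cbind(best, seq_len(q))] + em[t, ]
  }
  path <- integer(nT)
  path[nT] <- which.max(delta)
  if (nT > 1L) {
    for (t in rev(seq_len(nT - 1L))) path[t] <- psi[t + 1L, path[t + 1L]]
  }
  path
}

#' Complete-data joint log likelihood
#'
#' Evaluates the log of the HMM joint factorization
#' `p(y_1) p(x_1|y_1) prod_t p(y_t|y_{t-1}) p(x_t|y_t)` on a fully labelled
#' sequence, with the same probability flooring as [viterbi()].
#'
#' @param params an [HMMParams-class].
#' @param feat T x N binary feature matrix.
#' @param labels integer labels of length T.
#' @return scalar log likelihood.
#' @export
jointLogLik <- function(params, feat, labels) {
  labels <- .asLabelIndex(labels, params@classNames)
  stopifnot(length(labels) == nrow(feat))
  em <- bernoulliLogEmissions(params, feat)
  ll <- log(.clamp01(params@pi))[labels[1L]] +
    sum(em[cbind(seq_along(labels), labels)])
  if (length(labels) > 1L) {
    ll <- ll + sum(log(.clamp01(
      params@trans
    ))[cbind(labels[-length(labels)], labels[-1L])])
  }
  ll
}

#' Sample a labelled sequence from a Bernoulli HMM
#'
#' Draws states from the Markov chain `(pi, trans)` and observations from
#' the per-state independent Bernoulli emission model; used for parameter
#' recovery checks and simulation-based tests.
#'
#' @param params an [HMMParams-class].
#' @param nT number of slices to draw.
#' @param seed integer RNG seed.
#' @return list with `feat` (T x N binary matrix) and `labels` (integer T).
#' @export
sampleHMM <- function(params, nT, seed = 1L) {
  set.seed(seed)
  q <- length(params@pi)
  n <- ncol(params@mu)
  labels <- integer(nT)
  labels[1L] <- sample.int(q, 1L, prob = params@pi)
  for (t in seq_len(nT)[-1L]) {
    labels[t] <- sample.int(q, 1L, prob = params@trans[labels[t - 1L], ])
  }
  feat <- matrix(rbinom(nT * n, 1L, params@mu[labels, ]), nrow = nT)
  colnames(feat) <- params@featureNames
  list(feat = feat, labels = labels)
}

#' Decode with the pure generative model
#'
#' Viterbi decoding using the Bernoulli emission densities of `params`;
#' the classic fully generative baseline.
#'
#' @param params an [HMMParams-class].
#' @param feat T x N binary feature matrix.
#' @return integer label sequence.
#' @export
predictHMM <- function(params, feat) {
  viterbi(params@pi, params@trans, bernoulliLogEmissions(params, feat))
}

#' Serialize HMM parameters to JSON
#'
#' Writes (and reads back) a JSON document holding `pi`, `trans`, `mu`,
#' class and feature names, and the smoothing pseudocount.
#'
#' @param params an [HMMParams-class].
#' @param path output file.
#' @return `writeHMMParams`: the path, invisibly; `readHMMParams`: the
#'   reconstructed [HMMParams-class].
#' @export
writeHMMParams <- function(params, path) {
  doc <- list(
    pi = params@pi,
    trans = unname(params@trans),
    mu = unname(params@mu),
    class_names = params@classNames,
    feature_names = params@featureNames,
    alpha = params@alpha
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeHMMParams
#' @export
readHMMParams <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  trans <- as.matrix(doc$trans)
  mu <- as.matrix(doc$mu)
  dimnames(trans) <- list(doc$class_names, doc$class_names)
  dimnames(mu) <- list(doc$class_names, doc$feature_names)
  new("HMMParams", pi = doc$pi, trans = trans, mu = mu,
      classNames = doc$class_names, featureNames = doc$feature_names,
      alpha = doc$alpha)
}
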