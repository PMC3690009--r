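# Shared fixtures and independent oracles.

T0 <- as.POSIXct("2012-01-02 00:00:00", tz = "UTC")

# Exhaustive path enumeration: the independent check for Viterbi.
bruteForceViterbi <- function(pi, trans, em) {
  q <- length(pi)
  nT <- nrow(em)
  paths <- as.matrix(expand.grid(rep(list(seq_len(q)), nT)))
  scorePath <- function(p) {
    s <- log(pi[p[1L]]) + em[1L, p[1L]]
    if (nT > 1L) {
      s <- s + sum(log(trans[cbind(p[-nT], p[-1L])]) +
                     em[cbind(2:nT, p[-1L])])
    }
    s
  }
  scores <- apply(paths, 1L, scorePath)
  list(path = paths[which.max(scores), ], score = max(scores),
       scores = scores, paths = paths)
}

randomHMMInstance <- function(qMax = 4L, tMax = 6L) {
  q <- sample(2:qMax, 1L)
  nT <- sample(2:tMax, 1L)
  pi <- runif(q); pi <- pi / sum(pi)
  trans <- matrix(runif(q * q), q); trans <- trans / rowSums(trans)
  em <- matrix(log(runif(nT * q)), nT, q)
  list(pi = pi, trans = trans, em = em, q = q, nT = nT)
}

randomPosteriorMatrix <- function(nT, q) {
  p <- matrix(runif(nT * q), nT, q)
  p / rowSums(p)
}

# Tiny labelled toy: feature column 1 identifies the class perfectly.
separableToy <- function(nPerClass = 50L) {
  feat <- cbind(s1 = rep(c(0, 1), each = nPerClass),
                s2 = rep(c(1, 0), each = nPerClass))
  list(features = feat, labels = rep(1:2, each = nPerClass))
}
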