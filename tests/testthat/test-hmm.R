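test_that("supervised estimation matches hand counts", {
  # single class: degenerate one-state chain, mu = column means
  feat <- cbind(f = c(1, 1, 0))
  p1 <- estimateSupervised(feat, c(1, 1, 1), alpha = 0, classNames = "A")
  expect_equal(p1@pi, 1)
  expect_equal(unname(p1@trans), matrix(1, 1, 1))
  expect_equal(unname(p1@mu), matrix(2 / 3, 1, 1))

  # labels 1,1,2,2 with alpha = 0: pairs 1->1, 1->2, 2->2
  p2 <- estimateSupervised(cbind(f = c(1, 1, 0, 0)), c(1, 1, 2, 2),
                           alpha = 0, classNames = c("A", "B"))
  expect_equal(unname(p2@trans), rbind(c(0.5, 0.5), c(0, 1)))
  expect_equal(p2@pi, c(0.5, 0.5))
  expect_equal(unname(p2@mu), rbind(1, 0))

  # alpha > 0 keeps every parameter strictly inside (0, 1)
  p3 <- estimateSupervised(cbind(f = c(1, 1, 0, 0)), c(1, 1, 2, 2),
                           alpha = 1, classNames = c("A", "B", "C"))
  expect_true(all(p3@pi > 0 & p3@pi < 1))
  expect_true(all(p3@trans > 0 & p3@trans < 1))
  expect_true(all(p3@mu > 0 & p3@mu < 1))
  expect_true(validObject(p3))
})

test_that("an unobserved class with alpha = 0 is an estimation error", {
  expect_error(
    estimateSupervised(cbind(f = c(1, 0)), c(1, 1), alpha = 0,
                       classNames = c("A", "B")),
    "B"
  )
})

test_that("day lists pool counts without transitions across days", {
  featA <- cbind(f = c(1, 1)); featB <- cbind(f = c(0, 0))
  p <- estimateSupervised(list(featA, featB), list(c(1, 1), c(2, 2)),
                          alpha = 0, classNames = c("A", "B"))
  # only within-day pairs 1->1 and 2->2; never 1->2
  expect_equal(unname(p@trans), diag(2))
})

test_that("Bernoulli log emissions match the closed forms", {
  mk <- function(mu) {
    new("HMMParams", pi = rep(1 / nrow(mu), nrow(mu)),
        trans = matrix(1 / nrow(mu), nrow(mu), nrow(mu)), mu = mu,
        classNames = paste0("c", seq_len(nrow(mu))),
        featureNames = paste0("f", seq_len(ncol(mu))), alpha = 0)
  }
  pHalf <- mk(matrix(0.5, 2, 3))
  em <- bernoulliLogEmissions(pHalf, matrix(c(1, 0, 1), 1, 3))
  expect_equal(unname(em[1, ]), rep(3 * log(0.5), 2))

  p1 <- mk(matrix(0.9, 1, 1))
  expect_equal(
    unname(bernoulliLogEmissions(p1, matrix(1, 1, 1))[1, 1]), log(0.9)
  )

  p2 <- mk(matrix(c(0.9, 0.2), 1, 2))
  expect_equal(
    unname(bernoulliLogEmissions(p2, matrix(c(1, 0), 1, 2))[1, 1]),
    log(0.9) + log(0.8)
  )

  # degenerate mu stays finite through flooring
  p3 <- mk(matrix(c(0, 1), 1, 2))
  em3 <- bernoulliLogEmissions(p3, matrix(c(1, 0), 1, 2))
  expect_true(all(is.finite(em3)))
})

test_that("Viterbi handles the degenerate shapes", {
  expect_equal(viterbi(1, matrix(1, 1, 1), matrix(log(0.3), 5, 1)),
               rep(1L, 5))
  # T = 1: argmax of log pi + emission
  em <- matrix(log(c(0.2, 0.7)), 1, 2)
  expect_equal(viterbi(c(0.9, 0.1), diag(2), em), 1L)
  expect_equal(viterbi(c(0.5, 0.5), diag(2), em), 2L)
  # ties break toward the lowest state index
  expect_equal(viterbi(c(0.5, 0.5), matrix(0.5, 2, 2),
                       matrix(log(0.5), 3, 2)),
               rep(1L, 3))
})

test_that("Viterbi equals exhaustive enumeration on random instances", {
  set.seed(20)
  for (rep in 1:60) {
    inst <- randomHMMInstance()
    path <- viterbi(inst$pi, inst$trans, inst$em)
    oracle <- bruteForceViterbi(inst$pi, inst$trans, inst$em)
    scoreOf <- function(p) {
      s <- log(inst$pi[p[1]]) + inst$em[1, p[1]]
      if (inst$nT > 1) {
        s <- s + sum(log(inst$trans[cbind(p[-inst$nT], p[-1])]) +
                       inst$em[cbind(2:inst$nT, p[-1])])
      }
      s
    }
    expect_equal(scoreOf(path), oracle$score, tolerance = 1e-10)
  }
})

test_that("joint log likelihood matches term-by-term arithmetic", {
  p <- new("HMMParams", pi = c(0.6, 0.4),
           trans = rbind(c(0.8, 0.2), c(0.3, 0.7)),
           mu = rbind(c(0.9, 0.1), c(0.2, 0.8)),
           classNames = c("A", "B"), featureNames = c("f1", "f2"),
           alpha = 0)
  # T = 1
  expect_equal(jointLogLik(p, matrix(c(1, 0), 1, 2), 1L),
               log(0.6) + log(0.9) + log(0.9))
  # Q = 1, mu = 0.5, N = 1, T = 3 -> 3 log 0.5 (+ chain terms = 0)
  p1 <- new("HMMParams", pi = 1, trans = matrix(1, 1, 1),
            mu = matrix(0.5, 1, 1), classNames = "A",
            featureNames = "f", alpha = 0)
  expect_equal(jointLogLik(p1, matrix(c(1, 0, 1), 3, 1), c(1L, 1L, 1L)),
               3 * log(0.5))
  # hand-computed 2-step instance
  feat <- rbind(c(1, 0), c(0, 1))
  byHand <- log(0.6) + (log(0.9) + log(0.9)) +
    log(0.2) + (log(0.8) + log(0.8))
  expect_equal(jointLogLik(p, feat, c(1L, 2L)), byHand)
})

test_that("the Viterbi path is joint-likelihood optimal among all paths", {
  set.seed(77)
  q <- 3; n <- 2; nT <- 5
  mu <- matrix(runif(q * n, 0.1, 0.9), q, n)
  trans <- matrix(runif(q * q), q); trans <- trans / rowSums(trans)
  pi <- rep(1 / q, q)
  p <- new("HMMParams", pi = pi, trans = trans, mu = mu,
           classNames = paste0("c", 1:q),
           featureNames = paste0("f", 1:n), alpha = 0)
  feat <- matrix(rbinom(nT * n, 1, 0.5), nT, n)
  best <- viterbi(pi, trans, bernoulliLogEmissions(p, feat))
  paths <- as.matrix(expand.grid(rep(list(1:q), nT)))
  lls <- apply(paths, 1, function(pp) jointLogLik(p, feat, as.integer(pp)))
  expect_equal(jointLogLik(p, feat, best), max(lls), tolerance = 1e-10)
})

test_that("parameters of a simulated chain are recovered", {
  trans <- matrix(0.04, 4, 4); diag(trans) <- 0.88
  set.seed(13)
  mu <- matrix(runif(40, 0.1, 0.9), 4, 10)
  truth <- new("HMMParams", pi = rep(0.25, 4), trans = trans, mu = mu,
               classNames = paste0("c", 1:4),
               featureNames = paste0("f", 1:10), alpha = 0)
  samp <- sampleHMM(truth, 8000, seed = 21)
  est <- estimateSupervised(samp$feat, samp$labels, alpha = 0,
                            classNames = truth@classNames)
  expect_lt(max(abs(est@trans - trans)), 0.05)
  expect_lt(max(abs(est@mu - mu)), 0.05)
})

test_that("HMM parameters survive a JSON round trip", {
  p <- estimateSupervised(cbind(a = c(1, 0, 1, 0), b = c(0, 0, 1, 1)),
                          c(1, 1, 2, 2), alpha = 1,
                          classNames = c("A", "B"))
  path <- withr::local_tempfile(fileext = ".json")
  writeHMMParams(p, path)
  q <- readHMMParams(path)
  expect_equal(p@pi, q@pi)
  expect_equal(p@trans, q@trans)
  expect_equal(p@mu, q@mu)
  expect_identical(p@classNames, q@classNames)
})
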