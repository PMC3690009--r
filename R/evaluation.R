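#' Confusion matrix over a shared class set
#'
#' Rows are true classes, columns inferred classes; the diagonal holds the
#' true positives, row sums the totals of true labels (TT) and column sums
#' the totals of inferred labels (TI).
#'
#' @param yTrue,yPred equal-length label vectors (integer or factor).
#' @param classNames full ordered class set.
#' @return Q x Q integer matrix with `classNames` dimnames.
#' @export
confusionCounts <- function(yTrue, yPred, classNames) {
  if (length(yTrue) != length(yPred)) {
    stop("label sequences differ in length", call. = FALSE)
  }
  yTrue <- .asLabelIndex(yTrue, classNames)
  yPred <- .asLabelIndex(yPred, classNames)
  q <- length(classNames)
  cm <- table(factor(yTrue, levels = seq_len(q)),
              factor(yPred, levels = seq_len(q)))
  cm <- matrix(as.integer(cm), q, q,
               dimnames = list(true = classNames, inferred = classNames))
  cm
}

#' Macro-averaged precision, recall and F-measure
#'
#' Per-class precision `TP_i / TI_i` and recall `TP_i / TT_i` are averaged
#' over all Q classes (macro averaging, so rare activities weigh as much
#' as dominant ones), and the F-measure is the harmonic mean
#' `2 P R / (P + R)` of the two aggregates — not the mean of per-class F
#' values. A class with an empty denominator (never inferred, or never
#' true) contributes 0 to the corresponding average but still counts in Q;
#' this convention matters under heavy class imbalance and is applied
#' consistently throughout the package. `F = 0` when `P + R = 0`.
#'
#' @param cm Q x Q confusion matrix (rows true, columns inferred).
#' @return named numeric vector `c(precision, recall, fmeasure)`.
#' @examples
#' cm <- matrix(c(8, 3, 2, 7), 2)  # rows true, cols inferred
#' macroMetrics(cm)
#' @export
macroMetrics <- function(cm) {
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm), all(cm >= 0))
  tp <- diag(cm)
  ti <- colSums(cm)
  tt <- rowSums(cm)
  prec <- ifelse(ti > 0, tp / ti, 0)
  rec <- ifelse(tt > 0, tp / tt, 0)
  p <- mean(prec)
  r <- mean(rec)
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, fmeasure = f)
}

#' Leave-one-day-out cross-validation
#'
#' For each day, trains on all remaining days and scores the held-out day:
#' the standard protocol for single-home activity recognition, where
#' consecutive slices are strongly dependent and whole days are the
#' exchangeable unit. A class present only in the held-out day is still
#' scored (it contributes zero recall) with a warning.
#'
#' @param days list of days, each `list(features, labels)`.
#' @param fit function taking the list of training days and returning a
#'   fitted model.
#' @param predictFn function `(model, features) -> integer labels`.
#' @param classNames full ordered class set.
#' @return `data.frame` with one row per fold (`day`, `precision`,
#'   `recall`, `fmeasure`) and the per-fold confusion matrices in
#'   `attr(, "confusions")`.
#' @export
leaveOneDayOut <- function(days, fit, predictFn, classNames) {
  stopifnot(length(days) >= 2L)
  ids <- names(days)
  if (is.null(ids)) ids <- as.character(seq_along(days))
  res <- vector("list", length(days))
  confusions <- vector("list", length(days))
  for (d in seq_along(days)) {
    trainDays <- days[-d]
    testDay <- days[[d]]
    trainClasses <- unique(unlist(lapply(
      trainDays, function(x) .asLabelIndex(x$labels, classNames)
    )))
    testClasses <- unique(.asLabelIndex(testDay$labels, classNames))
    onlyTest <- setdiff(testClasses, trainClasses)
    if (length(onlyTest)) {
      warning(sprintf(
        "fold %s: class(es) %s present only in the test day",
        ids[d], paste(classNames[onlyTest], collapse = ", ")
      ), call. = FALSE)
    }
    model <- fit(trainDays)
    pred <- predictFn(model, testDay$features)
    cm <- confusionCounts(testDay$labels, pred, classNames)
    m <- macroMetrics(cm)
    confusions[[d]] <- cm
    res[[d]] <- data.frame(day = ids[d], precision = m["precision"],
                           recall = m["recall"], fmeasure = m["fmeasure"],
                           row.names = NULL)
  }
  out <- do.call(rbind, res)
  attr(out, "confusions") <- confusions
  out
}

#' Summarise fold scores as mean and standard deviation
#'
#' @param scores numeric per-fold scores.
#' @return named vector `c(mean, sd)`.
#' @export
foldSummary <- function(scores) {
  c(mean = mean(scores), sd = sd(scores))
}

#' Paired significance tests between two models' fold scores
#'
#' Runs a two-tailed paired Student t-test and a Wilcoxon signed-ranks
#' test on matched per-fold scores. The signed-rank statistic reported is
#' `W = min(W+, W-)` after dropping zero differences (ranks of the absolute
#' differences, average ranks on ties); the Wilcoxon p-value uses the exact
#' distribution for up to 25 nonzero differences without ties, and the
#' normal approximation otherwise. Degenerate inputs are flagged: all
#' differences zero (`flag = "all_equal"`, p = 1) and zero-variance nonzero
#' differences (`flag = "zero_variance"`, reported as a strong rejection).
#'
#' @param scoresA,scoresB equal-length numeric vectors of per-fold scores.
#' @return list with `t_statistic`, `t_pvalue`, `wilcoxon_statistic`,
#'   `wilcoxon_pvalue`, `flag` (`NA_character_` when none).
#' @export
pairedTests <- function(scoresA, scoresB) {
  stopifnot(length(scoresA) == length(scoresB), length(scoresA) >= 2L)
  d <- scoresA - scoresB
  flag <- NA_character_

  if (all(d == 0)) {
    return(list(t_statistic = 0, t_pvalue = 1,
                wilcoxon_statistic = NA_real_, wilcoxon_pvalue = 1,
                flag = "all_equal"))
  }
  if (sd(d) == 0) {
    tStat <- sign(mean(d)) * Inf
    tP <- 0
    flag <- "zero_variance"
  } else {
    tt <- t.test(scoresA, scoresB, paired = TRUE)
    tStat <- unname(tt$statistic)
    tP <- tt$p.value
  }

  dnz <- d[d != 0]
  rk <- rank(abs(dnz))
  wPlus <- sum(rk[dnz > 0])
  wMinus <- sum(rk[dnz < 0])
  wStat <- min(wPlus, wMinus)
  exact <- length(dnz) <= 25L && !anyDuplicated(abs(dnz))
  wP <- suppressWarnings(
    wilcox.test(dnz, mu = 0, exact = exact)$p.value
  )

  list(t_statistic = tStat, t_pvalue = tP,
       wilcoxon_statistic = wStat, wilcoxon_pvalue = wP, flag = flag)
}
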