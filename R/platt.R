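#' Platt sigmoid calibration
#'
#' Maps raw classifier decision values to probabilities with the
#' two-parameter sigmoid `p(s) = 1 / (1 + exp(-(slope * s - offset)))`,
#' fitted by minimizing the negative log likelihood on (score, indicator)
#' pairs. Following Platt, the binary targets are smoothed to
#' `(N+ + 1) / (N+ + 2)` for positives and `1 / (N- + 2)` for negatives,
#' which regularizes the fit on separable data. A positive `slope` makes
#' the probability increase with the score.
#'
#' This two-parameter form is equivalent, up to reparameterization, to the
#' unit-slope sigmoid `1 / (1 + A exp(-s + B))` sometimes written for SVM
#' output calibration.
#'
#' @param scores numeric decision values for one binary subproblem.
#' @param y logical (or 0/1) indicator of the positive class.
#' @return object of class `PlattParams`: list with `slope` and `offset`.
#' @examples
#' pp <- fitPlatt(c(-1, -1, 1, 1), c(FALSE, FALSE, TRUE, TRUE))
#' plattProb(pp, c(-2, 0, 2))
#' @export
fitPlatt <- function(scores, y) {
  y <- as.logical(y)
  stopifnot(length(scores) == length(y), !anyNA(scores), !anyNA(y))
  nPos <- sum(y)
  nNeg <- sum(!y)
  if (nPos == 0L || nNeg == 0L) {
    stop("Platt calibration needs both positive and negative examples",
         call. = FALSE)
  }
  target <- ifelse(y, (nPos + 1) / (nPos + 2), 1 / (nNeg + 2))
  nll <- function(par) {
    p <- .clamp01(plogis(par[1L] * scores - par[2L]))
    -sum(target * log(p) + (1 - target) * log(1 - p))
  }
  grad <- function(par) {
    p <- plogis(par[1L] * scores - par[2L])
    d <- p - target
    c(sum(d * scores), -sum(d))
  }
  fit <- optim(c(1, 0), nll, grad, method = "BFGS",
               control = list(maxit = 200))
  structure(list(slope = fit$par[1L], offset = fit$par[2L]),
            class = "PlattParams")
}

#' @rdname fitPlatt
#' @param params a `PlattParams` object.
#' @param scores decision values to calibrate.
#' @export
plattProb <- function(params, scores) {
  plogis(params$slope * scores - params$offset)
}

#' @export
print.PlattParams <- function(x, ...) {
  cat(sprintf("PlattParams: slope = %.4g, offset = %.4g\n",
              x$slope, x$offset))
  invisible(x)
}
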