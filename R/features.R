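#' Feature representations of a binary sensor stream
#'
#' Three encodings of the T x N observation matrix, all binary and all of
#' width N, usable standalone or concatenated:
#'
#' * **raw** — the matrix as observed: 1 while the sensor is active.
#' * **change point** — 1 exactly when a sensor changes state (0 to 1 or
#'   1 to 0) relative to the previous slice; the slice before the stream is
#'   taken to be all-zero, so a stream that starts active registers a
#'   change at its first slice.
#' * **last sensor** — 1 for the sensor(s) that changed state most
#'   recently (at or before the current slice), 0 for all others; all-zero
#'   until the first change. When several sensors change in the same most
#'   recent slice they all carry 1, since sub-slice ordering is not
#'   observable at slice granularity.
#'
#' Column names are prefixed `raw:`, `cp:` and `ls:` respectively.
#'
#' @param x a [SliceData-class] or a T x N binary matrix with column names.
#' @return T x N binary matrix.
#' @examples
#' m <- cbind(s1 = c(1, 1, 0), s2 = c(0, 0, 1))
#' changePoints(m)
#' lastSensor(m)
#' @name features
NULL

.featValues <- function(x) {
  if (is(x, "SliceData")) return(x@values)
  stopifnot(is.matrix(x), .isBinary(x))
  if (is.null(colnames(x))) colnames(x) <- paste0("s", seq_len(ncol(x)))
  x
}

#' @rdname features
#' @export
rawFeatures <- function(x) {
  v <- .featValues(x)
  colnames(v) <- paste0("raw:", colnames(v))
  v
}

#' @rdname features
#' @export
changePoints <- function(x) {
  v <- .featValues(x)
  prev <- rbind(0, v[-nrow(v), , drop = FALSE])
  out <- (v != prev) * 1
  colnames(out) <- paste0("cp:", colnames(v))
  out
}

#' @rdname features
#' @export
lastSensor <- function(x) {
  v <- .featValues(x)
  cp <- (v != rbind(0, v[-nrow(v), , drop = FALSE]))
  # per sensor, the most recent slice index with a change (0 = never)
  lastChange <- apply(cp * row(cp), 2L, cummax)
  lastChange <- matrix(lastChange, nrow = nrow(v))
  newest <- do.call(pmax, c(split(lastChange, col(lastChange)), list(0)))
  out <- (lastChange == newest & newest > 0) * 1
  colnames(out) <- paste0("ls:", colnames(v))
  out
}

#' Concatenate feature representations
#'
#' Column-binds feature matrices sharing the same number of slices;
#' combining representations this way expresses all seven standalone and
#' combined configurations (raw, cp, ls, raw+cp, raw+ls, cp+ls, raw+cp+ls).
#'
#' @param ... feature matrices, or a single list of them.
#' @return T x (sum of widths) binary matrix; column names preserved.
#' @export
concatFeatures <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) && !is.matrix(parts[[1]])) {
    parts <- parts[[1]]
  }
  stopifnot(length(parts) >= 1L)
  nT <- vapply(parts, nrow, integer(1))
  if (length(unique(nT)) != 1L) {
    stop("feature matrices disagree on the number of slices", call. = FALSE)
  }
  do.call(cbind, parts)
}

#' Build a named feature configuration
#'
#' Convenience wrapper mapping a representation string such as `"raw"`,
#' `"cp+ls"` or `"raw+cp+ls"` to the corresponding (concatenated) feature
#' matrix.
#'
#' @param x a [SliceData-class] or binary matrix.
#' @param representation string of `+`-separated codes among `raw`, `cp`,
#'   `ls`.
#' @return binary feature matrix.
#' @export
featurize <- function(x, representation = "raw") {
  codes <- strsplit(representation, "+", fixed = TRUE)[[1]]
  fns <- list(raw = rawFeatures, cp = changePoints, ls = lastSensor)
  bad <- setdiff(codes, names(fns))
  if (length(bad)) {
    stop(sprintf("unknown representation code(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  concatFeatures(lapply(codes, function(cc) fns[[cc]](x)))
}
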