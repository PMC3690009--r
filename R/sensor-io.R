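#' Read a binary-sensor event stream
#'
#' Events are timed activations of a binary state-change sensor: the sensor
#' switched on at `start` and off at `end`. The expected dialect is one
#' event per line, `start<TAB>end<TAB>sensor_id` with ISO-8601 timestamps
#' (`YYYY-mm-dd HH:MM:SS`); comma-delimited lines are accepted too, and
#' lines starting with `#` are treated as header/comments.
#'
#' @param source a file path or connection.
#' @return `data.frame` with columns `start`, `end` (`POSIXct`, UTC) and
#'   `sensor_id` (character), sorted by ascending `start`.
#' @examples
#' f <- tempfile()
#' writeLines(c("# start\tend\tsensor",
#'              "2011-11-28 02:27:59\t2011-11-28 10:18:11\tBed"), f)
#' readEvents(f)
#' @export
readEvents <- function(source) {
  .readTimedTable(source, idcol = "sensor_id")
}

#' Read activity annotations
#'
#' Same dialect as [readEvents()] with the third column holding the
#' activity label. Annotation intervals of one recording must not overlap;
#' overlapping intervals raise an error naming the offending lines.
#'
#' @param source a file path or connection.
#' @return `data.frame` with columns `start`, `end` (`POSIXct`, UTC) and
#'   `label` (character), sorted by ascending `start`.
#' @export
readActivities <- function(source) {
  acts <- .readTimedTable(source, idcol = "label")
  .checkNoOverlap(acts)
  acts
}

.readTimedTable <- function(source, idcol) {
  lines <- readLines(source)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    out <- data.frame(
      start = .parseStamp(character()), end = .parseStamp(character()),
      id = character(), stringsAsFactors = FALSE
    )
    names(out)[3L] <- idcol
    return(out)
  }
  parts <- lapply(lines, function(l) {
    f <- if (grepl("\t", l)) strsplit(l, "\t")[[1]] else strsplit(l, ",")[[1]]
    trimws(f)
  })
  nf <- lengths(parts)
  if (any(nf != 3L)) {
    bad <- lineno[nf != 3L]
    stop(sprintf("expected 3 delimited fields on line(s) %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  m <- do.call(rbind, parts)
  start <- .parseStamp(m[, 1L])
  end <- .parseStamp(m[, 2L])
  badStamp <- is.na(start) | is.na(end)
  if (any(badStamp)) {
    stop(sprintf("unparseable ISO-8601 timestamp on line(s) %s",
                 paste(lineno[badStamp], collapse = ", ")), call. = FALSE)
  }
  badOrder <- end < start
  if (any(badOrder)) {
    stop(sprintf("end precedes start on line(s) %s",
                 paste(lineno[badOrder], collapse = ", ")), call. = FALSE)
  }
  if (any(!nzchar(m[, 3L]))) {
    stop(sprintf("empty identifier on line(s) %s",
                 paste(lineno[!nzchar(m[, 3L])], collapse = ", ")),
         call. = FALSE)
  }
  out <- data.frame(start = start, end = end, id = m[, 3L],
                    stringsAsFactors = FALSE)
  names(out)[3L] <- idcol
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.checkNoOverlap <- function(acts) {
  if (nrow(acts) < 2L) return(invisible(acts))
  o <- order(acts$start)
  s <- acts$start[o]; e <- acts$end[o]; lab <- acts$label[o]
  clash <- which(s[-1L] < e[-length(e)])
  if (length(clash)) {
    i <- clash[1L]
    stop(sprintf(
      "overlapping activity intervals: '%s' [%s, %s) and '%s' [%s, %s)",
      lab[i], .formatStamp(s[i]), .formatStamp(e[i]),
      lab[i + 1L], .formatStamp(s[i + 1L]), .formatStamp(e[i + 1L])
    ), call. = FALSE)
  }
  invisible(acts)
}

#' Write event streams and activity annotations
#'
#' Emits the same dialect [readEvents()]/[readActivities()] consume:
#' tab-separated, ISO-8601 timestamps, one `#`-prefixed header line.
#'
#' @param x a `data.frame` as returned by [readEvents()] or
#'   [readActivities()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeEvents <- function(x, path) {
  .writeTimedTable(x, path, idcol = "sensor_id")
}

#' @rdname writeEvents
#' @export
writeActivities <- function(x, path) {
  .writeTimedTable(x, path, idcol = "label")
}

.writeTimedTable <- function(x, path, idcol) {
  stopifnot(all(c("start", "end", idcol) %in% names(x)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# start\tend\t%s", idcol), con)
  if (nrow(x)) {
    writeLines(sprintf("%s\t%s\t%s", .formatStamp(x$start),
                       .formatStamp(x$end), x[[idcol]]), con)
  }
  invisible(path)
}
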