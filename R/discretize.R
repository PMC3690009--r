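#' Construct a SliceData object
#'
#' Low-level constructor used by [discretize()] and the simulator; validates
#' all invariants of the time-slice representation.
#'
#' @param values T x N binary matrix.
#' @param sensorIds N sensor identifiers (column order).
#' @param t0 `POSIXct` start of slice 1.
#' @param dt slice length in seconds.
#' @param labels optional integer vector of per-slice labels in `1..Q`.
#' @param classNames activity names; index 1 is the idle/unlabeled class.
#' @return a [SliceData-class] object.
#' @export
sliceData <- function(values, sensorIds, t0, dt, labels = integer(),
                      classNames = character()) {
  storage.mode(values) <- "double"
  colnames(values) <- sensorIds
  new("SliceData", values = values, sensorIds = as.character(sensorIds),
      t0 = as.POSIXct(t0, tz = "UTC"), dt = as.numeric(dt),
      labels = as.integer(labels), classNames = as.character(classNames))
}

#' Discretize sensor events and annotations into time slices
#'
#' Cuts the span `[t0, t1)` into `T = floor((t1 - t0) / dt)` half-open
#' slices `[t, t + dt)` (a trailing partial slice is dropped). Entry
#' `(t, i)` of the observation matrix is 1 when an event of sensor `i`
#' overlaps slice `t` by at least one second. Each slice is labelled with
#' the activity that overlaps it longest (ties broken by the earlier
#' interval start); slices no activity touches get the idle class,
#' `classNames[1]`.
#'
#' @param events `data.frame` from [readEvents()] (columns `start`, `end`,
#'   `sensor_id`).
#' @param activities `data.frame` from [readActivities()] (columns `start`,
#'   `end`, `label`).
#' @param t0,t1 `POSIXct` span to discretize, `t1 > t0`.
#' @param dt slice length in seconds (default 60).
#' @param sensorIds ordered sensor identifiers defining the columns.
#' @param classNames ordered activity names; index 1 must be the
#'   idle/unlabeled class.
#' @param lenient if `TRUE`, events whose sensor is not in `sensorIds` are
#'   dropped with a warning instead of raising an error.
#' @return a [SliceData-class] with both observations and labels.
#' @examples
#' t0 <- as.POSIXct("2012-01-02 00:00:00", tz = "UTC")
#' ev <- data.frame(start = t0 + 30, end = t0 + 120, sensor_id = "Bed")
#' ac <- data.frame(start = t0, end = t0 + 180, label = "Sleeping")
#' discretize(ev, ac, t0, t0 + 180, dt = 60, sensorIds = "Bed",
#'            classNames = c("Idle", "Sleeping"))
#' @export
discretize <- function(events, activities, t0, t1, dt = 60,
                       sensorIds, classNames, lenient = FALSE) {
  t0 <- as.POSIXct(t0, tz = "UTC")
  t1 <- as.POSIXct(t1, tz = "UTC")
  stopifnot(t1 > t0, dt > 0)
  nT <- floor(as.numeric(difftime(t1, t0, units = "secs")) / dt)
  if (nT < 1L) stop("span shorter than one slice", call. = FALSE)
  n <- length(sensorIds)
  values <- matrix(0, nrow = nT, ncol = n, dimnames = list(NULL, sensorIds))

  if (nrow(events)) {
    sidx <- match(events$sensor_id, sensorIds)
    if (anyNA(sidx)) {
      unknown <- unique(events$sensor_id[is.na(sidx)])
      if (lenient) {
        warning(sprintf("dropping events of unknown sensor(s): %s",
                        paste(unknown, collapse = ", ")), call. = FALSE)
        events <- events[!is.na(sidx), , drop = FALSE]
        sidx <- sidx[!is.na(sidx)]
      } else {
        stop(sprintf("events reference unknown sensor(s): %s",
                     paste(unknown, collapse = ", ")), call. = FALSE)
      }
    }
    sSec <- as.numeric(difftime(events$start, t0, units = "secs"))
    eSec <- as.numeric(difftime(events$end, t0, units = "secs"))
    for (k in seq_along(sidx)) {
      rows <- .overlapSlices(sSec[k], eSec[k], dt, nT, minOverlap = 1)
      if (length(rows)) values[rows, sidx[k]] <- 1
    }
  }

  labels <- rep.int(1L, nT)
  bestOv <- numeric(nT)
  bestStart <- rep.int(Inf, nT)
  if (nrow(activities)) {
    lidx <- match(activities$label, classNames)
    if (anyNA(lidx)) {
      stop(sprintf("annotations reference unknown activity label(s): %s",
                   paste(unique(activities$label[is.na(lidx)]),
                         collapse = ", ")), call. = FALSE)
    }
    sSec <- as.numeric(difftime(activities$start, t0, units = "secs"))
    eSec <- as.numeric(difftime(activities$end, t0, units = "secs"))
    for (k in seq_along(lidx)) {
      ks <- max(0, floor(sSec[k] / dt))
      ke <- min(nT - 1, ceiling(eSec[k] / dt) - 1)
      if (ke < ks) next
      kk <- ks:ke
      ov <- pmin(eSec[k], (kk + 1) * dt) - pmax(sSec[k], kk * dt)
      pos <- ov > 0
      kk <- kk[pos]; ov <- ov[pos]
      if (!length(kk)) next
      rows <- kk + 1L
      take <- ov > bestOv[rows] |
        (ov == bestOv[rows] & sSec[k] < bestStart[rows])
      rows <- rows[take]
      labels[rows] <- lidx[k]
      bestOv[rows] <- ov[take]
      bestStart[rows] <- sSec[k]
    }
  }

  sliceData(values, sensorIds, t0, dt, labels = labels,
            classNames = classNames)
}

# Slice indices (1-based) that [sSec, eSec) overlaps by >= minOverlap secs.
.overlapSlices <- function(sSec, eSec, dt, nT, minOverlap = 1) {
  if (eSec <= 0 || sSec >= nT * dt || eSec <= sSec) return(integer())
  ks <- max(0, floor(sSec / dt))
  ke <- min(nT - 1, ceiling(eSec / dt) - 1)
  if (ke < ks) return(integer())
  kk <- ks:ke
  ov <- pmin(eSec, (kk + 1) * dt) - pmax(sSec, kk * dt)
  kk[ov >= minOverlap] + 1L
}

#' Split a recording into per-day sequences
#'
#' Days run midnight-to-midnight (UTC); each returned element is a
#' [SliceData-class] covering one calendar day. Used so that the HMM treats
#' each day as an independent sequence, matching the leave-one-day-out
#' protocol.
#'
#' @param x a [SliceData-class].
#' @return named list of `SliceData`, one per calendar day present.
#' @export
splitDays <- function(x) {
  nT <- nrow(x@values)
  sliceStart <- as.numeric(x@t0) + (seq_len(nT) - 1) * x@dt
  day <- floor(sliceStart / 86400)
  lapply(split(seq_len(nT), day), function(rows) {
    sliceData(x@values[rows, , drop = FALSE], x@sensorIds,
              as.POSIXct(sliceStart[rows[1L]], origin = "1970-01-01",
                         tz = "UTC"),
              x@dt,
              labels = if (length(x@labels)) x@labels[rows] else integer(),
              classNames = x@classNames)
  })
}

#' Export / import a SliceData object as delimited text
#'
#' Writes `<prefix>.tsv` (the binary matrix plus a `label` column when
#' labels are present) and a JSON sidecar `<prefix>.json` holding
#' `sensor_ids`, `class_names`, `t0` and `dt`, so the representation is
#' fully reconstructable.
#'
#' @param x a [SliceData-class].
#' @param prefix output path prefix (no extension).
#' @return `writeSliceData`: the prefix, invisibly. `readSliceData`: the
#'   reconstructed [SliceData-class].
#' @export
writeSliceData <- function(x, prefix) {
  df <- as.data.frame(x@values)
  if (length(x@labels)) df$label <- x@labels
  write.table(df, paste0(prefix, ".tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  meta <- list(sensor_ids = x@sensorIds, class_names = x@classNames,
               t0 = .formatStamp(x@t0), dt = x@dt)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(prefix)
}

#' @rdname writeSliceData
#' @export
readSliceData <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  df <- read.table(paste0(prefix, ".tsv"), sep = "\t", header = TRUE,
                   check.names = FALSE)
  labels <- integer()
  if ("label" %in% names(df)) {
    labels <- as.integer(df$label)
    df$label <- NULL
  }
  sliceData(as.matrix(df), meta$sensor_ids, .parseStamp(meta$t0), meta$dt,
            labels = labels, classNames = meta$class_names)
}
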