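#' Simulator configuration
#'
#' Describes a synthetic single-resident home: a set of activities with
#' mean dwell times and hour-of-day preference weights, a set of binary
#' sensors, and a per-activity firing probability for every sensor. The
#' generated schedule is a semi-Markov chain — dwell in an activity is
#' geometric (or lognormal) in slices with the configured mean, and the
#' next activity is drawn from the hour-weighted distribution excluding
#' the current one — which reproduces the statistical structure of real
#' recordings: strong temporal persistence, day-structured routines and
#' heavy class imbalance. Sensor readings are per-slice Bernoulli draws
#' given the active activity, optionally corrupted by independent bit
#' flips at `noiseFlipProb` (spurious firings and missed activations).
#'
#' @param nDays number of simulated days.
#' @param dt slice length in seconds; must divide 86400 (default 60).
#' @param activities `data.frame` with columns `name` and
#'   `meanDwellMinutes`; the first row is the idle/unlabeled class.
#' @param pattern activities x 24 matrix of nonnegative hour weights.
#' @param sensors character vector of sensor ids.
#' @param fireProb activities x sensors matrix of per-slice firing
#'   probabilities in `[0, 1]`.
#' @param noiseFlipProb probability of flipping each observation bit.
#' @param dwell `"geometric"` (matches first-order HMM assumptions) or
#'   `"lognormal"` (violates them; useful for robustness studies).
#' @param seed default RNG seed for [sampleHome()].
#' @return list of class `SimConfig`.
#' @seealso [smallHomeConfig()], [sampleHome()]
#' @export
simConfig <- function(nDays, dt = 60, activities, pattern, sensors,
                      fireProb, noiseFlipProb = 0,
                      dwell = c("geometric", "lognormal"), seed = 1L) {
  dwell <- match.arg(dwell)
  stopifnot(nDays >= 1L, dt > 0, 86400 %% dt == 0,
            nrow(activities) >= 2L, length(sensors) >= 1L,
            all(c("name", "meanDwellMinutes") %in% names(activities)),
            all(activities$meanDwellMinutes > 0),
            nrow(pattern) == nrow(activities), ncol(pattern) == 24L,
            all(pattern >= 0),
            all(dim(fireProb) == c(nrow(activities), length(sensors))),
            all(fireProb >= 0 & fireProb <= 1),
            noiseFlipProb >= 0, noiseFlipProb < 1)
  structure(list(nDays = as.integer(nDays), dt = as.numeric(dt),
                 activities = activities, pattern = unname(as.matrix(pattern)),
                 sensors = as.character(sensors),
                 fireProb = unname(as.matrix(fireProb)),
                 noiseFlipProb = noiseFlipProb, dwell = dwell,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

#' Default synthetic home configurations
#'
#' `smallHomeConfig()` is the packaged default: 8 activities (including
#' idle), 12 sensors and 14 days at 60 s slices, with dwell times and
#' hour-of-day routines chosen to echo published single-resident
#' deployments — a dominant sleeping/leisure share, a mid-size leaving
#' share and several sub-2% activities. `replicationConfig()` is the
#' scaled-down variant used by the package's own hybrid-vs-static
#' replication study: 6 days at 300 s slices with sensor noise
#' `noiseFlipProb = 0.05`.
#'
#' @param nDays number of days.
#' @param dt slice length in seconds.
#' @param noiseFlipProb observation bit-flip probability.
#' @param seed default seed.
#' @return a [simConfig()].
#' @export
smallHomeConfig <- function(nDays = 14L, dt = 60, noiseFlipProb = 0.01,
                            seed = 1L) {
  acts <- data.frame(
    name = c("Idle", "Leaving", "Toileting", "Showering", "Sleeping",
             "Breakfast", "Lunch", "SpareTime"),
    meanDwellMinutes = c(30, 240, 10, 15, 420, 20, 30, 120)
  )
  hours <- 0:23
  w <- function(...) {
    v <- rep(0.05, 24)
    args <- list(...)
    for (a in args) v[hours %in% a$h] <- a$w
    v
  }
  pattern <- rbind(
    Idle      = rep(1, 24),
    Leaving   = w(list(h = 9:18, w = 3)),
    Toileting = rep(0.8, 24),
    Showering = w(list(h = 7:9, w = 3)),
    Sleeping  = w(list(h = c(21:23, 0:5), w = 6)),
    Breakfast = w(list(h = 7:9, w = 3)),
    Lunch     = w(list(h = 13:15, w = 3)),
    SpareTime = w(list(h = 17:23, w = 4), list(h = 9:16, w = 1))
  )
  sensors <- c("Bed", "BedroomPIR", "BathroomDoor", "ToiletFlush", "Shower",
               "Basin", "FrontDoor", "KitchenPIR", "Fridge", "Cupboard",
               "Microwave", "LivingPIR")
  fp <- matrix(0.01, nrow(acts), length(sensors),
               dimnames = list(acts$name, sensors))
  fp["Idle", ] <- c(0.01, 0.05, 0.02, 0.01, 0.01, 0.02,
                    0.01, 0.05, 0.01, 0.01, 0.01, 0.10)
  fp["Leaving", ] <- 0.005
  fp["Leaving", "FrontDoor"] <- 0.02
  fp["Toileting", c("BathroomDoor", "ToiletFlush", "Basin",
                    "BedroomPIR")] <- c(0.5, 0.3, 0.3, 0.2)
  fp["Showering", c("Shower", "BathroomDoor", "Basin")] <- c(0.8, 0.3, 0.2)
  fp["Sleeping", ] <- 0.005
  fp["Sleeping", c("Bed", "BedroomPIR")] <- c(0.9, 0.1)
  fp["Breakfast", c("KitchenPIR", "Fridge", "Cupboard",
                    "Microwave")] <- c(0.8, 0.3, 0.3, 0.1)
  fp["Lunch", c("KitchenPIR", "Fridge", "Cupboard",
                "Microwave")] <- c(0.8, 0.4, 0.3, 0.3)
  fp["SpareTime", c("LivingPIR", "KitchenPIR")] <- c(0.8, 0.1)
  simConfig(nDays = nDays, dt = dt, activities = acts, pattern = pattern,
            sensors = sensors, fireProb = fp,
            noiseFlipProb = noiseFlipProb, seed = seed)
}

#' @rdname smallHomeConfig
#' @export
replicationConfig <- function(nDays = 6L, dt = 300, noiseFlipProb = 0.05,
                              seed = 1L) {
  smallHomeConfig(nDays = nDays, dt = dt, noiseFlipProb = noiseFlipProb,
                  seed = seed)
}

#' Simulate a single-resident smart home
#'
#' Draws an activity schedule, per-slice sensor firings and noise, then
#' assembles the three synchronized views of the recording: the raw event
#' stream (contiguous firing slices merged into one activation per sensor),
#' the activity annotation intervals (idle gaps left unannotated), and the
#' ground-truth [SliceData-class]. Draw order is fixed — schedule first
#' (alternating dwell and next-activity draws), then the firing matrix,
#' then the noise mask — so output is fully determined by the seed.
#' `discretize()` applied to the generated events and annotations
#' reproduces `truth` exactly.
#'
#' @param config a [simConfig()].
#' @param seed integer seed; defaults to `config$seed`.
#' @param t0 start timestamp of the recording (midnight).
#' @return list of class `SimOutput` with elements `events`, `activities`,
#'   `truth`, `config`, `seed`.
#' @export
sampleHome <- function(config, seed = config$seed,
                       t0 = as.POSIXct("2012-01-02 00:00:00", tz = "UTC")) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(seed)
  dt <- config$dt
  perDay <- 86400 %/% dt
  nT <- config$nDays * perDay
  q <- nrow(config$activities)
  meanSlices <- pmax(config$activities$meanDwellMinutes * 60 / dt, 1)
  classNames <- config$activities$name

  labels <- integer(nT)
  t <- 1L
  cur <- sample.int(q, 1L, prob = config$pattern[, 1L])
  while (t <= nT) {
    run <- if (config$dwell == "geometric") {
      1L + rgeom(1L, 1 / meanSlices[cur])
    } else {
      max(1L, round(rlnorm(1L, log(meanSlices[cur]) - 0.125, 0.5)))
    }
    run <- min(run, nT - t + 1L)
    labels[t:(t + run - 1L)] <- cur
    t <- t + run
    if (t > nT) break
    hour <- floor(((t - 1L) %% perDay) * dt / 3600) + 1L
    wts <- config$pattern[, hour]
    wts[cur] <- 0
    if (sum(wts) == 0) wts[-cur] <- 1
    cur <- sample.int(q, 1L, prob = wts)
  }

  n <- length(config$sensors)
  fires <- matrix(runif(nT * n) < config$fireProb[labels, ], nT, n)
  if (config$noiseFlipProb > 0) {
    flips <- matrix(runif(nT * n) < config$noiseFlipProb, nT, n)
    fires <- xor(fires, flips)
  }
  values <- fires * 1

  events <- .runsToIntervals(values, t0, dt, config$sensors,
                             idcol = "sensor_id")
  labelRuns <- rle(labels)
  ends <- cumsum(labelRuns$lengths)
  starts <- ends - labelRuns$lengths + 1L
  keep <- labelRuns$values != 1L  # idle time left unannotated
  activities <- data.frame(
    start = t0 + (starts[keep] - 1L) * dt,
    end = t0 + ends[keep] * dt,
    label = classNames[labelRuns$values[keep]],
    stringsAsFactors = FALSE
  )

  truth <- sliceData(values, config$sensors, t0, dt, labels = labels,
                     classNames = classNames)
  structure(list(events = events, activities = activities, truth = truth,
                 config = config, seed = as.integer(seed)),
            class = "SimOutput")
}

.runsToIntervals <- function(values, t0, dt, ids, idcol) {
  out <- list()
  for (j in seq_len(ncol(values))) {
    r <- rle(values[, j])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    on <- r$values == 1
    if (!any(on)) next
    out[[length(out) + 1L]] <- data.frame(
      start = t0 + (starts[on] - 1L) * dt,
      end = t0 + ends[on] * dt,
      id = ids[j], stringsAsFactors = FALSE
    )
  }
  if (!length(out)) {
    res <- data.frame(start = t0[0], end = t0[0], id = character())
  } else {
    res <- do.call(rbind, out)
    res <- res[order(res$start, res$id), , drop = FALSE]
    rownames(res) <- NULL
  }
  names(res)[3L] <- idcol
  res
}

#' @export
print.SimOutput <- function(x, ...) {
  cat(sprintf(
    "SimOutput: %d days at dt = %gs (%d slices), %d events, seed %d\n",
    x$config$nDays, x$config$dt, nrow(x$truth@values), nrow(x$events),
    x$seed
  ))
  invisible(x)
}

#' Write a simulated recording as a text fixture
#'
#' Emits `events.tsv` and `activities.tsv` in the package's delimited
#' dialect plus a `sidecar.json` with everything needed to re-discretize
#' (sensor ids, class names, t0, dt, slice count) and to regenerate the
#' simulation (seed, day count, noise level). `loadFixture()` reads the
#' three files back and re-discretizes.
#'
#' @param dir output directory (created if missing).
#' @param sim a `SimOutput` from [sampleHome()].
#' @return `writeFixture`: the directory, invisibly; `loadFixture`: a
#'   [SliceData-class].
#' @export
writeFixture <- function(dir, sim) {
  stopifnot(inherits(sim, "SimOutput"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeEvents(sim$events, file.path(dir, "events.tsv"))
  writeActivities(sim$activities, file.path(dir, "activities.tsv"))
  truth <- sim$truth
  meta <- list(
    synthetic = TRUE,
    sensor_ids = truth@sensorIds,
    class_names = truth@classNames,
    t0 = .formatStamp(truth@t0),
    dt = truth@dt,
    n_slices = nrow(truth@values),
    n_days = sim$config$nDays,
    noise_flip_prob = sim$config$noiseFlipProb,
    seed = sim$seed
  )
  jsonlite::write_json(meta, file.path(dir, "sidecar.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname writeFixture
#' @export
loadFixture <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "sidecar.json"),
                              simplifyVector = TRUE)
  events <- readEvents(file.path(dir, "events.tsv"))
  activities <- readActivities(file.path(dir, "activities.tsv"))
  t0 <- .parseStamp(meta$t0)
  discretize(events, activities, t0, t0 + meta$n_slices * meta$dt,
             dt = meta$dt, sensorIds = meta$sensor_ids,
             classNames = meta$class_names)
}
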