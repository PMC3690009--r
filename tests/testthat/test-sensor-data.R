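test_that("event files parse, sort and round-trip", {
  f <- withr::local_tempfile()
  writeLines(character(), f)
  expect_equal(nrow(readEvents(f)), 0L)

  writeLines("2011-11-28 02:27:59, 2011-11-28 10:18:11, Bed", f)
  ev <- readEvents(f)
  expect_equal(ev$sensor_id, "Bed")
  expect_equal(ev$start, as.POSIXct("2011-11-28 02:27:59", tz = "UTC"))
  expect_equal(ev$end, as.POSIXct("2011-11-28 10:18:11", tz = "UTC"))

  # out-of-order lines come back sorted ascending by start
  writeLines(c("# start\tend\tsensor_id",
               "2011-11-28 10:00:00\t2011-11-28 11:00:00\tDoor",
               "2011-11-28 02:00:00\t2011-11-28 03:00:00\tBed"), f)
  ev <- readEvents(f)
  expect_equal(ev$sensor_id, c("Bed", "Door"))

  out <- withr::local_tempfile()
  writeEvents(ev, out)
  expect_identical(readEvents(out), ev)
})

test_that("malformed event lines are reported with line numbers", {
  f <- withr::local_tempfile()
  writeLines(c("# header",
               "2011-11-28 02:00:00\t2011-11-28 03:00:00\tBed",
               "not-a-date\t2011-11-28 03:00:00\tBed"), f)
  expect_error(readEvents(f), "line\\(s\\) 3")

  writeLines("2011-11-28 05:00:00\t2011-11-28 03:00:00\tBed", f)
  expect_error(readEvents(f), "end precedes start")
})

test_that("overlapping activity intervals are rejected, naming both", {
  f <- withr::local_tempfile()
  writeLines(c("2011-11-28 02:00:00\t2011-11-28 04:00:00\tSleeping",
               "2011-11-28 03:30:00\t2011-11-28 05:00:00\tToileting"), f)
  expect_error(readActivities(f), "Sleeping.*Toileting")
})

test_that("discretize reproduces the slice-count arithmetic", {
  empty <- data.frame(start = T0[0], end = T0[0], sensor_id = character())
  emptyAct <- data.frame(start = T0[0], end = T0[0], label = character())
  x <- discretize(empty, emptyAct, T0, T0 + 12 * 86400, dt = 60,
                  sensorIds = "s", classNames = "Idle")
  expect_equal(nrow(obsMatrix(x)), 17280L)
  expect_true(all(obsMatrix(x) == 0))
  expect_true(all(sliceLabels(x) == 1L))

  # trailing partial slice is dropped
  y <- discretize(empty, emptyAct, T0, T0 + 150, dt = 60,
                  sensorIds = "s", classNames = "Idle")
  expect_equal(nrow(obsMatrix(y)), 2L)
})

test_that("events mark every slice they overlap by at least a second", {
  ev <- data.frame(start = T0 + 30, end = T0 + 120, sensor_id = "Bed")
  act <- data.frame(start = T0[0], end = T0[0], label = character())
  x <- discretize(ev, act, T0, T0 + 180, dt = 60,
                  sensorIds = c("Bed", "Door"), classNames = "Idle")
  expect_equal(unname(obsMatrix(x)[, "Bed"]), c(1, 1, 0))
  expect_equal(unname(obsMatrix(x)[, "Door"]), c(0, 0, 0))

  # sub-second residue does not count: [0, 60) event stops at slice 1
  ev2 <- data.frame(start = T0, end = T0 + 60, sensor_id = "Bed")
  x2 <- discretize(ev2, act, T0, T0 + 180, dt = 60,
                   sensorIds = "Bed", classNames = "Idle")
  expect_equal(unname(obsMatrix(x2)[, 1]), c(1, 0, 0))
})

test_that("slice labels follow majority overlap with earlier-start ties", {
  act <- data.frame(
    start = c(T0, T0 + 80),
    end = c(T0 + 80, T0 + 180),
    label = c("Sleeping", "Toileting")
  )
  ev <- data.frame(start = T0[0], end = T0[0], sensor_id = character())
  x <- discretize(ev, act, T0, T0 + 240, dt = 60, sensorIds = "s",
                  classNames = c("Idle", "Sleeping", "Toileting"))
  # slice 2 ([60,120)): Sleeping 20 s vs Toileting 40 s -> Toileting
  expect_equal(sliceLabels(x), c(2L, 3L, 3L, 1L))

  # exact tie: both overlap slice by 30 s -> earlier interval start wins
  act2 <- data.frame(start = c(T0, T0 + 30), end = c(T0 + 30, T0 + 60),
                     label = c("Sleeping", "Toileting"))
  x2 <- discretize(ev, act2, T0, T0 + 60, dt = 60, sensorIds = "s",
                   classNames = c("Idle", "Sleeping", "Toileting"))
  expect_equal(sliceLabels(x2), 2L)
})

test_that("unknown sensors error, or drop with a warning when lenient", {
  ev <- data.frame(start = T0, end = T0 + 90, sensor_id = "Ghost")
  act <- data.frame(start = T0[0], end = T0[0], label = character())
  expect_error(
    discretize(ev, act, T0, T0 + 120, 60, "Bed", "Idle"),
    "Ghost"
  )
  expect_warning(
    x <- discretize(ev, act, T0, T0 + 120, 60, "Bed", "Idle",
                    lenient = TRUE),
    "Ghost"
  )
  expect_true(all(obsMatrix(x) == 0))
})

test_that("adding an event is monotone: zeros can only become ones", {
  set.seed(11)
  act <- data.frame(start = T0[0], end = T0[0], label = character())
  base <- data.frame(
    start = T0 + sort(sample(0:500, 5)),
    end = T0 + sort(sample(0:500, 5)) + sample(30:200, 5),
    sensor_id = sample(c("a", "b"), 5, replace = TRUE)
  )
  before <- obsMatrix(discretize(base, act, T0, T0 + 720, 60,
                                 c("a", "b"), "Idle"))
  extra <- rbind(base, data.frame(start = T0 + 333, end = T0 + 400,
                                  sensor_id = "b"))
  after <- obsMatrix(discretize(extra, act, T0, T0 + 720, 60,
                                c("a", "b"), "Idle"))
  expect_true(all(after >= before))
})

test_that("SliceData text export round-trips bit-exactly", {
  cfg <- smallHomeConfig(nDays = 1)
  sim <- sampleHome(cfg, seed = 4)
  prefix <- file.path(withr::local_tempdir(), "day")
  writeSliceData(sim$truth, prefix)
  back <- readSliceData(prefix)
  expect_identical(obsMatrix(back), obsMatrix(sim$truth))
  expect_identical(sliceLabels(back), sliceLabels(sim$truth))
  expect_identical(classNames(back), classNames(sim$truth))
  expect_equal(startTime(back), startTime(sim$truth))
})
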