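test_that("simulation is deterministic given config and seed", {
  cfg <- replicationConfig(nDays = 2)
  a <- sampleHome(cfg, seed = 42)
  b <- sampleHome(cfg, seed = 42)
  expect_identical(a$events, b$events)
  expect_identical(a$activities, b$activities)
  expect_identical(obsMatrix(a$truth), obsMatrix(b$truth))
  expect_identical(sliceLabels(a$truth), sliceLabels(b$truth))
  c <- sampleHome(cfg, seed = 43)
  expect_false(identical(obsMatrix(a$truth), obsMatrix(c$truth)))
})

test_that("12 simulated days at 60 s slices give 17280 rows", {
  cfg <- smallHomeConfig(nDays = 12)
  sim <- sampleHome(cfg, seed = 1)
  expect_equal(nrow(obsMatrix(sim$truth)), 17280L)
})

test_that("discretizing the generated streams reproduces the truth", {
  cfg <- smallHomeConfig(nDays = 2, noiseFlipProb = 0.02)
  sim <- sampleHome(cfg, seed = 7)
  nT <- nrow(obsMatrix(sim$truth))
  redis <- discretize(sim$events, sim$activities, startTime(sim$truth),
                      startTime(sim$truth) + nT * cfg$dt, cfg$dt,
                      cfg$sensors, classNames(sim$truth))
  expect_identical(obsMatrix(redis), obsMatrix(sim$truth))
  expect_identical(sliceLabels(redis), sliceLabels(sim$truth))
})

test_that("deterministic firing makes truth a function of the schedule", {
  cfg0 <- smallHomeConfig(nDays = 1, noiseFlipProb = 0)
  fp <- (cfg0$fireProb > 0.4) * 1  # push rates to {0, 1}
  cfg <- simConfig(nDays = 1, dt = cfg0$dt, activities = cfg0$activities,
                   pattern = cfg0$pattern, sensors = cfg0$sensors,
                   fireProb = fp, noiseFlipProb = 0)
  sim <- sampleHome(cfg, seed = 3)
  expect_identical(unname(obsMatrix(sim$truth)),
                   unname(fp[sliceLabels(sim$truth), ]))
})

test_that("empirical firing rates converge to the configured ones", {
  cfg <- smallHomeConfig(nDays = 60, noiseFlipProb = 0)
  sim <- sampleHome(cfg, seed = 15)
  labs <- sliceLabels(sim$truth)
  v <- obsMatrix(sim$truth)
  counts <- tabulate(labs, nbins = nrow(cfg$fireProb))
  # rates are estimable only for activities with enough dwell time
  for (i in which(counts >= 2000)) {
    emp <- colMeans(v[labs == i, , drop = FALSE])
    expect_lt(max(abs(emp - cfg$fireProb[i, ])), 0.02)
  }
  expect_gte(sum(counts >= 2000), 3)
})

test_that("the configured routine produces realistic class imbalance", {
  sim <- sampleHome(smallHomeConfig(nDays = 14), seed = 6)
  shares <- tabulate(sliceLabels(sim$truth), nbins = 8) /
    length(sliceLabels(sim$truth))
  expect_gt(max(shares), 0.3)   # a dominant class (sleeping/leisure)
  expect_lt(min(shares), 0.02)  # and several rare activities
})

test_that("fixtures round-trip through the text formats", {
  dir <- withr::local_tempdir()
  cfg <- replicationConfig(nDays = 2)
  sim <- sampleHome(cfg, seed = 9)
  writeFixture(dir, sim)
  expect_true(all(file.exists(file.path(
    dir, c("events.tsv", "activities.tsv", "sidecar.json")
  ))))
  back <- loadFixture(dir)
  expect_identical(obsMatrix(back), obsMatrix(sim$truth))
  expect_identical(sliceLabels(back), sliceLabels(sim$truth))
  # regenerability: the sidecar's seed reproduces the same simulation
  meta <- jsonlite::read_json(file.path(dir, "sidecar.json"),
                              simplifyVector = TRUE)
  again <- sampleHome(replicationConfig(nDays = meta$n_days), seed = meta$seed)
  expect_identical(obsMatrix(again$truth), obsMatrix(sim$truth))
})

test_that("an all-quiet simulation writes a valid empty events file", {
  cfg0 <- smallHomeConfig(nDays = 1, noiseFlipProb = 0)
  cfg <- simConfig(nDays = 1, dt = 60, activities = cfg0$activities,
                   pattern = cfg0$pattern, sensors = cfg0$sensors,
                   fireProb = matrix(0, nrow(cfg0$activities),
                                     length(cfg0$sensors)),
                   noiseFlipProb = 0)
  sim <- sampleHome(cfg, seed = 2)
  expect_equal(nrow(sim$events), 0L)
  dir <- withr::local_tempdir()
  writeFixture(dir, sim)
  expect_equal(nrow(readEvents(file.path(dir, "events.tsv"))), 0L)
})

test_that("a supervised HMM learned from one home beats the prior-only rule", {
  cfg <- replicationConfig(nDays = 4)
  sim <- sampleHome(cfg, seed = 23)
  days <- splitDays(sim$truth)
  cn <- classNames(sim$truth)
  trainFeat <- lapply(days[1:3], obsMatrix)
  trainLab <- lapply(days[1:3], sliceLabels)
  params <- estimateSupervised(trainFeat, trainLab, alpha = 1,
                               classNames = cn)
  test <- days[[4]]
  decoded <- predictHMM(params, obsMatrix(test))
  majority <- rep(which.max(tabulate(unlist(trainLab), length(cn))),
                  nrow(obsMatrix(test)))
  fHMM <- macroMetrics(confusionCounts(sliceLabels(test), decoded, cn))
  fPrior <- macroMetrics(confusionCounts(sliceLabels(test), majority, cn))
  expect_gt(fHMM["fmeasure"], fPrior["fmeasure"])
})
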