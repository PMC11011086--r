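test_that("scenario construction validates its fields", {
  expect_error(scenario(duration = 1.1, fps = 3), "integer frame count")
  d <- dogSpec(schedule = data.frame(state = "ASLEEP", duration = 30))
  expect_error(scenario(duration = 60, dogs = list(d)), "schedule")
  expect_error(scenario(dogs = list(d, d, d), duration = 30), "at most 2")
  big <- dogSpec(size = 80, start = c(10, 10),
                 schedule = data.frame(state = "ASLEEP", duration = 60))
  expect_error(scenario(width = 64, height = 64, duration = 60,
                        dogs = list(big)), "exceeds the arena")
  expect_error(dogSpec(twitchProb = 1.5), "twitchProb")
})

test_that("rendering is deterministic given the seed", {
  sc <- smallNightScenario(seed = 9, duration = 6)
  r1 <- renderScenario(sc)
  r2 <- renderScenario(sc)
  expect_identical(r1$stream@frames, r2$stream@frames)
  expect_identical(r1$truth@detections, r2$truth@detections)
  sc2 <- smallNightScenario(seed = 10, duration = 6)
  expect_false(identical(renderScenario(sc2)$stream@frames,
                         r1$stream@frames))
})

test_that("an all-asleep dog without twitches is pixel-static", {
  sc <- scenario(width = 80, height = 60, fps = 5, duration = 4, seed = 2,
                 dogs = list(dogSpec(size = 24, start = c(40, 30),
                   schedule = data.frame(state = "ASLEEP", duration = 4))))
  r <- renderScenario(sc)
  f <- r$stream@frames
  for (t in 2:length(f)) expect_identical(f[[t]], f[[1]])
})

test_that("adding a nuisance does not change dog trajectories", {
  mkSc <- function(nu) scenario(width = 100, height = 80, fps = 5,
    duration = 8, seed = 4,
    dogs = list(dogSpec(size = 24, start = c(50, 40),
      schedule = data.frame(state = "AWAKE", duration = 8))),
    nuisance = nu)
  clean <- renderScenario(mkSc(nuisanceSpec()))
  noisy <- renderScenario(mkSc(nuisanceSpec(sensorNoiseSd = 3,
                                            flickerAmplitude = 5)))
  # boxes (hence positions) identical; only pixel values differ
  expect_identical(clean$truth@detections[, c("x_min", "y_min")],
                   noisy$truth@detections[, c("x_min", "y_min")])
  expect_false(identical(clean$stream@frames, noisy$stream@frames))
})

test_that("ground truth matches the schedule and its own summary", {
  sc <- scenario(width = 100, height = 80, fps = 5, duration = 40, seed = 6,
    dogs = list(dogSpec(size = 26, start = c(50, 40),
      schedule = data.frame(state = c("AWAKE", "ASLEEP", "AWAKE"),
                            duration = c(10, 20, 10)))))
  r <- renderScenario(sc)
  truth <- r$truth
  sm <- truth@summaries[["1"]]
  expect_equal(boutCount(sm), 1)
  expect_equal(totalSleep(sm), 20)
  b <- extractBouts(truth@states[["1"]])
  expect_equal(c(b$start, b$end), c(10, 30))
  # stored summary equals summarize() of the stored sequence
  expect_equal(totalSleep(summarizeSleep(truth@states[["1"]])),
               totalSleep(sm))
  # boxes lie inside the arena and enclose a plausible body
  d <- truth@detections
  expect_true(all(d$x_min >= 0 & d$x_max <= 100 &
                  d$y_min >= 0 & d$y_max <= 80))
  expect_true(all((d$x_max - d$x_min) * (d$y_max - d$y_min) > 100))
})

test_that("day-colour frames carry three channels and night frames one", {
  scN <- smallNightScenario(duration = 2)
  expect_true(is.matrix(renderScenario(scN)$stream@frames[[1]]))
  scD <- scenarioFromYaml(system.file("extdata", "scenario_two_dogs_day.yaml",
                                      package = "dogsleep"))
  scD@duration <- 2
  scD@dogs <- lapply(scD@dogs, function(d) {
    d@schedule <- data.frame(state = "ASLEEP", duration = 2); d
  })
  fr <- renderScenario(scD)$stream@frames[[1]]
  expect_equal(dim(fr)[3], 3)
  expect_equal(getFrame(renderScenario(scD)$stream, 0)@mode, "DAY_COLOUR")
})

test_that("a rendered bundle on disk is internally consistent", {
  sc <- smallNightScenario(duration = 4)
  dir <- withr::local_tempdir()
  r <- renderScenario(sc, dir = dir)
  expect_length(list.files(dir, pattern = "frame_.*png"), 20)
  # disk frames equal in-memory frames
  s <- openFrameSource(dir, fpsOverride = 5)
  expect_identical(getFrame(s, 7)@pixels, r$stream@frames[[8]])
  # truth annotation log round-trips to the truth summary
  seqs <- readObservationLog(file.path(dir, "truth_annotations.csv"),
                             sessionDuration = 4, fps = 5)
  expect_equal(totalSleep(summarizeSleep(seqs[["1"]])),
               totalSleep(r$truth@summaries[["1"]]))
  js <- jsonlite::read_json(file.path(dir, "truth_summary.json"))
  expect_equal(js[["1"]]$bout_count, boutCount(r$truth@summaries[["1"]]))
  det <- readDetections(file.path(dir, "truth_detections.csv"))
  expect_equal(det, r$truth@detections)
})

test_that("scenario YAML parsing surfaces bad fields", {
  p <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("width: 100", "height: 80", "fps: 5", "duration: 10",
               "dogs:", "  - size: 24"), p)
  expect_error(scenarioFromYaml(p), "schedule")
  sc <- scenarioFromYaml(system.file("extdata", "scenario_kennel_night.yaml",
                                     package = "dogsleep"))
  expect_equal(sc@duration, 300)
  expect_equal(length(sc@dogs), 1)
  expect_equal(scenarioFromYaml(system.file(
    "extdata", "scenario_kennel_night.yaml", package = "dogsleep"),
    seed = 99)@seed, 99L)
})

test_that("observer error model is identity at zero error and deletes all at lapse 1", {
  set.seed(51)
  truth <- stateSequence(
    c(rep("AWAKE", 10), rep("ASLEEP", 20), rep("AWAKE", 5),
      rep("ASLEEP", 10), rep("AWAKE", 5)), fps = 1)
  same <- observerErrorModel(truth, lapseProb = 0, boundaryJitterSd = 0)
  expect_identical(states(same), states(truth))
  gone <- observerErrorModel(truth, lapseProb = 1, boundaryJitterSd = 0)
  expect_true(all(states(gone) == "AWAKE"))
  # deterministic given seed, different across seeds
  j1 <- observerErrorModel(truth, 0, 2, seed = 5)
  j2 <- observerErrorModel(truth, 0, 2, seed = 5)
  j3 <- observerErrorModel(truth, 0, 2, seed = 6)
  expect_identical(states(j1), states(j2))
  expect_false(identical(states(j1), states(j3)))
  # jitter shifts totals by the summed seeded draws
  b <- extractBouts(truth)
  set.seed(5 %% 1000000)
  exp_sleep <- 0
  for (k in seq_len(nrow(b))) {
    s <- b$start[k] + rnorm(1, 0, 2)
    e <- b$end[k] + rnorm(1, 0, 2)
    runif(1)  # lapse draw
    f0 <- max(0, ceiling(s * 1 - 1e-6))
    f1 <- min(49, ceiling(e * 1 - 1e-6) - 1)
    exp_sleep <- exp_sleep + max(0, f1 - f0 + 1)
  }
  expect_equal(totalSleep(summarizeSleep(j1)), exp_sleep)
  # zero lapse preserves bout count while jittered bouts stay separated
  expect_equal(boutCount(summarizeSleep(j1)), nrow(b))
})

test_that("camera shake raises the false-awake rate on sleeping frames", {
  rate <- function(sd) {
    sc <- scenario(width = 120, height = 100, fps = 5, duration = 60,
      seed = 11,
      dogs = list(dogSpec(size = 30, start = c(60, 50),
        schedule = data.frame(state = c("AWAKE", "ASLEEP"),
                              duration = c(10, 50)))),
      nuisance = nuisanceSpec(shakeSd = sd))
    r <- renderScenario(sc)
    res <- analyzeSession(r$stream,
                          groundTruthDetector(r$truth@detections,
                                              nframes(r$stream)))
    est <- mergeSingleDogStates(res$states, 5, 60)
    tr <- states(r$truth@states[["1"]])
    # ignore the decision-window lag after sleep onset
    idx <- which(tr == "ASLEEP")
    idx <- idx[idx > 50 + 15]
    mean(states(est)[idx] == "AWAKE")
  }
  r0 <- rate(0); r2 <- rate(2); r4 <- rate(4)
  expect_lte(r0, r2)
  expect_lte(r2, r4 + 1e-9)
  expect_gt(r4, r0)
})
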