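meas <- function(frames, moved) {
  data.frame(frame_index = frames, subject_id = 1L,
             area = ifelse(is.na(moved), NA_integer_, 100L), moved = moved)
}

test_that("no movement means asleep; constant movement means awake", {
  p <- stateParams(window = 5, maxAwakeFramesInWindow = 0)
  s1 <- classifyStates(meas(0:49, rep(FALSE, 50)), p, fps = 5)
  expect_true(all(states(s1) == "ASLEEP"))
  s2 <- classifyStates(meas(0:49, rep(TRUE, 50)), p, fps = 5)
  expect_true(all(states(s2) == "AWAKE"))
  empty <- data.frame(frame_index = integer(), subject_id = integer(),
                      area = integer(), moved = logical())
  expect_error(classifyStates(empty, p, fps = 5, duration = 10), "empty")
})

test_that("a movement burst wakes the trailing window and early frames inherit", {
  moved <- rep(FALSE, 100); moved[41:50] <- TRUE  # frames 40-49, 0-based
  p <- stateParams(window = 10, maxAwakeFramesInWindow = 0)
  s <- classifyStates(meas(0:99, moved), p, fps = 10)
  st <- states(s)
  expect_true(all(st[41:59] == "AWAKE"))   # frames 40-58
  expect_true(all(st[-(41:59)] == "ASLEEP"))
})

test_that("undetected frames are UNKNOWN and never interpolated", {
  p <- stateParams(window = 3)
  m <- meas(c(0:9, 20:29), rep(FALSE, 20))
  s <- classifyStates(m, p, fps = 1, duration = 30)
  st <- states(s)
  expect_true(all(st[11:20] == "UNKNOWN"))
  expect_true(all(st[c(1:10, 21:30)] == "ASLEEP"))
  # a frame whose own motion is unmeasured (NA) still receives a state
  m2 <- meas(0:9, c(NA, rep(TRUE, 9)))
  st2 <- states(classifyStates(m2, stateParams(window = 2), fps = 1))
  expect_false(any(st2 == "UNKNOWN"))
})

test_that("classification is deterministic and order-independent", {
  set.seed(11)
  m <- meas(0:59, sample(c(TRUE, FALSE), 60, TRUE))
  p <- stateParams(window = 7, maxAwakeFramesInWindow = 1)
  a <- classifyStates(m, p, fps = 5)
  b <- classifyStates(m[sample(nrow(m)), ], p, fps = 5)
  expect_identical(states(a), states(b))
})

test_that("bouts are maximal sleep runs; UNKNOWN breaks them; boundaries count", {
  s <- stateSequence(c("AWAKE", "ASLEEP", "AWAKE", "ASLEEP", "ASLEEP",
                       "AWAKE"), fps = 1)
  b <- extractBouts(s)
  expect_equal(nrow(b), 2)
  expect_equal(b$duration, c(1, 2))
  expect_equal(b$start, c(1, 3))
  expect_equal(nrow(extractBouts(stateSequence(rep("AWAKE", 5), 1))), 0)
  # boundary runs count by default, not under strict W-S-W
  sws <- stateSequence(c("ASLEEP", "AWAKE", "ASLEEP"), fps = 1)
  expect_equal(nrow(extractBouts(sws)), 2)
  expect_equal(nrow(extractBouts(sws, strictWSW = TRUE)), 0)
  mid <- stateSequence(c("AWAKE", "ASLEEP", "AWAKE", "ASLEEP"), fps = 1)
  expect_equal(nrow(extractBouts(mid, strictWSW = TRUE)), 1)
  # UNKNOWN splits a run unless bridged
  u <- stateSequence(c("ASLEEP", "ASLEEP", "UNKNOWN", "ASLEEP"), fps = 1)
  expect_equal(nrow(extractBouts(u)), 2)
  expect_equal(nrow(extractBouts(u, bridgeUnknownMaxS = 1)), 1)
  expect_equal(nrow(extractBouts(u, bridgeUnknownMaxS = 0.5)), 2)
})

test_that("bout durations always sum to total sleep, at any fps", {
  set.seed(12)
  for (i in 1:50) {
    s <- randomStateSequence()
    b <- extractBouts(s)
    expect_equal(sum(b$duration), totalSleep(summarizeSleep(s)))
  }
})

test_that("bout count is invariant under fps rescaling of one pattern", {
  set.seed(13)
  pattern <- sample(c("ASLEEP", "AWAKE", "UNKNOWN"), 40, TRUE)
  counts <- vapply(c(1, 2, 5, 10), function(f) {
    expanded <- rep(pattern, each = f)
    nrow(extractBouts(stateSequence(expanded, fps = f)))
  }, numeric(1))
  expect_true(all(counts == counts[1]))
})

test_that("summaries account for every frame and render H:MM:SS", {
  s <- stateSequence(c(rep("ASLEEP", 6), rep("AWAKE", 4)), fps = 1)
  sm <- summarizeSleep(s)
  expect_equal(percentAsleep(sm), 60)
  expect_equal(totalSleep(sm) + sm@totalAwakeS + sm@totalUnknownS,
               sessionDuration(sm))
  expect_equal(formatHMS(43556), "12:05:56")
  expect_equal(parseHMS("12:05:56"), 43556)
  expect_equal(formatHMS(43556.9), "12:05:56")  # truncation, not rounding
  allU <- summarizeSleep(stateSequence(rep("UNKNOWN", 10), fps = 2))
  expect_true(is.na(percentAsleep(allU)))
  expect_equal(totalSleep(allU), 0)
})

test_that("percentOfTime follows the sleep fraction of known time", {
  s <- summarizeSleep(stateSequence(
    c(rep("ASLEEP", 6), rep("AWAKE", 6)), fps = 1))
  expect_equal(percentOfTime(s), 50)
  z <- summarizeSleep(stateSequence(rep("AWAKE", 5), fps = 1))
  expect_equal(percentOfTime(z), 0)
  expect_equal(round(100 * 43556 / (43556 + 21244), 2), 67.22)
  u <- summarizeSleep(stateSequence(rep("UNKNOWN", 5), fps = 1))
  expect_error(percentOfTime(u), "no known time")
})
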