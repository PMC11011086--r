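test_that("frame agreement counts jointly known matching frames", {
  a <- stateSequence(rep(c("ASLEEP", "AWAKE"), 10), fps = 1)
  expect_equal(frameAgreement(a, a), 100)
  b <- stateSequence(rep(c("AWAKE", "ASLEEP"), 10), fps = 1)
  expect_equal(frameAgreement(a, b), 0)
  expect_equal(frameAgreement(a, b), frameAgreement(b, a))
  # UNKNOWN frames are excluded from the denominator
  c1 <- stateSequence(c("ASLEEP", "UNKNOWN", "AWAKE", "AWAKE"), fps = 1)
  c2 <- stateSequence(c("ASLEEP", "AWAKE", "UNKNOWN", "ASLEEP"), fps = 1)
  expect_equal(frameAgreement(c1, c2), 50)
  allU <- stateSequence(rep("UNKNOWN", 4), fps = 1)
  expect_error(frameAgreement(allU, c1), "no jointly known")
  expect_error(frameAgreement(a, c1), "length")
})

test_that("a 5340/6000 split scores 89 percent", {
  truth <- stateSequence(rep("ASLEEP", 6000), fps = 5)
  est <- stateSequence(c(rep("ASLEEP", 5340), rep("AWAKE", 660)), fps = 5)
  expect_equal(frameAgreement(est, truth), 89)
})

test_that("paired t-test follows the textbook formula", {
  r <- pairedTTest(c(1, 2, 3), c(0, 0, 0))
  expect_equal(r@statistic, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(r@df, 2)
  expect_error(pairedTTest(c(1, 2), c(0, 0, 0)), "equal length")
  expect_error(pairedTTest(c(1), c(0)), "n >= 2")
  err <- tryCatch(pairedTTest(c(1, 2, 3), c(0, 1, 2)), error = identity)
  expect_s3_class(err, "dogsleepDegenerate")
})

test_that("paired t-test matches the brute-force oracle to 1e-9", {
  set.seed(31)
  for (i in 1:40) {
    n <- sample(3:25, 1)
    x <- rnorm(n, sd = runif(1, 0.5, 20))
    y <- x + rnorm(n, mean = runif(1, -2, 2))
    got <- pairedTTest(x, y)
    want <- oraclePairedT(x, y)
    expect_equal(got@statistic, want$t, tolerance = 1e-9)
    expect_equal(got@p, want$p, tolerance = 1e-9)
    # antisymmetry
    rev <- pairedTTest(y, x)
    expect_equal(rev@statistic, -got@statistic, tolerance = 1e-12)
    expect_equal(rev@p, got@p, tolerance = 1e-12)
    # cross-check against the reference implementation
    ref <- t.test(x, y, paired = TRUE)
    expect_equal(got@statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(got@p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("Anderson-Darling statistic matches nortest and behaves at the tails", {
  skip_if_not_installed("nortest")
  set.seed(32)
  for (i in 1:20) {
    x <- rnorm(sample(8:60, 1), sd = runif(1, 0.5, 5))
    got <- andersonDarlingNormality(x)
    n <- length(x)
    want <- unname(nortest::ad.test(x)$statistic) *
      (1 + 0.75 / n + 2.25 / n^2)
    expect_equal(got@statistic, want, tolerance = 1e-10)
  }
  # evenly spaced values look normal enough; a gross outlier does not
  even <- andersonDarlingNormality(1:11)
  expect_lt(even@statistic, 0.752)
  expect_false(even@significant)
  set.seed(33)
  heavy <- c(rnorm(50), 40)
  expect_true(andersonDarlingNormality(heavy)@significant)
  expect_error(andersonDarlingNormality(rep(3, 10)), class = "dogsleepDegenerate")
  expect_error(andersonDarlingNormality(rnorm(4)), "n >= 5")
})

test_that("column summaries report mean, sample sd and extremes", {
  expect_equal(columnSummary(c(1, 2, 3)),
               c(mean = 2, sd = 1, min = 1, max = 3))
  one <- columnSummary(7)
  expect_equal(unname(one[c("mean", "min", "max")]), c(7, 7, 7))
  expect_true(is.na(one[["sd"]]))
  expect_error(columnSummary(numeric()), "empty")
})

test_that("the validation-table fixture reproduces the published analysis", {
  ps <- readTable1Fixture()
  rep <- comparisonReport(ps)
  tdur <- rep@tests$duration
  expect_equal(tdur@statistic, 2.805, tolerance = 5e-4)
  expect_equal(tdur@df, 10)
  expect_true(tdur@significant)
  expect_equal(round(tdur@p, 3), 0.019)
  # percent-of-time and bout-count tests are not significant
  expect_false(rep@tests$percent@significant)
  expect_false(rep@tests$bouts@significant)
  # bout column summaries
  expect_equal(unname(rep@summaries$bouts_system[c("mean", "sd")]), c(15, 5))
  expect_equal(unname(rep@summaries$bouts_manual[c("mean", "sd")]),
               c(16.27, 3.5), tolerance = 1e-2)
  # printed percent-difference column
  expect_equal(rep@summaries$pctdiff_sleep[["mean"]], 0.88, tolerance = 1e-9)
  expect_equal(rep@summaries$pctdiff_sleep[["max"]], 2.68)
})

test_that("identical sessions yield a degenerate 'identical' report", {
  mk <- function(sleep) summarizeSleep(stateSequence(
    c(rep("ASLEEP", sleep), rep("AWAKE", 10 - sleep)), fps = 1))
  sys <- list(a = mk(4), b = mk(6), c = mk(8))
  res <- compareSessions(sys, sys)
  expect_identical(res$report@tests$duration, "identical")
  expect_identical(res$report@tests$bouts, "identical")
})

test_that("a two-session report matches hand-computed numbers", {
  mk <- function(sleepS, awakeS, id) new("SleepSummary",
    subjectId = id, totalSleepS = sleepS, totalAwakeS = awakeS,
    totalUnknownS = 0, observedS = sleepS + awakeS, boutCount = 3L,
    percentAsleep = 100 * sleepS / (sleepS + awakeS))
  ps <- pairedSessions(c("s1", "s2"),
                       list(mk(100, 100, "d"), mk(150, 50, "d")),
                       list(mk(90, 110, "d"), mk(120, 80, "d")))
  rep <- comparisonReport(ps)
  # d = (10, 30): t = 20 / (sqrt(200)/sqrt(2)) = 2
  expect_equal(rep@tests$duration@statistic, 2, tolerance = 1e-12)
  expect_equal(rep@tests$duration@df, 1)
  expect_equal(rep@summaries$sleep_system_s[["mean"]], 125)
  expect_identical(rep@tests$bouts, "identical")
})

test_that("comparison reports serialize to CSV and JSON", {
  ps <- readTable1Fixture()
  rep <- comparisonReport(ps)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  writeComparisonReport(rep, csv = csv, json = js)
  back <- utils::read.csv(csv)
  expect_equal(nrow(back), 11)
  expect_equal(back$sleep_system[1], "12:05:56")
  j <- jsonlite::read_json(js)
  expect_equal(j$tests$duration$df, 10)
  expect_true(j$tests$duration$significant)
})

test_that("unmatched sessions are excluded and reported", {
  mk <- function(n) summarizeSleep(stateSequence(
    sample(c("ASLEEP", "AWAKE"), 20, TRUE), fps = 1))
  set.seed(40)
  sys <- list(a = mk(), b = mk(), c = mk())
  man <- list(b = mk(), c = mk(), d = mk())
  res <- compareSessions(sys, man)
  expect_setequal(res$excluded, c("a", "d"))
  expect_equal(nrow(res$report@sessions), 2)
  expect_error(compareSessions(list(a = mk()), list(b = mk())),
               "zero overlapping")
})
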