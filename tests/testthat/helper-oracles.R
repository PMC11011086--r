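`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force oracles: straight-line per-pixel loops and
# direct formula evaluation, deliberately sharing no code with the
# package implementations they check.

oracleGauss <- function(k) {
  s <- 0.3 * ((k - 1) / 2 - 1) + 0.8
  c0 <- (k - 1) / 2
  w <- exp(-((0:(k - 1)) - c0)^2 / (2 * s^2))
  w / sum(w)
}

oracleReflect <- function(i, n) {
  j <- (i - 1) %% (2 * n)
  if (j < n) j + 1 else 2 * n - j
}

oracleBlur <- function(img, k) {
  if (k == 1) return(img)
  w <- oracleGauss(k)
  r <- (k - 1) / 2
  n <- nrow(img); p <- ncol(img)
  tmp <- matrix(0, n, p); out <- matrix(0, n, p)
  for (i in 1:n) for (j in 1:p) {
    acc <- 0
    for (d in -r:r) acc <- acc + w[d + r + 1] * img[oracleReflect(i + d, n), j]
    tmp[i, j] <- acc
  }
  for (i in 1:n) for (j in 1:p) {
    acc <- 0
    for (d in -r:r) acc <- acc + w[d + r + 1] * tmp[i, oracleReflect(j + d, p)]
    out[i, j] <- acc
  }
  round(out)
}

oracleDilate <- function(b, k, iters) {
  r <- (k - 1) / 2
  n <- nrow(b); p <- ncol(b)
  out <- (b > 0) + 0
  if (iters == 0 || r == 0) return(out)
  for (it in 1:iters) {
    nb <- matrix(0, n, p)
    for (i in 1:n) for (j in 1:p) {
      v <- 0
      for (di in -r:r) for (dj in -r:r) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= n && jj >= 1 && jj <= p && out[ii, jj] > 0)
          v <- 1
      }
      nb[i, j] <- v
    }
    out <- nb
  }
  out
}

oracleComponents <- function(b) {
  n <- nrow(b); p <- ncol(b)
  seen <- matrix(FALSE, n, p)
  areas <- integer()
  for (i in 1:n) for (j in 1:p) {
    if (b[i, j] > 0 && !seen[i, j]) {
      stack <- list(c(i, j)); seen[i, j] <- TRUE; a <- 0
      while (length(stack)) {
        q <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        a <- a + 1
        for (di in -1:1) for (dj in -1:1) {
          ii <- q[1] + di; jj <- q[2] + dj
          if (ii >= 1 && ii <= n && jj >= 1 && jj <= p &&
              b[ii, jj] > 0 && !seen[ii, jj]) {
            seen[ii, jj] <- TRUE
            stack[[length(stack) + 1]] <- c(ii, jj)
          }
        }
      }
      areas <- c(areas, a)
    }
  }
  sort(as.integer(areas), decreasing = TRUE)
}

# Qualifying movement area via the six steps, all by brute force.
oracleMotionArea <- function(prev, cur, mp) {
  b1 <- oracleBlur(prev, mp@blurKernel)
  b2 <- oracleBlur(cur, mp@blurKernel)
  delta <- abs(b2 - b1)
  bin <- (delta > mp@deltaThreshold) + 0
  dil <- oracleDilate(bin, mp@dilateKernel, mp@dilateIterations)
  ar <- oracleComponents(dil)
  sum(ar[ar >= mp@minComponentArea])
}

randomMotionParams <- function() {
  motionParams(blurKernel = sample(c(1, 3, 5, 7), 1),
               deltaThreshold = sample(5:60, 1),
               dilateKernel = sample(c(1, 3, 5), 1),
               dilateIterations = sample(0:2, 1),
               minComponentArea = sample(1:30, 1),
               minMotionFraction = runif(1, 0, 0.02))
}

randomCropPair <- function(n = 32) {
  a <- matrix(sample(0:255, n * n, TRUE), n, n)
  b <- pmin(pmax(a + matrix(sample(-40:40, n * n, TRUE), n, n), 0), 255)
  list(a = a, b = b)
}

# Two-sided paired-t p-value by explicit formula plus numerical
# integration of the t density (no pt/pbeta).
oraclePairedT <- function(x, y) {
  d <- x - y
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  df <- n - 1
  dens <- function(u) {
    exp(lgamma((df + 1) / 2) - lgamma(df / 2)) / sqrt(df * pi) *
      (1 + u^2 / df)^(-(df + 1) / 2)
  }
  p <- 2 * stats::integrate(dens, abs(t), Inf, rel.tol = 1e-12)$value
  list(t = t, df = df, p = p)
}

randomStateSequence <- function(n = NULL, fps = NULL,
                                withUnknown = TRUE) {
  if (is.null(n)) n <- sample(5:120, 1)
  if (is.null(fps)) fps <- sample(c(1, 2, 5, 10), 1)
  pool <- if (withUnknown) c("ASLEEP", "AWAKE", "UNKNOWN")
          else c("ASLEEP", "AWAKE")
  stateSequence(sample(pool, n, TRUE), fps,
                subjectId = paste0("dog-", sample(9, 1)))
}

# A small noiseless night scenario used by several tests.  The default
# schedule scales with the requested duration (wake / sleep / wake in a
# 1:4:1 split).
smallNightScenario <- function(seed = 3, duration = 60,
                               schedule = data.frame(
                                 state = c("AWAKE", "ASLEEP", "AWAKE"),
                                 duration = duration * c(1, 4, 1) / 6)) {
  scenario(width = 120, height = 100, fps = 5, duration = duration,
           seed = seed,
           dogs = list(dogSpec(size = 30, start = c(60, 50),
                               schedule = schedule)))
}

# Merge per-track state sequences of a single-dog session into one
# per-frame sequence (tracking may re-label a track under heavy shake).
mergeSingleDogStates <- function(states, fps, duration) {
  n <- round(duration * fps)
  out <- rep("UNKNOWN", n)
  for (s in states) {
    known <- states(s) != "UNKNOWN"
    out[known] <- states(s)[known]
  }
  stateSequence(out, fps, "merged", duration)
}
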