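#' Construct a synthetic dog
#'
#' @param size body length in pixels.
#' @param start centre `(x, y)` at frame 0.
#' @param schedule data frame (`state`, `duration` seconds) whose
#'   durations sum to the scenario duration.
#' @param awakeMotionSd,awakeMinStep awake step distribution (pixels).
#' @param territory per-axis confinement radius around the start position
#'   (pixels; `Inf` = whole arena).
#' @param twitchProb,twitchAmplitude sleep twitches: per-frame
#'   probability and pixel sd of the transient offset.
#' @param bodyIntensity,textureSd,jitterSd appearance: mean intensity,
#'   frozen texture sd, and per-awake-frame limb-jitter sd.
#' @return a [DogSpec-class].
#' @export
dogSpec <- function(size = 40, start = c(60, 60),
                    schedule = data.frame(state = "ASLEEP", duration = 60),
                    territory = Inf,
                    awakeMotionSd = 2, awakeMinStep = 2,
                    twitchProb = 0, twitchAmplitude = 2,
                    bodyIntensity = 200, textureSd = 15, jitterSd = 20) {
  new("DogSpec", size = as.numeric(size), start = as.numeric(start),
      schedule = data.frame(state = as.character(schedule$state),
                            duration = as.numeric(schedule$duration)),
      territory = as.numeric(territory),
      awakeMotionSd = as.numeric(awakeMotionSd),
      awakeMinStep = as.numeric(awakeMinStep),
      twitchProb = as.numeric(twitchProb),
      twitchAmplitude = as.numeric(twitchAmplitude),
      bodyIntensity = as.numeric(bodyIntensity),
      textureSd = as.numeric(textureSd), jitterSd = as.numeric(jitterSd))
}

#' Construct a nuisance specification
#'
#' @param shakeSd camera shake, pixels/frame.
#' @param flickerAmplitude,flickerPeriod light flicker, intensity units
#'   and seconds.
#' @param sensorNoiseSd per-pixel Gaussian noise, intensity units.
#' @return a [NuisanceSpec-class].
#' @export
nuisanceSpec <- function(shakeSd = 0, flickerAmplitude = 0,
                         flickerPeriod = 30, sensorNoiseSd = 0) {
  new("NuisanceSpec", shakeSd = as.numeric(shakeSd),
      flickerAmplitude = as.numeric(flickerAmplitude),
      flickerPeriod = as.numeric(flickerPeriod),
      sensorNoiseSd = as.numeric(sensorNoiseSd))
}

#' Construct a scenario
#'
#' @param width,height arena size in pixels.
#' @param fps frames per second.
#' @param duration seconds; `duration * fps` must be an integer.
#' @param seed integer; rendering is bit-reproducible given it.
#' @param dogs list of [DogSpec-class] (0--2 dogs).
#' @param mode `"NIGHT_GRAY"` or `"DAY_COLOUR"`.
#' @param nuisance a [NuisanceSpec-class].
#' @return a [Scenario-class].
#' @export
scenario <- function(width = 160, height = 120, fps = 5, duration = 60,
                     seed = 1, dogs = list(), mode = "NIGHT_GRAY",
                     nuisance = nuisanceSpec()) {
  new("Scenario", width = as.integer(width), height = as.integer(height),
      fps = as.numeric(fps), duration = as.numeric(duration),
      seed = as.integer(seed), dogs = dogs, mode = mode,
      nuisance = nuisance)
}

#' Read a scenario from YAML
#'
#' Keys: `width`, `height`, `fps`, `duration`, `seed`, `mode`,
#' `nuisance` (`shake_sd`, `flicker_amplitude`, `flicker_period`,
#' `sensor_noise_sd`) and `dogs`, a list whose entries carry `size`,
#' `start`, `awake_motion_sd`, `awake_min_step`, `twitch_prob`,
#' `twitch_amplitude`, `body_intensity`, and a `schedule` list of
#' `{state, duration}` entries.  Missing keys fall back to the
#' constructors' defaults.  Invalid content raises an error naming the
#' offending field.
#'
#' @param path YAML file.
#' @param seed optional seed overriding the file's.
#' @return a [Scenario-class].
#' @export
scenarioFromYaml <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  pick <- function(l, key, default) if (is.null(l[[key]])) default else l[[key]]
  nu <- y$nuisance
  dogs <- lapply(seq_along(y$dogs), function(i) {
    d <- y$dogs[[i]]
    if (is.null(d$schedule))
      stop(sprintf("dog %d: missing field 'schedule'", i))
    sched <- data.frame(
      state = vapply(d$schedule, function(e) as.character(
        pick(e, "state", stop(sprintf("dog %d: schedule entry lacks 'state'", i)))),
        character(1)),
      duration = vapply(d$schedule, function(e) as.numeric(
        pick(e, "duration", stop(sprintf("dog %d: schedule entry lacks 'duration'", i)))),
        numeric(1)))
    dogSpec(size = pick(d, "size", 40),
            start = unlist(pick(d, "start", c(60, 60))),
            schedule = sched,
            territory = pick(d, "territory", Inf),
            awakeMotionSd = pick(d, "awake_motion_sd", 2),
            awakeMinStep = pick(d, "awake_min_step", 2),
            twitchProb = pick(d, "twitch_prob", 0),
            twitchAmplitude = pick(d, "twitch_amplitude", 2),
            bodyIntensity = pick(d, "body_intensity", 200),
            textureSd = pick(d, "texture_sd", 15),
            jitterSd = pick(d, "jitter_sd", 20))
  })
  scenario(width = pick(y, "width", 160), height = pick(y, "height", 120),
           fps = pick(y, "fps", 5), duration = pick(y, "duration", 60),
           seed = if (is.null(seed)) pick(y, "seed", 1) else seed,
           dogs = dogs, mode = pick(y, "mode", "NIGHT_GRAY"),
           nuisance = nuisanceSpec(
             shakeSd = pick(nu, "shake_sd", 0),
             flickerAmplitude = pick(nu, "flicker_amplitude", 0),
             flickerPeriod = pick(nu, "flicker_period", 30),
             sensorNoiseSd = pick(nu, "sensor_noise_sd", 0)))
}

# Per-frame schedule states for one dog.
.scheduleStates <- function(schedule, fps, n) {
  cum <- cumsum(schedule$duration)
  times <- (seq_len(n) - 1L) / fps
  idx <- findInterval(times + 1e-9, c(0, cum[-length(cum)]))
  schedule$state[idx]
}

# Elliptical body mask as (row, col) offsets around the centre.
.bodyMask <- function(size) {
  a <- size / 2; b <- size / 3
  dj <- seq(-ceiling(a), ceiling(a))
  di <- seq(-ceiling(b), ceiling(b))
  grid <- expand.grid(di = di, dj = dj)
  keep <- (grid$dj / a)^2 + (grid$di / b)^2 <= 1
  grid[keep, , drop = FALSE]
}

.clampIdx <- function(i, n) pmin(pmax(i, 1L), n)

#' Render a synthetic scenario
#'
#' Draws each dog as a textured ellipse on a textured static background.
#' Awake frames displace the dog by a zero-mean symmetric step per axis
#' and perturb its texture (limb jitter); asleep frames are pixel-static
#' apart from optional transient twitches.  Nuisances (global camera
#' shake, light flicker, per-pixel sensor noise) are applied after
#' compositing.  Rendering is deterministic given the scenario seed, with
#' one substream per dog and per nuisance, so switching a nuisance on
#' does not change dog trajectories.  Realism is explicitly not the goal:
#' the generator reproduces the statistical structure behavioural sleep
#' scoring assumes -- perceivable movement if and only if awake.
#'
#' @param sc a [Scenario-class].
#' @param dir optional output directory; when given, frames are written
#'   as `frame_%06d.png` together with `truth_detections.csv` (detection
#'   schema), `truth_annotations.csv` (observation-log dialect) and
#'   `truth_summary.json`.
#' @return list with elements `stream` (a [MemoryFrameStream-class]) and
#'   `truth` (a [GroundTruth-class], whose boxes tightly enclose each dog
#'   every frame).
#' @export
renderScenario <- function(sc, dir = NULL) {
  validObject(sc)
  n <- as.integer(round(sc@duration * sc@fps))
  w <- sc@width; h <- sc@height
  base <- as.integer(sc@seed %% 1000000L)
  seedSave <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(seedSave))
    assign(".Random.seed", seedSave, globalenv()), add = TRUE)

  night <- sc@mode == "NIGHT_GRAY"
  bgLevel <- 30
  set.seed(base * 7L + 11L)
  bg <- pmin(pmax(round(bgLevel + matrix(stats::rnorm(h * w, 0, 6), h, w)),
                  0), 255)

  ndog <- length(sc@dogs)
  dogData <- vector("list", ndog)
  for (i in seq_len(ndog)) {
    d <- sc@dogs[[i]]
    mask <- .bodyMask(d@size)
    npix <- nrow(mask)
    st <- .scheduleStates(d@schedule, sc@fps, n)
    set.seed(base * 7L + 100L + i)
    texture <- pmin(pmax(round(d@bodyIntensity +
                               stats::rnorm(npix, 0, d@textureSd)), 0), 255)
    rx <- stats::rnorm(n); ry <- stats::rnorm(n)
    dx <- sign(rx) * (d@awakeMinStep + d@awakeMotionSd * abs(rx))
    dy <- sign(ry) * (d@awakeMinStep + d@awakeMotionSd * abs(ry))
    tu <- stats::runif(n)
    tox <- stats::rnorm(n, 0, d@twitchAmplitude)
    toy <- stats::rnorm(n, 0, d@twitchAmplitude)
    jitter <- matrix(stats::rnorm(npix * n, 0, d@jitterSd), npix, n)

    a <- ceiling(d@size / 2) + 1; b <- ceiling(d@size / 3) + 1
    clampX <- function(x) min(max(x, a, d@start[1] - d@territory),
                              w - 1 - a, d@start[1] + d@territory)
    clampY <- function(y) min(max(y, b, d@start[2] - d@territory),
                              h - 1 - b, d@start[2] + d@territory)
    pos <- matrix(0, 2, n)
    pos[, 1] <- c(clampX(d@start[1]), clampY(d@start[2]))
    for (t in seq_len(n)[-1]) {
      if (st[t] == "AWAKE")
        pos[, t] <- c(clampX(pos[1, t - 1] + dx[t]),
                      clampY(pos[2, t - 1] + dy[t]))
      else pos[, t] <- pos[, t - 1]
    }
    twitching <- st == "ASLEEP" & tu < d@twitchProb
    dogData[[i]] <- list(spec = d, mask = mask, texture = texture,
                         states = st, pos = pos, twitching = twitching,
                         tox = tox, toy = toy, jitter = jitter)
  }

  nu <- sc@nuisance
  set.seed(base * 7L + 999L)
  shake <- matrix(round(stats::rnorm(2L * n, 0, nu@shakeSd)), 2, n)
  flicker <- if (nu@flickerAmplitude > 0)
    nu@flickerAmplitude *
      sin(2 * pi * (seq_len(n) - 1L) / (sc@fps * nu@flickerPeriod))
  else numeric(n)

  chans <- if (night) 1L else 3L
  chanScale <- c(1.0, 0.85, 0.6)     # warm dog coat on a cool background
  bgScale <- c(0.9, 1.0, 1.1)

  frames <- vector("list", n)
  det <- vector("list", n)
  for (t in seq_len(n)) {
    layers <- lapply(seq_len(chans), function(ch)
      if (night) bg else pmin(pmax(round(bg * bgScale[ch]), 0), 255))
    rows <- NULL
    for (i in seq_len(ndog)) {
      dd <- dogData[[i]]
      cx <- round(dd$pos[1, t] + if (dd$twitching[t]) dd$tox[t] else 0)
      cy <- round(dd$pos[2, t] + if (dd$twitching[t]) dd$toy[t] else 0)
      rr <- .clampIdx(cy + dd$mask$di + 1L, h)
      cc <- .clampIdx(cx + dd$mask$dj + 1L, w)
      vals <- dd$texture
      if (dd$states[t] == "AWAKE") vals <- vals + dd$jitter[, t]
      for (ch in seq_len(chans)) {
        v <- pmin(pmax(round(vals * if (night) 1 else chanScale[ch]), 0), 255)
        layers[[ch]][cbind(rr, cc)] <- v
      }
      box <- clipBox(c(cx + min(dd$mask$dj) + shake[1, t],
                       cy + min(dd$mask$di) + shake[2, t],
                       cx + max(dd$mask$dj) + 1L + shake[1, t],
                       cy + max(dd$mask$di) + 1L + shake[2, t]), w, h)
      rows <- rbind(rows, data.frame(
        frame_index = t - 1L, subject_id = i,
        x_min = box[[1]], y_min = box[[2]],
        x_max = box[[3]], y_max = box[[4]], confidence = 1))
    }
    if (shake[1, t] != 0L || shake[2, t] != 0L) {
      sr <- .clampIdx(seq_len(h) - shake[2, t], h)
      sco <- .clampIdx(seq_len(w) - shake[1, t], w)
      layers <- lapply(layers, function(m) m[sr, sco, drop = FALSE])
    }
    if (flicker[t] != 0)
      layers <- lapply(layers, function(m) m + flicker[t])
    if (nu@sensorNoiseSd > 0)
      layers <- lapply(layers, function(m)
        m + matrix(stats::rnorm(h * w, 0, nu@sensorNoiseSd), h, w))
    layers <- lapply(layers, function(m) pmin(pmax(round(m), 0), 255))
    frames[[t]] <- if (night) layers[[1]] else
      array(unlist(layers), c(h, w, 3L))
    det[[t]] <- rows
  }

  detections <- do.call(rbind, det)
  if (is.null(detections)) detections <- .emptyDetections()
  states <- list()
  summaries <- list()
  for (i in seq_len(ndog)) {
    id <- as.character(i)
    seq <- stateSequence(dogData[[i]]$states, sc@fps, id, sc@duration)
    states[[id]] <- seq
    summaries[[id]] <- summarizeSleep(seq)
  }
  truth <- new("GroundTruth", detections = detections, states = states,
               summaries = summaries, scenario = sc)
  stream <- new("MemoryFrameStream", frames = frames, fps = sc@fps,
                nframes = n, mode = sc@mode)

  if (!is.null(dir)) {
    writeFrames(stream, dir)
    writeDetections(detections, file.path(dir, "truth_detections.csv"))
    writeObservationLog(states, file.path(dir, "truth_annotations.csv"))
    jsonlite::write_json(
      lapply(summaries, function(s) list(
        subject = s@subjectId, total_sleep_s = s@totalSleepS,
        total_awake_s = s@totalAwakeS, unknown_s = s@totalUnknownS,
        observed_s = s@observedS, bout_count = s@boutCount,
        percent_asleep = s@percentAsleep)),
      file.path(dir, "truth_summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(stream = stream, truth = truth)
}

#' Perturb a true state sequence like a human observer
#'
#' Emulates observer error for testing the comparison machinery: every
#' bout boundary is shifted by a seeded zero-mean Gaussian draw and each
#' bout is independently missed (deleted) with probability `lapseProb`.
#' Frames outside bouts are AWAKE; the result is a valid
#' [StateSequence-class] over the same session.
#'
#' @param truth a [StateSequence-class].
#' @param lapseProb probability in \[0, 1\] of missing a bout entirely.
#' @param boundaryJitterSd sd (seconds) of the boundary shifts.
#' @param seed integer seed.
#' @return a [StateSequence-class].
#' @export
observerErrorModel <- function(truth, lapseProb = 0, boundaryJitterSd = 0,
                               seed = 1) {
  bouts <- extractBouts(truth)
  seedSave <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(seedSave))
    assign(".Random.seed", seedSave, globalenv()), add = TRUE)
  set.seed(as.integer(seed %% 1000000L))
  n <- length(truth@states)
  st <- rep("AWAKE", n)
  for (k in seq_len(nrow(bouts))) {
    s <- bouts$start[k] + stats::rnorm(1, 0, boundaryJitterSd)
    e <- bouts$end[k] + stats::rnorm(1, 0, boundaryJitterSd)
    keep <- stats::runif(1) >= lapseProb
    if (!keep) next
    f0 <- max(0L, ceiling(s * truth@fps - 1e-6))
    f1 <- min(n - 1L, ceiling(e * truth@fps - 1e-6) - 1L)
    if (f1 >= f0) st[(f0 + 1L):(f1 + 1L)] <- "ASLEEP"
  }
  stateSequence(st, truth@fps, truth@subjectId, truth@duration)
}
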