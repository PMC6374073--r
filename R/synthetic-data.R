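#' Generator configuration for synthetic sessions
#'
#' Holds every generative default of the synthetic-data module. The defaults
#' are the population statistics that the analysis pipeline is expected to
#' recover: complex spike (CS) baseline rates per response phenotype, the
#' motion-onset response magnitude, the rotational-velocity gain and
#' post-stimulus depression, luminance response probability and latency,
#' simple spike (SS) rest and in-bout rates, granule cell rates, the fictive
#' swim cycle frequency, bout duration/interval ranges, the GCaMP kernel,
#' and the CS share of the calcium signal.
#'
#' @param seed integer seed; identical configs (including seed) produce
#'   bit-identical sessions.
#' @param ... name = value overrides of any default listed below.
#'
#' @section Defaults:
#' \describe{
#'   \item{ephysRate}{1000 samples/s (8300 available by option).}
#'   \item{imagingRate}{30 samples/s for dF/F traces.}
#'   \item{nTrials, nBlankTrials}{4 stimulus trials and 2 blank trials
#'     (a ~12-min session, comparable to repeated-protocol cell-attached
#'     recordings).}
#'   \item{csBaseline}{named Hz: motion_onset 0.20, rotational_velocity
#'     0.77, luminance 0.28, motor 0.34.}
#'   \item{onsetSpikes}{1.2 CS per preferred-direction 500-ms onset window.}
#'   \item{rotGain, rotNonPref, rotDepress}{preferred-direction rate =
#'     baseline x 4.4; non-preferred 0.32 Hz; 1-s post-stimulus depression
#'     to 0.37 of baseline.}
#'   \item{lumSpikes, lumLatencyRange, lumJitterSD}{0.80 CS per preferred
#'     transition at a fixed per-cell latency in [150, 400] ms with 5-ms
#'     jitter.}
#'   \item{ssRest, ssBout}{7.6 and 14.5 Hz, in-bout rate graded by vigor.}
#'   \item{granuleRest, granuleBout}{1.3 and 25.7 Hz.}
#'   \item{vrCycleFreq}{26.7 Hz intra-bout burst cycle.}
#'   \item{boutDurRange, gapRange}{bouts 0.2-0.6 s; rest gaps 1-5 s.}
#'   \item{tau}{1.6 s GCaMP kernel decay constant.}
#'   \item{csShare}{0.784 CS share of the calcium signal at the default
#'     paired-recording spike rates (0.5 Hz CS, 10 Hz SS); the CS/SS
#'     amplitude ratio is derived from it.}
#'   \item{nNuclei}{433 nuclei in the default volume.}
#' }
#' @return list of class "GeneratorConfig".
#' @export
generatorConfig <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    ephysRate = 1000, imagingRate = 30, eyeRate = 100,
    nTrials = 4L, nBlankTrials = 2L,
    epochDur = 5, pauseDur = 5, preStim = 5,
    gratingSpeeds = c(3, 10, 30), lateralSpeed = 10,
    windmillFreq = 0.2, windmillAmp = 1, ambientLum = 0.5,
    csBaseline = c(motion_onset = 0.20, rotational_velocity = 0.77,
                   luminance = 0.28, motor = 0.34),
    onsetSpikes = 1.2, onsetWindow = 0.5,
    rotGain = 4.4, rotNonPref = 0.32, rotDepress = 0.37, rotDepressDur = 1,
    lumSpikes = 0.80, lumLatencyRange = c(0.150, 0.400), lumJitterSD = 0.005,
    motorBoutProb = 0.38,
    ssRest = 7.6, ssBout = 14.5,
    csSsInteraction = FALSE, csSsGain = 0, csSsWindow = 0.050,
    granuleRest = 1.3, granuleBout = 25.7,
    granulePhaseLock = TRUE, granulePhaseDepth = 0.8,
    vrCycleFreq = 26.7, burstDuty = 0.4,
    boutDurRange = c(0.2, 0.6), gapRange = c(1, 5),
    boutRateRest = 0.22, boutRateMotion = 0.55,
    vrNoiseSD = 1, vrBurstAmp = 8, vigorCV = 0.3,
    eyeGainCV = 0.3, eyeLowpass = 0.2,
    refractory = 0.002,
    tau = 1.6, csShare = 0.784, pairedCsRate = 0.5, pairedSsRate = 10,
    aSS = 0.03, calciumNoiseSD = 0.02,
    phenotypeMix = c(motion_onset = 31L, rotational_velocity = 12L,
                     luminance = 9L, motor = 9L),
    nNuclei = 433L, volShape = c(128L, 128L, 48L), blobSigma = 2,
    volSNR = 8, volMinSepSigma = 4)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  rates <- c(cfg$ephysRate, cfg$imagingRate, cfg$eyeRate, cfg$vrCycleFreq)
  if (any(rates <= 0)) stop("all rates must be positive")
  if (any(cfg$phenotypeMix < 0)) stop("phenotype counts must be >= 0")
  if (any(cfg$csBaseline <= 0)) stop("CS baseline rates must be positive")
  class(cfg) <- "GeneratorConfig"
  cfg
}

# Amplitude ratio A_cs / A_ss that yields the configured CS share of the
# calcium signal. For Poisson trains convolved with a common kernel the
# component SD is amplitude * sqrt(rate * integral(k^2)) (Campbell's
# theorem); the kernel factor cancels in the ratio.
.calciumAmpRatio <- function(cfg) {
  p <- cfg$csShare
  (p / (1 - p)) * sqrt(cfg$pairedSsRate / cfg$pairedCsRate)
}

# Dead-time correction: generator intensity that yields the target observed
# rate under an absolute refractory period tr (interval = tr + Exp(lambda)).
.deadTimeCorrect <- function(rate, tr) {
  if (any(rate * tr >= 0.9)) stop("target rate too high for refractory period")
  rate / (1 - rate * tr)
}

#' Build the default stimulus protocol
#'
#' One stimulus trial contains, in order: a pre-stimulus static period;
#' forward-moving gratings at 3, 10 and 30 mm/s (5 s each, 5 s static
#' pauses); reverse, leftward and rightward gratings at 10 mm/s; whole-field
#' and both half-field windmills rotating at 0.2 Hz with sinusoidal
#' velocity; and whole-field luminance flashes (light/dark alternation).
#' Blank trials contain a static grating only. The session concatenates
#' `nTrials` stimulus trials followed by `nBlankTrials` blank trials of the
#' same length.
#'
#' @param config a [generatorConfig()].
#' @return A [StimulusProtocol-class].
#' @export
makeProtocol <- function(config = generatorConfig()) {
  d <- config$epochDur; p <- config$pauseDur
  amb <- config$ambientLum
  ep <- list()
  add <- function(kind, direction, speed, freq, ampl, lum, t_on, t_off)
    ep[[length(ep) + 1L]] <<- data.frame(
      kind = kind, direction = direction, speed = speed, freq_hz = freq,
      amplitude = ampl, luminance = lum, t_on = t_on, t_off = t_off)
  trialEpochs <- function(offset) {
    t <- offset + config$preStim
    for (sp in config$gratingSpeeds) {
      add("grating", "forward", sp, NA, NA, amb, t, t + d); t <- t + d + p
    }
    for (dir in c("reverse", "left", "right")) {
      add("grating", dir, config$lateralSpeed, NA, NA, amb, t, t + d)
      t <- t + d + p
    }
    for (field in c("none", "left", "right")) {
      add("windmill", field, NA, config$windmillFreq, config$windmillAmp,
          amb, t, t + d)
      t <- t + d + p
    }
    lums <- c(1, 0, 1, 0)
    for (lv in lums) { add("flash", "none", NA, NA, NA, lv, t, t + d); t <- t + d }
    t + p - offset  # trial length
  }
  tl <- NULL
  trialRows <- list()
  nS <- config$nTrials; nB <- config$nBlankTrials
  off <- 0
  for (i in seq_len(nS)) {
    tl <- trialEpochs(off)
    trialRows[[i]] <- data.frame(trial = i, t_start = off, t_end = off + tl,
                                 blank = FALSE)
    off <- off + tl
  }
  if (is.null(tl)) tl <- 115  # blank-only sessions use the canonical length
  for (i in seq_len(nB)) {
    add("blank", "none", NA, NA, NA, amb, off, off + tl)
    trialRows[[nS + i]] <- data.frame(trial = nS + i, t_start = off,
                                      t_end = off + tl, blank = TRUE)
    off <- off + tl
  }
  StimulusProtocol(do.call(rbind, ep), do.call(rbind, trialRows))
}

# Signed windmill angular velocity (positive = clockwise) at times t for a
# given field ("none" = whole field, "left"/"right" = half field).
.windmillVelocityAt <- function(protocol, t, field = "none") {
  ep <- epochs(protocol)
  ep <- ep[ep$kind == "windmill" & ep$direction == field, , drop = FALSE]
  v <- numeric(length(t))
  for (i in seq_len(nrow(ep))) {
    sel <- t >= ep$t_on[i] & t < ep$t_off[i]
    v[sel] <- ep$amplitude[i] *
      sin(2 * pi * ep$freq_hz[i] * (t[sel] - ep$t_on[i]))
  }
  v
}

# Ambient luminance level at times t, and the table of luminance transitions.
.luminanceAt <- function(protocol, t) {
  ep <- epochs(protocol)
  amb <- if (nrow(ep)) ep$luminance[which(ep$kind != "flash")[1]] else 0.5
  if (is.na(amb)) amb <- 0.5
  lv <- rep(amb, length(t))
  fl <- ep[ep$kind == "flash", , drop = FALSE]
  for (i in seq_len(nrow(fl))) {
    sel <- t >= fl$t_on[i] & t < fl$t_off[i]
    lv[sel] <- fl$luminance[i]
  }
  lv
}

.luminanceEvents <- function(protocol) {
  ep <- epochs(protocol)
  fl <- ep[ep$kind == "flash", , drop = FALSE]
  amb <- if (nrow(ep)) ep$luminance[which(ep$kind != "flash")[1]] else 0.5
  if (is.na(amb)) amb <- 0.5
  if (!nrow(fl)) return(data.frame(t = numeric(0), direction = character(0)))
  fl <- fl[order(fl$t_on), , drop = FALSE]
  tt <- dir <- c()
  prevLum <- amb; prevOff <- -Inf
  for (i in seq_len(nrow(fl))) {
    lev <- if (fl$t_on[i] - prevOff > 1e-9) amb else prevLum
    if (abs(fl$luminance[i] - lev) > 1e-12) {
      tt <- c(tt, fl$t_on[i])
      dir <- c(dir, if (fl$luminance[i] > lev) "increase" else "decrease")
    }
    prevLum <- fl$luminance[i]; prevOff <- fl$t_off[i]
  }
  # return to ambient after the last flash of each contiguous block
  gaps <- which(c(diff(fl$t_on) > (fl$t_off - fl$t_on)[-nrow(fl)] + 1e-9, TRUE))
  for (i in gaps) {
    if (abs(fl$luminance[i] - amb) > 1e-12) {
      tt <- c(tt, fl$t_off[i])
      dir <- c(dir, if (amb > fl$luminance[i]) "increase" else "decrease")
    }
  }
  o <- order(tt)
  data.frame(t = tt[o], direction = dir[o])
}

# Epochs of a given kind/direction as an on/off window matrix.
.epochWindows <- function(protocol, kind, direction = NULL) {
  ep <- epochs(protocol)
  sel <- ep$kind == kind
  if (!is.null(direction)) sel <- sel & ep$direction %in% direction
  ep <- ep[sel, , drop = FALSE]
  list(on = ep$t_on, off = ep$t_off)
}

#' Simulate fictive swim behavior for a protocol
#'
#' Generates a ventral-root (VR) trace with bursty swim episodes, the
#' planted bout table, and left/right eye traces. Bout onsets follow an
#' inhomogeneous Poisson process whose rate is elevated during forward and
#' lateral grating motion and unchanged (spontaneous) during reverse motion,
#' static periods and blanks. Each bout is an integer number of burst cycles
#' at the default 26.7-Hz intra-bout frequency, with a per-bout vigor factor
#' that also scales simple spike and granule rates downstream. Eye traces
#' are low-pass-filtered copies of the windmill velocity with per-trial gain
#' jitter and slow drift.
#'
#' @param protocol a [StimulusProtocol-class].
#' @param config a [generatorConfig()].
#' @param seed optional seed override (defaults to the config seed).
#' @return list with `vr` ([TimeSeries-class]), `boutTruth`
#'   ([BoutTable-class] with the planted bouts; `mean_vigor` holds the
#'   planted vigor factor), and `eyes` (list of left/right
#'   [TimeSeries-class]).
#' @export
simulateBehavior <- function(protocol, config = generatorConfig(),
                             seed = NULL) {
  if (is.null(seed)) seed <- .childSeed(config$seed, 1L)
  .withSeed(seed, {
    dur <- protocolDuration(protocol)
    if (dur <= 0) stop("protocol covers no time")
    rate <- config$ephysRate
    n <- round(dur * rate)
    # context-dependent bout-onset intensity
    mot <- .epochWindows(protocol, "grating", c("forward", "left", "right"))
    onsetIntensity <- function(t) {
      ifelse(.inWindows(t, mot$on, mot$off),
             config$boutRateMotion, config$boutRateRest)
    }
    cand <- if (config$boutRateMotion > 0)
      .samplePoisson(onsetIntensity, dur, config$boutRateMotion,
                     refractory = 0) else numeric(0)
    cyc <- 1 / config$vrCycleFreq
    active <- config$burstDuty * cyc
    onsets <- offsets <- vig <- numeric(0)
    lastOff <- -Inf
    for (t0 in cand) {
      if (t0 < lastOff + config$gapRange[1]) next
      d <- stats::runif(1, config$boutDurRange[1], config$boutDurRange[2])
      k <- max(1L, round(d / cyc))
      tOff <- t0 + (k - 1) * cyc + active
      if (tOff > dur - 0.05) next
      onsets <- c(onsets, t0); offsets <- c(offsets, tOff)
      vig <- c(vig, max(0.1, stats::rnorm(1, 1, config$vigorCV)))
      lastOff <- tOff
    }
    x <- stats::rnorm(n, 0, config$vrNoiseSD)
    for (i in seq_along(onsets)) {
      k <- round((offsets[i] - onsets[i] - active) / cyc) + 1L
      for (j in seq_len(k)) {
        a0 <- onsets[i] + (j - 1) * cyc
        i0 <- floor(a0 * rate) + 1L
        i1 <- min(n, floor((a0 + active) * rate))
        if (i1 >= i0)
          x[i0:i1] <- x[i0:i1] * config$vrBurstAmp * vig[i]
      }
    }
    bt <- BoutTable(data.frame(t_on = onsets, t_off = offsets,
                               mean_vigor = vig, peak_vigor = vig))
    # eyes: filtered windmill velocity, whole field plus half fields at
    # half gain, per-trial gain jitter, slow drift
    en <- round(dur * config$eyeRate)
    et <- (seq_len(en) - 1) / config$eyeRate
    v <- .windmillVelocityAt(protocol, et, "none") +
      0.5 * .windmillVelocityAt(protocol, et, "left") +
      0.5 * .windmillVelocityAt(protocol, et, "right")
    tr <- trials(protocol)
    gain <- rep(1, en)
    for (i in seq_len(nrow(tr))) {
      g <- max(0, stats::rnorm(1, 1, config$eyeGainCV))
      gain[et >= tr$t_start[i] & et < tr$t_end[i]] <- g
    }
    lp <- function(z) {
      w <- max(1L, round(config$eyeLowpass * config$eyeRate))
      as.numeric(stats::filter(z, rep(1 / w, w), sides = 2, circular = TRUE))
    }
    drift <- function() cumsum(stats::rnorm(en, 0, 0.02 / sqrt(config$eyeRate)))
    eyeL <- TimeSeries(lp(v * gain) * 1.0 + drift(), config$eyeRate)
    eyeR <- TimeSeries(lp(v * gain) * stats::runif(1, 0.9, 1.1) + drift(),
                       config$eyeRate)
    list(vr = TimeSeries(x, rate), boutTruth = bt,
         eyes = list(left = eyeL, right = eyeR))
  })
}

# Piecewise-constant vigor signal from planted bouts: vigor factor inside a
# bout, 0 outside.
.vigorAt <- function(behavior, t) {
  b <- bouts(behavior$boutTruth)
  v <- numeric(length(t))
  for (i in seq_len(nrow(b))) {
    sel <- t >= b$t_on[i] & t < b$t_off[i]
    v[sel] <- b$mean_vigor[i]
  }
  v
}

.phenotypes <- c("motion_onset", "rotational_velocity", "luminance", "motor")

# Sample a soma position for a phenotype. Three rostrocaudal regions for the
# visual phenotypes (rostromedial motion-onset, central luminance, caudal
# rotational), motor cells mixed; coordinates in um, midline x = 0,
# rostral = +y.
.samplePosition <- function(phenotype) {
  ymu <- switch(phenotype, motion_onset = 60, luminance = 0,
                rotational_velocity = -60, motor = 0, granule = 0)
  ysd <- if (phenotype %in% c("motor", "granule")) 50 else 15
  x <- sample(c(-1, 1), 1) * stats::runif(1, 20, 100)
  c(x = x, y = stats::rnorm(1, ymu, ysd), z = stats::runif(1, -30, 0))
}

#' Simulate a Purkinje cell of a given complex spike phenotype
#'
#' Complex spikes are drawn from a thinned inhomogeneous Poisson process
#' (2-ms absolute refractory period, dead-time-corrected intensities) whose
#' intensity profile depends on the phenotype: motion-onset cells add a
#' 500-ms response window at preferred-direction motion onsets (1.2 spikes
#' per window); rotational-velocity cells multiply their baseline by 4.4
#' during preferred-direction rotation, fall to 0.32 Hz during
#' non-preferred rotation, and are depressed to 0.37 of baseline for 1 s
#' after rotation; luminance cells fire one spike with probability 0.80 at
#' a fixed per-cell latency (150-400 ms, 5-ms jitter) after their preferred
#' luminance transition; motor cells elevate their in-bout intensity so a
#' complex spike occurs on a fraction 0.38 of bouts. Simple spikes fire at
#' a rest rate multiplicatively scaled by instantaneous vigor so the mean
#' in-bout rate is the configured in-bout default; optionally a post-CS
#' multiplicative gain window (pause or facilitation) is applied.
#'
#' @param protocol a [StimulusProtocol-class].
#' @param behavior output of [simulateBehavior()].
#' @param phenotype one of "motion_onset", "rotational_velocity",
#'   "luminance", "motor".
#' @param config a [generatorConfig()].
#' @param seed optional seed override.
#' @param cellId identifier stored on the cell.
#' @return list of class "SyntheticCell": `cellId`, `phenotype`, `position`,
#'   `hemisphere`, `preferredDirection`, `cs`, `ss` ([SpikeTrain-class]),
#'   and `groundTruth` (every planted parameter).
#' @export
simulatePurkinje <- function(protocol, behavior, phenotype,
                             config = generatorConfig(), seed = NULL,
                             cellId = "cell") {
  if (!phenotype %in% .phenotypes)
    stop("unknown phenotype: ", phenotype)
  if (is.null(seed)) seed <- .childSeed(config$seed, 100L)
  .withSeed(seed, {
    dur <- protocolDuration(protocol)
    tr <- config$refractory
    b <- unname(config$csBaseline[phenotype])
    gt <- list(csBaseline = b, phenotype = phenotype)
    pref <- NULL
    csTimes <- NULL
    if (phenotype == "motion_onset") {
      pref <- sample(c("forward", "reverse", "left", "right"), 2)
      win <- .epochWindows(protocol, "grating", pref)
      extra <- (config$onsetSpikes - b * config$onsetWindow) /
        config$onsetWindow
      intensity <- function(t) {
        inWin <- .inWindows(t, win$on, win$off + 0) &
          .inWindows(t, win$on, win$on + config$onsetWindow)
        .deadTimeCorrect(b + extra * inWin, tr)
      }
      lmax <- .deadTimeCorrect(b + extra, tr)
      gt$onsetSpikes <- config$onsetSpikes
      gt$preferredDirections <- pref
    } else if (phenotype == "rotational_velocity") {
      pref <- sample(c("cw", "ccw"), 1)
      ep <- epochs(protocol)
      wm <- ep[ep$kind == "windmill" & ep$direction == "none", , drop = FALSE]
      sgn <- if (pref == "cw") 1 else -1
      intensity <- function(t) {
        lam <- rep(b, length(t))
        for (i in seq_len(nrow(wm))) {
          sel <- t >= wm$t_on[i] & t < wm$t_off[i]
          v <- sin(2 * pi * wm$freq_hz[i] * (t[sel] - wm$t_on[i])) * sgn
          lam[sel] <- ifelse(v > 0, b * config$rotGain, config$rotNonPref)
          dep <- t >= wm$t_off[i] & t < wm$t_off[i] + config$rotDepressDur
          lam[dep] <- b * config$rotDepress
        }
        .deadTimeCorrect(lam, tr)
      }
      lmax <- .deadTimeCorrect(b * config$rotGain, tr)
      gt$rotGain <- config$rotGain
      gt$rotNonPref <- config$rotNonPref
      gt$rotDepress <- config$rotDepress
      gt$preferredRotation <- pref
    } else if (phenotype == "luminance") {
      pref <- sample(c("increase", "decrease"), 1)
      latency <- stats::runif(1, config$lumLatencyRange[1],
                              config$lumLatencyRange[2])
      ev <- .luminanceEvents(protocol)
      ev <- ev[ev$direction == pref, , drop = FALSE]
      hits <- ev$t[stats::runif(nrow(ev)) < config$lumSpikes]
      evoked <- hits + latency + stats::rnorm(length(hits),
                                              0, config$lumJitterSD)
      intensity <- function(t) rep(.deadTimeCorrect(b, tr), length(t))
      lmax <- .deadTimeCorrect(b, tr)
      csTimes <- evoked
      gt$lumLatency <- latency
      gt$lumSpikes <- config$lumSpikes
      gt$preferredTransition <- pref
    } else { # motor
      bt <- bouts(behavior$boutTruth)
      meanDur <- if (nrow(bt)) mean(bt$t_off - bt$t_on) else
        mean(config$boutDurRange)
      lamBout <- -log(1 - config$motorBoutProb) / meanDur
      intensity <- function(t) {
        inB <- .inWindows(t, bt$t_on, bt$t_off)
        .deadTimeCorrect(ifelse(inB, lamBout, b), tr)
      }
      lmax <- .deadTimeCorrect(max(lamBout, b), tr)
      gt$motorBoutProb <- config$motorBoutProb
      gt$inBoutCsRate <- lamBout
    }
    base <- .samplePoisson(intensity, dur, lmax, refractory = tr)
    cs <- sort(c(base, csTimes))
    cs <- cs[cs >= 0 & cs <= dur]
    if (length(cs) > 1) { # enforce refractory across merged sources
      keep <- c(TRUE, diff(cs) >= tr)
      cs <- cs[keep]
    }
    # simple spikes: rest rate multiplicatively scaled by vigor
    g <- config$ssBout / config$ssRest - 1
    ssIntensity <- function(t)
      .deadTimeCorrect(config$ssRest * (1 + g * .vigorAt(behavior, t)), tr)
    ssMax <- .deadTimeCorrect(config$ssRest * (1 + g * 2.5), tr)
    ss <- .samplePoisson(ssIntensity, dur, ssMax, refractory = tr)
    if (config$csSsInteraction && length(cs) && length(ss)) {
      gain <- config$csSsGain
      inWin <- .inWindows(ss, cs, cs + config$csSsWindow)
      drop <- inWin & stats::runif(length(ss)) > gain
      ss <- ss[!drop]
    }
    gt$ssRest <- config$ssRest
    gt$ssBout <- config$ssBout
    pos <- .samplePosition(phenotype)
    structure(list(
      cellId = cellId, phenotype = phenotype, position = pos,
      hemisphere = if (pos[["x"]] < 0) "L" else "R",
      preferredDirection = pref,
      cs = SpikeTrain(cs, "complex", duration = dur),
      ss = SpikeTrain(ss, "simple", duration = dur),
      groundTruth = gt), class = "SyntheticCell")
  })
}

#' Simulate a granule cell
#'
#' Granule spiking at a low rest rate and a high in-bout rate graded by the
#' per-bout vigor factor. When phase-locked (the default), in-bout intensity
#' is modulated sinusoidally at the ventral-root burst cycle frequency so
#' the spike autocorrelation peaks at the cycle period.
#'
#' @inheritParams simulatePurkinje
#' @param phaseLock override the config's `granulePhaseLock`.
#' @return A "SyntheticCell" list with `ss` holding the granule train
#'   (label "granule") and `cs = NULL`.
#' @export
simulateGranule <- function(protocol, behavior, config = generatorConfig(),
                            seed = NULL, cellId = "gc",
                            phaseLock = NULL) {
  if (is.null(seed)) seed <- .childSeed(config$seed, 200L)
  if (is.null(phaseLock)) phaseLock <- config$granulePhaseLock
  .withSeed(seed, {
    dur <- protocolDuration(protocol)
    tr <- config$refractory
    bt <- bouts(behavior$boutTruth)
    f <- config$vrCycleFreq
    m <- if (phaseLock) config$granulePhaseDepth else 0
    phase <- stats::runif(1, 0, 2 * pi)
    g <- config$granuleBout / config$granuleRest - 1
    intensity <- function(t) {
      v <- .vigorAt(behavior, t)
      lam <- config$granuleRest * (1 + g * v)
      if (m > 0 && nrow(bt)) {
        idx <- findInterval(t, bt$t_on)
        inB <- v > 0
        tOn <- rep(NA_real_, length(t))
        tOn[inB] <- bt$t_on[pmax(idx[inB], 1L)]
        mod <- rep(1, length(t))
        mod[inB] <- 1 + m * cos(2 * pi * f * (t[inB] - tOn[inB]) - phase)
        lam <- lam * mod
      }
      .deadTimeCorrect(pmin(lam, 0.9 / tr * 0.9), tr)
    }
    lmax <- .deadTimeCorrect(
      min(config$granuleRest * (1 + g * 2.5) * (1 + m), 0.81 / tr), tr)
    ssT <- .samplePoisson(intensity, dur, lmax, refractory = tr)
    pos <- .samplePosition("granule")
    structure(list(
      cellId = cellId, phenotype = "granule", position = pos,
      hemisphere = if (pos[["x"]] < 0) "L" else "R",
      preferredDirection = NULL, cs = NULL,
      ss = SpikeTrain(ssT, "granule", duration = dur),
      groundTruth = list(granuleRest = config$granuleRest,
                         granuleBout = config$granuleBout,
                         phaseLock = phaseLock, phase = phase)),
      class = "SyntheticCell")
  })
}

#' @export
print.SyntheticCell <- function(x, ...) {
  cat(sprintf("SyntheticCell %s (%s): %s%d SS, pos (%.0f, %.0f, %.0f) um\n",
              x$cellId, x$phenotype,
              if (!is.null(x$cs)) sprintf("%d CS, ", nSpikes(x$cs)) else "",
              nSpikes(x$ss), x$position[["x"]], x$position[["y"]],
              x$position[["z"]]))
  invisible(x)
}

#' Simulate a calcium (dF/F) trace from paired spike trains
#'
#' dF/F is the sum of the complex and simple spike delta trains convolved
#' with a single-exponential GCaMP kernel (decay constant `tau`, default
#' 1.6 s) at their respective amplitudes, plus Gaussian noise. The CS
#' amplitude exceeds the SS amplitude; their ratio is derived from the
#' configured CS share of the signal.
#'
#' @param cs,ss [SpikeTrain-class] inputs (either may be empty).
#' @param config a [generatorConfig()].
#' @param duration trace duration, s (defaults to the trains' duration).
#' @param noiseSD Gaussian noise SD (default from config; 0 disables).
#' @param seed optional seed override.
#' @return A [TimeSeries-class] dF/F trace at the imaging rate.
#' @export
simulateCalcium <- function(cs, ss, config = generatorConfig(),
                            duration = NULL, noiseSD = NULL, seed = NULL) {
  if (is.null(seed)) seed <- .childSeed(config$seed, 300L)
  if (is.null(noiseSD)) noiseSD <- config$calciumNoiseSD
  aSS <- config$aSS
  aCS <- aSS * .calciumAmpRatio(config)
  if (aCS < 0 || aSS < 0) stop("amplitudes must be non-negative")
  if (aCS <= aSS) stop("CS amplitude must exceed SS amplitude")
  if (is.null(duration))
    duration <- max(cs@duration, ss@duration, na.rm = TRUE)
  .withSeed(seed, {
    rate <- config$imagingRate
    n <- round(duration * rate)
    drive <- aCS * .binEvents(spikeTimes(cs), rate, n) +
      aSS * .binEvents(spikeTimes(ss), rate, n)
    y <- .expFilter(drive, rate, config$tau)
    if (noiseSD > 0) y <- y + stats::rnorm(n, 0, noiseSD)
    TimeSeries(y, rate)
  })
}

#' Simulate a nuclear-labelled image volume
#'
#' Places `n` spherical-Gaussian blobs at random non-overlapping centers
#' inside the volume and adds Gaussian noise. Centers are returned as
#' ground truth for the template-matching counter.
#'
#' @param n number of nuclei (default from config, 433).
#' @param shape integer vector (nx, ny, nz) in voxels.
#' @param config a [generatorConfig()].
#' @param centers optional matrix of centers to use instead of random
#'   placement; pairwise distances below 2*sigma are rejected.
#' @param snr peak blob amplitude over noise SD.
#' @param seed optional seed override.
#' @return list with `volume` (3D array), `centers` (n x 3 matrix, voxel
#'   coordinates), `sigma`, `snr`.
#' @export
simulateNucleiVolume <- function(n = NULL, shape = NULL,
                                 config = generatorConfig(), centers = NULL,
                                 snr = NULL, seed = NULL) {
  if (is.null(n)) n <- config$nNuclei
  if (is.null(shape)) shape <- config$volShape
  if (is.null(snr)) snr <- config$volSNR
  if (is.null(seed)) seed <- .childSeed(config$seed, 400L)
  sigma <- config$blobSigma
  minSep <- config$volMinSepSigma * sigma
  .withSeed(seed, {
    if (!is.null(centers)) {
      centers <- as.matrix(centers)
      if (nrow(centers) > 1 &&
          min(stats::dist(centers)) < 2 * sigma)
        stop("centers closer than 2*sigma violate the blob-separation ",
             "precondition")
      n <- nrow(centers)
    } else if (n > 0) {
      margin <- ceiling(3 * sigma) + 2
      lo <- rep(margin, 3); hi <- shape - margin
      if (any(hi <= lo)) stop("volume too small for the blob size")
      centers <- matrix(NA_real_, n, 3)
      placed <- 0L
      tries <- 0L
      maxTries <- 200L * n
      while (placed < n && tries < maxTries) {
        tries <- tries + 1L
        cand <- lo + stats::runif(3) * (hi - lo)
        ok <- placed == 0L ||
          min(sqrt(colSums((t(centers[seq_len(placed), , drop = FALSE]) -
                              cand)^2))) >= minSep
        if (ok) { placed <- placed + 1L; centers[placed, ] <- cand }
      }
      if (placed < n)
        stop("could not place ", n, " non-overlapping nuclei in the volume")
    } else centers <- matrix(numeric(0), 0, 3)
    vol <- array(stats::rnorm(prod(shape), 0, 1 / snr), dim = shape)
    r <- ceiling(4 * sigma)
    for (i in seq_len(nrow(centers))) {
      cx <- centers[i, ]
      ix <- max(1, floor(cx[1] - r)):min(shape[1], ceiling(cx[1] + r))
      iy <- max(1, floor(cx[2] - r)):min(shape[2], ceiling(cx[2] + r))
      iz <- max(1, floor(cx[3] - r)):min(shape[3], ceiling(cx[3] + r))
      gx <- exp(-(ix - cx[1])^2 / (2 * sigma^2))
      gy <- exp(-(iy - cx[2])^2 / (2 * sigma^2))
      gz <- exp(-(iz - cx[3])^2 / (2 * sigma^2))
      vol[ix, iy, iz] <- vol[ix, iy, iz] + outer(outer(gx, gy), gz)
    }
    list(volume = vol, centers = centers, sigma = sigma, snr = snr)
  })
}

#' Simulate a dendritic morphology point cloud with a target planarity
#'
#' Anisotropic Gaussian point cloud whose planted axis variances give the
#' requested third-to-second principal component (variance) ratio in
#' expectation, randomly rotated and translated.
#'
#' @param planarityTarget target PC3/PC2 variance ratio in [0, 1].
#' @param nPoints number of points.
#' @param config a [generatorConfig()].
#' @param seed optional seed override.
#' @return nPoints x 3 matrix of coordinates (um).
#' @export
simulateMorphology <- function(planarityTarget, nPoints = 500,
                               config = generatorConfig(), seed = NULL) {
  if (planarityTarget < 0 || planarityTarget > 1)
    stop("planarityTarget must lie in [0, 1]")
  if (is.null(seed)) seed <- .childSeed(config$seed, 500L)
  .withSeed(seed, {
    sds <- c(20, 12, 12 * sqrt(planarityTarget))
    pts <- cbind(stats::rnorm(nPoints, 0, sds[1]),
                 stats::rnorm(nPoints, 0, sds[2]),
                 stats::rnorm(nPoints, 0, sds[3]))
    rot <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
    pts %*% rot
  })
}

#' Render a cell-attached voltage trace from spike trains
#'
#' Places stereotyped waveforms (a wide multiphasic complex spike shape and
#' a narrow simple spike shape) on a noise floor, for testing the
#' amplitude-threshold sorter end to end.
#'
#' @param cs,ss [SpikeTrain-class] trains.
#' @param rate sampling rate, samples/s.
#' @param duration trace duration, s.
#' @param csAmp,ssAmp waveform peak amplitudes.
#' @param noiseSD Gaussian noise SD.
#' @param seed optional RNG seed for the noise.
#' @return A [TimeSeries-class] trace.
#' @export
renderEphysTrace <- function(cs, ss, rate = 1000, duration = NULL,
                             csAmp = 10, ssAmp = 3, noiseSD = 0.2,
                             seed = NULL) {
  if (is.null(duration))
    duration <- max(cs@duration, ss@duration, na.rm = TRUE)
  n <- round(duration * rate)
  .withSeed(seed, {
    x <- if (noiseSD > 0) stats::rnorm(n, 0, noiseSD) else numeric(n)
    place <- function(times, shape, amp) {
      for (t0 in times) {
        i <- round(t0 * rate) + 1L
        idx <- i + seq_along(shape) - 1L
        ok <- idx >= 1L & idx <= n
        x[idx[ok]] <<- x[idx[ok]] + amp * shape[ok]
      }
    }
    place(spikeTimes(cs), c(0.3, 1, 0.6, 0.35, -0.2), csAmp)
    place(spikeTimes(ss), c(1, -0.3), ssAmp)
    TimeSeries(x, rate)
  })
}

#' Simulate a complete session
#'
#' Generates the protocol, fictive behavior, and a population of Purkinje
#' and (optionally) granule cells with the configured phenotype mix, all
#' under one seed.
#'
#' @param config a [generatorConfig()].
#' @param nGranule number of granule cells to add (default 0).
#' @return list of class "SyntheticSession" with `protocol`, `behavior`,
#'   `cells` (list of SyntheticCell), and `config`.
#' @export
simulateSession <- function(config = generatorConfig(), nGranule = 0L) {
  protocol <- makeProtocol(config)
  behavior <- simulateBehavior(protocol, config)
  cells <- list()
  i <- 0L
  for (ph in names(config$phenotypeMix)) {
    for (k in seq_len(config$phenotypeMix[[ph]])) {
      i <- i + 1L
      cells[[i]] <- simulatePurkinje(
        protocol, behavior, ph, config,
        seed = .childSeed(config$seed, 1000L + i),
        cellId = sprintf("pc%02d_%s", i, ph))
    }
  }
  for (k in seq_len(nGranule)) {
    i <- i + 1L
    cells[[i]] <- simulateGranule(
      protocol, behavior, config,
      seed = .childSeed(config$seed, 5000L + k),
      cellId = sprintf("gc%02d", k))
  }
  structure(list(protocol = protocol, behavior = behavior, cells = cells,
                 config = config), class = "SyntheticSession")
}

#' @export
print.SyntheticSession <- function(x, ...) {
  cat(sprintf("SyntheticSession: %.0f s, %d bouts, %d cells (seed %d)\n",
              protocolDuration(x$protocol), nBouts(x$behavior$boutTruth),
              length(x$cells), x$config$seed))
  invisible(x)
}
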