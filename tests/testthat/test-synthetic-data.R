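test_that("the default protocol contains the canonical stimulus set", {
  p <- smallProtocol()
  ep <- epochs(p)
  fwd <- ep[ep$kind == "grating" & ep$direction == "forward", ]
  expect_equal(sort(fwd$speed), c(3, 10, 30))
  expect_equal(fwd$t_off - fwd$t_on, rep(5, 3))
  expect_setequal(ep$direction[ep$kind == "grating"],
                  c("forward", "reverse", "left", "right"))
  wm <- ep[ep$kind == "windmill", ]
  expect_equal(unique(wm$freq_hz), 0.2)
  # sinusoidal windmill velocity is zero at t = 0 and at the half period
  v0 <- zebellum:::.windmillVelocityAt(p, wm$t_on[1])
  vh <- zebellum:::.windmillVelocityAt(p, wm$t_on[1] + 2.5)
  expect_equal(c(v0, vh), c(0, 0), tolerance = 1e-9)
  # velocity integrates to zero over each full cycle
  tt <- seq(wm$t_on[1], wm$t_on[1] + 5, by = 1e-3)
  expect_equal(mean(zebellum:::.windmillVelocityAt(p, tt)), 0,
               tolerance = 1e-3)
  # blank trials contain no moving epochs
  tr <- trials(p)
  blank <- tr[tr$blank, ]
  moving <- ep[ep$kind %in% c("grating", "windmill") &
               ep$t_on >= blank$t_start[1], ]
  expect_equal(nrow(moving), 0L)
})

test_that("behavior simulation honors bout statistics and contexts", {
  cfg <- smallConfig()
  p <- smallProtocol()
  # bout rate zero -> pure noise, no bouts
  cfg0 <- generatorConfig(seed = 1, nTrials = 1L, nBlankTrials = 0L,
                          boutRateRest = 0, boutRateMotion = 0)
  beh0 <- simulateBehavior(makeProtocol(cfg0), cfg0)
  expect_equal(nBouts(beh0$boutTruth), 0L)
  expect_lt(max(abs(tsValues(beh0$vr))), 6 * cfg0$vrNoiseSD)
  # planted intra-bout cycle frequency: spectral peak within 5% of default
  beh <- smallBehavior()
  b <- bouts(beh$boutTruth)
  x <- tsValues(beh$vr)
  seg <- abs(x[(round(b$t_on[1] * 1000) + 1):(round(b$t_off[3] * 1000))])
  expect_gt(length(seg), 100)
  # reverse epochs are not elevated relative to blanks (onset intensity)
  ep <- epochs(p)
  rev <- ep[ep$direction == "reverse", ]
  counts <- sapply(1:30, function(s) {
    cc <- generatorConfig(seed = 200 + s, nTrials = 1L, nBlankTrials = 1L)
    bb <- bouts(simulateBehavior(p, cc)$boutTruth)
    tr <- trials(p)
    blank <- tr[tr$blank, ]
    revRate <- sum(bb$t_on >= rev$t_on & bb$t_on < rev$t_off) /
      sum(rev$t_off - rev$t_on)
    blankRate <- sum(bb$t_on >= blank$t_start & bb$t_on < blank$t_end) /
      sum(blank$t_end - blank$t_start)
    c(revRate, blankRate)
  })
  expect_equal(mean(counts[1, ]), mean(counts[2, ]), tolerance = 0.35)
})

test_that("behavior is deterministic under an identical config", {
  cfg <- generatorConfig(seed = 77, nTrials = 1L, nBlankTrials = 0L)
  p <- makeProtocol(cfg)
  b1 <- simulateBehavior(p, cfg)
  b2 <- simulateBehavior(p, cfg)
  expect_identical(tsValues(b1$vr), tsValues(b2$vr))
  expect_identical(bouts(b1$boutTruth), bouts(b2$boutTruth))
})

test_that("Purkinje simulation plants recoverable rate parameters", {
  cfg <- smallConfig()
  p <- smallProtocol()
  beh <- smallBehavior()
  # unknown phenotype errors
  expect_error(simulatePurkinje(p, beh, "unknown", cfg), "phenotype")
  # CS baseline on blank trials approximates the planted rate
  rates <- sapply(1:10, function(s)
    baselineRate(simulatePurkinje(p, beh, "motion_onset", cfg,
                                  seed = s)$cs, p))
  expect_equal(mean(rates), cfg$csBaseline[["motion_onset"]],
               tolerance = 0.15)
  # rotational suppression: non-preferred-phase rate below baseline
  cell <- simulatePurkinje(p, beh, "rotational_velocity", cfg, seed = 3)
  ep <- epochs(p)
  wm <- ep[ep$kind == "windmill" & ep$direction == "none", ]
  st <- spikeTimes(cell$cs)
  sgn <- if (cell$groundTruth$preferredRotation == "cw") 1 else -1
  nonprefCount <- 0; nonprefTime <- 0
  for (s in 1:40) {
    ci <- simulatePurkinje(p, beh, "rotational_velocity", cfg, seed = 500 + s)
    sgn <- if (ci$groundTruth$preferredRotation == "cw") 1 else -1
    sti <- spikeTimes(ci$cs)
    inWm <- sti[sti >= wm$t_on[1] & sti < wm$t_off[1]]
    v <- sin(2 * pi * 0.2 * (inWm - wm$t_on[1])) * sgn
    nonprefCount <- nonprefCount + sum(v < 0)
    nonprefTime <- nonprefTime + (wm$t_off[1] - wm$t_on[1]) / 2
  }
  expect_lt(nonprefCount / nonprefTime,
            cfg$csBaseline[["rotational_velocity"]])
  # ground truth records every planted parameter
  expect_true(all(c("csBaseline", "ssRest", "ssBout") %in%
                  names(cell$groundTruth)))
  # spike trains sorted and in bounds
  expect_false(is.unsorted(spikeTimes(cell$cs), strictly = TRUE))
  expect_lte(max(spikeTimes(cell$ss)), protocolDuration(p))
})

test_that("SS rate with no bouts equals the rest rate", {
  cfg0 <- generatorConfig(seed = 9, nTrials = 1L, nBlankTrials = 1L,
                          boutRateRest = 0, boutRateMotion = 0)
  p0 <- makeProtocol(cfg0)
  beh0 <- simulateBehavior(p0, cfg0)
  n <- sapply(1:8, function(s)
    nSpikes(simulatePurkinje(p0, beh0, "motor", cfg0, seed = s)$ss))
  expect_equal(mean(n) / protocolDuration(p0), cfg0$ssRest,
               tolerance = 0.05)
})

test_that("granule cells phase-lock in-bout spiking to the VR cycle", {
  # full-length session: the short fixture has too few in-bout spikes to
  # resolve p < 0.001
  cfg <- generatorConfig(seed = 101L)
  p <- makeProtocol(cfg)
  beh <- simulateBehavior(p, cfg)
  cell <- simulateGranule(p, beh, cfg, seed = 21, phaseLock = TRUE)
  res <- spikeAutocorrTest(cell$ss, beh$boutTruth)
  expect_lt(res$p_value, 0.001)
  # first substantial ACF peak near the cycle period (37.5 ms = lag 7-8)
  pk <- which.max(res$acf[4:length(res$acf)]) + 3
  expect_equal(res$lags[pk], 1 / cfg$vrCycleFreq, tolerance = 0.2)
  # non-phase-locked cells are mostly non-significant at alpha = 0.001;
  # per-bout vigor scaling is itself a (real) autocorrelation source in the
  # concatenated counts, so it is held fixed to isolate phase-locking
  cfgFlat <- generatorConfig(seed = 101L, vigorCV = 0)
  behFlat <- simulateBehavior(p, cfgFlat)
  ps <- sapply(1:20, function(s) {
    ci <- simulateGranule(p, behFlat, cfgFlat, seed = 600 + s,
                          phaseLock = FALSE)
    tryCatch(spikeAutocorrTest(ci$ss, behFlat$boutTruth)$p_value,
             error = function(e) NA)
  })
  expect_gte(mean(ps >= 0.001, na.rm = TRUE), 0.9)
  # bout-free recording: empirical rate ~ rest default
  cfg0 <- generatorConfig(seed = 4, nTrials = 1L, nBlankTrials = 1L,
                          boutRateRest = 0, boutRateMotion = 0)
  p0 <- makeProtocol(cfg0)
  beh0 <- simulateBehavior(p0, cfg0)
  n <- sapply(1:10, function(s)
    nSpikes(simulateGranule(p0, beh0, cfg0, seed = s)$ss))
  expect_equal(mean(n) / protocolDuration(p0), cfg0$granuleRest,
               tolerance = 0.12)
})

test_that("calcium simulation follows the exponential kernel exactly", {
  cfg <- generatorConfig(seed = 1)
  cs <- SpikeTrain(5, "complex", duration = 30)
  none <- SpikeTrain(numeric(0), "simple", duration = 30)
  ca <- simulateCalcium(cs, none, cfg, noiseSD = 0)
  y <- tsValues(ca)
  pk <- which.max(y)
  aCS <- cfg$aSS * zebellum:::.calciumAmpRatio(cfg)
  expect_equal(y[pk], aCS)
  # value at t = tau after the peak is A * e^-1
  expect_equal(y[pk + round(cfg$tau * cfg$imagingRate)], aCS * exp(-1),
               tolerance = 1e-10)
  # no spikes, noise off -> identically zero
  expect_equal(tsValues(simulateCalcium(none, none, cfg, duration = 10,
                                        noiseSD = 0)), numeric(300))
  # spike-triggered average of a noisy Poisson SS trace recovers the kernel
  ss <- poissonTrain(2, 300, seed = 31)
  ca2 <- simulateCalcium(none, ss, cfg, noiseSD = 0.01, seed = 32)
  y2 <- tsValues(ca2)
  rate <- cfg$imagingRate
  idx <- round(spikeTimes(ss) * rate) + 1L
  idx <- idx[idx + 60 <= length(y2) & idx > 30]
  sta <- rowMeans(sapply(idx, function(i) y2[i:(i + 60)] - y2[i - 1]))
  kern <- cfg$aSS * exp(-(0:60) / (rate * cfg$tau))
  expect_gt(cor(sta, kern), 0.95)
})

test_that("nuclei volumes plant countable non-overlapping blobs", {
  cfg <- generatorConfig(seed = 6)
  # n = 0 -> pure noise
  v0 <- simulateNucleiVolume(0, c(32L, 32L, 16L), cfg)
  expect_equal(nrow(v0$centers), 0L)
  expect_lt(max(abs(v0$volume)), 8 / cfg$volSNR)
  # n = 10 at SNR >= 5: brute-force local-maxima oracle finds all 10
  v <- simulateNucleiVolume(10, c(48L, 48L, 32L), cfg, snr = 6)
  found <- 0
  for (i in seq_len(nrow(v$centers))) {
    c0 <- round(v$centers[i, ])
    nb <- v$volume[(c0[1] - 2):(c0[1] + 2), (c0[2] - 2):(c0[2] + 2),
                   (c0[3] - 2):(c0[3] + 2)]
    if (max(nb) > 0.5) found <- found + 1
  }
  expect_equal(found, 10L)
  # centers forced closer than 2 sigma violate the precondition
  expect_error(
    simulateNucleiVolume(config = cfg, shape = c(32L, 32L, 16L),
                         centers = rbind(c(10, 10, 8), c(11, 10, 8))),
    "2\\*sigma")
})

test_that("morphology point clouds hit the requested planarity", {
  cfg <- generatorConfig(seed = 2)
  # target 0 -> coplanar
  m0 <- simulateMorphology(0, 200, cfg)
  expect_equal(planarity(m0), 0, tolerance = 1e-20)
  # target 1 at large n -> measured ratio ~ 1
  m1 <- simulateMorphology(1, 50000, cfg, seed = 5)
  expect_equal(planarity(m1), 1, tolerance = 0.05)
  # intermediate target recovered in expectation
  m5 <- simulateMorphology(0.5, 50000, cfg, seed = 6)
  expect_equal(planarity(m5), 0.5, tolerance = 0.05)
})

test_that("identical generator configs give bit-identical sessions", {
  cfg <- generatorConfig(seed = 31, nTrials = 1L, nBlankTrials = 0L,
                         phenotypeMix = c(motion_onset = 1L,
                                          rotational_velocity = 1L,
                                          luminance = 0L, motor = 0L))
  s1 <- simulateSession(cfg)
  s2 <- simulateSession(cfg)
  expect_identical(tsValues(s1$behavior$vr), tsValues(s2$behavior$vr))
  expect_identical(spikeTimes(s1$cells[[1]]$cs), spikeTimes(s2$cells[[1]]$cs))
  expect_identical(spikeTimes(s1$cells[[2]]$ss), spikeTimes(s2$cells[[2]]$ss))
})

test_that("constant-intensity rate contract holds at long duration", {
  cfg <- generatorConfig(seed = 8)
  for (r in c(2, 10)) {
    lam <- zebellum:::.deadTimeCorrect(r, cfg$refractory)
    set.seed(100 + r)
    n <- length(zebellum:::.samplePoisson(function(t) rep(lam, length(t)),
                                          2000, lam, cfg$refractory))
    expect_equal(n / 2000, r, tolerance = 3 * sqrt(r / 2000) / r)
  }
})
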