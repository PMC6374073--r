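test_that("CS-triggered SS histograms normalize correctly", {
  # SS independent of CS: all normalized bins ~ 1 in expectation
  set.seed(1)
  means <- replicate(40, {
    cs <- poissonTrain(0.5, 200, seed = sample.int(1e6, 1),
                       label = "complex")
    ss <- poissonTrain(20, 200, seed = sample.int(1e6, 1))
    h <- csTriggeredSS(cs, ss)
    mean(h$normalized)
  })
  expect_equal(mean(means), 1, tolerance = 3 * sd(means) / sqrt(40))
  # hard 50-ms silence after each CS: bins in (0, 50] ms ~ 0, later ~ 1
  cs <- poissonTrain(1, 300, seed = 2, label = "complex")
  ss0 <- poissonTrain(30, 300, seed = 3)
  keep <- !zebellum:::.inWindows(spikeTimes(ss0), spikeTimes(cs),
                                 spikeTimes(cs) + 0.05)
  ss <- SpikeTrain(spikeTimes(ss0)[keep], "simple", 300)
  h <- csTriggeredSS(cs, ss)
  ctr <- h$binCenters
  expect_lt(max(h$normalized[ctr > 0 & ctr < 0.05]), 0.1)
  expect_equal(mean(h$normalized[ctr > 0.1]), 1, tolerance = 0.15)
  # fewer than ten triggers -> excluded
  h9 <- csTriggeredSS(SpikeTrain(1:9, "complex", 20), ss0)
  expect_true(h9$excluded)
})

test_that("context splitting partitions complex spikes", {
  p <- smallProtocol()
  bt <- BoutTable(data.frame(t_on = 1.0, t_off = 1.4))
  cs <- SpikeTrain(c(0.5, 1.2, 2.0), "complex", 10)
  sp <- splitContext(cs, bt, p)
  expect_equal(sp$motor, 2L)
  expect_setequal(sp$non_motor, c(1L, 3L))
  expect_length(c(sp$motor, sp$non_motor), nSpikes(cs))
  # no bouts -> all non-motor
  sp0 <- splitContext(cs, BoutTable(), p)
  expect_length(sp0$motor, 0L)
  expect_length(sp0$non_motor, 3L)
})

test_that("bout-triggered rates recover planted in-bout gain", {
  set.seed(4)
  onsets <- cumsum(runif(60, 2, 4))
  bt <- BoutTable(data.frame(t_on = onsets, t_off = onsets + 0.5))
  dur <- max(onsets) + 2
  # constant-rate train: flat aligned trace at the rate
  tr <- poissonTrain(12, dur, seed = 5)
  r1 <- boutTriggeredRate(tr, bt, "onset")
  expect_equal(mean(r1$rate), 12, tolerance = 0.1)
  smoothed <- stats::filter(r1$rate, rep(1 / 200, 200), sides = 2)
  expect_lt(diff(range(smoothed, na.rm = TRUE)), 6)
  # planted 2x in-bout gain: post/pre ratio ~ 2
  base <- poissonTrain(8, dur, seed = 6)
  extra <- poissonTrain(8, dur, seed = 7)
  keepX <- zebellum:::.inWindows(spikeTimes(extra), bouts(bt)$t_on,
                                 bouts(bt)$t_off)
  tr2 <- SpikeTrain(sort(c(spikeTimes(base), spikeTimes(extra)[keepX])),
                    "simple", dur)
  r2 <- boutTriggeredRate(tr2, bt, "onset")
  pre <- mean(r2$rate[r2$time < -0.1])
  expect_equal(r2$postOnsetMean / pre, 2, tolerance = 0.15)
  expect_error(boutTriggeredRate(tr, BoutTable()), "bouts")
})

test_that("Ljung-Box flags periodic in-bout spiking and is calibrated", {
  # periodic train at 25 Hz during bouts: p < 0.001, ACF peak at 40 ms
  onsets <- seq(1, 60, by = 3)
  bt <- BoutTable(data.frame(t_on = onsets, t_off = onsets + 1))
  spk <- unlist(lapply(onsets, function(o) o + seq(0.02, 0.98, by = 0.04)))
  res <- spikeAutocorrTest(SpikeTrain(spk, "granule", 62), bt)
  expect_lt(res$p_value, 0.001)
  expect_equal(res$lags[which.max(res$acf)], 0.040, tolerance = 1e-9)
  # Poisson null: rejection rate compatible with alpha (calibration)
  set.seed(8)
  ps <- replicate(200, {
    tr <- poissonTrain(40, 62, seed = sample.int(1e6, 1), label = "granule")
    spikeAutocorrTest(tr, bt)$p_value
  })
  alpha <- 0.05
  rej <- mean(ps < alpha)
  ci <- qbinom(c(0.025, 0.975), 200, alpha) / 200
  expect_gte(rej, ci[1])
  expect_lte(rej, ci[2])
  expect_error(spikeAutocorrTest(SpikeTrain(numeric(0), "granule", 62), bt),
               "fewer")
})

test_that("direction selectivity index follows the contrast definition", {
  expect_equal(directionSelectivity(
    c(forward = 10, reverse = 0, left = 0, right = 0)), 1)
  expect_equal(directionSelectivity(
    c(forward = 5, reverse = 5, left = 5, right = 5)), 0)
  expect_equal(directionSelectivity(
    c(forward = 3, reverse = 1, left = 2, right = 2)), 0.5)
  expect_error(directionSelectivity(
    c(forward = 0, reverse = 0, left = 0, right = 0)), "all-zero")
  # vector-sum alternative is bounded and zero for symmetric input
  expect_equal(directionSelectivity(
    c(forward = 5, reverse = 5, left = 5, right = 5), method = "vector"), 0)
})

test_that("first-spike latency statistics recover planted latencies", {
  ev <- seq(10, 100, by = 10)
  cs <- SpikeTrain(ev + 0.2, "complex", 110)
  r <- firstSpikeLatency(cs, ev)
  expect_equal(r$meanLatency, 0.2)
  expect_equal(r$jitterSD, 0)
  expect_equal(r$responseProbability, 1)
  # no CS in any window
  r0 <- firstSpikeLatency(SpikeTrain(numeric(0), "complex", 110), ev)
  expect_equal(r0$responseProbability, 0)
  expect_true(is.na(r0$meanLatency))
  # planted latency 250 +/- 5 ms recovered within 2 ms
  set.seed(9)
  evts <- seq(5, 600, by = 6)
  lat <- rnorm(length(evts), 0.250, 0.005)
  csj <- SpikeTrain(evts + lat, "complex", 610)
  rj <- firstSpikeLatency(csj, evts)
  expect_equal(rj$meanLatency, 0.250, tolerance = 0.002 / 0.250)
  expect_equal(rj$jitterSD, 0.005, tolerance = 0.3)
})

test_that("per-event CS probability matches the Poisson prediction", {
  ev <- seq(5, 95, by = 5)
  cs <- SpikeTrain(ev + 0.1, "complex", 100)
  expect_equal(csProbabilityPerEvent(cs, ev), 1)
  half <- SpikeTrain(ev[seq(1, length(ev), by = 2)] + 0.1, "complex", 100)
  expect_equal(csProbabilityPerEvent(half, ev), 0.5, tolerance = 0.06)
  # Poisson CS at rate r, window w: P ~ 1 - exp(-r w)
  set.seed(10)
  probs <- replicate(30, {
    tr <- poissonTrain(2, 200, seed = sample.int(1e6, 1), label = "complex")
    csProbabilityPerEvent(tr, seq(2, 198, by = 2), window = 0.5)
  })
  expect_equal(mean(probs), 1 - exp(-2 * 0.5), tolerance = 0.02)
})

test_that("post-CS window effects separate motor and non-motor contexts", {
  # planted 50-ms post-CS silence plus an in-bout SS gain; motor complex
  # spikes ride at bout onset, so simple spiking returns to the elevated
  # in-bout level once the pause ends: the normalized motor-minus-non-motor
  # difference is ~0 only inside the first 50 ms and positive thereafter
  set.seed(11)
  dur <- 600
  onsets <- cumsum(runif(150, 2.5, 4.5))
  onsets <- onsets[onsets < dur - 2]
  bt <- BoutTable(data.frame(t_on = onsets, t_off = onsets + 0.8))
  bon <- bouts(bt)$t_on; boff <- bouts(bt)$t_off
  ssAll <- poissonTrain(10, dur, seed = 12)
  extra <- poissonTrain(10, dur, seed = 13)
  inB <- zebellum:::.inWindows(spikeTimes(extra), bon, boff)
  ss0 <- sort(c(spikeTimes(ssAll), spikeTimes(extra)[inB]))
  csMotor <- bon + 0.02
  csOther <- poissonTrain(0.8, dur, seed = 14, label = "complex")
  outB <- !zebellum:::.inWindows(spikeTimes(csOther), bon - 0.5, boff + 0.5)
  csOther <- spikeTimes(csOther)[outB]
  csAll <- sort(c(csMotor, csOther))
  keepSS <- !zebellum:::.inWindows(ss0, csAll, csAll + 0.05)
  ss <- SpikeTrain(ss0[keepSS], "simple", dur)
  hM <- csTriggeredSS(SpikeTrain(csMotor, "complex", dur), ss)
  hN <- csTriggeredSS(SpikeTrain(csOther, "complex", dur), ss)
  dd <- hM$normalized - hN$normalized
  ctr <- hM$binCenters
  expect_lt(mean(abs(dd[ctr > 0 & ctr <= 0.05])), 0.35)
  expect_gt(mean(dd[ctr > 0.07 & ctr <= 0.25]), 0.3)
})
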