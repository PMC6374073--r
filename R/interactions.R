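#' Complex-spike-triggered simple spike histogram
#'
#' Mean simple spike count in bins (default 10 ms) around each complex
#' spike, normalized to the mean per-bin count over the 100 ms preceding
#' the trigger. Cells with fewer than `minTriggers` complex spikes are
#' flagged excluded.
#'
#' @param cs,ss [SpikeTrain-class] trains.
#' @param window numeric length-2, histogram window around the trigger, s.
#' @param bin bin width, s.
#' @param normWindow length of the pre-trigger normalization period, s.
#' @param minTriggers minimum trigger count (default 10).
#' @return list of class "TriggeredHistogram": `binEdges`, `binCenters`,
#'   `counts` (mean per-trigger), `normalized`, `nTriggers`, `excluded`.
#' @export
csTriggeredSS <- function(cs, ss, window = c(-0.3, 0.3), bin = 0.010,
                          normWindow = 0.100, minTriggers = 10L) {
  trig <- spikeTimes(cs)
  st <- spikeTimes(ss)
  edges <- seq(window[1], window[2], by = bin)
  nb <- length(edges) - 1L
  counts <- numeric(nb)
  for (t0 in trig) {
    rel <- st - t0
    rel <- rel[rel >= window[1] & rel < window[2]]
    if (length(rel))
      counts <- counts + tabulate(findInterval(rel, edges), nbins = nb)
  }
  nT <- length(trig)
  excluded <- nT < minTriggers
  meanCounts <- if (nT > 0) counts / nT else counts
  # normalization: mean per-bin count over the preceding normWindow
  pre <- vapply(trig, function(t0)
    sum(st >= t0 - normWindow & st < t0), numeric(1))
  base <- if (nT > 0) mean(pre) / (normWindow / bin) else NA_real_
  normalized <- if (!is.na(base) && base > 0) meanCounts / base
                else rep(NA_real_, nb)
  structure(list(binEdges = edges, binCenters = edges[-1] - bin / 2,
                 counts = meanCounts, normalized = normalized,
                 baseline = base, nTriggers = nT, excluded = excluded),
            class = "TriggeredHistogram")
}

#' @export
print.TriggeredHistogram <- function(x, ...) {
  cat(sprintf("TriggeredHistogram: %d triggers, %d bins%s\n", x$nTriggers,
              length(x$counts), if (x$excluded) " [excluded: <10 triggers]"
              else ""))
  invisible(x)
}

#' Split complex spikes by behavioral and sensory context
#'
#' Assigns each complex spike to the motor context (inside a fictive bout)
#' or non-motor context, and to sensory subsets by the stimulus epoch
#' containing it (full epoch extent): preferred stimulus, other stimulus,
#' or blank.
#'
#' @param cs a [SpikeTrain-class].
#' @param boutTable a [BoutTable-class].
#' @param protocol a [StimulusProtocol-class].
#' @param preferredWindows optional list with `on`/`off` vectors marking the
#'   preferred-stimulus epochs.
#' @return list of class "ContextSplit" with index vectors `motor`,
#'   `non_motor`, `preferred_sensory`, `other_sensory`, `blank`.
#' @export
splitContext <- function(cs, boutTable, protocol, preferredWindows = NULL) {
  t <- spikeTimes(cs)
  b <- bouts(boutTable)
  motor <- .inWindows(t, b$t_on, b$t_off)
  tr <- trials(protocol)
  blankTr <- tr[tr$blank, , drop = FALSE]
  inBlank <- .inWindows(t, blankTr$t_start, blankTr$t_end)
  ep <- epochs(protocol)
  stim <- ep[ep$kind != "blank", , drop = FALSE]
  inStim <- .inWindows(t, stim$t_on, stim$t_off)
  pref <- if (!is.null(preferredWindows))
    .inWindows(t, preferredWindows$on, preferredWindows$off)
  else rep(FALSE, length(t))
  structure(list(
    motor = which(motor), non_motor = which(!motor),
    preferred_sensory = which(pref & !inBlank),
    other_sensory = which(inStim & !pref),
    blank = which(inBlank), times = t), class = "ContextSplit")
}

#' Bout-triggered mean firing rate
#'
#' Averages 20-ms-filtered firing-rate segments aligned to bout onsets or
#' offsets, and reports the 300-ms post-onset mean used for sorting cells.
#'
#' @param train a [SpikeTrain-class].
#' @param boutTable a [BoutTable-class] with at least one bout.
#' @param align "onset" or "offset".
#' @param window numeric length-2 window around the alignment point, s.
#' @param rate sampling rate of the rate trace, samples/s.
#' @param filterWidth rate filter width, s.
#' @return list: `time` (s, relative), `rate` (Hz, mean over bouts),
#'   `postOnsetMean` (Hz over [0, 0.3] s), `nBouts`.
#' @export
boutTriggeredRate <- function(train, boutTable, align = c("onset", "offset"),
                              window = c(-0.5, 1.0), rate = 1000,
                              filterWidth = 0.020) {
  align <- match.arg(align)
  b <- bouts(boutTable)
  if (!nrow(b)) stop("no bouts to align to")
  dur <- if (is.na(train@duration)) max(b$t_off) + window[2] else
    train@duration
  rt <- rateFromTrain(train, rate, filterWidth, duration = dur)
  x <- tsValues(rt)
  ref <- if (align == "onset") b$t_on else b$t_off
  i0 <- round(window[1] * rate); i1 <- round(window[2] * rate) - 1L
  segs <- matrix(NA_real_, length(ref), i1 - i0 + 1L)
  for (k in seq_along(ref)) {
    idx <- round(ref[k] * rate) + 1L + (i0:i1)
    ok <- idx >= 1L & idx <= length(x)
    segs[k, ok] <- x[idx[ok]]
  }
  m <- colMeans(segs, na.rm = TRUE)
  tt <- (i0:i1) / rate
  post <- mean(m[tt >= 0 & tt < 0.3])
  list(time = tt, rate = m, postOnsetMean = post, nBouts = length(ref))
}

#' Ljung-Box test of in-bout spike autocorrelation
#'
#' Bins in-bout spikes (default 5-ms bins), concatenates bouts, computes
#' the autocorrelation, and tests it with the Ljung-Box Q statistic
#' (chi-square with `lags` degrees of freedom).
#'
#' @param train a [SpikeTrain-class].
#' @param boutTable a [BoutTable-class].
#' @param bin bin width, s.
#' @param lags number of lags entering the Q statistic.
#' @param minSpikes minimum in-bout spike count.
#' @return list with `acf`, `lags` (s), `statistic`, `p_value`, `nSpikes`.
#' @export
spikeAutocorrTest <- function(train, boutTable, bin = 0.005, lags = 20L,
                              minSpikes = 20L) {
  b <- bouts(boutTable)
  st <- spikeTimes(train)
  segs <- list()
  nIn <- 0L
  for (i in seq_len(nrow(b))) {
    sel <- st >= b$t_on[i] & st < b$t_off[i]
    nIn <- nIn + sum(sel)
    nb <- max(1L, floor((b$t_off[i] - b$t_on[i]) / bin))
    segs[[i]] <- .binEvents(st[sel] - b$t_on[i], 1 / bin, nb)
  }
  if (nIn < minSpikes)
    stop("fewer than ", minSpikes, " in-bout spikes")
  x <- unlist(segs)
  lags <- min(lags, length(x) - 1L)
  bt <- stats::Box.test(x, lag = lags, type = "Ljung-Box")
  ac <- stats::acf(x, lag.max = lags, plot = FALSE)$acf[-1, 1, 1]
  list(acf = ac, lags = seq_len(lags) * bin,
       statistic = unname(bt$statistic), p_value = bt$p.value,
       nSpikes = nIn)
}

#' Direction selectivity index
#'
#' Contrast between the preferred direction (largest response) and its
#' opposite: (R_pref - R_opp) / (R_pref + R_opp). The alternative
#' vector-sum index (1 - circular variance over the four cardinal
#' responses) is available via `method = "vector"`.
#'
#' @param rates named numeric responses for directions forward, reverse,
#'   left, right (all >= 0).
#' @param method "opposite" (default) or "vector".
#' @return index in [0, 1].
#' @export
directionSelectivity <- function(rates, method = c("opposite", "vector")) {
  method <- match.arg(method)
  need <- c("forward", "reverse", "left", "right")
  if (!all(need %in% names(rates))) stop("need all four cardinal responses")
  r <- rates[need]
  if (any(r < 0)) stop("responses must be non-negative")
  if (sum(r) == 0) stop("all-zero responses have no direction preference")
  if (method == "opposite") {
    opp <- c(forward = "reverse", reverse = "forward",
             left = "right", right = "left")
    pref <- need[which.max(r)]
    (r[[pref]] - r[[opp[[pref]]]]) / (r[[pref]] + r[[opp[[pref]]]])
  } else {
    ang <- c(forward = 0, reverse = pi, left = pi / 2, right = -pi / 2)
    v <- sum(r * exp(1i * ang[need]))
    Mod(v) / sum(r)
  }
}

#' First-spike latency statistics around events
#'
#' For each event, the first complex spike within the response window; the
#' mean and SD of the latency over hits, and the fraction of events with a
#' response.
#'
#' @param cs a [SpikeTrain-class].
#' @param events event onset times, s.
#' @param window response window length, s.
#' @return list: `meanLatency`, `jitterSD` (s), `responseProbability`,
#'   `latencies` (NA for misses).
#' @export
firstSpikeLatency <- function(cs, events, window = 0.5) {
  if (!length(events)) stop("at least one event is required")
  st <- spikeTimes(cs)
  lat <- vapply(events, function(t0) {
    d <- st[st >= t0 & st < t0 + window] - t0
    if (length(d)) min(d) else NA_real_
  }, numeric(1))
  hits <- lat[!is.na(lat)]
  list(meanLatency = if (length(hits)) mean(hits) else NA_real_,
       jitterSD = if (length(hits) > 1) stats::sd(hits) else
         if (length(hits) == 1) 0 else NA_real_,
       responseProbability = length(hits) / length(events),
       latencies = lat)
}

#' Probability of a complex spike per event
#'
#' Fraction of events with at least one complex spike within the window.
#'
#' @inheritParams firstSpikeLatency
#' @return probability in [0, 1].
#' @export
csProbabilityPerEvent <- function(cs, events, window = 0.5) {
  if (!length(events)) stop("at least one event is required")
  st <- spikeTimes(cs)
  mean(vapply(events, function(t0)
    any(st >= t0 & st < t0 + window), logical(1)))
}
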