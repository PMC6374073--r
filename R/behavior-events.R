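#' Moving-standard-deviation envelope of a trace
#'
#' Centered rolling standard deviation of a ventral-root or tail trace,
#' same length as the input (windows shrink to the valid range at the
#' edges). This is the standard envelope from which fictive swim bouts and
#' vigor are derived.
#'
#' @param trace a [TimeSeries-class].
#' @param sdWindow window length, s (default 10 ms, suited to resolving the
#'   ~27 Hz fictive tail-beat cycle; use 50 ms for tail traces).
#' @return A [TimeSeries-class] envelope on the same clock.
#' @export
envelopeSD <- function(trace, sdWindow = 0.010) {
  stopifnot(is(trace, "TimeSeries"))
  w <- round(sdWindow * tsRate(trace))
  if (w < 2) stop("sdWindow must span at least 2 samples")
  TimeSeries(.rollingSD(tsValues(trace), w), rate = tsRate(trace),
             t0 = trace@t0)
}

#' Detect swim bouts from an envelope
#'
#' Supra-threshold runs of the envelope are candidate episodes; runs
#' separated by less than `mergeGap` (default 100 ms) are considered part of
#' the same bout and merged. Vigor summaries per bout are computed from the
#' median-filtered envelope.
#'
#' @param env envelope [TimeSeries-class] (from [envelopeSD()]).
#' @param threshold envelope threshold (> 0). Default 3x the envelope
#'   median, a rest-dominated robust scale.
#' @param mergeGap maximum sub-threshold gap inside one bout, s.
#' @param vigorMedianWindow median-filter window for vigor summaries, s.
#' @return A [BoutTable-class] (possibly empty).
#' @export
detectBouts <- function(env, threshold = NULL, mergeGap = 0.100,
                        vigorMedianWindow = 0.200) {
  stopifnot(is(env, "TimeSeries"))
  x <- tsValues(env)
  rate <- tsRate(env)
  if (is.null(threshold)) threshold <- 3 * stats::median(x)
  if (threshold <= 0) stop("threshold must be positive")
  above <- x > threshold
  if (!any(above)) return(BoutTable())
  d <- diff(c(FALSE, above, FALSE))
  on <- env@t0 + (which(d == 1L) - 1L) / rate
  off <- env@t0 + (which(d == -1L) - 1L) / rate
  m <- .mergeIntervals(on, off, mergeGap)
  vig <- .rollingMedian(x, round(vigorMedianWindow * rate))
  tt <- tsTimes(env)
  mv <- pv <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) {
    sel <- tt >= m$on[i] & tt < m$off[i]
    mv[i] <- mean(vig[sel])
    pv[i] <- max(vig[sel])
  }
  BoutTable(data.frame(t_on = m$on, t_off = m$off, mean_vigor = mv,
                       peak_vigor = pv))
}

# Merge sorted intervals whose gap is strictly less than mergeGap.
# The convention at the boundary: a gap exactly equal to mergeGap is NOT
# merged ("separated by an interval of less than" the gap is merged).
.mergeIntervals <- function(on, off, mergeGap) {
  if (!length(on)) return(data.frame(on = numeric(0), off = numeric(0)))
  o <- order(on)
  on <- on[o]; off <- off[o]
  ro <- on[1]; rf <- off[1]
  outOn <- outOff <- numeric(0)
  for (i in seq_along(on)[-1]) {
    if (on[i] - rf < mergeGap) {
      rf <- max(rf, off[i])
    } else {
      outOn <- c(outOn, ro); outOff <- c(outOff, rf)
      ro <- on[i]; rf <- off[i]
    }
  }
  data.frame(on = c(outOn, ro), off = c(outOff, rf))
}

#' Swim vigor from a tail trace
#'
#' Rolling standard deviation over a 50-ms buffer, then median filtered
#' (default 200 ms) so that vigor is carried across the whole bout rather
#' than oscillating with individual tail beats.
#'
#' @param tail a [TimeSeries-class] tail trace (>= 40 samples/s).
#' @param sdWindow rolling-SD window, s.
#' @param medianWindow median-filter window, s (0 to disable).
#' @return A [TimeSeries-class] vigor trace.
#' @export
vigorTrace <- function(tail, sdWindow = 0.050, medianWindow = 0.200) {
  stopifnot(is(tail, "TimeSeries"))
  if (tsRate(tail) < 40) stop("tail trace must be sampled at >= 40 samples/s")
  env <- .rollingSD(tsValues(tail), round(sdWindow * tsRate(tail)))
  if (medianWindow > 0)
    env <- .rollingMedian(env, round(medianWindow * tsRate(tail)))
  TimeSeries(env, rate = tsRate(tail), t0 = tail@t0)
}

#' Fictive swim frequency from the ventral-root autocorrelation
#'
#' Binarizes the envelope at a threshold, restricts to in-bout segments,
#' pools the per-bout autocorrelation of the binary signal, and reads the
#' swim frequency from the lag of the first significant positive peak.
#' Significance is assessed against a shuffled null: in-bout samples are
#' permuted within each bout and the 95% pointwise band of the shuffled
#' autocorrelation is the significance bound.
#'
#' @param env envelope [TimeSeries-class].
#' @param threshold binarization threshold (default 3x envelope median).
#' @param bouts optional [BoutTable-class]; detected from `env` if missing.
#' @param maxLag maximum lag examined, s.
#' @param nShuffle number of within-bout permutations for the null band.
#' @param interpolate parabolic interpolation of the peak lag (reduces lag
#'   quantization at moderate sampling rates).
#' @return list with `frequency` (Hz, NA when flagged), `lag` (s), `acf`,
#'   `lags`, and `defined` (FALSE when no significant peak exists).
#' @export
swimFrequency <- function(env, threshold = NULL, bouts = NULL, maxLag = 0.25,
                          nShuffle = 100, interpolate = TRUE) {
  stopifnot(is(env, "TimeSeries"))
  x <- tsValues(env)
  rate <- tsRate(env)
  if (is.null(threshold)) threshold <- 3 * stats::median(x)
  if (is.null(bouts)) bouts <- detectBouts(env, threshold = threshold)
  b <- bouts(bouts)
  binary <- as.numeric(x > threshold)
  tt <- tsTimes(env)
  nlag <- round(maxLag * rate)
  segs <- list()
  for (i in seq_len(nrow(b))) {
    sel <- which(tt >= b$t_on[i] & tt < b$t_off[i])
    if (length(sel) > 3) segs[[length(segs) + 1L]] <- binary[sel]
  }
  flagged <- list(frequency = NA_real_, lag = NA_real_, acf = NULL,
                  lags = NULL, defined = FALSE)
  if (!length(segs)) return(flagged)
  pooled <- .pooledACF(segs, nlag)
  if (all(is.na(pooled))) return(flagged)
  null <- matrix(NA_real_, nShuffle, nlag)
  for (s in seq_len(nShuffle))
    null[s, ] <- .pooledACF(lapply(segs, sample), nlag)
  bound <- apply(null, 2, stats::quantile, probs = 0.95, na.rm = TRUE)
  lags <- seq_len(nlag) / rate
  # first local maximum exceeding the null band
  pk <- NA_integer_
  for (k in 2:(nlag - 1)) {
    if (is.na(pooled[k])) next
    if (pooled[k] > bound[k] && pooled[k] >= pooled[k - 1] &&
        pooled[k] >= pooled[k + 1] && pooled[k] > 0) { pk <- k; break }
  }
  if (is.na(pk)) return(flagged)
  lag <- lags[pk]
  if (interpolate && pk > 1 && pk < nlag &&
      all(is.finite(pooled[(pk - 1):(pk + 1)]))) {
    y1 <- pooled[pk - 1]; y2 <- pooled[pk]; y3 <- pooled[pk + 1]
    den <- y1 - 2 * y2 + y3
    if (abs(den) > .Machine$double.eps) {
      delta <- 0.5 * (y1 - y3) / den
      lag <- lag + max(-0.5, min(0.5, delta)) / rate
    }
  }
  list(frequency = 1 / lag, lag = lag, acf = pooled, lags = lags,
       defined = TRUE)
}

# Pooled autocovariance over segments (each demeaned), normalized to the
# pooled lag-0 autocovariance.
.pooledACF <- function(segs, nlag) {
  num <- numeric(nlag)
  den <- 0
  cnt <- integer(nlag)
  for (s in segs) {
    n <- length(s)
    kmax <- min(nlag, n - 1L)
    if (kmax < 1) next
    acv <- stats::acf(s, lag.max = kmax, type = "covariance",
                      demean = TRUE, plot = FALSE)$acf[, 1, 1]
    den <- den + acv[1] * n
    k <- seq_len(kmax)
    num[k] <- num[k] + acv[k + 1L] * n
    cnt[k] <- cnt[k] + 1L
  }
  if (den <= 0) return(rep(NA_real_, nlag))
  out <- num / den
  out[cnt == 0L] <- NA_real_
  out
}

#' Eye kinematic channels from left/right eye position traces
#'
#' Builds the twelve-channel decomposition of eye movement used as motor
#' regressors: per eye, signed position, positive- and negative-rectified
#' position, signed velocity (smoothed first difference), and positive- and
#' negative-rectified velocity.
#'
#' @param left,right [TimeSeries-class] eye position traces on one clock.
#' @param velocitySmooth smoothing width for the first difference, s.
#' @return named list of 12 [TimeSeries-class] channels
#'   (`L_pos`, `L_pos_plus`, ..., `R_vel_minus`).
#' @export
eyeKinematics <- function(left, right, velocitySmooth = 0.050) {
  stopifnot(is(left, "TimeSeries"), is(right, "TimeSeries"))
  if (tsRate(left) != tsRate(right) || length(left) != length(right) ||
      left@t0 != right@t0)
    stop("left and right eye traces must share one clock")
  rate <- tsRate(left)
  out <- list()
  for (side in c("L", "R")) {
    p <- if (side == "L") tsValues(left) else tsValues(right)
    v <- c(0, diff(p)) * rate
    if (velocitySmooth > 0) v <- .boxcarFilter(v, rate, velocitySmooth)
    chans <- list(pos = p, pos_plus = pmax(p, 0), pos_minus = pmax(-p, 0),
                  vel = v, vel_plus = pmax(v, 0), vel_minus = pmax(-v, 0))
    for (nm in names(chans))
      out[[paste(side, nm, sep = "_")]] <-
        TimeSeries(chans[[nm]], rate = rate, t0 = left@t0)
  }
  out
}
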