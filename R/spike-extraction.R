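#' Spike sorting parameters for cell-attached recordings
#'
#' Complex and simple spikes in cell-attached Purkinje recordings separate
#' cleanly by event amplitude, so sorting reduces to amplitude thresholding
#' of the high-pass filtered trace. A short period after each complex spike
#' is blanked so that the multiphasic complex spike waveform is not counted
#' again as simple spikes.
#'
#' @param csThreshold amplitude threshold above which an excursion is a
#'   complex spike (NA to initialize automatically by an Otsu split of
#'   excursion peak amplitudes).
#' @param ssThreshold amplitude threshold above which an excursion is a
#'   spike at all (NA for automatic initialization).
#' @param highpassCutoff high-pass corner frequency, Hz (1-10).
#' @param blankAfterCS blanking period after each complex spike, s.
#' @param rateFilterWidth boxcar width used when converting trains to rates, s.
#' @param rectify if TRUE threshold the rectified (absolute) trace rather
#'   than signed positive excursions.
#' @return A list of class "SortingParams".
#' @export
sortingParams <- function(csThreshold = NA_real_, ssThreshold = NA_real_,
                          highpassCutoff = 3, blankAfterCS = 0.0025,
                          rateFilterWidth = 0.020, rectify = FALSE) {
  if (!is.na(csThreshold) && !is.na(ssThreshold) &&
      !(csThreshold > ssThreshold && ssThreshold > 0))
    stop("thresholds must satisfy csThreshold > ssThreshold > 0")
  if (blankAfterCS < 0) stop("blankAfterCS must be >= 0")
  if (highpassCutoff < 1 || highpassCutoff > 10)
    stop("highpassCutoff must lie in [1, 10] Hz")
  structure(list(csThreshold = csThreshold, ssThreshold = ssThreshold,
                 highpassCutoff = highpassCutoff, blankAfterCS = blankAfterCS,
                 rateFilterWidth = rateFilterWidth, rectify = rectify),
            class = "SortingParams")
}

# Zero-phase first-order high-pass (forward-backward butterworth).
.highpass <- function(x, rate, cutoff) {
  bf <- signal::butter(1, cutoff / (rate / 2), type = "high")
  signal::filtfilt(bf, x)
}

# Otsu threshold on a vector of amplitudes: the split maximizing
# between-class variance over a fine quantile grid.
.otsu <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n < 2L) return(max(x))
  best <- -Inf
  thr <- x[1]
  cands <- unique(stats::quantile(x, probs = seq(0.02, 0.98, by = 0.02),
                                  names = FALSE, type = 1))
  for (cand in cands) {
    lo <- x[x <= cand]; hi <- x[x > cand]
    if (!length(lo) || !length(hi)) next
    w <- length(lo) / n
    bc <- w * (1 - w) * (mean(lo) - mean(hi))^2
    if (bc > best) { best <- bc; thr <- cand }
  }
  thr
}

# Contiguous supra-threshold excursions of x; returns peak index and peak
# value per excursion.
.excursions <- function(x, thr) {
  above <- x > thr
  if (!any(above)) return(data.frame(peak_idx = integer(0),
                                     peak = numeric(0)))
  d <- diff(c(FALSE, above, FALSE))
  starts <- which(d == 1L)
  ends <- which(d == -1L) - 1L
  peak_idx <- mapply(function(s, e) s - 1L + which.max(x[s:e]), starts, ends)
  data.frame(peak_idx = as.integer(peak_idx), peak = x[peak_idx])
}

#' Detect complex and simple spikes by amplitude thresholding
#'
#' High-pass filters a cell-attached trace (zero-phase, first-order), finds
#' contiguous supra-threshold excursions, and classifies each excursion by
#' its peak amplitude: above `csThreshold` it is a complex spike, otherwise a
#' simple spike. One event is emitted per excursion, timed at the excursion
#' peak. Simple spikes within `blankAfterCS` (default 2.5 ms) after a
#' complex spike are discarded so the complex spike waveform cannot recross
#' the simple spike threshold.
#'
#' When thresholds are NA they are initialized automatically: the spike
#' floor is 4x the median absolute deviation of the filtered trace and the
#' CS/SS boundary is an Otsu split of the excursion peak amplitudes.
#'
#' @param trace a [TimeSeries-class] voltage trace (>= 500 samples/s).
#' @param params a [sortingParams()] object.
#' @return list with elements `cs` and `ss`, both [SpikeTrain-class].
#' @examples
#' tr <- renderEphysTrace(SpikeTrain(c(0.5, 1.5)), SpikeTrain(1.0, "simple"),
#'                        rate = 1000, duration = 2, noiseSD = 0)
#' detectSpikes(tr, sortingParams(csThreshold = 5, ssThreshold = 1))
#' @export
detectSpikes <- function(trace, params = sortingParams()) {
  stopifnot(is(trace, "TimeSeries"))
  if (tsRate(trace) < 500)
    stop("trace sampling rate must be at least 500 samples/s")
  x <- tsValues(trace)
  if (!length(x) || any(!is.finite(x))) stop("flat or non-finite trace")
  xf <- .highpass(x, tsRate(trace), params$highpassCutoff)
  if (params$rectify) xf <- abs(xf)
  if (stats::sd(xf) == 0) stop("flat trace")
  ssThr <- params$ssThreshold
  csThr <- params$csThreshold
  if (is.na(ssThr))
    ssThr <- 4 * stats::mad(xf)
  exc <- .excursions(xf, ssThr)
  if (is.na(csThr))
    csThr <- if (nrow(exc) >= 2) .otsu(exc$peak) else Inf
  if (!(csThr > ssThr)) stop("thresholds must satisfy csThreshold > ssThreshold")
  tt <- trace@t0 + (exc$peak_idx - 1L) / tsRate(trace)
  isCS <- exc$peak > csThr
  csT <- tt[isCS]
  ssT <- tt[!isCS]
  if (length(csT) && length(ssT) && params$blankAfterCS > 0) {
    blanked <- vapply(ssT, function(t)
      any(t > csT & t <= csT + params$blankAfterCS), logical(1))
    ssT <- ssT[!blanked]
  }
  dur <- tsDuration(trace)
  list(cs = SpikeTrain(csT, "complex", duration = trace@t0 + dur),
       ss = SpikeTrain(ssT, "simple", duration = trace@t0 + dur))
}

#' Convert a spike train to a firing-rate time series
#'
#' Convolves the delta train with a unit-area boxcar (default 20 ms), so the
#' integral of the output equals the spike count and the units are Hz.
#'
#' @param train a [SpikeTrain-class].
#' @param rate output sampling rate, samples/s.
#' @param width boxcar width, s.
#' @param duration output duration, s (defaults to the train's duration).
#' @param t0 output start time, s.
#' @return A [TimeSeries-class] firing rate in Hz.
#' @export
rateFromTrain <- function(train, rate, width = 0.020, duration = NULL,
                          t0 = 0) {
  stopifnot(is(train, "SpikeTrain"), width > 0)
  if (is.null(duration)) duration <- train@duration
  if (is.na(duration)) stop("duration must be given when the train has none")
  n <- round(duration * rate)
  counts <- .binEvents(spikeTimes(train), rate, n, t0 = t0)
  TimeSeries(.boxcarFilter(counts * rate, rate, width), rate = rate, t0 = t0)
}

#' Baseline firing rate from blank trials or pre-stimulus windows
#'
#' Uses blank trials (no visual stimulus) when present; otherwise the 2-s
#' window at the beginning of each stimulus trial before the first stimulus
#' onset. The rate is the pooled count over pooled duration.
#'
#' @param train a [SpikeTrain-class].
#' @param protocol a [StimulusProtocol-class].
#' @param useBlanks if FALSE, ignore blank trials even when present.
#' @param preWindow length of the pre-stimulus window, s.
#' @return baseline rate, Hz.
#' @export
baselineRate <- function(train, protocol, useBlanks = TRUE, preWindow = 2) {
  stopifnot(is(train, "SpikeTrain"), is(protocol, "StimulusProtocol"))
  tr <- trials(protocol)
  ep <- epochs(protocol)
  blank <- tr[tr$blank, , drop = FALSE]
  if (useBlanks && nrow(blank)) {
    on <- blank$t_start; off <- blank$t_end
  } else {
    stim <- tr[!tr$blank, , drop = FALSE]
    on <- off <- numeric(0)
    for (i in seq_len(nrow(stim))) {
      e <- ep[ep$t_on >= stim$t_start[i] - 1e-9 &
              ep$t_on < stim$t_end[i] & ep$kind != "blank", , drop = FALSE]
      first <- if (nrow(e)) min(e$t_on) else stim$t_end[i]
      if (first >= stim$t_start[i] + preWindow) {
        on <- c(on, stim$t_start[i])
        off <- c(off, stim$t_start[i] + preWindow)
      }
    }
    if (!length(on))
      stop("no eligible baseline window: no blank trials and stimulation ",
           "starts within ", preWindow, " s of every trial start")
  }
  .rateInWindows(spikeTimes(train), on, off)
}
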