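#' @import methods
NULL

#' Uniformly sampled time series
#'
#' Container for a regularly sampled signal (electrophysiology trace,
#' envelope, vigor, dF/F, regressor column). Values are stored with the
#' sampling rate in samples/s and the time of the first sample in seconds.
#'
#' @slot values numeric vector of samples.
#' @slot rate sampling rate, samples/s.
#' @slot t0 time of the first sample, s.
#'
#' @exportClass TimeSeries
setClass("TimeSeries",
  representation(values = "numeric", rate = "numeric", t0 = "numeric"),
  prototype(values = numeric(0), rate = 1, t0 = 0))

setValidity("TimeSeries", function(object) {
  msg <- NULL
  if (length(object@rate) != 1L || !is.finite(object@rate) || object@rate <= 0)
    msg <- c(msg, "'rate' must be a single positive number")
  if (length(object@t0) != 1L || !is.finite(object@t0))
    msg <- c(msg, "'t0' must be a single finite number")
  if (is.null(msg)) TRUE else msg
})

#' Construct a TimeSeries
#'
#' @param values numeric vector of samples.
#' @param rate sampling rate in samples/s.
#' @param t0 time of the first sample (s).
#' @return A [TimeSeries-class] object.
#' @examples
#' ts <- TimeSeries(sin(seq(0, 2 * pi, length.out = 100)), rate = 100)
#' tsRate(ts)
#' @export
TimeSeries <- function(values, rate, t0 = 0) {
  new("TimeSeries", values = as.numeric(values), rate = as.numeric(rate),
      t0 = as.numeric(t0))
}

#' Labelled spike train
#'
#' Sorted event times with a label identifying the spike type.
#'
#' @slot times strictly increasing spike times, s.
#' @slot label one of "complex", "simple", "granule".
#' @slot duration recording duration the train was observed over, s.
#'
#' @exportClass SpikeTrain
setClass("SpikeTrain",
  representation(times = "numeric", label = "character", duration = "numeric"),
  prototype(times = numeric(0), label = "complex", duration = NA_real_))

setValidity("SpikeTrain", function(object) {
  msg <- NULL
  if (is.unsorted(object@times, strictly = TRUE))
    msg <- c(msg, "'times' must be strictly increasing")
  if (!object@label %in% c("complex", "simple", "granule"))
    msg <- c(msg, "'label' must be complex, simple or granule")
  if (length(object@times) && !is.na(object@duration) &&
      (min(object@times) < 0 || max(object@times) > object@duration))
    msg <- c(msg, "spike times must lie within [0, duration]")
  if (is.null(msg)) TRUE else msg
})

#' Construct a SpikeTrain
#'
#' @param times spike times in seconds (sorted; duplicates dropped).
#' @param label spike type: "complex", "simple" or "granule".
#' @param duration recording duration in seconds (NA if unknown).
#' @return A [SpikeTrain-class] object.
#' @export
SpikeTrain <- function(times, label = c("complex", "simple", "granule"),
                       duration = NA_real_) {
  label <- match.arg(label)
  times <- sort(unique(as.numeric(times)))
  new("SpikeTrain", times = times, label = label,
      duration = as.numeric(duration))
}

#' Visual stimulus protocol
#'
#' Ordered stimulus epochs plus the trial layout of a session. Epochs carry
#' kind (grating, windmill, flash, blank), direction, speed or sinusoid
#' parameters, luminance level and on/off times; trials mark which stretches
#' of the session are stimulus trials and which are blanks.
#'
#' @slot epochs data.frame with columns kind, direction, speed, freq_hz,
#'   amplitude, luminance, t_on, t_off.
#' @slot trials data.frame with columns trial, t_start, t_end, blank.
#'
#' @exportClass StimulusProtocol
setClass("StimulusProtocol",
  representation(epochs = "data.frame", trials = "data.frame"))

setValidity("StimulusProtocol", function(object) {
  msg <- NULL
  need <- c("kind", "direction", "speed", "freq_hz", "amplitude",
            "luminance", "t_on", "t_off")
  if (!all(need %in% names(object@epochs)))
    msg <- c(msg, "epochs must have kind/direction/speed/freq_hz/amplitude/luminance/t_on/t_off")
  else {
    e <- object@epochs
    if (nrow(e) && any(e$t_off <= e$t_on))
      msg <- c(msg, "every epoch must have t_off > t_on")
    if (nrow(e) && any(!e$kind %in% c("grating", "windmill", "flash", "blank")))
      msg <- c(msg, "unknown epoch kind")
    # non-overlap within a channel (motion epochs may coexist with flashes)
    for (ch in unique(e$kind)) {
      ee <- e[e$kind == ch, , drop = FALSE]
      ee <- ee[order(ee$t_on), , drop = FALSE]
      if (nrow(ee) > 1 && any(ee$t_on[-1] < ee$t_off[-nrow(ee)] - 1e-9))
        msg <- c(msg, sprintf("overlapping '%s' epochs", ch))
    }
  }
  if (!all(c("trial", "t_start", "t_end", "blank") %in% names(object@trials)))
    msg <- c(msg, "trials must have trial/t_start/t_end/blank")
  if (is.null(msg)) TRUE else msg
})

#' Construct a StimulusProtocol
#'
#' @param epochs epoch table (see [StimulusProtocol-class]).
#' @param trials trial table.
#' @return A [StimulusProtocol-class] object.
#' @export
StimulusProtocol <- function(epochs, trials) {
  new("StimulusProtocol", epochs = as.data.frame(epochs),
      trials = as.data.frame(trials))
}

#' Detected (or planted) swim bouts
#'
#' @slot bouts data.frame with columns t_on, t_off, mean_vigor, peak_vigor.
#'
#' @exportClass BoutTable
setClass("BoutTable", representation(bouts = "data.frame"))

setValidity("BoutTable", function(object) {
  b <- object@bouts
  msg <- NULL
  if (!all(c("t_on", "t_off", "mean_vigor", "peak_vigor") %in% names(b)))
    msg <- c(msg, "bouts must have t_on/t_off/mean_vigor/peak_vigor")
  else if (nrow(b)) {
    if (any(b$t_off <= b$t_on)) msg <- c(msg, "t_off must exceed t_on")
    if (is.unsorted(b$t_on)) msg <- c(msg, "bouts must be time-ordered")
    if (nrow(b) > 1 && any(b$t_on[-1] < b$t_off[-nrow(b)]))
      msg <- c(msg, "bouts must not overlap")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a BoutTable
#'
#' @param bouts data.frame with t_on, t_off and optional vigor summaries.
#' @return A [BoutTable-class] object.
#' @export
BoutTable <- function(bouts = data.frame()) {
  if (nrow(bouts) == 0)
    bouts <- data.frame(t_on = numeric(0), t_off = numeric(0),
                        mean_vigor = numeric(0), peak_vigor = numeric(0))
  if (is.null(bouts$mean_vigor)) bouts$mean_vigor <- NA_real_
  if (is.null(bouts$peak_vigor)) bouts$peak_vigor <- NA_real_
  bouts <- bouts[order(bouts$t_on), c("t_on", "t_off", "mean_vigor",
                                      "peak_vigor"), drop = FALSE]
  rownames(bouts) <- NULL
  new("BoutTable", bouts = bouts)
}

#' Design matrix of stimulus and motor regressors
#'
#' @slot values T x R numeric matrix, one column per regressor.
#' @slot category named character vector mapping each column to its feature
#'   category (motion_onset, motion_duration, motion_velocity, rotation,
#'   luminance, swim, eye).
#' @slot rate sampling rate of the rows, samples/s.
#' @slot t0 time of the first row, s.
#'
#' @exportClass RegressorMatrix
setClass("RegressorMatrix",
  representation(values = "matrix", category = "character", rate = "numeric",
                 t0 = "numeric"),
  prototype(t0 = 0))

.regressor_categories <- c("motion_onset", "motion_duration",
                           "motion_velocity", "rotation", "luminance",
                           "swim", "eye")

setValidity("RegressorMatrix", function(object) {
  msg <- NULL
  cn <- colnames(object@values)
  if (is.null(cn) || anyDuplicated(cn))
    msg <- c(msg, "columns must have unique names")
  if (!identical(sort(names(object@category)), sort(cn)))
    msg <- c(msg, "'category' must name every column exactly once")
  if (!all(object@category %in% .regressor_categories))
    msg <- c(msg, "unknown regressor category")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "regressor values must be finite")
  if (object@rate <= 0) msg <- c(msg, "'rate' must be positive")
  if (is.null(msg)) TRUE else msg
})

#' Construct a RegressorMatrix
#'
#' @param values numeric matrix with named columns.
#' @param category named character vector, one category per column.
#' @param rate row sampling rate, samples/s.
#' @param t0 time of the first row (s).
#' @return A [RegressorMatrix-class] object.
#' @export
RegressorMatrix <- function(values, category, rate, t0 = 0) {
  new("RegressorMatrix", values = as.matrix(values),
      category = category[colnames(values)], rate = as.numeric(rate),
      t0 = as.numeric(t0))
}

#' Fitted feature-encoding model
#'
#' @slot coefficients named per-regressor coefficients (on the z-scored
#'   design scale).
#' @slot intercept fitted intercept.
#' @slot rSquared coefficient of determination.
#' @slot nonzeroCount number of nonzero coefficients.
#' @slot normalizedWeights abs(beta) / sum(abs(beta)).
#' @slot categoryFractions share of total absolute weight per category.
#' @slot bestRegressor name of the regressor with the largest weight.
#' @slot bestCategory phenotype-level label of the best regressor.
#' @slot flags character vector of quality flags ("rank_deficient",
#'   "ambiguous", "all_zero", ...).
#'
#' @exportClass EncodingFit
setClass("EncodingFit",
  representation(coefficients = "numeric", intercept = "numeric",
                 rSquared = "numeric", nonzeroCount = "integer",
                 normalizedWeights = "numeric", categoryFractions = "numeric",
                 bestRegressor = "character", bestCategory = "character",
                 flags = "character"))

setValidity("EncodingFit", function(object) {
  msg <- NULL
  if (object@nonzeroCount > length(object@coefficients))
    msg <- c(msg, "nonzeroCount exceeds number of regressors")
  s <- sum(object@categoryFractions)
  if (length(object@categoryFractions) && sum(abs(object@coefficients)) > 0 &&
      abs(s - 1) > 1e-8)
    msg <- c(msg, "categoryFractions must sum to 1")
  if (is.null(msg)) TRUE else msg
})
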