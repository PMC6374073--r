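#' @describeIn TimeSeries-class sample values
#' @param object,x a TimeSeries
#' @export
setGeneric("tsValues", function(object) standardGeneric("tsValues"))
#' @describeIn TimeSeries-class sampling rate (samples/s)
#' @export
setGeneric("tsRate", function(object) standardGeneric("tsRate"))
#' @describeIn TimeSeries-class time of each sample (s)
#' @export
setGeneric("tsTimes", function(object) standardGeneric("tsTimes"))
#' @describeIn TimeSeries-class duration spanned by the samples (s)
#' @export
setGeneric("tsDuration", function(object) standardGeneric("tsDuration"))

setMethod("tsValues", "TimeSeries", function(object) object@values)
setMethod("tsRate", "TimeSeries", function(object) object@rate)
setMethod("tsTimes", "TimeSeries", function(object)
  object@t0 + (seq_along(object@values) - 1L) / object@rate)
setMethod("tsDuration", "TimeSeries", function(object)
  length(object@values) / object@rate)

#' @describeIn TimeSeries-class number of samples
#' @export
setMethod("length", "TimeSeries", function(x) length(x@values))

setMethod("show", "TimeSeries", function(object) {
  cat(sprintf("TimeSeries: %d samples @ %g Hz, t0 = %g s (%.3f s)\n",
              length(object@values), object@rate, object@t0,
              length(object@values) / object@rate))
})

#' @describeIn SpikeTrain-class event times (s)
#' @param object a SpikeTrain
#' @export
setGeneric("spikeTimes", function(object) standardGeneric("spikeTimes"))
#' @describeIn SpikeTrain-class spike-type label
#' @export
setGeneric("spikeLabel", function(object) standardGeneric("spikeLabel"))
#' @describeIn SpikeTrain-class number of spikes
#' @export
setGeneric("nSpikes", function(object) standardGeneric("nSpikes"))

setMethod("spikeTimes", "SpikeTrain", function(object) object@times)
setMethod("spikeLabel", "SpikeTrain", function(object) object@label)
setMethod("nSpikes", "SpikeTrain", function(object) length(object@times))

setMethod("show", "SpikeTrain", function(object) {
  cat(sprintf("SpikeTrain (%s): %d spikes over %s s\n", object@label,
              length(object@times),
              ifelse(is.na(object@duration), "?",
                     format(object@duration))))
})

#' @describeIn StimulusProtocol-class epoch table
#' @param object a StimulusProtocol
#' @export
setGeneric("epochs", function(object) standardGeneric("epochs"))
#' @describeIn StimulusProtocol-class trial table
#' @export
setGeneric("trials", function(object) standardGeneric("trials"))
#' @describeIn StimulusProtocol-class total protocol duration (s)
#' @export
setGeneric("protocolDuration", function(object)
  standardGeneric("protocolDuration"))

setMethod("epochs", "StimulusProtocol", function(object) object@epochs)
setMethod("trials", "StimulusProtocol", function(object) object@trials)
setMethod("protocolDuration", "StimulusProtocol", function(object)
  if (nrow(object@trials)) max(object@trials$t_end) else 0)

setMethod("show", "StimulusProtocol", function(object) {
  cat(sprintf("StimulusProtocol: %d epochs, %d trials (%d blank), %.1f s\n",
              nrow(object@epochs), nrow(object@trials),
              sum(object@trials$blank), protocolDuration(object)))
})

#' @describeIn BoutTable-class bout table as a data.frame
#' @param object a BoutTable
#' @export
setGeneric("bouts", function(object) standardGeneric("bouts"))
#' @describeIn BoutTable-class number of bouts
#' @export
setGeneric("nBouts", function(object) standardGeneric("nBouts"))

setMethod("bouts", "BoutTable", function(object) object@bouts)
setMethod("nBouts", "BoutTable", function(object) nrow(object@bouts))

setMethod("show", "BoutTable", function(object) {
  b <- object@bouts
  cat(sprintf("BoutTable: %d bouts%s\n", nrow(b),
              if (nrow(b)) sprintf(", median duration %.0f ms",
                                   1000 * stats::median(b$t_off - b$t_on))
              else ""))
})

#' @describeIn RegressorMatrix-class regressor values (T x R matrix)
#' @param object a RegressorMatrix
#' @export
setGeneric("designMatrix", function(object) standardGeneric("designMatrix"))
#' @describeIn RegressorMatrix-class column category map
#' @export
setGeneric("regressorCategories", function(object)
  standardGeneric("regressorCategories"))
#' @describeIn RegressorMatrix-class regressor names
#' @export
setGeneric("regressorNames", function(object)
  standardGeneric("regressorNames"))

setMethod("designMatrix", "RegressorMatrix", function(object) object@values)
setMethod("regressorCategories", "RegressorMatrix",
          function(object) object@category)
setMethod("regressorNames", "RegressorMatrix",
          function(object) colnames(object@values))
setMethod("tsRate", "RegressorMatrix", function(object) object@rate)

setMethod("show", "RegressorMatrix", function(object) {
  cat(sprintf("RegressorMatrix: %d samples x %d regressors @ %g Hz\n",
              nrow(object@values), ncol(object@values), object@rate))
  tb <- table(object@category)
  cat("  ", paste(sprintf("%s:%d", names(tb), tb), collapse = " "), "\n")
})

#' @describeIn EncodingFit-class per-regressor coefficients
#' @param object an EncodingFit
#' @export
setGeneric("fitCoefficients", function(object)
  standardGeneric("fitCoefficients"))
#' @describeIn EncodingFit-class normalized absolute weights
#' @export
setGeneric("normalizedWeights", function(object)
  standardGeneric("normalizedWeights"))
#' @describeIn EncodingFit-class per-category weight fractions
#' @export
setGeneric("categoryFractions", function(object)
  standardGeneric("categoryFractions"))
#' @describeIn EncodingFit-class R squared of the fit
#' @export
setGeneric("rSquared", function(object) standardGeneric("rSquared"))

setMethod("fitCoefficients", "EncodingFit", function(object)
  object@coefficients)
setMethod("normalizedWeights", "EncodingFit", function(object)
  object@normalizedWeights)
setMethod("categoryFractions", "EncodingFit", function(object)
  object@categoryFractions)
setMethod("rSquared", "EncodingFit", function(object) object@rSquared)

setMethod("show", "EncodingFit", function(object) {
  cat(sprintf(
    "EncodingFit: %d/%d nonzero, R^2 = %.3f, best = %s (%s)%s\n",
    object@nonzeroCount, length(object@coefficients), object@rSquared,
    object@bestRegressor, object@bestCategory,
    if (length(object@flags)) paste0(" [", paste(object@flags,
                                                 collapse = ","), "]")
    else ""))
})
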