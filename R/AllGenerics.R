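#' Accessors for ecochg classes
#'
#' Small generic accessors used across the package: `samplingRate()`,
#' `nEpochs()`, `epochSamples()`, `conEpochs()`, `rarEpochs()`, `stimulus()`,
#' `recordingId()`, `groundTruth()`, `difTrace()`, `sumTrace()`,
#' `difEpochs()`, `snrDb()`, `nExcluded()`, `tvm()`.
#'
#' @param object an ecochg object.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("nEpochs", function(object) standardGeneric("nEpochs"))
#' @rdname accessors
#' @export
setGeneric("epochSamples", function(object) standardGeneric("epochSamples"))
#' @rdname accessors
#' @export
setGeneric("conEpochs", function(object) standardGeneric("conEpochs"))
#' @rdname accessors
#' @export
setGeneric("rarEpochs", function(object) standardGeneric("rarEpochs"))
#' @rdname accessors
#' @export
setGeneric("stimulus", function(object) standardGeneric("stimulus"))
#' @rdname accessors
#' @export
setGeneric("recordingId", function(object) standardGeneric("recordingId"))
#' @rdname accessors
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setGeneric("difTrace", function(object) standardGeneric("difTrace"))
#' @rdname accessors
#' @export
setGeneric("sumTrace", function(object) standardGeneric("sumTrace"))
#' @rdname accessors
#' @export
setGeneric("difEpochs", function(object) standardGeneric("difEpochs"))
#' @rdname accessors
#' @export
setGeneric("snrDb", function(object) standardGeneric("snrDb"))
#' @rdname accessors
#' @export
setGeneric("nExcluded", function(object) standardGeneric("nExcluded"))
#' @rdname accessors
#' @export
setGeneric("tvm", function(object) standardGeneric("tvm"))

#' @rdname accessors
setMethod("samplingRate", "EpochMatrix", function(object) object@samplingRate)
#' @rdname accessors
setMethod("samplingRate", "ECochGRecording", function(object) object@con@samplingRate)
#' @rdname accessors
setMethod("samplingRate", "DerivedResponse", function(object) object@samplingRate)
#' @rdname accessors
setMethod("nEpochs", "EpochMatrix", function(object) nrow(object@samples))
#' @rdname accessors
setMethod("nEpochs", "ECochGRecording", function(object) nrow(object@con@samples))
#' @rdname accessors
setMethod("epochSamples", "EpochMatrix", function(object) object@samples)
#' @rdname accessors
setMethod("conEpochs", "ECochGRecording", function(object) object@con)
#' @rdname accessors
setMethod("rarEpochs", "ECochGRecording", function(object) object@rar)
#' @rdname accessors
setMethod("stimulus", "ECochGRecording", function(object) object@stimulus)
#' @rdname accessors
setMethod("stimulus", "DerivedResponse", function(object) object@stimulus)
#' @rdname accessors
setMethod("recordingId", "ECochGRecording", function(object) object@recordingId)
#' @rdname accessors
setMethod("recordingId", "DerivedResponse", function(object) object@recordingId)
#' @rdname accessors
setMethod("recordingId", "Scalogram", function(object) object@recordingId)
#' @rdname accessors
setMethod("groundTruth", "ECochGRecording", function(object) object@groundTruth)
#' @rdname accessors
setMethod("difTrace", "DerivedResponse", function(object) object@difTrace)
#' @rdname accessors
setMethod("sumTrace", "DerivedResponse", function(object) object@sumTrace)
#' @rdname accessors
setMethod("difEpochs", "DerivedResponse", function(object) object@difEpochs)
#' @rdname accessors
setMethod("snrDb", "DerivedResponse", function(object) object@snrDb)
#' @rdname accessors
setMethod("nExcluded", "DerivedResponse", function(object) object@nExcluded)
#' @rdname accessors
setMethod("tvm", "TVMMatrix", function(object) object@V)

setMethod("show", "StimulusSpec", function(object) {
  cat(sprintf("StimulusSpec: %g Hz pure tone (%s-threshold)\n",
              object@frequency, object@thresholdCategory))
  cat(sprintf("  duration %g ms | delay %g ms | window %g ms | level %s/%g dB HL\n",
              object@stimulusDuration, object@recordingDelay,
              object@measurementWindow,
              ifelse(is.na(object@level), "NA", format(object@level)),
              object@maxAmplitude))
})

setMethod("show", "EpochMatrix", function(object) {
  cat(sprintf("EpochMatrix [%s]: %d epochs x %d samples @ %g Hz\n",
              object@polarity, nrow(object@samples), ncol(object@samples),
              object@samplingRate))
})

setMethod("show", "ECochGRecording", function(object) {
  cat(sprintf("ECochGRecording '%s' (%s, electrode %d)\n",
              object@recordingId, object@timing, object@electrode))
  cat(sprintf("  %g Hz stimulus, %d epochs/polarity x %d samples @ %g Hz\n",
              object@stimulus@frequency, nEpochs(object),
              ncol(object@con@samples), samplingRate(object)))
  if (!is.na(object@groundTruth))
    cat(sprintf("  ground truth: CM %s\n",
                if (object@groundTruth) "present" else "absent"))
})

setMethod("show", "DerivedResponse", function(object) {
  cat(sprintf("DerivedResponse '%s': %d DIF epochs x %d samples\n",
              object@recordingId, nrow(object@difEpochs),
              ncol(object@difEpochs)))
  cat(sprintf("  plus-minus SNR: %.2f dB%s | %d epoch pair(s) excluded\n",
              object@snrDb, if (object@snrSaturated) " (saturated)" else "",
              object@nExcluded))
})

setMethod("show", "TVMMatrix", function(object) {
  cat(sprintf("TVMMatrix: N = %d epochs x Q = %d time-voltage means\n",
              nrow(object@V), ncol(object@V)))
})

setMethod("show", "Scalogram", function(object) {
  cat(sprintf("Scalogram '%s': 224 x 224 x 3 (morlet, %.0f-%.0f Hz)%s\n",
              object@recordingId, min(object@scaleFreqs),
              max(object@scaleFreqs),
              if (object@allZero) " [all-zero source]" else ""))
})
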