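#' @import methods
#' @importFrom stats cor cov median pf pnorm qnorm rnorm runif sd glm binomial
#'   plogis predict coef fft setNames quantile rbinom aggregate
#' @importFrom utils read.csv write.csv head modifyList
NULL

## Stimulus settings for the six pure-tone frequencies: stimulus duration,
## recording delay, measurement window (all ms) and the maximum admissible
## stimulation level (dB HL).
.stimulusTable <- data.frame(
  frequency         = c(250, 500, 750, 1000, 1500, 2000),
  stimulusDuration  = c(12, 8, 6.67, 5, 4, 3),
  recordingDelay    = c(1, 1, 1, 1, 1, 1),
  measurementWindow = c(19.1, 9.6, 9.6, 8.0, 8.0, 6.5),
  maxAmplitude      = c(109, 115, 123, 122, 122, 122)
)

.thresholdCategories <- c("supra", "near", "sub")

#' StimulusSpec: acoustic stimulation settings
#'
#' Describes the pure-tone stimulus of one ECochG recording: frequency,
#' stimulus duration, recording delay, measurement window and level. Defaults
#' for duration, delay, window and maximum level are filled per frequency from
#' the standard stimulation settings (e.g. 500 Hz: 8 ms tone, 1 ms delay,
#' 9.6 ms window, at most 115 dB HL).
#'
#' @slot frequency stimulus frequency in Hz; one of 250, 500, 750, 1000,
#'   1500, 2000.
#' @slot stimulusDuration tone duration in ms.
#' @slot recordingDelay delay between stimulus onset and response onset in ms.
#' @slot measurementWindow recorded window length in ms; at least the
#'   stimulus duration.
#' @slot level stimulation level in dB HL; bounded by \code{maxAmplitude}.
#' @slot thresholdCategory one of \code{"supra"}, \code{"near"}, \code{"sub"}
#'   (relative to the subject's behavioural threshold).
#' @slot maxAmplitude maximum admissible stimulation level in dB HL.
#'
#' @seealso [stimulusSpec()]
#' @exportClass StimulusSpec
setClass("StimulusSpec",
  representation(
    frequency         = "numeric",
    stimulusDuration  = "numeric",
    recordingDelay    = "numeric",
    measurementWindow = "numeric",
    level             = "numeric",
    thresholdCategory = "character",
    maxAmplitude      = "numeric"
  )
)

setValidity("StimulusSpec", function(object) {
  msg <- character()
  if (!(object@frequency %in% .stimulusTable$frequency))
    msg <- c(msg, sprintf("frequency must be one of %s Hz",
                          paste(.stimulusTable$frequency, collapse = ", ")))
  if (object@measurementWindow < object@stimulusDuration)
    msg <- c(msg, "measurementWindow must be >= stimulusDuration")
  if (object@recordingDelay < 0)
    msg <- c(msg, "recordingDelay must be non-negative")
  if (!is.na(object@level) && object@level > object@maxAmplitude)
    msg <- c(msg, "level exceeds maxAmplitude for this frequency")
  if (!(object@thresholdCategory %in% .thresholdCategories))
    msg <- c(msg, "thresholdCategory must be 'supra', 'near' or 'sub'")
  if (length(msg)) msg else TRUE
})

#' Construct a StimulusSpec
#'
#' Builds a validated [StimulusSpec-class] object, filling stimulus duration,
#' recording delay, measurement window and maximum level from the standard
#' per-frequency settings unless overridden.
#'
#' @param frequency stimulus frequency in Hz (250, 500, 750, 1000, 1500 or
#'   2000).
#' @param level stimulation level in dB HL; defaults to the maximum admissible
#'   level for the frequency.
#' @param thresholdCategory `"supra"`, `"near"` or `"sub"`.
#' @param stimulusDuration,recordingDelay,measurementWindow,maxAmplitude
#'   optional overrides (ms, ms, ms, dB HL).
#' @return A [StimulusSpec-class] object.
#' @examples
#' stimulusSpec(500)
#' stimulusSpec(250, thresholdCategory = "near")
#' @export
stimulusSpec <- function(frequency, level = NA_real_,
                         thresholdCategory = "supra",
                         stimulusDuration = NULL, recordingDelay = NULL,
                         measurementWindow = NULL, maxAmplitude = NULL) {
  row <- .stimulusTable[match(frequency, .stimulusTable$frequency), ]
  if (is.na(row$frequency))
    stop("unsupported stimulus frequency: ", frequency)
  new("StimulusSpec",
      frequency         = as.numeric(frequency),
      stimulusDuration  = as.numeric(if (is.null(stimulusDuration)) row$stimulusDuration else stimulusDuration),
      recordingDelay    = as.numeric(if (is.null(recordingDelay)) row$recordingDelay else recordingDelay),
      measurementWindow = as.numeric(if (is.null(measurementWindow)) row$measurementWindow else measurementWindow),
      level             = as.numeric(level),
      thresholdCategory = thresholdCategory,
      maxAmplitude      = as.numeric(if (is.null(maxAmplitude)) row$maxAmplitude else maxAmplitude))
}

.polarities <- c("CON", "RAR", "DIF", "SUM")

#' EpochMatrix: an ensemble of stimulus-locked sweeps
#'
#' A matrix of voltages (epochs in rows, time samples in columns, microvolts)
#' together with its sampling rate and acoustic polarity.
#'
#' @slot samples numeric matrix, epochs x time samples, in microvolts.
#' @slot samplingRate sampling rate in Hz.
#' @slot polarity `"CON"`, `"RAR"`, `"DIF"` or `"SUM"`.
#' @seealso [epochMatrix()]
#' @exportClass EpochMatrix
setClass("EpochMatrix",
  representation(
    samples      = "matrix",
    samplingRate = "numeric",
    polarity     = "character"
  )
)

setValidity("EpochMatrix", function(object) {
  msg <- character()
  if (!is.numeric(object@samples))
    msg <- c(msg, "samples must be a numeric matrix")
  if (nrow(object@samples) < 4L)
    msg <- c(msg, "at least 4 epochs are required")
  if (ncol(object@samples) < 2L)
    msg <- c(msg, "epochs must have at least 2 samples")
  if (!(object@samplingRate > 0))
    msg <- c(msg, "samplingRate must be positive")
  if (!(object@polarity %in% .polarities))
    msg <- c(msg, "polarity must be one of CON, RAR, DIF, SUM")
  if (length(msg)) msg else TRUE
})

#' Construct an EpochMatrix
#'
#' @param samples numeric matrix of voltages, epochs x samples (microvolts).
#' @param samplingRate sampling rate in Hz.
#' @param polarity `"CON"`, `"RAR"`, `"DIF"` or `"SUM"`.
#' @return An [EpochMatrix-class] object.
#' @export
epochMatrix <- function(samples, samplingRate, polarity) {
  new("EpochMatrix", samples = as.matrix(samples),
      samplingRate = samplingRate, polarity = polarity)
}

#' ECochGRecording: one paired-polarity recording
#'
#' The unit every detector consumes: a condensation and a rarefaction epoch
#' ensemble recorded at one electrode for one stimulus, plus metadata. The
#' polarity-inverting cochlear microphonic changes sign between the two
#' ensembles, which is what the difference potential (DIF) exploits.
#'
#' @slot con condensation-polarity [EpochMatrix-class].
#' @slot rar rarefaction-polarity [EpochMatrix-class].
#' @slot stimulus the [StimulusSpec-class].
#' @slot recordingId opaque identifier.
#' @slot electrode recording electrode, one of 1, 4, 7, 10 (1 = apical tip).
#' @slot timing `"intraoperative"` or `"postoperative"`.
#' @slot groundTruth logical; whether a CM component is truly present
#'   (known for synthetic recordings only, otherwise `NA`).
#' @slot meta list of extra attributes (preserved on round-trip) and
#'   preprocessing bookkeeping.
#' @seealso [ecochgRecording()], [synthRecording()], [preprocessRecording()]
#' @exportClass ECochGRecording
setClass("ECochGRecording",
  representation(
    con         = "EpochMatrix",
    rar         = "EpochMatrix",
    stimulus    = "StimulusSpec",
    recordingId = "character",
    electrode   = "integer",
    timing      = "character",
    groundTruth = "logical",
    meta        = "list"
  )
)

setValidity("ECochGRecording", function(object) {
  msg <- character()
  if (!identical(dim(object@con@samples), dim(object@rar@samples)))
    msg <- c(msg, "con and rar must have identical epoch x sample shape")
  if (object@con@samplingRate != object@rar@samplingRate)
    msg <- c(msg, "con and rar must share one sampling rate")
  if (!(object@electrode %in% c(1L, 4L, 7L, 10L)))
    msg <- c(msg, "electrode must be one of 1, 4, 7, 10")
  if (!(object@timing %in% c("intraoperative", "postoperative")))
    msg <- c(msg, "timing must be 'intraoperative' or 'postoperative'")
  if (length(msg)) msg else TRUE
})

#' Construct an ECochGRecording
#'
#' @param con,rar [EpochMatrix-class] ensembles of identical shape.
#' @param stimulus a [StimulusSpec-class].
#' @param recordingId identifier string.
#' @param electrode electrode number (1, 4, 7 or 10).
#' @param timing `"intraoperative"` or `"postoperative"`.
#' @param groundTruth logical or `NA`.
#' @param meta list of extra attributes.
#' @return An [ECochGRecording-class] object.
#' @export
ecochgRecording <- function(con, rar, stimulus, recordingId = "rec",
                            electrode = 1L, timing = "intraoperative",
                            groundTruth = NA, meta = list()) {
  new("ECochGRecording", con = con, rar = rar, stimulus = stimulus,
      recordingId = as.character(recordingId),
      electrode = as.integer(electrode), timing = timing,
      groundTruth = as.logical(groundTruth), meta = meta)
}

#' DerivedResponse: DIF/SUM traces and ensemble SNR
#'
#' The paired-polarity derivation of a recording: the per-pair difference
#' epochs (which emphasize the cochlear microphonic), the per-pair sum epochs
#' (which cancel it), their averaged traces, and the plus-minus SNR estimate
#' of the difference ensemble.
#'
#' @slot difTrace averaged DIF waveform (microvolts).
#' @slot sumTrace averaged SUM waveform (microvolts).
#' @slot difEpochs per-pair DIF matrix (epochs x samples).
#' @slot samplingRate Hz.
#' @slot snrDb plus-minus SNR of the DIF ensemble in dB.
#' @slot snrSaturated logical; `TRUE` when the noise estimate vanished and
#'   `snrDb` sits at the reporting cap.
#' @slot nExcluded number of epoch pairs dropped during preprocessing.
#' @slot stimulus the [StimulusSpec-class] of the source recording.
#' @slot recordingId identifier of the source recording.
#' @seealso [deriveDifSum()]
#' @exportClass DerivedResponse
setClass("DerivedResponse",
  representation(
    difTrace     = "numeric",
    sumTrace     = "numeric",
    difEpochs    = "matrix",
    samplingRate = "numeric",
    snrDb        = "numeric",
    snrSaturated = "logical",
    nExcluded    = "integer",
    stimulus     = "StimulusSpec",
    recordingId  = "character"
  )
)

setValidity("DerivedResponse", function(object) {
  msg <- character()
  if (length(object@difTrace) != ncol(object@difEpochs))
    msg <- c(msg, "difTrace length must equal the number of samples")
  if (length(object@sumTrace) != length(object@difTrace))
    msg <- c(msg, "sumTrace and difTrace must have equal length")
  if (!is.finite(object@snrDb) && !object@snrSaturated)
    msg <- c(msg, "snrDb must be finite unless flagged saturated")
  if (length(msg)) msg else TRUE
})

#' TVMMatrix: time-voltage means for the Hotelling detector
#'
#' The N x Q matrix of time-voltage means (TVMs): each epoch's measurement
#' window is partitioned into Q contiguous windows and the mean voltage of
#' each window forms one column. Rows are the condensation epochs followed by
#' the sign-flipped rarefaction epochs, so that under the no-response null
#' every row has expectation zero.
#'
#' @slot V numeric matrix, N epochs x Q voltage means.
#' @slot windowBounds integer vector of Q+1 sample offsets; window j covers
#'   samples `windowBounds[j]+1 .. windowBounds[j+1]`.
#' @seealso [buildTVM()], [hotellingT2()]
#' @exportClass TVMMatrix
setClass("TVMMatrix",
  representation(
    V            = "matrix",
    windowBounds = "integer"
  )
)

setValidity("TVMMatrix", function(object) {
  msg <- character()
  q <- ncol(object@V)
  if (length(object@windowBounds) != q + 1L)
    msg <- c(msg, "windowBounds must have Q + 1 entries")
  if (any(diff(object@windowBounds) <= 0L))
    msg <- c(msg, "windows must be contiguous and non-empty")
  if (q > nrow(object@V) - 1L)
    msg <- c(msg, "Q must not exceed N - 1")
  if (length(msg)) msg else TRUE
})

#' Scalogram: a CWT time-frequency image
#'
#' Morlet continuous-wavelet-transform magnitude of a DIF trace, min-max
#' normalized and resampled to a 224 x 224 x 3 image for the convolutional
#' classifier.
#'
#' @slot image numeric array 224 x 224 x 3 with values in `[0, 1]`.
#' @slot wavelet wavelet name (`"morlet"`).
#' @slot scaleFreqs pseudo-frequencies (Hz) of the scale grid, one per
#'   scalogram row before resampling.
#' @slot recordingId source recording identifier.
#' @slot allZero logical; `TRUE` when the source trace was identically zero
#'   (the image is left at zero rather than divided by a zero range).
#' @seealso [cwtScalogram()]
#' @exportClass Scalogram
setClass("Scalogram",
  representation(
    image       = "array",
    wavelet     = "character",
    scaleFreqs  = "numeric",
    recordingId = "character",
    allZero     = "logical"
  )
)

setValidity("Scalogram", function(object) {
  msg <- character()
  if (!identical(dim(object@image), c(224L, 224L, 3L)))
    msg <- c(msg, "image must be 224 x 224 x 3")
  rng <- range(object@image)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    msg <- c(msg, "image values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
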