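## Plain-text single-file recording container.
##
## Line 1: a JSON header (format tag, metadata, stimulus fields, shape).
## Then "CON" followed by one line per epoch, then "RAR" likewise. Voltages
## are written with "%.17g", which round-trips IEEE doubles exactly, so the
## container is lossless at 64-bit float precision while staying diffable
## and language-portable.

.formatTag <- "ecochg-recording"
.formatVersion <- 1L

#' Write an ECochG recording to a plain-text container file
#'
#' @param rec a validated [ECochGRecording-class].
#' @param path output file path.
#' @param overwrite logical; overwriting an existing file requires
#'   `overwrite = TRUE`.
#' @return Invisibly, `path`.
#' @seealso [readRecording()]
#' @export
writeRecording <- function(rec, path, overwrite = FALSE) {
  stopifnot(is(rec, "ECochGRecording"))
  validObject(rec)
  if (file.exists(path) && !overwrite)
    stop("file exists and overwrite = FALSE: ", path)
  stim <- rec@stimulus
  header <- list(
    format = .formatTag, version = .formatVersion,
    recording_id = rec@recordingId,
    electrode = rec@electrode, timing = rec@timing,
    ground_truth = if (is.na(rec@groundTruth)) NULL else rec@groundTruth,
    sampling_rate = samplingRate(rec),
    n_epochs = nEpochs(rec), n_samples = ncol(rec@con@samples),
    stimulus = list(
      frequency = stim@frequency,
      stimulus_duration = stim@stimulusDuration,
      recording_delay = stim@recordingDelay,
      measurement_window = stim@measurementWindow,
      level_dB_HL = if (is.na(stim@level)) NULL else stim@level,
      threshold_category = stim@thresholdCategory,
      max_amplitude_dB_HL = stim@maxAmplitude),
    extra = if (length(rec@meta)) rec@meta else NULL)
  fmtRows <- function(m)
    apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(header, auto_unbox = TRUE, null = "null",
                              digits = NA), con)
  writeLines("CON", con)
  writeLines(fmtRows(rec@con@samples), con)
  writeLines("RAR", con)
  writeLines(fmtRows(rec@rar@samples), con)
  invisible(path)
}

#' Read an ECochG recording from a plain-text container file
#'
#' Reads a file written by [writeRecording()], validating the declared shape
#' against the stored voltage rows. Unknown extra header attributes are
#' preserved in the recording's `meta` list.
#'
#' @param path file path.
#' @return A validated [ECochGRecording-class].
#' @export
readRecording <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  header <- tryCatch(jsonlite::fromJSON(lines[[1L]], simplifyVector = TRUE),
                     error = function(e) stop("malformed header in ", path,
                                              ": ", conditionMessage(e)))
  if (!identical(header$format, .formatTag))
    stop("not an ", .formatTag, " file: ", path)
  nE <- as.integer(header$n_epochs)
  nS <- as.integer(header$n_samples)
  parseBlock <- function(tag, from) {
    if (from > length(lines) || lines[[from]] != tag)
      stop("missing ", tag, " block in ", path)
    rows <- lines[(from + 1L):(from + nE)]
    vals <- as.numeric(unlist(strsplit(rows, " ", fixed = TRUE),
                              use.names = FALSE))
    if (length(vals) != nE * nS || anyNA(vals))
      stop(tag, " block shape does not match header (", nE, " x ", nS, ")")
    matrix(vals, nrow = nE, ncol = nS, byrow = TRUE)
  }
  conM <- parseBlock("CON", 2L)
  rarM <- parseBlock("RAR", 2L + nE + 1L)
  st <- header$stimulus
  stim <- stimulusSpec(st$frequency,
                       level = st$level_dB_HL %||% NA_real_,
                       thresholdCategory = st$threshold_category,
                       stimulusDuration = st$stimulus_duration,
                       recordingDelay = st$recording_delay,
                       measurementWindow = st$measurement_window,
                       maxAmplitude = st$max_amplitude_dB_HL)
  fs <- as.numeric(header$sampling_rate)
  ecochgRecording(
    con = epochMatrix(conM, fs, "CON"),
    rar = epochMatrix(rarM, fs, "RAR"),
    stimulus = stim, recordingId = header$recording_id,
    electrode = header$electrode, timing = header$timing,
    groundTruth = header$ground_truth %||% NA,
    meta = as.list(header$extra %||% list()))
}

#' Read or write rater label tables
#'
#' Labels are kept as CSV with columns `recording_id`, `rater_id`, `round`
#' (1 or 2) and `response_present` (logical), one row per label.
#'
#' @param path CSV file path.
#' @return `readLabels()` returns a data.frame of label records.
#' @export
readLabels <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("recording_id", "rater_id", "round", "response_present")
  if (!all(need %in% names(df)))
    stop("label file must have columns: ", paste(need, collapse = ", "))
  df$round <- as.integer(df$round)
  if (any(!df$round %in% c(1L, 2L))) stop("round must be 1 or 2")
  df$response_present <- as.logical(df$response_present)
  if (anyDuplicated(df[c("recording_id", "rater_id", "round")]))
    stop("duplicate (recording, rater, round) label")
  df
}

#' @param labels data.frame with the four label columns.
#' @rdname readLabels
#' @export
writeLabels <- function(labels, path) {
  need <- c("recording_id", "rater_id", "round", "response_present")
  stopifnot(all(need %in% names(labels)))
  write.csv(labels[need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
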