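# Multichannel EEG recording container and acquisition-contract validation.

#' Construct a multichannel EEG recording
#'
#' @param data channels x samples numeric matrix, microvolts.
#' @param channel_labels character vector naming the rows of `data`.
#' @param fs_hz sampling rate in Hz.
#' @param reference reference label (e.g. `"linked-ears"`).
#' @param subject_id,visit identifiers.
#' @param annotations data.frame with columns `onset_s`, `duration_s`,
#'   `label` (may have zero rows).
#' @return object of class `recording`.
#' @export
new_recording <- function(data, channel_labels, fs_hz,
                          reference = "linked-ears",
                          subject_id = "unknown", visit = "pre",
                          annotations = data.frame(onset_s = numeric(0),
                                                   duration_s = numeric(0),
                                                   label = character(0))) {
  data <- as.matrix(data)
  if (nrow(data) != length(channel_labels)) {
    stop("channel_labels length (", length(channel_labels),
         ") does not match data rows (", nrow(data), ")")
  }
  if (anyDuplicated(channel_labels)) stop("channel labels must be unique")
  if (fs_hz <= 0) stop("fs_hz must be > 0")
  structure(list(data = data,
                 channel_labels = as.character(channel_labels),
                 fs_hz = fs_hz, reference = reference,
                 subject_id = subject_id, visit = visit,
                 annotations = annotations),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s/%s: %d channels x %d samples @ %g Hz (%.1f s), ref %s\n",
              x$subject_id, x$visit, nrow(x$data), ncol(x$data), x$fs_hz,
              ncol(x$data) / x$fs_hz, x$reference))
  invisible(x)
}

# Recording duration in seconds.
rec_duration <- function(rec) ncol(rec$data) / rec$fs_hz

#' Validate a recording against the study acquisition contract
#'
#' Checks the montage (19 named 10-20 channels; matching is
#' case-insensitive and literal, so T3/T7-style synonyms are not aliased),
#' the sampling rate, and the minimum duration of 6 minutes.
#'
#' @param rec a `recording`.
#' @param required_labels expected channel names.
#' @param fs_expected expected sampling rate (Hz).
#' @param min_duration_s minimum acceptable duration (seconds).
#' @param strict if `TRUE`, duration and extra-channel findings are
#'   failures; otherwise warnings.
#' @return list with `ok` (logical), `failures`, `warnings` (character
#'   vectors), and `missing` / `extra` label sets; serializable as JSON.
#' @export
validate_montage <- function(rec, required_labels = channels_1020,
                             fs_expected = 256, min_duration_s = 360,
                             strict = FALSE) {
  lab <- tolower(rec$channel_labels)
  req <- tolower(required_labels)
  missing <- required_labels[!req %in% lab]
  extra <- rec$channel_labels[!lab %in% req]
  failures <- character(0)
  warnings <- character(0)
  if (length(missing)) {
    failures <- c(failures, paste0("missing channel(s): ",
                                   paste(missing, collapse = ", ")))
  }
  if (length(extra)) {
    msg <- paste0("unexpected channel(s): ", paste(extra, collapse = ", "))
    if (strict) failures <- c(failures, msg) else warnings <- c(warnings, msg)
  }
  if (!isTRUE(all.equal(rec$fs_hz, fs_expected))) {
    failures <- c(failures, sprintf("sampling rate %g Hz; expected %g Hz",
                                    rec$fs_hz, fs_expected))
  }
  if (rec_duration(rec) < min_duration_s) {
    msg <- sprintf("duration %.1f s below the required %.0f s",
                   rec_duration(rec), min_duration_s)
    if (strict) failures <- c(failures, msg) else warnings <- c(warnings, msg)
  }
  if (anyNA(rec$data)) failures <- c(failures, "data contain NA values")
  list(ok = length(failures) == 0, failures = failures, warnings = warnings,
       missing = missing, extra = extra)
}
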