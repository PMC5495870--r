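#' Multi-trial EEG recording container
#'
#' Lightweight container for multi-subject, multi-trial, multi-channel EEG-like
#' time series. `data` is a 4-D array indexed `[subject, trial, channel,
#' sample]` in microvolts. `onset_sample` is the 1-based index of the first
#' sample of the unstable-surface (post-onset) condition within each epoch;
#' with sampling rate `fs`, sample `i` sits at epoch-local time `(i - 1) / fs`
#' seconds.
#'
#' @param data 4-D numeric array `[subject, trial, channel, sample]` (microvolts).
#' @param fs Sampling rate in Hz.
#' @param channel_names Character vector, one unique label per channel.
#' @param onset_sample 1-based index of the first post-onset sample (or `NA`
#'   for continuous, un-epoched data).
#' @param eog_channel Label of the electrooculogram channel, or `NULL` if none.
#' @param ground_truth For synthetic data, the [sim_config()] that generated it.
#' @return An object of class `bn_recording`.
#' @export
new_recording <- function(data, fs, channel_names, onset_sample = NA_integer_,
                          eog_channel = NULL, ground_truth = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 4)
  if (dim(data)[3] != length(channel_names)) {
    stop("channel_names length does not match the channel dimension")
  }
  if (anyDuplicated(channel_names)) stop("channel_names must be unique")
  if (anyNA(data)) stop("recording data must not contain NA")
  if (!is.na(onset_sample) &&
      (onset_sample < 1 || onset_sample > dim(data)[4])) {
    stop("onset_sample must lie within the epoch")
  }
  structure(
    list(data = data, fs = fs, channel_names = channel_names,
         onset_sample = as.integer(onset_sample), eog_channel = eog_channel,
         ground_truth = ground_truth),
    class = "bn_recording"
  )
}

#' @export
print.bn_recording <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<bn_recording> %d subject(s) x %d trial(s) x %d channel(s) x %d samples @ %g Hz\n",
    d[1], d[2], d[3], d[4], x$fs))
  if (!is.na(x$onset_sample)) {
    cat(sprintf("  onset at sample %d (t = %.2f s)\n", x$onset_sample,
                (x$onset_sample - 1) / x$fs))
  }
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' Names of the EEG (non-EOG) channels of a recording
#' @param rec A [new_recording()] object.
#' @return Character vector of scalp channel labels.
#' @export
eeg_channels <- function(rec) {
  setdiff(rec$channel_names, rec$eog_channel)
}

#' Extract one subject's trials as a channels x samples x trials cube
#'
#' @param rec A `bn_recording`.
#' @param subject Subject index.
#' @param channels Channel labels to keep (default: all EEG channels).
#' @return Numeric array `[channel, sample, trial]`.
#' @export
subject_cube <- function(rec, subject = 1, channels = eeg_channels(rec)) {
  ci <- match(channels, rec$channel_names)
  if (anyNA(ci)) stop("unknown channel(s): ",
                      paste(channels[is.na(ci)], collapse = ", "))
  d <- dim(rec$data)
  x <- rec$data[subject, , ci, , drop = FALSE]   # 1 x trials x ch x samples
  aperm(array(x, dim = dim(x)[2:4]), c(2, 3, 1))
}

#' Epoch-local time axis of a recording
#' @param rec A `bn_recording`.
#' @return Numeric vector of times in seconds, starting at 0.
#' @export
rec_times <- function(rec) (seq_len(dim(rec$data)[4]) - 1) / rec$fs
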