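#' Onset detector configuration
#'
#' The onset of the unstable condition is the first sample at which the
#' platform displacement deviates from its baseline mean by more than
#' `threshold_sd` baseline standard deviations on either axis, with baseline
#' statistics computed over the `baseline_window` seconds immediately
#' preceding the candidate sample (the 5 s / 5 SD rule).
#'
#' @param baseline_window Baseline window length in seconds.
#' @param threshold_sd Threshold in multiples of the baseline SD.
#' @return A list of class `bn_onset_config`.
#' @export
onset_config <- function(baseline_window = 5, threshold_sd = 5) {
  stopifnot(baseline_window > 0, threshold_sd > 0)
  structure(list(baseline_window = baseline_window, threshold_sd = threshold_sd),
            class = "bn_onset_config")
}

#' Detect the platform-release onset in a platform trace
#'
#' @param trace A [new_platform_trace()].
#' @param cfg An [onset_config()].
#' @return 1-based sample index of the detected onset.
#' @export
detect_onset <- function(trace, cfg = onset_config()) {
  w <- round(cfg$baseline_window * trace$fs)
  n <- ncol(trace$displacement)
  if (n <= w + 1) stop("trace shorter than baseline_window + 1 sample")
  hit <- rep(FALSE, n)
  for (ax in 1:2) {
    x <- trace$displacement[ax, ]
    cs <- cumsum(x); cs2 <- cumsum(x^2)
    i <- (w + 1):n
    m <- (cs[i - 1] - c(0, cs)[i - w]) / w
    v <- pmax(0, (cs2[i - 1] - c(0, cs2)[i - w]) / w - m^2)
    s <- sqrt(v * w / (w - 1))
    hit[i] <- hit[i] | abs(x[i] - m) > cfg$threshold_sd * s
  }
  idx <- which(hit)
  if (length(idx) == 0) stop("no onset: threshold never crossed")
  idx[1]
}

#' Epoch specification around the onset
#'
#' @param pre_onset Seconds of stable-surface data kept before the onset.
#' @param post_onset Seconds of unstable-surface data kept from the onset.
#' @return A list of class `bn_epoch_spec`.
#' @export
epoch_spec <- function(pre_onset = 3, post_onset = 5) {
  stopifnot(pre_onset > 0, post_onset > 0)
  structure(list(pre_onset = pre_onset, post_onset = post_onset),
            class = "bn_epoch_spec")
}

#' Segment continuous trials into onset-aligned epochs
#'
#' Each epoch keeps `pre_onset` seconds before and `post_onset` seconds from
#' the per-trial onset, so the onset falls at epoch-local time `pre_onset`
#' exactly. Trials without sufficient margin on any subject are dropped with a
#' warning.
#'
#' @param rec A continuous [new_recording()].
#' @param onsets Onset sample indices: a scalar, a vector over trials, or an
#'   `n_subjects x n_trials` matrix.
#' @param spec An [epoch_spec()].
#' @return An epoched `bn_recording` with `onset_sample = pre_onset * fs + 1`.
#' @export
segment_epochs <- function(rec, onsets, spec = epoch_spec()) {
  d <- dim(rec$data)
  pre_n <- round(spec$pre_onset * rec$fs)
  post_n <- round(spec$post_onset * rec$fs)
  on_mat <- matrix(onsets, nrow = d[1], ncol = d[2],
                   byrow = is.vector(onsets) && length(onsets) == d[2])
  ok <- on_mat - pre_n >= 1 & on_mat + post_n - 1 <= d[4]
  keep <- which(apply(ok, 2, all))
  if (length(keep) < d[2]) {
    warning(sprintf("dropped %d trial(s) with insufficient margin around onset",
                    d[2] - length(keep)))
  }
  if (length(keep) == 0) stop("no trial has sufficient margin around the onset")
  out <- array(0, dim = c(d[1], length(keep), d[3], pre_n + post_n))
  for (s in seq_len(d[1])) {
    for (j in seq_along(keep)) {
      on <- on_mat[s, keep[j]]
      out[s, j, , ] <- rec$data[s, keep[j], , (on - pre_n):(on + post_n - 1)]
    }
  }
  new_recording(out, fs = rec$fs, channel_names = rec$channel_names,
                onset_sample = pre_n + 1L, eog_channel = rec$eog_channel,
                ground_truth = rec$ground_truth)
}

#' Re-reference to the common average of the EEG channels
#'
#' Subtracts, at every sample, the mean over all scalp channels (the EOG
#' channel is excluded from the average and left untouched), making the mean
#' across EEG channels exactly zero and the downstream analysis
#' reference-free.
#'
#' @param rec A [new_recording()] with at least 2 EEG channels.
#' @return The re-referenced recording.
#' @export
rereference_common_average <- function(rec) {
  eeg <- match(eeg_channels(rec), rec$channel_names)
  if (length(eeg) < 2) stop("common average reference needs >= 2 EEG channels")
  d <- dim(rec$data)
  out <- rec$data
  for (s in seq_len(d[1])) {
    for (r in seq_len(d[2])) {
      x <- out[s, r, , ]
      avg <- colMeans(x[eeg, , drop = FALSE])
      x[eeg, ] <- sweep(x[eeg, , drop = FALSE], 2, avg, "-")
      out[s, r, , ] <- x
    }
  }
  rec$data <- out
  rec
}

#' Regression-based ocular correction (Gratton-Coles family)
#'
#' For each subject and scalp channel, a single blink-propagation coefficient
#' `b` is estimated by regressing the event-related-average-subtracted EEG on
#' the event-related-average-subtracted EOG, pooled across trials; the
#' corrected signal is `EEG - b * EOG` (raw traces). Subtracting the
#' event-related averages first prevents stimulus-locked brain activity common
#' to EEG and EOG from inflating the coefficient.
#'
#' @param rec A [new_recording()] containing an EOG channel.
#' @param eog_channel Label of the EOG channel.
#' @return A list-free `bn_recording` with corrected EEG; the estimated
#'   coefficients are attached as attribute `"ocular_coefficients"` (a
#'   subjects x channels matrix).
#' @export
correct_ocular <- function(rec, eog_channel = rec$eog_channel) {
  if (is.null(eog_channel) || !(eog_channel %in% rec$channel_names)) {
    stop("EOG channel not present in the recording")
  }
  d <- dim(rec$data)
  ei <- match(eog_channel, rec$channel_names)
  eeg <- setdiff(seq_len(d[3]), ei)
  B <- matrix(0, d[1], length(eeg),
              dimnames = list(NULL, rec$channel_names[eeg]))
  out <- rec$data
  for (s in seq_len(d[1])) {
    x <- rec$data[s, , , , drop = FALSE]            # 1 x trials x ch x samp
    x <- array(x, dim = d[2:4])
    era <- apply(x, c(2, 3), mean)                   # ch x samp
    eog_c <- sweep(x[, ei, , drop = FALSE], 3, era[ei, ], "-")
    denom <- sum(eog_c^2)
    if (denom < .Machine$double.eps * length(eog_c)) {
      warning(sprintf("subject %d: zero-variance EOG, coefficients set to 0", s))
      next
    }
    for (j in seq_along(eeg)) {
      ch <- eeg[j]
      eeg_c <- sweep(x[, ch, , drop = FALSE], 3, era[ch, ], "-")
      b <- sum(eeg_c * eog_c) / denom
      B[s, j] <- b
      out[s, , ch, ] <- rec$data[s, , ch, ] - b * rec$data[s, , ei, ]
    }
  }
  rec$data <- out
  attr(rec, "ocular_coefficients") <- B
  rec
}

#' Decimate a recording (low-pass filter + downsample)
#'
#' Applies a zero-phase (forward-backward) order-8 Chebyshev Type I low-pass
#' filter with 0.05 dB passband ripple and cutoff `0.8 * (fs/2) / factor` (the
#' classic decimation convention), then keeps every `factor`-th sample.
#' Zero-phase filtering avoids latency shifts that would move the onset.
#'
#' @param rec A [new_recording()].
#' @param factor Integer decimation factor (>= 1).
#' @return The decimated recording with `fs = fs / factor`.
#' @export
downsample <- function(rec, factor) {
  if (factor < 1) stop("decimation factor must be >= 1")
  factor <- as.integer(factor)
  if (factor == 1L) return(rec)
  d <- dim(rec$data)
  keep <- seq(1L, d[4], by = factor)
  cf <- signal::cheby1(8, 0.05, 0.8 / factor)
  out <- array(0, dim = c(d[1], d[2], d[3], length(keep)))
  for (s in seq_len(d[1])) {
    for (r in seq_len(d[2])) {
      for (ch in seq_len(d[3])) {
        y <- signal::filtfilt(cf, rec$data[s, r, ch, ])
        out[s, r, ch, ] <- y[keep]
      }
    }
  }
  onset <- if (is.na(rec$onset_sample)) NA_integer_ else
    as.integer(floor((rec$onset_sample - 1) / factor) + 1L)
  new_recording(out, fs = rec$fs / factor, channel_names = rec$channel_names,
                onset_sample = onset, eog_channel = rec$eog_channel,
                ground_truth = rec$ground_truth)
}
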