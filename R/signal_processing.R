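# Cleaning of EEG/GSR/PPG streams and mapping of the apex frame into each
# stream to cut the signal region of interest.
#
# Sample indices are 0-based; windows are half-open [start, end).
# Channel matrices are channels x samples.

#' Zero-phase Butterworth band-pass filter
#'
#' A Butterworth band-pass applied forward and backward
#' (`signal::filtfilt`), i.e. zero phase shift and squared magnitude
#' response. Default bands used by the pipeline: EEG 1-45 Hz, PPG
#' 0.7-2.5 Hz, GSR 0.1-15 Hz.
#'
#' @param x Numeric vector, or channels x samples matrix (filtered per row).
#' @param rate Sampling rate in Hz.
#' @param low,high Band edges in Hz; `0 < low < high < rate/2`.
#' @param order Filter order of the underlying Butterworth prototype.
#' @return Filtered data, same shape as `x`.
#' @export
bandpass <- function(x, rate, low, high, order = 4) {
  assert_that(is_number(low, min = 1e-12) && is_number(high) && low < high,
              "band edges must satisfy 0 < low < high")
  assert_that(high < rate / 2, "high (", high, " Hz) must be below the Nyquist rate")
  assert_that(is_count(order), "order must be a positive count")
  n <- if (is.matrix(x)) ncol(x) else length(x)
  assert_that(n > 3 * order, "signal too short for the requested filter order")
  bf <- signal::butter(order, c(low, high) / (rate / 2), type = "pass")
  run <- function(v) signal::filtfilt(bf, v)
  if (is.matrix(x)) t(apply(x, 1, run)) else run(x)
}

#' Common average reference
#'
#' Subtracts, at every sample, the cross-channel mean from each EEG channel.
#' The referenced matrix has zero cross-channel mean everywhere, and the
#' operation is idempotent.
#'
#' @param eeg Channels x samples matrix with >= 2 channels.
#' @return Re-referenced matrix, same shape.
#' @export
common_average_reference <- function(eeg) {
  assert_that(is.matrix(eeg), "eeg must be a channels x samples matrix")
  assert_that(nrow(eeg) >= 2, "common average reference needs >= 2 channels")
  sweep(eeg, 2, colMeans(eeg), "-")
}

#' Median filter for GSR artifact removal
#'
#' Sliding-window median with reflected edges, removing rapid transient
#' spikes narrower than half the kernel.
#'
#' @param gsr Numeric vector.
#' @param kernel_samples Odd window length in samples, `<= length(gsr)`.
#' @return Filtered vector, same length.
#' @export
median_filter_gsr <- function(gsr, kernel_samples) {
  assert_that(is.numeric(gsr) && length(gsr) > 0, "gsr must be a numeric vector")
  assert_that(is_count(kernel_samples) && kernel_samples %% 2 == 1,
              "kernel_samples must be an odd count")
  assert_that(kernel_samples <= length(gsr), "kernel longer than the signal")
  if (kernel_samples == 1) return(gsr)
  n <- length(gsr); h <- (kernel_samples - 1) / 2
  # reflect about the end points (end points not repeated)
  left <- gsr[pmin(h, n - 1):1 + 1]
  right <- gsr[n - 1:pmin(h, n - 1)]
  padded <- c(left, gsr, right)
  out <- stats::runmed(padded, kernel_samples, endrule = "keep")
  out[(length(left) + 1):(length(left) + n)]
}

#' Per-channel z-score normalization
#'
#' Centres each channel to mean 0 and scales it to population SD 1 over the
#' full trial. A constant channel cannot be scaled and is returned as zeros
#' with a warning.
#'
#' @param x Numeric vector or channels x samples matrix.
#' @return Normalized data, same shape.
#' @export
normalize_signal <- function(x) {
  zscore <- function(v) {
    s <- sd_pop(v)
    if (s == 0) {
      warning("constant channel normalized to zeros")
      return(rep(0, length(v)))
    }
    (v - mean(v)) / s
  }
  if (is.matrix(x)) t(apply(x, 1, zscore)) else zscore(x)
}

#' Drop the lead-in period of a trial
#'
#' Removes the first `trim_seconds` of data (e.g. 8 s for recordings that
#' include a 3 s baseline plus 5 s engagement time before genuine
#' stimulation). Use 0 for recordings without a lead-in.
#'
#' @param x Numeric vector or channels x samples matrix.
#' @param rate Sampling rate in Hz.
#' @param trim_seconds Seconds to drop from the start.
#' @return Trimmed data, same type as `x`.
#' @export
trim_lead <- function(x, rate, trim_seconds = 8) {
  assert_that(is_number(trim_seconds, min = 0), "trim_seconds must be >= 0")
  drop_n <- round(trim_seconds * rate)
  n <- if (is.matrix(x)) ncol(x) else length(x)
  assert_that(drop_n < n, "trial (", n, " samples) is not longer than the trim")
  if (drop_n == 0) return(x)
  if (is.matrix(x)) x[, -(1:drop_n), drop = FALSE] else x[-(1:drop_n)]
}

#' Map a video frame index to a signal sample index
#'
#' `round(apex_frame / fps * rate)`, aligning the apex time across streams
#' with different sampling rates. Indices are 0-based.
#'
#' @param apex_frame 0-based frame index.
#' @param fps Video frame rate (frames/s).
#' @param rate Target signal sampling rate (Hz).
#' @return 0-based sample index.
#' @export
frame_to_sample <- function(apex_frame, fps, rate) {
  assert_that(is_number(fps, min = 1e-12) && is_number(rate, min = 1e-12),
              "fps and rate must be > 0")
  assert_that(is_number(apex_frame, min = 0), "apex_frame must be >= 0")
  as.integer(round(apex_frame / fps * rate))
}

#' Cut the signal region of interest around the apex sample
#'
#' A window of `seconds` is centred on `apex_sample`; when the centred
#' window would overrun the trial it is shifted (not shrunk) to fit, so the
#' extracted length is always exactly `round(seconds * rate)`. Passing
#' `seconds = "all"` returns the whole trial.
#'
#' @param x Numeric vector or channels x samples matrix.
#' @param rate Sampling rate in Hz.
#' @param apex_sample 0-based apex sample index (see [frame_to_sample()]).
#' @param seconds ROI duration in seconds, or `"all"`.
#' @return A list of class `"signal_roi"`: `start_sample`, `end_sample`
#'   (0-based, half-open), `rate`, `seconds`, `data` (same type as `x`).
#' @export
extract_signal_roi <- function(x, rate, apex_sample, seconds = 15) {
  n <- if (is.matrix(x)) ncol(x) else length(x)
  if (identical(seconds, "all")) {
    return(structure(list(start_sample = 0L, end_sample = as.integer(n),
                          rate = rate, seconds = n / rate, data = x),
                     class = "signal_roi"))
  }
  assert_that(is_number(seconds, min = 1e-12), "seconds must be > 0 or \"all\"")
  len <- round(seconds * rate)
  assert_that(len >= 1, "ROI shorter than one sample")
  assert_that(len <= n, "requested ROI (", len, " samples) is longer than the trial (", n, ")")
  assert_that(is_number(apex_sample, min = 0) && apex_sample < n,
              "apex_sample out of range")
  start <- apex_sample - floor(len / 2)
  start <- min(max(start, 0), n - len)
  idx <- (start + 1):(start + len)
  structure(list(start_sample = as.integer(start),
                 end_sample = as.integer(start + len),
                 rate = rate, seconds = seconds,
                 data = if (is.matrix(x)) x[, idx, drop = FALSE] else x[idx]),
            class = "signal_roi")
}

#' Standard cleaning for each modality
#'
#' Convenience wrappers applying the pipeline's default cleaning chains:
#' EEG: band-pass 1-45 Hz, common average reference, z-score.
#' GSR: band-pass 0.1-15 Hz, median filter (~0.5 s kernel), z-score.
#' PPG: band-pass 0.7-2.5 Hz, z-score.
#'
#' @param eeg Channels x samples matrix.
#' @param gsr,ppg Numeric vectors.
#' @param rate Sampling rate in Hz.
#' @return Cleaned data, same shape as the input.
#' @export
clean_eeg <- function(eeg, rate) {
  normalize_signal(common_average_reference(bandpass(eeg, rate, 1, 45)))
}

#' @rdname clean_eeg
#' @export
clean_gsr <- function(gsr, rate) {
  k <- round(0.5 * rate)
  if (k %% 2 == 0) k <- k + 1
  normalize_signal(median_filter_gsr(bandpass(gsr, rate, 0.1, 15), k))
}

#' @rdname clean_eeg
#' @export
clean_ppg <- function(ppg, rate) {
  normalize_signal(bandpass(ppg, rate, 0.7, 2.5))
}
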