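# Per-window feature extraction: EEG band powers and GSR/PPG statistical
# summaries, assembled into windowed feature sequences for the sequence
# classifiers.

#' Standard EEG band definitions
#'
#' Delta 1-4, theta 4-8, alpha 8-12, beta 12-30 and gamma 30-45 Hz.
#' Bins are assigned low-inclusive, high-exclusive.
#'
#' @return A data frame with columns `name`, `low`, `high` (Hz).
#' @export
band_definitions <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta", "gamma"),
             low = c(1, 4, 8, 12, 30),
             high = c(4, 8, 12, 30, 45),
             stringsAsFactors = FALSE)
}

#' Partition a signal into non-overlapping windows
#'
#' Consecutive windows of `window_seconds`; a trailing partial window is
#' dropped.
#'
#' @param x Numeric vector or channels x samples matrix.
#' @param rate Sampling rate in Hz.
#' @param window_seconds Window duration (default 1 s).
#' @return List of windows (same type as `x`).
#' @export
window_trial <- function(x, rate, window_seconds = 1) {
  wlen <- round(window_seconds * rate)
  assert_that(wlen >= 1, "window_seconds * rate must be >= 1 sample")
  n <- if (is.matrix(x)) ncol(x) else length(x)
  nw <- floor(n / wlen)
  assert_that(nw >= 1, "signal (", n, " samples) is shorter than one window")
  lapply(seq_len(nw), function(i) {
    idx <- ((i - 1) * wlen + 1):(i * wlen)
    if (is.matrix(x)) x[, idx, drop = FALSE] else x[idx]
  })
}

#' EEG band powers of one window
#'
#' Periodogram power (squared FFT magnitude, no taper) averaged over the
#' frequency bins of each band with `low <= f < high`, per channel, then
#' averaged across channels: one scalar per band, ordered delta, theta,
#' alpha, beta, gamma.
#'
#' @param window Channels x samples matrix (a vector is treated as one
#'   channel); at least 1 s of samples.
#' @param rate Sampling rate in Hz.
#' @param bands Band table, as from [band_definitions()].
#' @return Named numeric vector of length `nrow(bands)`.
#' @export
eeg_band_powers <- function(window, rate, bands = band_definitions()) {
  if (!is.matrix(window)) window <- matrix(window, nrow = 1)
  s <- ncol(window)
  assert_that(s >= rate, "window must hold at least 1 s of samples")
  assert_that(all(bands$high <= rate / 2),
              "band above the Nyquist frequency (", rate / 2, " Hz)")
  freqs <- (0:(s - 1)) * rate / s
  half <- seq_len(floor(s / 2) + 1)
  power <- abs(t(stats::mvfft(t(window))))^2 / s   # channels x bins
  out <- vapply(seq_len(nrow(bands)), function(b) {
    sel <- half[freqs[half] >= bands$low[b] & freqs[half] < bands$high[b]]
    if (length(sel) == 0) return(0)
    mean(rowMeans(power[, sel, drop = FALSE]))
  }, numeric(1))
  names(out) <- bands$name
  out
}

#' GSR statistical features of one window
#'
#' `[mean, SD, mean |first difference|, mean |second difference|]`, with the
#' population SD convention. The absolute-difference summaries capture the
#' magnitude of phasic change inside the window.
#'
#' @param window Numeric vector of >= 3 samples.
#' @param rate Sampling rate in Hz (kept for interface symmetry).
#' @return Named numeric vector of length 4.
#' @export
gsr_feature_vector <- function(window, rate = NULL) {
  assert_that(is.numeric(window) && length(window) >= 3,
              "GSR window must have >= 3 samples")
  c(gsr_mean = mean(window), gsr_sd = sd_pop(window),
    gsr_diff1 = mean(abs(diff(window))),
    gsr_diff2 = mean(abs(diff(window, differences = 2))))
}

#' PPG statistical features of one window
#'
#' `[mean, SD]` (population SD).
#'
#' @param window Numeric vector of >= 2 samples.
#' @return Named numeric vector of length 2.
#' @export
ppg_feature_vector <- function(window) {
  assert_that(is.numeric(window) && length(window) >= 2,
              "PPG window must have >= 2 samples")
  c(ppg_mean = mean(window), ppg_sd = sd_pop(window))
}

# Build a feature_sequence container from a windows x features matrix.
feature_sequence <- function(mat, modality, window_seconds = 1) {
  structure(list(windows = mat, modality = modality,
                 window_seconds = window_seconds,
                 feature_names = colnames(mat)),
            class = "feature_sequence")
}

#' Windowed feature sequence for an EEG ROI
#'
#' Partitions the (cleaned) EEG ROI into non-overlapping windows and maps
#' each to its 5 band powers. Regardless of channel count the stored
#' sequence is n_windows x 5.
#'
#' @param eeg Channels x samples matrix.
#' @param rate Sampling rate in Hz.
#' @param window_seconds Window duration.
#' @param bands Band table, as from [band_definitions()].
#' @return A `"feature_sequence"` with a `n_windows x 5` matrix.
#' @export
eeg_feature_sequence <- function(eeg, rate, window_seconds = 1,
                                 bands = band_definitions()) {
  wins <- window_trial(eeg, rate, window_seconds)
  mat <- t(vapply(wins, eeg_band_powers, numeric(nrow(bands)),
                  rate = rate, bands = bands))
  feature_sequence(mat, "eeg", window_seconds)
}

#' Windowed physiological feature sequence (GSR ++ PPG)
#'
#' Per window, the 4 GSR features followed by the 2 PPG features; window
#' counts of the two streams must match.
#'
#' @param gsr,ppg Cleaned numeric vectors over the same ROI.
#' @param rate Sampling rate in Hz.
#' @param window_seconds Window duration.
#' @return A `"feature_sequence"` with a `n_windows x 6` matrix.
#' @export
physio_feature_sequence <- function(gsr, ppg, rate, window_seconds = 1) {
  gw <- window_trial(gsr, rate, window_seconds)
  pw <- window_trial(ppg, rate, window_seconds)
  gmat <- t(vapply(gw, gsr_feature_vector, numeric(4), rate = rate))
  pmat <- t(vapply(pw, ppg_feature_vector, numeric(2)))
  concat_physio(feature_sequence(gmat, "gsr", window_seconds),
                feature_sequence(pmat, "ppg", window_seconds))
}

#' Concatenate GSR and PPG feature sequences into physiological features
#'
#' Per-window vectors of length 6 (GSR features first), preserving window
#' order; the two sequences must have equal window counts.
#'
#' @param gsr_seq,ppg_seq `"feature_sequence"` objects.
#' @return A `"feature_sequence"` with modality `"physio"`.
#' @export
concat_physio <- function(gsr_seq, ppg_seq) {
  assert_that(inherits(gsr_seq, "feature_sequence") &&
                inherits(ppg_seq, "feature_sequence"),
              "inputs must be feature_sequence objects")
  assert_that(nrow(gsr_seq$windows) == nrow(ppg_seq$windows),
              "window counts differ (", nrow(gsr_seq$windows), " vs ",
              nrow(ppg_seq$windows), ")")
  feature_sequence(cbind(gsr_seq$windows, ppg_seq$windows), "physio",
                   gsr_seq$window_seconds)
}

#' @export
print.feature_sequence <- function(x, ...) {
  cat(sprintf("feature_sequence [%s]: %d windows x %d features (%g s windows)\n",
              x$modality, nrow(x$windows), ncol(x$windows), x$window_seconds))
  invisible(x)
}
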