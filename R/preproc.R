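#' Continuous EEG recording container
#'
#' @param data Numeric matrix, channels x samples (microvolts).
#' @param sampling_rate Hz.
#' @param channel_names Optional character vector (defaults to
#'   `ch001, ch002, ...`).
#' @param events Tibble with columns `sample` (1-based sample index of
#'   stimulus onset) and `stimulus_id`; an optional logical `repeat_flag`
#'   column marks one-back repetition trials.
#' @return Object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, sampling_rate, channel_names = NULL, events = NULL) {
  data <- as.matrix(data)
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  if (is.null(channel_names)) channel_names <- sprintf("ch%03d", seq_len(nrow(data)))
  if (length(channel_names) != nrow(data)) stop("one channel name per data row required")
  if (is.null(events)) events <- tibble::tibble(sample = integer(), stimulus_id = integer())
  if (!all(c("sample", "stimulus_id") %in% names(events))) {
    stop("events need columns `sample` and `stimulus_id`")
  }
  if (nrow(events) && (min(events$sample) < 1 || max(events$sample) > ncol(data))) {
    stop("event sample indices outside the recording")
  }
  structure(
    list(data = data, sampling_rate = sampling_rate,
         channel_names = channel_names, events = tibble::as_tibble(events)),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz, %d events\n",
              nrow(x$data), ncol(x$data), x$sampling_rate, nrow(x$events)))
  invisible(x)
}

#' Re-reference to a single channel
#'
#' Subtracts the reference channel's signal from every channel; the
#' reference itself becomes identically zero. Idempotent.
#'
#' @param recording An `eeg_recording`.
#' @param reference Channel name (or index) to re-reference against, e.g.
#'   the vertex electrode.
#' @return The re-referenced `eeg_recording`.
#' @export
eeg_rereference <- function(recording, reference) {
  stopifnot(inherits(recording, "eeg_recording"))
  idx <- if (is.character(reference)) match(reference, recording$channel_names) else as.integer(reference)
  if (is.na(idx) || idx < 1 || idx > nrow(recording$data)) {
    stop("unknown reference channel: ", reference)
  }
  recording$data <- sweep(recording$data, 2, recording$data[idx, ], "-")
  recording
}

#' Zero-phase band-pass filter
#'
#' Butterworth IIR applied forward and backward (`signal::filtfilt`), so the
#' filter is zero-phase; realized as a high-pass/low-pass cascade, which is
#' numerically robust for very low high-pass corners (0.01 Hz at kHz
#' sampling rates). Default band 0.01-80 Hz. Effective order is twice
#' `order` because of the forward-backward pass.
#'
#' @param recording An `eeg_recording`.
#' @param low_hz,high_hz Band edges; `0 < low < high < Nyquist`.
#' @param order Order of each Butterworth section (default 2, i.e. a
#'   4th-order band-pass before the backward pass).
#' @return Filtered `eeg_recording`.
#' @export
eeg_bandpass <- function(recording, low_hz = 0.01, high_hz = 80, order = 2) {
  stopifnot(inherits(recording, "eeg_recording"))
  nyq <- recording$sampling_rate / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq)) {
    stop("need 0 < low_hz < high_hz < Nyquist (", nyq, " Hz)")
  }
  hp <- signal::butter(order, low_hz / nyq, type = "high")
  lp <- signal::butter(order, high_hz / nyq, type = "low")
  recording$data <- t(apply(recording$data, 1, function(ch) {
    signal::filtfilt(lp, signal::filtfilt(hp, ch))
  }))
  recording
}

#' Segment a continuous recording into stimulus-locked epochs
#'
#' Cuts one epoch per event on the half-open window `[tmin_ms, tmax_ms)`
#' relative to stimulus onset (the onset sample is included at t = 0).
#' Events too close to the recording edges for the full window are dropped
#' and the count reported via `message()`.
#'
#' @param recording An `eeg_recording` with events.
#' @param tmin_ms,tmax_ms Epoch window in ms (defaults -200 and 1100).
#' @param catalog Optional stimulus catalog attached to the result.
#' @return An `epoch_set`.
#' @export
eeg_epoch <- function(recording, tmin_ms = -200, tmax_ms = 1100, catalog = NULL) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (tmax_ms <= tmin_ms) stop("tmax_ms must exceed tmin_ms")
  if (!nrow(recording$events)) stop("recording has no events to epoch")
  fs <- recording$sampling_rate
  k0 <- ceiling(tmin_ms * fs / 1000)
  k1 <- ceiling(tmax_ms * fs / 1000) - 1
  n_samp <- ncol(recording$data)
  ev <- recording$events
  ok <- ev$sample + k0 >= 1 & ev$sample + k1 <= n_samp
  if (sum(!ok)) {
    message(sum(!ok), " event(s) dropped: epoch window extends past the recording edge")
  }
  ev <- ev[ok, ]
  if (!nrow(ev)) stop("no epochs remain after boundary exclusion")
  n_t <- k1 - k0 + 1
  data <- array(NA_real_, c(nrow(ev), nrow(recording$data), n_t))
  for (i in seq_len(nrow(ev))) {
    data[i, , ] <- recording$data[, (ev$sample[i] + k0):(ev$sample[i] + k1)]
  }
  rf <- if ("repeat_flag" %in% names(ev)) ev$repeat_flag else rep(FALSE, nrow(ev))
  new_epoch_set(data, (k0:k1) * 1000 / fs, ev$stimulus_id, rf, fs, catalog)
}

#' Downsample an epoch set
#'
#' Anti-alias low-pass filters each trial/channel (zero-phase Butterworth at
#' 80% of the target Nyquist) and decimates by the integer factor
#' `sampling_rate / target_rate`, keeping the sample grid aligned so the
#' timepoint closest to stimulus onset is retained.
#'
#' @param epochs An `epoch_set`.
#' @param target_rate Target sampling rate in Hz; must divide the source
#'   rate.
#' @return The downsampled `epoch_set`.
#' @export
eeg_downsample <- function(epochs, target_rate = 256) {
  stopifnot(inherits(epochs, "epoch_set"))
  fs <- epochs$sampling_rate
  if (target_rate >= fs) stop("target_rate must be below the current rate (", fs, " Hz)")
  q <- fs / target_rate
  if (abs(q - round(q)) > 1e-9) stop("target_rate must divide the source rate")
  q <- as.integer(round(q))
  lp <- signal::butter(4, 0.8 * (target_rate / 2) / (fs / 2), type = "low")
  d <- dim(epochs$data)
  filt <- epochs$data
  for (i in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      # filter around the epoch mean: avoids DC edge transients and keeps
      # constant signals exactly constant
      x <- epochs$data[i, ch, ]
      m <- mean(x)
      filt[i, ch, ] <- signal::filtfilt(lp, x - m) + m
    }
  }
  idx0 <- which.min(abs(epochs$time_ms))
  keep <- which((seq_len(d[3]) - idx0) %% q == 0)
  new_epoch_set(filt[, , keep, drop = FALSE], epochs$time_ms[keep],
                epochs$labels, epochs$repeat_flag, target_rate,
                epochs$catalog, epochs$seed)
}
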