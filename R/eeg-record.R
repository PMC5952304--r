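#' Construct an EEG record
#'
#' A uniformly sampled single-channel voltage trace. All package functions
#' take voltages in microvolts and times in seconds from the recording
#' origin (`start_time`); intervals are half-open `[onset, offset)`.
#'
#' @param samples Numeric vector of voltages (uV).
#' @param sampling_rate Sampling rate in Hz (the study standard is 500 Hz).
#' @param start_time Time of the first sample in seconds from the recording
#'   origin.
#' @param channel_label Free-text channel name.
#' @return An object of class `eeg_record`.
#' @examples
#' rec <- eeg_record(sin(2 * pi * 10 * seq(0, 1, by = 1 / 500)), 500)
#' rec
#' @export
eeg_record <- function(samples, sampling_rate, start_time = 0,
                       channel_label = "EEG") {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("`samples` must be non-empty")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("`sampling_rate` must be a single positive number (Hz)")
  }
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         start_time = start_time, channel_label = as.character(channel_label)),
    class = "eeg_record"
  )
}

#' @export
print.eeg_record <- function(x, ...) {
  dur <- length(x$samples) / x$sampling_rate
  cat(sprintf("<eeg_record> %s: %d samples @ %g Hz (%.1f s), RMS %.2f uV\n",
              x$channel_label, length(x$samples), x$sampling_rate, dur,
              sqrt(mean(x$samples^2))))
  invisible(x)
}

#' @export
length.eeg_record <- function(x) length(x$samples)

#' Duration of a record in seconds
#' @param record An [eeg_record()].
#' @return Duration in seconds.
#' @export
eeg_duration <- function(record) {
  stopifnot(inherits(record, "eeg_record"))
  length(record$samples) / record$sampling_rate
}

#' Sample times of a record
#' @param record An [eeg_record()].
#' @return Numeric vector of times (s) for each sample.
#' @export
eeg_times <- function(record) {
  record$start_time +
    (seq_along(record$samples) - 1L) / record$sampling_rate
}

# index range (1-based, clamped) of the half-open time window [t0, t1)
.sample_window <- function(record, t0, t1) {
  fs <- record$sampling_rate
  i0 <- floor((t0 - record$start_time) * fs) + 1L
  i1 <- ceiling((t1 - record$start_time) * fs)
  c(max(1L, i0), min(length(record$samples), i1))
}

.window_samples <- function(record, t0, t1) {
  ix <- .sample_window(record, t0, t1)
  if (ix[1] > ix[2]) stop("window [", t0, ", ", t1, ") lies outside the record")
  record$samples[ix[1]:ix[2]]
}
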