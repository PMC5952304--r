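# Band-power quantification: zero-phase band-pass filtering, epoch power
# in the study's uV^2/min convention, baseline-relative power, windowed
# means, and movement-artifact removal.

#' Band-pass filter specification
#'
#' The study's two standard bands are 1-100 Hz (acquisition band) and
#' 20-70 Hz (the gamma band used for power quantification, which
#' minimizes movement-artifact contamination). Filtering is a Butterworth
#' design applied forward and backward (zero phase); `order` is the
#' one-pass filter order.
#'
#' @param low_cut,high_cut Band edges in Hz.
#' @param order One-pass Butterworth order (default 4).
#' @param zero_phase Apply forward-backward (default TRUE).
#' @return A `filter_spec` object.
#' @export
filter_spec <- function(low_cut, high_cut, order = 4L, zero_phase = TRUE) {
  stopifnot(low_cut > 0, high_cut > low_cut, order >= 1)
  structure(list(low_cut = low_cut, high_cut = high_cut,
                 order = as.integer(order), zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' Zero-phase band-pass filtering
#'
#' @param record An [eeg_record()].
#' @param spec A [filter_spec()]; band edges must lie below the Nyquist
#'   frequency.
#' @return The filtered [eeg_record()].
#' @examples
#' rec <- eeg_record(rnorm(5000), 500)
#' filtered <- bandpass(rec, filter_spec(20, 70))
#' @export
bandpass <- function(record, spec) {
  stopifnot(inherits(record, "eeg_record"), inherits(spec, "filter_spec"))
  nyq <- record$sampling_rate / 2
  if (spec$high_cut >= nyq) {
    stop("band edge ", spec$high_cut, " Hz is at or above Nyquist (", nyq,
         " Hz)")
  }
  # signal::butter's n is the prototype order; a band-pass doubles it, so
  # n = order/2 realizes the requested one-pass order
  n_proto <- max(1L, as.integer(round(spec$order / 2)))
  bf <- signal::butter(n_proto, c(spec$low_cut, spec$high_cut) / nyq,
                       type = "pass")
  x <- record$samples
  y <- if (spec$zero_phase) {
    signal::filtfilt(bf, x)
  } else {
    signal::filter(bf, x)
  }
  out <- record
  out$samples <- as.numeric(y)
  out
}

#' Per-epoch integrated band power
#'
#' Power in epoch e is the integral of the squared signal over the epoch
#' divided by the epoch length in minutes:
#' `power(e) = sum(x^2 * dt) / (epoch_duration / 60)`, in uV^2/min. A
#' trailing partial epoch is dropped with a message. The input should
#' already be band-pass filtered to the band of interest.
#'
#' @param record An [eeg_record()] (filtered).
#' @param epoch_duration Epoch length in seconds (study standard 300).
#' @return A `band_power_series` object: a data.frame with
#'   `epoch_start` (s) and `power`, plus epoch metadata attributes.
#' @export
epoch_power <- function(record, epoch_duration = 300) {
  stopifnot(inherits(record, "eeg_record"), epoch_duration > 0)
  fs <- record$sampling_rate
  spe <- as.integer(round(epoch_duration * fs))
  n <- length(record$samples)
  if (n < spe) stop("record (", n / fs, " s) is shorter than one epoch (",
                    epoch_duration, " s)")
  n_ep <- n %/% spe
  dropped <- n - n_ep * spe
  if (dropped > 0L) {
    message("epoch_power: dropping trailing partial epoch (",
            round(dropped / fs, 3), " s)")
  }
  x2 <- record$samples[seq_len(n_ep * spe)]^2
  energy <- colSums(matrix(x2, nrow = spe)) / fs       # uV^2 * s per epoch
  power <- energy / (epoch_duration / 60)              # uV^2 / min
  out <- data.frame(
    epoch_start = record$start_time + (seq_len(n_ep) - 1L) * epoch_duration,
    power = power)
  attr(out, "epoch_duration") <- epoch_duration
  attr(out, "relative") <- FALSE
  attr(out, "baseline_mean_power") <- NULL
  class(out) <- c("band_power_series", "data.frame")
  out
}

#' Baseline-relative band power
#'
#' Subtracts the mean power over a baseline window from every epoch, the
#' convention under which quiet post-treatment recordings can show small
#' negative group means. The baseline window is matched against epoch
#' start times (half-open `[t0, t1)`).
#'
#' @param series A `band_power_series` from [epoch_power()].
#' @param baseline_window Numeric `c(t0, t1)` in seconds.
#' @return The series with centred `power` and the `relative` flag set;
#'   the subtracted mean is kept in the `baseline_mean_power` attribute.
#' @export
relative_power <- function(series, baseline_window) {
  stopifnot(inherits(series, "band_power_series"),
            length(baseline_window) == 2L)
  in_base <- series$epoch_start >= baseline_window[1] &
    series$epoch_start < baseline_window[2]
  if (!any(in_base)) {
    stop("baseline window [", baseline_window[1], ", ", baseline_window[2],
         ") covers no epoch")
  }
  base <- mean(series$power[in_base])
  series$power <- series$power - base
  attr(series, "relative") <- TRUE
  attr(series, "baseline_mean_power") <- base
  series
}

#' Mean power over a time window
#'
#' Arithmetic mean of the epochs whose start time lies in `[t0, t1)`,
#' with the window given in hours (the convention of the study's 0-5 h
#' and 10-24 h summaries).
#'
#' @param series A `band_power_series`.
#' @param t0,t1 Window in hours from the series origin.
#' @return A list with `window` (hours), `mean_power` (uV^2/min) and
#'   `n_epochs`.
#' @export
window_mean_power <- function(series, t0, t1) {
  stopifnot(inherits(series, "band_power_series"), t0 < t1)
  sel <- series$epoch_start >= t0 * 3600 & series$epoch_start < t1 * 3600
  if (!any(sel)) stop("window [", t0, ", ", t1, ") h overlaps no epoch")
  list(window = c(t0, t1), mean_power = mean(series$power[sel]),
       n_epochs = sum(sel))
}

#' Remove isolated movement-artifact transients
#'
#' A movement artifact is operationalized as a supra-threshold excursion
#' (amplitude above `profile$multiplier` times the baseline amplitude
#' statistic) that is isolated -- no other supra-threshold excursion
#' within +/- 2 s -- and shorter than 200 ms at half peak. Each such
#' transient is replaced by linear interpolation across a padded window.
#' Excursions inside supplied seizure intervals are never touched.
#'
#' @param record An [eeg_record()].
#' @param baseline A [compute_baseline()] result.
#' @param profile A [detection_profile()]; its multiplier sets the
#'   excursion threshold.
#' @param seizure_intervals Optional two-column matrix / data.frame of
#'   protected `[onset, offset]` intervals (s).
#' @return A list with the cleaned `record` and `annotations`, an
#'   [annotation_set()] of the removed transients.
#' @export
remove_artifact_transients <- function(record, baseline,
                                       profile = detection_profile("acute"),
                                       seizure_intervals = NULL) {
  stopifnot(inherits(record, "eeg_record"), inherits(baseline, "baseline_stats"))
  spikes <- detect_spikes(record, baseline, profile)
  if (nrow(spikes) == 0L) {
    return(list(record = record,
                annotations = annotation_set(character(), numeric())))
  }
  protected <- function(t) {
    if (is.null(seizure_intervals) || NROW(seizure_intervals) == 0L) {
      return(FALSE)
    }
    any(t >= seizure_intervals[, 1] & t <= seizure_intervals[, 2])
  }
  # isolation: nearest other excursion > 2 s away
  tt <- spikes$time
  gap_prev <- c(Inf, diff(tt))
  gap_next <- c(diff(tt), Inf)
  isolated <- pmin(gap_prev, gap_next) > 2
  narrow <- spikes$width_ms < 200
  x <- record$samples
  fs <- record$sampling_rate
  removed <- logical(nrow(spikes))
  for (j in seq_len(nrow(spikes))) {
    if (!isolated[j] || !narrow[j] || protected(tt[j])) next
    pad <- as.integer(round(0.06 * fs))
    i0 <- max(1L, spikes$i_start[j] - pad)
    i1 <- min(length(x), spikes$i_end[j] + pad)
    x[i0:i1] <- seq(x[i0], x[i1], length.out = i1 - i0 + 1L)
    removed[j] <- TRUE
  }
  out <- record
  out$samples <- x
  ann <- annotation_set(kind = rep("artifact", sum(removed)),
                        onset = tt[removed])
  list(record = out, annotations = ann)
}
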