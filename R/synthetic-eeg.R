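# Seeded generative model of rodent cortical EEG with ground-truth labels.
#
# Background: band-limited (1-100 Hz) Gaussian noise with 1/f spectral
# shaping, passed through a soft saturation at 3.7x RMS so an event-free
# trace provably contains no excursion beyond 4x RMS. Spikes are biphasic
# derivative-of-Gaussian wavelets (~60 ms support). Ictal events follow a
# linear amplitude ramp, a sustained spiking plateau, an abrupt offset and
# a post-ictal suppression of the background RMS.

# RMS of a*tanh(N(0,1)/a) for a = 3.7, by quadrature; the saturated noise
# is rescaled by 1/.NOISE_RMS so its RMS is exactly the requested value.
.NOISE_SAT <- 3.7
.NOISE_RMS <- 0.9370188574
# 95th percentile of |saturated background| in units of its RMS
# (= 3.7 * tanh(qnorm(0.975)/3.7) / .NOISE_RMS)
.NOISE_Q95 <- 1.9157757369

#' Nominal baseline amplitude statistic of the synthetic background
#'
#' The 95th percentile of the absolute value of the generator's background
#' noise, the amplitude reference against which synthetic spike and
#' seizure multipliers are programmed. Detectors estimate the same
#' statistic empirically via [compute_baseline()].
#'
#' @param baseline_rms Background RMS in uV.
#' @return Amplitude statistic in uV.
#' @export
nominal_amplitude_stat <- function(baseline_rms) .NOISE_Q95 * baseline_rms

#' Simulation configuration
#'
#' @param duration Total duration in seconds.
#' @param sampling_rate Sampling rate in Hz (study standard 500).
#' @param baseline_rms Background RMS in uV.
#' @param spike_amplitude_multiplier Peak amplitude of isolated spikes
#'   relative to the baseline amplitude statistic.
#' @param seizure_specs List of [seizure_spec()] objects.
#' @param artifact_rate Movement-artifact rate in events/hour (Poisson).
#' @param artifact_amplitude_multiplier Artifact peak relative to the
#'   baseline amplitude statistic.
#' @param seed Integer RNG seed; mandatory, a fixed seed makes the output
#'   bit-identical across calls.
#' @return A `sim_config` object.
#' @export
sim_config <- function(duration, sampling_rate = 500, baseline_rms = 20,
                       spike_amplitude_multiplier = 4,
                       seizure_specs = list(), artifact_rate = 0,
                       artifact_amplitude_multiplier = 6, seed) {
  if (missing(seed)) stop("`seed` is mandatory for reproducible simulation")
  stopifnot(duration > 0, sampling_rate > 0, baseline_rms > 0,
            spike_amplitude_multiplier > 0, artifact_rate >= 0,
            artifact_amplitude_multiplier > 0)
  if (duration < 2) stop("`duration` must be at least 2 s")
  specs <- lapply(seizure_specs, function(s) {
    if (!inherits(s, "seizure_spec")) stop("seizure_specs must be a list of seizure_spec objects")
    s
  })
  if (length(specs)) {
    specs <- specs[order(vapply(specs, `[[`, 0, "onset"))]
    spans <- t(vapply(specs, function(s) c(s$onset, .spec_end(s)), c(0, 0)))
    if (any(spans[, 2] > duration)) {
      stop("seizure spec extends past the recording duration")
    }
    if (nrow(spans) > 1L && any(spans[-1L, 1] < spans[-nrow(spans), 2])) {
      stop("seizure specs overlap (including post-ictal suppression)")
    }
  }
  structure(list(duration = duration, sampling_rate = sampling_rate,
                 baseline_rms = baseline_rms,
                 spike_amplitude_multiplier = spike_amplitude_multiplier,
                 seizure_specs = specs, artifact_rate = artifact_rate,
                 artifact_amplitude_multiplier = artifact_amplitude_multiplier,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Specification of one synthetic ictal event
#'
#' Defaults emulate a typical spontaneous recurrent seizure: a gradual
#' ~8-s intensification, ~30 s of sustained high-amplitude spiking at 5x
#' the baseline amplitude statistic, an abrupt 0.5-s offset and 60 s of
#' post-ictal suppression at one quarter of the baseline RMS.
#'
#' @param onset Ramp start, seconds from recording start.
#' @param ramp_duration Seconds over which spike amplitude rises linearly
#'   from baseline level to the plateau.
#' @param plateau_duration Seconds of sustained spiking.
#' @param offset_duration Seconds over which activity shuts off.
#' @param plateau_amplitude_multiplier Plateau spike peak relative to the
#'   baseline amplitude statistic (> 3 so the chronic detector threshold
#'   is exceeded).
#' @param suppression_duration Post-ictal suppression length (s).
#' @param suppression_fraction Post-ictal background RMS as a fraction of
#'   baseline RMS (in `[0, 1)`).
#' @param spike_rate Spikes per second during ramp and plateau.
#' @return A `seizure_spec` object.
#' @export
seizure_spec <- function(onset, ramp_duration = 8, plateau_duration = 30,
                         offset_duration = 0.5,
                         plateau_amplitude_multiplier = 5,
                         suppression_duration = 60,
                         suppression_fraction = 0.25, spike_rate = 10) {
  stopifnot(onset >= 0, ramp_duration >= 0, plateau_duration >= 0,
            offset_duration >= 0, plateau_amplitude_multiplier > 0,
            suppression_duration >= 0,
            suppression_fraction >= 0, suppression_fraction < 1,
            spike_rate > 0)
  structure(list(onset = onset, ramp_duration = ramp_duration,
                 plateau_duration = plateau_duration,
                 offset_duration = offset_duration,
                 plateau_amplitude_multiplier = plateau_amplitude_multiplier,
                 suppression_duration = suppression_duration,
                 suppression_fraction = suppression_fraction,
                 spike_rate = spike_rate),
            class = "seizure_spec")
}

.spec_end <- function(s) {
  s$onset + s$ramp_duration + s$plateau_duration + s$offset_duration +
    s$suppression_duration
}

# ---- background noise -------------------------------------------------------

# One chunk of unit-RMS 1/f-shaped band-limited (1-100 Hz) Gaussian noise.
.pink_chunk <- function(n, fs) {
  white <- stats::rnorm(n)
  freq <- (seq_len(n) - 1L) * fs / n
  fr <- pmin(freq, fs - freq)
  gain <- ifelse(fr >= 1 & fr <= 100, 1 / sqrt(fr), 0)
  x <- Re(stats::fft(stats::fft(white) * gain, inverse = TRUE)) / n
  # theoretical process SD, so chunks stay statistically homogeneous
  # (an empirical per-chunk rescale would force every chunk's total
  # power equal and bias band power between chunks)
  x / sqrt(mean(gain^2))
}

# Long traces are built from ~70-min chunks cross-faded over 1 s with
# sin/cos amplitude weights (variance-preserving for independent chunks).
.pink_noise <- function(n, fs) {
  chunk <- 2^21L
  if (n <= chunk) return(.pink_chunk(n, fs))
  ov <- as.integer(round(fs))
  hop <- chunk - ov
  w_dn <- cos(pi / 2 * (seq_len(ov) - 1L) / ov)
  w_up <- sin(pi / 2 * (seq_len(ov) - 1L) / ov)
  x <- numeric(n)
  for (s in seq(1L, n, by = hop)) {
    L <- min(chunk, n - s + 1L)
    piece <- .pink_chunk(L, fs)
    if (s == 1L) {
      x[seq_len(L)] <- piece
    } else {
      k <- min(ov, L)
      fade <- s:(s + k - 1L)
      x[fade] <- w_dn[seq_len(k)] * x[fade] + w_up[seq_len(k)] * piece[seq_len(k)]
      if (L > k) x[(s + k):(s + L - 1L)] <- piece[(k + 1L):L]
    }
    if (s + L - 1L >= n) break
  }
  x
}

# soft saturation bounding |x| below 4x RMS, exact RMS restored
.saturate <- function(x) {
  .NOISE_SAT * tanh(x / .NOISE_SAT) / .NOISE_RMS
}

# ---- spike wavelet ----------------------------------------------------------

# biphasic derivative-of-Gaussian, |peak| = 1, support +/- 4 sigma
.dog_wavelet <- function(fs, sigma = 0.010) {
  t <- seq(-4 * sigma, 4 * sigma, by = 1 / fs)
  (t / sigma) * exp(0.5 - t^2 / (2 * sigma^2))
}

# add `amp * wavelet` centred at time `at` (s), clipped to the trace
.add_wavelet <- function(x, fs, at, amp, sigma = 0.010) {
  w <- .dog_wavelet(fs, sigma)
  half <- (length(w) - 1L) %/% 2L
  centre <- as.integer(round(at * fs)) + 1L
  idx <- (centre - half):(centre + half)
  keep <- idx >= 1L & idx <= length(x)
  x[idx[keep]] <- x[idx[keep]] + amp * w[keep]
  x
}
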