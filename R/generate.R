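# Realization of simulated recordings and their ground-truth labels.

# chronic detection reference (3x) used only to label the first spike of a
# ground-truth seizure that a 3x-threshold reader could see; keeps the
# ground-truth duration definition independent of any detector object
.REF_MULT <- 3

.ground_truth <- function(duration, spikes, seizures, artifacts,
                          se_interval = NULL) {
  structure(list(duration = duration, spikes = spikes, seizures = seizures,
                 artifacts = artifacts, se_interval = se_interval),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %.0f s: %d spikes, %d seizures, %d artifacts%s\n",
              x$duration, nrow(x$spikes), nrow(x$seizures),
              length(x$artifacts),
              if (is.null(x$se_interval)) "" else
                sprintf(", SE [%.0f, %.0f] s", x$se_interval[1],
                        x$se_interval[2])))
  invisible(x)
}

.empty_spikes <- function() {
  data.frame(time = numeric(), multiplier = numeric(), seizure = integer())
}

.empty_seizures <- function() {
  data.frame(onset = numeric(), offset = numeric(),
             t_first_spike = numeric(), t_last_spike = numeric(),
             n_spikes = integer(), duration = numeric())
}

# spike times at `rate`/s with +/-20% jittered intervals on [from, to)
.spike_times <- function(from, to, rate) {
  if (to <= from) return(numeric())
  n_max <- ceiling((to - from) * rate * 1.4) + 2L
  gaps <- (1 / rate) * stats::runif(n_max, 0.8, 1.2)
  t <- from + c(0, cumsum(gaps))
  t[t < to]
}

.add_spikes <- function(x, fs, times, amps, sigma = 0.010) {
  w <- .dog_wavelet(fs, sigma)
  half <- (length(w) - 1L) %/% 2L
  n <- length(x)
  for (j in seq_along(times)) {
    centre <- as.integer(round(times[j] * fs)) + 1L
    idx <- (centre - half):(centre + half)
    keep <- which(idx >= 1L & idx <= n)
    x[idx[keep]] <- x[idx[keep]] + amps[j] * w[keep]
  }
  x
}

# multiply noise by the post-ictal envelope of one seizure spec:
# 1 -> fraction across the offset ramp, fraction during suppression,
# then back to 1 over a 1-s recovery
.apply_suppression <- function(x, fs, spec) {
  f <- spec$suppression_fraction
  t_off <- spec$onset + spec$ramp_duration + spec$plateau_duration
  n <- length(x)
  seg <- function(t0, t1) {
    i0 <- max(1L, as.integer(floor(t0 * fs)) + 1L)
    i1 <- min(n, as.integer(ceiling(t1 * fs)))
    if (i0 > i1) integer() else i0:i1
  }
  io <- seg(t_off, t_off + spec$offset_duration)
  if (length(io)) x[io] <- x[io] * seq(1, f, length.out = length(io))
  is <- seg(t_off + spec$offset_duration,
            t_off + spec$offset_duration + spec$suppression_duration)
  if (length(is)) x[is] <- x[is] * f
  ir <- seg(t_off + spec$offset_duration + spec$suppression_duration,
            t_off + spec$offset_duration + spec$suppression_duration + 1)
  if (length(ir)) x[ir] <- x[ir] * seq(f, 1, length.out = length(ir))
  x
}

# realize spike times/amplitudes of one seizure spec
.plan_seizure <- function(spec, stat) {
  M <- spec$plateau_amplitude_multiplier
  t_plateau_end <- spec$onset + spec$ramp_duration + spec$plateau_duration
  times <- .spike_times(spec$onset, t_plateau_end, spec$spike_rate)
  if (!length(times)) stop("seizure spec realizes no spikes")
  m <- ifelse(spec$ramp_duration > 0 & times < spec$onset + spec$ramp_duration,
              1 + (M - 1) * (times - spec$onset) / spec$ramp_duration, M)
  jitter <- stats::runif(length(times), 0.95, 1.05)
  sgn <- sample(c(-1, 1), length(times), replace = TRUE)
  list(times = times, amps = sgn * m * jitter * stat, multipliers = m)
}

# realized absolute peak of the trace around each spike time (+/- 30 ms)
.realized_peaks <- function(x, fs, times) {
  n <- length(x)
  half <- as.integer(round(0.03 * fs))
  vapply(times, function(t) {
    c0 <- as.integer(round(t * fs)) + 1L
    max(abs(x[max(1L, c0 - half):min(n, c0 + half)]))
  }, numeric(1))
}

# ground-truth detectable span of one realized seizure: first/last spike
# of the sustained run whose realized peak exceeds the chronic 3x
# reference (capped at the spec's own plateau multiplier), matching what
# an ideal rule-based reader of the realized trace measures
.label_span <- function(x, fs, times, stat, M) {
  peaks <- .realized_peaks(x, fs, times)
  thr <- min(.REF_MULT, M * 0.999) * stat
  above <- times[peaks > thr]
  if (!length(above)) return(c(times[1], times[length(times)]))
  .sustained_run_bounds(above)
}

#' Generate a synthetic EEG recording with ground truth
#'
#' Realizes the background-noise model, every [seizure_spec()] in the
#' configuration and (optionally) Poisson-placed isolated movement
#' artifacts, under a single RNG stream seeded from `config$seed`.
#' Artifacts are kept at least 5 s away from any seizure (including its
#' post-ictal suppression) and from each other, so artifact labels are
#' unambiguous.
#'
#' @param config A [sim_config()].
#' @return A list with elements `record` (an [eeg_record()]) and `truth`
#'   (a `ground_truth` object with spike times, seizure intervals and
#'   labelled detectable spans, and artifact times).
#' @export
generate_eeg <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  fs <- config$sampling_rate
  n <- as.integer(round(config$duration * fs))
  stat <- nominal_amplitude_stat(config$baseline_rms)

  x <- .saturate(.pink_noise(n, fs)) * config$baseline_rms
  for (spec in config$seizure_specs) x <- .apply_suppression(x, fs, spec)

  spikes <- .empty_spikes()
  seizures <- .empty_seizures()
  for (k in seq_along(config$seizure_specs)) {
    spec <- config$seizure_specs[[k]]
    plan <- .plan_seizure(spec, stat)
    x <- .add_spikes(x, fs, plan$times, plan$amps)
    span <- .label_span(x, fs, plan$times, stat,
                        spec$plateau_amplitude_multiplier)
    spikes <- rbind(spikes, data.frame(time = plan$times,
                                       multiplier = plan$multipliers,
                                       seizure = k))
    offset <- spec$onset + spec$ramp_duration + spec$plateau_duration +
      spec$offset_duration
    seizures <- rbind(seizures, data.frame(
      onset = spec$onset, offset = offset,
      t_first_spike = span[1], t_last_spike = span[2],
      n_spikes = length(plan$times),
      duration = span[2] - span[1]))
  }

  art_times <- numeric()
  if (config$artifact_rate > 0) {
    n_art <- stats::rpois(1L, config$artifact_rate * config$duration / 3600)
    cand <- sort(stats::runif(n_art, 1, config$duration - 1))
    art_times <- .isolate_times(cand, seizures, min_gap = 5)
    if (length(art_times)) {
      sgn <- sample(c(-1, 1), length(art_times), replace = TRUE)
      x <- .add_spikes(x, fs, art_times,
                       sgn * config$artifact_amplitude_multiplier * stat,
                       sigma = 0.008)
    }
  }

  record <- eeg_record(x, fs, channel_label = "SYN")
  truth <- .ground_truth(config$duration, spikes, seizures, art_times)
  list(record = record, truth = truth)
}

# keep candidate times >= `min_gap` s from any seizure span (incl.
# suppression via offset + 61 s guard handled by caller margins), from
# each other, and from an optional extra interval
.isolate_times <- function(cand, seizures, min_gap = 5, extra = NULL,
                           suppression_pad = 61) {
  if (!length(cand)) return(numeric())
  keep <- rep(TRUE, length(cand))
  if (nrow(seizures)) {
    for (i in seq_len(nrow(seizures))) {
      keep <- keep & (cand < seizures$onset[i] - min_gap |
                        cand > seizures$offset[i] + suppression_pad + min_gap)
    }
  }
  if (!is.null(extra)) {
    keep <- keep & (cand < extra[1] - min_gap | cand > extra[2] + min_gap)
  }
  cand <- cand[keep]
  if (length(cand) > 1L) {
    ok <- c(TRUE, diff(cand) >= min_gap)
    cand <- cand[ok]
  }
  cand
}

#' Generate a status-epilepticus scenario
#'
#' An initial discrete electrographic seizure at `se_onset` (2-s ramp to
#' 4x amplitude, ~20 s of spiking, then rapid quieting for 30 s) followed
#' by near-continuous supra-threshold spiking until
#' `se_onset + se_duration`, emulating the persistent large-amplitude
#' high-frequency spiking of organophosphate-induced SE. With
#' `se_duration = 0` the output equals [generate_eeg()] under the same
#' seed, with a degenerate `se_interval`.
#'
#' @param config A [sim_config()] without seizure specs.
#' @param se_onset SE onset time (s).
#' @param se_duration SE duration (s); 0 or at least 60.
#' @return As [generate_eeg()]; `truth$se_interval` is set.
#' @export
generate_se_scenario <- function(config, se_onset, se_duration) {
  stopifnot(inherits(config, "sim_config"))
  if (length(config$seizure_specs)) {
    stop("generate_se_scenario expects a config without seizure_specs")
  }
  if (se_onset < 0 || se_onset + se_duration > config$duration) {
    stop("SE interval [", se_onset, ", ", se_onset + se_duration,
         "] extends past the recording duration")
  }
  if (se_duration == 0) {
    out <- generate_eeg(config)
    out$truth$se_interval <- c(se_onset, se_onset)
    return(out)
  }
  if (se_duration < 60) {
    stop("`se_duration` must be 0 or at least 60 s for the full ",
         "seizure/quieting/continuous-spiking structure")
  }
  set.seed(config$seed)
  fs <- config$sampling_rate
  n <- as.integer(round(config$duration * fs))
  stat <- nominal_amplitude_stat(config$baseline_rms)
  x <- .saturate(.pink_noise(n, fs)) * config$baseline_rms

  # initial discrete seizure: 2-s ramp to 4x, spiking to +20 s
  init_spec <- seizure_spec(onset = se_onset, ramp_duration = 2,
                            plateau_duration = 18, offset_duration = 0.5,
                            plateau_amplitude_multiplier = 4,
                            suppression_duration = 0,
                            suppression_fraction = 0.5, spike_rate = 10)
  plan <- .plan_seizure(init_spec, stat)
  x <- .add_spikes(x, fs, plan$times, plan$amps)
  span <- .label_span(x, fs, plan$times, stat, 4)

  # rapid quieting for 30 s, then near-continuous spiking
  t_cont <- se_onset + 50
  t_end <- se_onset + se_duration
  ct <- .spike_times(t_cont, t_end, rate = 8)
  cm <- stats::runif(length(ct), 2.5, 4.5)
  sgn <- sample(c(-1, 1), length(ct), replace = TRUE)
  x <- .add_spikes(x, fs, ct, sgn * cm * stat)

  spikes <- rbind(
    data.frame(time = plan$times, multiplier = plan$multipliers, seizure = 1L),
    data.frame(time = ct, multiplier = cm, seizure = NA_integer_))
  seizures <- data.frame(onset = se_onset, offset = se_onset + 20.5,
                         t_first_spike = span[1],
                         t_last_spike = span[2],
                         n_spikes = length(plan$times),
                         duration = span[2] - span[1])

  art_times <- numeric()
  if (config$artifact_rate > 0) {
    n_art <- stats::rpois(1L, config$artifact_rate * config$duration / 3600)
    cand <- sort(stats::runif(n_art, 1, config$duration - 1))
    art_times <- .isolate_times(cand, seizures, extra = c(se_onset, t_end),
                                suppression_pad = 0)
    if (length(art_times)) {
      sgn <- sample(c(-1, 1), length(art_times), replace = TRUE)
      x <- .add_spikes(x, fs, art_times,
                       sgn * config$artifact_amplitude_multiplier * stat,
                       sigma = 0.008)
    }
  }

  record <- eeg_record(x, fs, channel_label = "SYN")
  truth <- .ground_truth(config$duration, spikes, seizures, art_times,
                         se_interval = c(se_onset, t_end))
  list(record = record, truth = truth)
}

#' Inject isolated movement artifacts into a recording
#'
#' Adds one biphasic transient (width < 100 ms) per requested time, with
#' peak amplitude `multiplier` times the record's baseline amplitude
#' statistic (95th percentile of the absolute signal unless supplied).
#' Everything else is left unchanged.
#'
#' @param record An [eeg_record()].
#' @param times Artifact centre times (s); must lie within the record.
#' @param multiplier Peak amplitude relative to the amplitude statistic.
#' @param amplitude_stat Optional explicit amplitude statistic (uV).
#' @return A list with the modified `record` and a `truth` object whose
#'   `artifacts` field lists the injected times.
#' @export
inject_artifacts <- function(record, times, multiplier,
                             amplitude_stat = NULL) {
  stopifnot(inherits(record, "eeg_record"))
  dur <- eeg_duration(record)
  t0 <- record$start_time
  if (length(times) && (min(times) < t0 || max(times) > t0 + dur)) {
    stop("artifact times fall outside the record span")
  }
  if (is.null(amplitude_stat)) {
    amplitude_stat <- stats::quantile(abs(record$samples), 0.95, names = FALSE)
  }
  x <- record$samples
  if (length(times)) {
    # alternate polarity deterministically; injection consumes no RNG
    sgn <- rep_len(c(1, -1), length(times))
    x <- .add_spikes(x, record$sampling_rate, times - t0,
                     sgn * multiplier * amplitude_stat, sigma = 0.008)
  }
  out <- record
  out$samples <- x
  truth <- .ground_truth(dur, .empty_spikes(), .empty_seizures(),
                         sort(as.numeric(times)))
  list(record = out, truth = truth)
}

#' Canonical spontaneous-recurrent-seizure validation scenario
#'
#' A seeded recording containing `n_seizures` spec-compliant seizures
#' (default [seizure_spec()] shape) evenly spaced so that every event is
#' preceded by more than 5 min of quiet baseline, plus `n_artifacts`
#' isolated movement artifacts placed midway between events. This is the
#' fixture used to validate detector sensitivity, precision and duration
#' recovery.
#'
#' @param seed Integer seed.
#' @param n_seizures,n_artifacts Event counts.
#' @param duration Recording length (s); default 2 h.
#' @param baseline_rms Background RMS (uV).
#' @param artifact_multiplier Artifact amplitude multiplier.
#' @return As [generate_eeg()], with artifact labels merged into `truth`.
#' @export
generate_srs_study <- function(seed, n_seizures = 20, n_artifacts = 20,
                               duration = 7200, baseline_rms = 20,
                               artifact_multiplier = 6) {
  lead <- 400
  tail <- 110
  spacing <- if (n_seizures > 1) {
    (duration - lead - tail) / (n_seizures - 1)
  } else {
    0
  }
  if (n_seizures > 1 && spacing < 340) {
    stop("duration too short to keep >5 min of quiet before every seizure")
  }
  onsets <- lead + spacing * (seq_len(n_seizures) - 1L)
  specs <- lapply(onsets, function(o) seizure_spec(onset = o))
  cfg <- sim_config(duration = duration, baseline_rms = baseline_rms,
                    seizure_specs = specs, artifact_rate = 0, seed = seed)
  sim <- generate_eeg(cfg)
  if (n_artifacts > 0) {
    anchors <- c(50, onsets[-n_seizures] + 180)
    k <- seq_len(n_artifacts) - 1L
    at <- anchors[(k %% length(anchors)) + 1L] + 25 * (k %/% length(anchors))
    inj <- inject_artifacts(sim$record, at, artifact_multiplier,
                            amplitude_stat = nominal_amplitude_stat(baseline_rms))
    sim$record <- inj$record
    sim$truth$artifacts <- sort(c(sim$truth$artifacts, inj$truth$artifacts))
  }
  sim
}

#' Export ground-truth labels as an annotation set
#'
#' @param truth A `ground_truth` object.
#' @return An [annotation_set()] with spike, seizure, artifact and
#'   `se_onset` rows.
#' @export
ground_truth_annotations <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  kinds <- c(rep("spike", nrow(truth$spikes)),
             rep("seizure", nrow(truth$seizures)),
             rep("artifact", length(truth$artifacts)))
  onsets <- c(truth$spikes$time, truth$seizures$onset, truth$artifacts)
  offsets <- c(truth$spikes$time, truth$seizures$offset, truth$artifacts)
  if (!is.null(truth$se_interval)) {
    kinds <- c(kinds, "se_onset")
    onsets <- c(onsets, truth$se_interval[1])
    offsets <- c(offsets, truth$se_interval[2])
  }
  annotation_set(kind = kinds, onset = onsets, offset = offsets)
}
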