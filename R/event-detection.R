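# Rule-based detectors: baseline amplitude statistic, threshold spike
# detection, SE-onset detection, the five-criterion spontaneous-recurrent-
# seizure detector, and seizure-duration measurement.
#
# Conventions shared by all detectors:
#   * the spike threshold is `multiplier x amplitude_stat`, with a STRICT
#     inequality at the crossing;
#   * the envelope statistic is the RMS in a centred 1-s sliding window;
#   * envelope-level comparisons (quieting, shutoff) use 2x the baseline
#     RMS, and post-ictal suppression uses `suppression_rms_fraction` x
#     baseline RMS.

#' Baseline amplitude statistics
#'
#' Computes the amplitude reference used by all detectors over a quiet
#' window: the 95th percentile of the absolute (band-filtered) signal,
#' plus the window RMS. The window must be at least 60 s long and, when
#' ground truth is available, free of labelled events.
#'
#' @param record An [eeg_record()] (already filtered to the analysis
#'   band).
#' @param window Numeric `c(t0, t1)` in seconds.
#' @return A `baseline_stats` object with `amplitude_stat` (uV), `rms`
#'   (uV), `window` and `duration`.
#' @export
compute_baseline <- function(record, window) {
  stopifnot(inherits(record, "eeg_record"), length(window) == 2L)
  dur <- window[2] - window[1]
  if (dur < 60) stop("baseline window must be at least 60 s (got ", dur, " s)")
  x <- .window_samples(record, window[1], window[2])
  stat <- stats::quantile(abs(x), 0.95, names = FALSE)
  if (stat <= 0) stop("baseline window has zero amplitude; cannot form a ",
                      "spike threshold")
  structure(list(window = window, amplitude_stat = stat,
                 rms = sqrt(mean(x^2)), duration = dur),
            class = "baseline_stats")
}

#' @export
print.baseline_stats <- function(x, ...) {
  cat(sprintf("<baseline_stats> [%g, %g] s: amplitude_stat %.2f uV, RMS %.2f uV\n",
              x$window[1], x$window[2], x$amplitude_stat, x$rms))
  invisible(x)
}

#' Detection profiles
#'
#' Two standard profiles: `"acute"` (2x a 10-min baseline, used around
#' the chemoconvulsant exposure) and `"chronic"` (3x a 5-min baseline,
#' used for spontaneous recurrent seizure screening). All rule
#' parameters can be overridden.
#'
#' @param type `"acute"` or `"chronic"`.
#' @param ... Named overrides of the profile fields: `multiplier`,
#'   `baseline_duration`, `min_quiet_before`, `min_ictal_duration`,
#'   `min_suppression_duration`, `min_ramp_duration`,
#'   `max_shutoff_duration`, `suppression_rms_fraction`,
#'   `refractory`, `max_spike_width_ms`, `candidate_gap`,
#'   `envelope_window`.
#' @return A `detection_profile` object.
#' @export
detection_profile <- function(type = c("acute", "chronic"), ...) {
  type <- match.arg(type)
  p <- list(
    type = type,
    multiplier = if (type == "acute") 2 else 3,
    baseline_duration = if (type == "acute") 600 else 300,
    min_quiet_before = 300,
    min_ictal_duration = 20,
    min_suppression_duration = 30,
    min_ramp_duration = 2,
    max_shutoff_duration = 2,
    suppression_rms_fraction = 0.5,
    refractory = 0.05,
    max_spike_width_ms = 200,
    candidate_gap = 5,
    envelope_window = 1
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) stop("unknown profile field(s): ", paste(bad, collapse = ", "))
  p[names(dots)] <- dots
  stopifnot(p$multiplier > 0, p$baseline_duration > 0,
            p$min_ictal_duration > 0, p$min_suppression_duration > 0)
  structure(p, class = "detection_profile")
}

# centred sliding-window RMS envelope, O(n) via cumulative sums
.rms_envelope <- function(x, fs, window = 1) {
  n <- length(x)
  half <- as.integer(round(window * fs / 2))
  cs <- c(0, cumsum(x^2))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  sqrt((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
}

#' Detect epileptiform spikes
#'
#' A spike is a contiguous excursion with `|x|` strictly greater than
#' `multiplier x amplitude_stat`, grouped with a 50-ms refractory merge
#' and gated on sharpness (width at half peak below 200 ms). Events are
#' returned sorted by time.
#'
#' @param record An [eeg_record()].
#' @param baseline A [compute_baseline()] result from the same recording
#'   (or explicitly supplied).
#' @param profile A [detection_profile()].
#' @return A data.frame with one row per spike: `time` (s, at the peak),
#'   `peak_amplitude` (uV), `ratio` (peak / amplitude_stat), `width_ms`,
#'   and the sample extent `i_start`, `i_end` of the excursion group.
#' @export
detect_spikes <- function(record, baseline,
                          profile = detection_profile("acute")) {
  stopifnot(inherits(record, "eeg_record"),
            inherits(baseline, "baseline_stats"),
            inherits(profile, "detection_profile"))
  if (baseline$amplitude_stat <= 0) stop("baseline amplitude statistic is zero")
  thr <- profile$multiplier * baseline$amplitude_stat
  x <- record$samples
  fs <- record$sampling_rate
  ax <- abs(x)
  above <- ax > thr
  empty <- data.frame(time = numeric(), peak_amplitude = numeric(),
                      ratio = numeric(), width_ms = numeric(),
                      i_start = integer(), i_end = integer())
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  starts <- starts[r$values]
  ends <- ends[r$values]
  # refractory merge on peak distance: runs whose |x| peaks fall within
  # 50 ms are one biphasic event (the two lobes of one transient),
  # whichever threshold carved them up
  pk <- vapply(seq_along(starts), function(j) {
    seg <- starts[j]:ends[j]
    seg[which.max(ax[seg])]
  }, integer(1))
  grp <- if (length(pk) > 1L) {
    cumsum(c(1L, as.integer(diff(pk) / fs >= profile$refractory)))
  } else {
    rep(1L, length(pk))
  }
  starts <- as.integer(tapply(starts, grp, min))
  ends <- as.integer(tapply(ends, grp, max))
  m <- length(starts)
  time <- peak <- width <- numeric(m)
  for (j in seq_len(m)) {
    seg <- starts[j]:ends[j]
    p <- seg[which.max(ax[seg])]
    v <- ax[p]
    half <- v / 2
    lo <- p
    while (lo > 1L && ax[lo - 1L] >= half) lo <- lo - 1L
    hi <- p
    while (hi < length(x) && ax[hi + 1L] >= half) hi <- hi + 1L
    time[j] <- record$start_time + (p - 1L) / fs
    peak[j] <- v
    width[j] <- (hi - lo + 1L) / fs * 1000
  }
  keep <- width < profile$max_spike_width_ms
  out <- data.frame(time = time, peak_amplitude = peak,
                    ratio = peak / baseline$amplitude_stat,
                    width_ms = width,
                    i_start = as.integer(starts), i_end = as.integer(ends))
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# group spike times into trains with inter-spike gaps <= max_gap
.spike_trains <- function(times, max_gap) {
  if (!length(times)) return(integer())
  cumsum(c(1L, as.integer(diff(times) > max_gap)))
}

# first/last spike of the sustained high-frequency run (>= `k` spikes
# inside `span` seconds); falls back to the full extent when no such run
# exists. Shared by the detector and the ground-truth labeller so both
# use one definition of the "initial spike" of continuous spiking.
.sustained_run_bounds <- function(times, k = 3L, span = 1) {
  m <- length(times)
  if (m < k) return(c(times[1], times[m]))
  hit <- which(times[k:m] - times[1:(m - k + 1L)] <= span)
  if (!length(hit)) return(c(times[1], times[m]))
  c(times[hit[1]], times[hit[length(hit)] + k - 1L])
}

#' Detect the onset of status epilepticus
#'
#' SE onset is the first time a supra-threshold spike train persists for
#' more than 10 s (no inter-spike gap above 2 s) and is followed within
#' 60 s by the 1-s RMS envelope dropping below 2x the baseline RMS (the
#' "rapid quieting" after the initial discrete seizure).
#'
#' @param record An [eeg_record()].
#' @param baseline A [compute_baseline()] result.
#' @param profile A [detection_profile()] (the acute 2x profile by
#'   default).
#' @return Onset time in seconds, or `NULL` when no qualifying train is
#'   found.
#' @export
detect_se_onset <- function(record, baseline,
                            profile = detection_profile("acute")) {
  spikes <- detect_spikes(record, baseline, profile)
  if (nrow(spikes) == 0L) return(NULL)
  env <- .rms_envelope(record$samples, record$sampling_rate,
                       profile$envelope_window)
  fs <- record$sampling_rate
  quiet_level <- 2 * baseline$rms
  grp <- .spike_trains(spikes$time, max_gap = 2)
  for (g in unique(grp)) {
    tt <- spikes$time[grp == g]
    if (tt[length(tt)] - tt[1] <= 10) next
    i0 <- min(length(env), as.integer(round((tt[length(tt)] -
                                               record$start_time) * fs)) + 1L)
    i1 <- min(length(env), i0 + as.integer(60 * fs))
    if (any(env[i0:i1] < quiet_level)) return(tt[1])
  }
  NULL
}

#' Detect spontaneous recurrent seizures (five-criterion rule)
#'
#' Candidate events are supra-threshold spike trains (inter-spike gap at
#' most `candidate_gap`, default 5 s) with onset/offset at the first and
#' last spike. Each candidate is scored on the five criteria:
#'
#' 1. `quiet_before` -- no supra-threshold spike in the
#'    `min_quiet_before` (300 s) window before onset AND pre-onset RMS
#'    below 2x the baseline RMS;
#' 2. `gradual_ramp` -- the 1-s RMS envelope needs at least
#'    `min_ramp_duration` (2 s) from onset to reach 90% of the event
#'    maximum;
#' 3. `sustained_spiking` -- duration above `min_ictal_duration` (20 s)
#'    and at least 80% of the non-overlapping 1-s windows inside the
#'    event contain a supra-threshold spike;
#' 4. `abrupt_shutoff` -- the envelope falls from its last crossing of
#'    50% of the event maximum to below 2x baseline RMS within
#'    `max_shutoff_duration` (2 s);
#' 5. `postictal_suppression` -- the envelope stays at or below
#'    `suppression_rms_fraction` (0.5) x baseline RMS for at least
#'    `min_suppression_duration` (30 s), beginning within 5 s of offset.
#'
#' An event is accepted if and only if all five flags are true; rejected
#' candidates are returned as well, with their flags, for audit.
#' Movement artifacts should be removed first (see
#' [remove_artifact_transients()]); an isolated artifact spike inside a
#' pre-onset window otherwise (correctly) voids criterion 1.
#'
#' @param record An [eeg_record()].
#' @param baseline A [compute_baseline()] result (5-min chronic window).
#' @param profile A [detection_profile()] (the chronic 3x profile by
#'   default).
#' @return A data.frame of candidates: `onset`, `offset`, `duration`
#'   (all anchored on the sustained run), `cand_onset` (first detected
#'   spike of the candidate, build-up fringe included), `n_spikes`, the
#'   five criterion flags, `suppression_duration` and `accepted`. The
#'   profile is attached as attribute `profile`.
#' @export
detect_srs <- function(record, baseline,
                       profile = detection_profile("chronic")) {
  stopifnot(inherits(profile, "detection_profile"))
  need <- profile$min_quiet_before + profile$min_ictal_duration +
    profile$min_suppression_duration
  if (eeg_duration(record) < need) {
    stop("record (", eeg_duration(record), " s) is shorter than the ",
         "minimum analyzable span (", need, " s)")
  }
  spikes <- detect_spikes(record, baseline, profile)
  out <- data.frame(onset = numeric(), offset = numeric(),
                    duration = numeric(), cand_onset = numeric(),
                    n_spikes = integer(),
                    quiet_before = logical(), gradual_ramp = logical(),
                    sustained_spiking = logical(),
                    abrupt_shutoff = logical(),
                    postictal_suppression = logical(),
                    suppression_duration = numeric(), accepted = logical())
  attr(out, "profile") <- profile
  if (nrow(spikes) == 0L) return(out)

  x <- record$samples
  fs <- record$sampling_rate
  env <- .rms_envelope(x, fs, profile$envelope_window)
  t_of <- function(i) record$start_time + (i - 1L) / fs
  i_of <- function(t) {
    pmin(length(x), pmax(1L, as.integer(round((t - record$start_time) * fs)) + 1L))
  }
  quiet_level <- 2 * baseline$rms
  supp_level <- profile$suppression_rms_fraction * baseline$rms

  grp <- .spike_trains(spikes$time, max_gap = profile$candidate_gap)
  rows <- lapply(unique(grp), function(g) {
    tt <- spikes$time[grp == g]
    # the event is the sustained high-frequency run: anchor onset/offset
    # at its first/last spike, so a lone noise-assisted fringe crossing
    # does not stretch the measured span; the candidate's first spike
    # (fringe included) still marks where the build-up begins
    cand_onset <- tt[1]
    bounds <- .sustained_run_bounds(tt)
    tt <- tt[tt >= bounds[1] & tt <= bounds[2]]
    onset <- tt[1]
    offset <- tt[length(tt)]
    duration <- offset - onset

    # (1) quiet baseline before the event's build-up
    pre0 <- cand_onset - profile$min_quiet_before
    quiet_before <- FALSE
    if (pre0 >= record$start_time) {
      other <- spikes$time[grp != g]
      no_spike <- !any(other >= pre0 & other < cand_onset)
      pre_rms <- sqrt(mean(x[i_of(pre0):i_of(cand_onset)]^2))
      quiet_before <- no_spike && pre_rms < quiet_level
    }

    ev <- i_of(onset):i_of(offset)
    emax <- max(env[ev])

    # (2) gradual ramp: time from onset to 90% of event max
    i90 <- ev[which(env[ev] >= 0.9 * emax)[1]]
    gradual_ramp <- (t_of(i90) - onset) >= profile$min_ramp_duration

    # (3) sustained spiking in >= 80% of 1-s windows, duration > 20 s
    wins <- floor(duration)
    covered <- if (wins >= 1L) {
      w <- findInterval(tt, onset + 0:wins, rightmost.closed = FALSE)
      length(unique(w[w >= 1L & w <= wins])) / wins
    } else {
      0
    }
    sustained <- duration > profile$min_ictal_duration && covered >= 0.8

    # (4) abrupt shutoff: last 50%-of-max crossing to below 2x RMS
    i50 <- ev[max(which(env[ev] >= 0.5 * emax))]
    post <- i_of(t_of(i50)):i_of(min(t_of(length(x)),
                                     t_of(i50) + 4 * profile$max_shutoff_duration))
    below <- which(env[post] < quiet_level)
    shutoff <- length(below) > 0 &&
      (below[1] - 1L) / fs <= profile$max_shutoff_duration

    # (5) post-ictal suppression >= 30 s, starting within 5 s of offset;
    # the envelope can wiggle around the threshold at the crossing, so
    # take the longest below-threshold run starting inside the window
    supp_dur <- 0
    j0 <- i_of(offset)
    jend <- i_of(min(t_of(length(x)), offset + 5 + 300))
    below <- env[j0:jend] <= supp_level
    r5 <- rle(below)
    run_end <- cumsum(r5$lengths)
    run_start <- run_end - r5$lengths + 1L
    ok <- r5$values & run_start <= 5 * fs + 1L
    if (any(ok)) supp_dur <- max(r5$lengths[ok]) / fs
    suppression <- supp_dur >= profile$min_suppression_duration

    data.frame(onset = onset, offset = offset, duration = duration,
               cand_onset = cand_onset,
               n_spikes = length(tt), quiet_before = quiet_before,
               gradual_ramp = gradual_ramp, sustained_spiking = sustained,
               abrupt_shutoff = shutoff,
               postictal_suppression = suppression,
               suppression_duration = supp_dur,
               accepted = quiet_before && gradual_ramp && sustained &&
                 shutoff && suppression)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "profile") <- profile
  out
}

#' Seizure duration from spike times
#'
#' The study convention: duration is measured from the initial spike to
#' the last detectable spike just before the post-ictal depression.
#'
#' @param event One detected event (a row of [detect_srs()] output, or
#'   any list with `onset` and `offset`).
#' @param spikes A [detect_spikes()] table (or vector of spike times).
#' @return Duration in seconds.
#' @export
seizure_duration <- function(event, spikes) {
  times <- if (is.data.frame(spikes)) spikes$time else as.numeric(spikes)
  inside <- times[times >= event$onset & times <= event$offset]
  if (length(inside) < 2L) {
    stop("need at least two spikes within the event span to measure a duration")
  }
  max(inside) - min(inside)
}

#' Score detections against ground truth
#'
#' Matches accepted detections to ground-truth seizures by interval
#' overlap and reports sensitivity, precision and duration errors
#' (detected duration minus the ground-truth first-to-last-spike
#' duration).
#'
#' @param detections A [detect_srs()] result.
#' @param truth A `ground_truth` object.
#' @return A list with `sensitivity`, `precision`, `n_true`,
#'   `n_detected`, and `duration_errors` (one per matched pair).
#' @export
score_detections <- function(detections, truth) {
  stopifnot(inherits(truth, "ground_truth"))
  acc <- detections[detections$accepted, , drop = FALSE]
  gt <- truth$seizures
  n_true <- nrow(gt)
  n_det <- nrow(acc)
  if (n_true == 0L || n_det == 0L) {
    return(list(sensitivity = if (n_true == 0L) NA_real_ else 0,
                precision = if (n_det == 0L) NA_real_ else 0,
                n_true = n_true, n_detected = n_det,
                duration_errors = numeric()))
  }
  matched_gt <- logical(n_true)
  matched_det <- logical(n_det)
  errors <- numeric()
  for (i in seq_len(n_true)) {
    ov <- which(acc$onset <= gt$offset[i] & acc$offset >= gt$onset[i])
    if (length(ov)) {
      j <- ov[1]
      matched_gt[i] <- TRUE
      matched_det[j] <- TRUE
      errors <- c(errors, acc$duration[j] - gt$duration[i])
    }
  }
  list(sensitivity = mean(matched_gt), precision = mean(matched_det),
       n_true = n_true, n_detected = n_det, duration_errors = errors)
}
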