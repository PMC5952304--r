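# Shared fixtures, memoized so expensive simulations run once per suite.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# 600-s recording with one spec-compliant seizure at 400 s
fixture_one_seizure <- function(seed = 2) {
  memo(paste0("one_seizure_", seed), {
    cfg <- sim_config(duration = 600,
                      seizure_specs = list(seizure_spec(onset = 400)),
                      seed = seed)
    sim <- generate_eeg(cfg)
    sim$baseline <- compute_baseline(sim$record, c(0, 300))
    sim
  })
}

# full validation recording: 20 seizures + 20 artifacts over 2 h,
# artifact-cleaned, with chronic detections and scores
fixture_study <- function(seed) {
  memo(paste0("study_", seed), {
    sim <- generate_srs_study(seed)
    profile <- detection_profile("chronic")
    baseline <- compute_baseline(sim$record, c(0, 300))
    cleaned <- remove_artifact_transients(sim$record, baseline, profile)
    detections <- detect_srs(cleaned$record, baseline, profile)
    list(sim = sim, baseline = baseline, cleaned = cleaned,
         detections = detections,
         score = score_detections(detections, sim$truth))
  })
}

# Independent brute-force re-check of the five detection criteria for
# one event, written with naive loops (no shared code with detect_srs
# beyond the public spike threshold definition).
oracle_criteria <- function(record, baseline, profile, onset, offset,
                            quiet_end = onset) {
  x <- record$samples
  fs <- record$sampling_rate
  thr <- profile$multiplier * baseline$amplitude_stat
  naive_rms <- function(t0, t1) {
    i <- (max(1, floor(t0 * fs) + 1)):(min(length(x), ceiling(t1 * fs)))
    sqrt(mean(x[i]^2))
  }
  # 1-s window RMS scan at 0.05-s steps
  env_at <- function(t) naive_rms(t - 0.5, t + 0.5)
  scan <- seq(onset, offset, by = 0.05)
  env <- vapply(scan, env_at, numeric(1))
  emax <- max(env)

  spike_windows <- function(t0, t1) {
    # does [t0, t1) contain a sample with |x| > thr?
    i <- (max(1, floor(t0 * fs) + 1)):(min(length(x), ceiling(t1 * fs)))
    any(abs(x[i]) > thr)
  }

  quiet_before <- !spike_windows(quiet_end - 300, quiet_end - 1e-6) &&
    naive_rms(quiet_end - 300, quiet_end) < 2 * baseline$rms
  t90 <- scan[which(env >= 0.9 * emax)[1]]
  gradual_ramp <- (t90 - onset) >= profile$min_ramp_duration
  wins <- floor(offset - onset)
  frac <- mean(vapply(seq_len(wins) - 1L, function(k) {
    spike_windows(onset + k, onset + k + 1)
  }, logical(1)))
  sustained <- (offset - onset) > profile$min_ictal_duration && frac >= 0.8
  t50 <- scan[max(which(env >= 0.5 * emax))]
  post <- seq(t50, t50 + 4 * profile$max_shutoff_duration, by = 0.05)
  below <- post[vapply(post, env_at, numeric(1)) < 2 * baseline$rms]
  shutoff <- length(below) > 0 &&
    (below[1] - t50) <= profile$max_shutoff_duration
  supp_level <- profile$suppression_rms_fraction * baseline$rms
  supp_scan <- seq(offset, offset + 5, by = 0.1)
  supp_ok <- FALSE
  for (s in supp_scan) {
    if (env_at(s) <= supp_level) {
      run <- seq(s, s + profile$min_suppression_duration, by = 0.5)
      if (all(vapply(run, env_at, numeric(1)) <= supp_level * 1.02)) {
        supp_ok <- TRUE
        break
      }
    }
  }
  c(quiet_before = quiet_before, gradual_ramp = gradual_ramp,
    sustained_spiking = sustained, abrupt_shutoff = shutoff,
    postictal_suppression = supp_ok)
}
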