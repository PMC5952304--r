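fs <- 500

test_that("baseline statistic is the 95th amplitude percentile", {
  t <- seq(0, 120 - 1 / fs, by = 1 / fs)
  for (A in c(1, 8)) {
    rec <- eeg_record(A * sin(2 * pi * 7 * t), fs)
    b <- compute_baseline(rec, c(0, 120))
    # analytic: 95th percentile of |A sin| = A sin(0.95 pi / 2)
    expect_equal(b$amplitude_stat, A * sin(0.95 * pi / 2), tolerance = 1e-3)
    expect_gte(b$amplitude_stat, 0.9 * A)
    expect_lte(b$amplitude_stat, A)
  }

  expect_error(compute_baseline(eeg_record(rep(0, 200 * fs), fs), c(0, 200)),
               "zero amplitude")
  expect_error(compute_baseline(eeg_record(rnorm(100 * fs), fs), c(0, 30)),
               "at least 60 s")

  # homogeneity: scaling the trace scales the statistic
  sim <- generate_eeg(sim_config(duration = 120, seed = 2))
  b1 <- compute_baseline(sim$record, c(0, 120))
  scaled <- sim$record
  scaled$samples <- 3 * scaled$samples
  b3 <- compute_baseline(scaled, c(0, 120))
  expect_equal(b3$amplitude_stat, 3 * b1$amplitude_stat)
})

test_that("spike detection honours the strict threshold and sharpness gate", {
  base_rec <- eeg_record(sin(2 * pi * 7 * seq(0, 120 - 1 / fs, 1 / fs)), fs)
  b <- compute_baseline(base_rec, c(0, 120))
  profile <- detection_profile("acute")

  flat <- eeg_record(rep(0, 60 * fs), fs)
  expect_equal(nrow(detect_spikes(flat, b, profile)), 0L)

  # single sample exactly at the threshold: strict inequality, no spike
  thr <- profile$multiplier * b$amplitude_stat
  x <- rep(0, 60 * fs)
  x[30 * fs] <- thr
  expect_equal(nrow(detect_spikes(eeg_record(x, fs), b, profile)), 0L)
  x[30 * fs] <- thr * 1.001
  sp <- detect_spikes(eeg_record(x, fs), b, profile)
  expect_equal(nrow(sp), 1L)

  # an injected transient at 3x reads back with ratio ~ 3
  sim <- generate_eeg(sim_config(duration = 300, seed = 21))
  bb <- compute_baseline(sim$record, c(0, 300))
  inj <- inject_artifacts(sim$record, 150, 3,
                          amplitude_stat = bb$amplitude_stat)
  got <- detect_spikes(inj$record, bb, detection_profile("acute"))
  got <- got[abs(got$time - 150) < 0.2, ]
  expect_equal(nrow(got), 1L)
  expect_equal(got$ratio, 3, tolerance = 0.2)
  expect_lt(got$width_ms, 200)

  # a slow 1-Hz lump above threshold fails the sharpness gate
  slow <- rep(0, 60 * fs)
  tt <- seq(0, 1, by = 1 / fs)
  slow[(20 * fs):(20 * fs + length(tt) - 1)] <- thr * 1.5 * sin(pi * tt)
  expect_equal(nrow(detect_spikes(eeg_record(slow, fs), b, profile)), 0L)
})

test_that("raising the multiplier never increases spike counts", {
  sim <- fixture_one_seizure()
  b <- sim$baseline
  counts <- vapply(c(2, 2.5, 3, 4, 5), function(m) {
    nrow(detect_spikes(sim$record, b, detection_profile("chronic",
                                                        multiplier = m)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("detections are equivariant under joint amplitude scaling", {
  sim <- fixture_one_seizure()
  b <- sim$baseline
  profile <- detection_profile("chronic")
  d1 <- detect_srs(sim$record, b, profile)

  scaled <- sim$record
  scaled$samples <- 2.5 * scaled$samples
  b2 <- compute_baseline(scaled, c(0, 300))
  d2 <- detect_srs(scaled, b2, profile)
  expect_equal(d2$onset, d1$onset)
  expect_equal(d2$offset, d1$offset)
  expect_equal(d2$accepted, d1$accepted)
})

test_that("SE onset detection needs >10 s of spiking then rapid quieting", {
  profile <- detection_profile("acute")

  quiet <- generate_eeg(sim_config(duration = 900, seed = 23))
  bq <- compute_baseline(quiet$record, c(0, 600))
  expect_null(detect_se_onset(quiet$record, bq, profile))

  cfg <- sim_config(duration = 2400, seed = 7)
  se <- generate_se_scenario(cfg, se_onset = 600, se_duration = 1500)
  b <- compute_baseline(se$record, c(0, 540))
  onset <- detect_se_onset(se$record, b, profile)
  expect_false(is.null(onset))
  expect_lt(abs(onset - 600), 1)

  # an 8-s train fails the >10 s persistence rule
  sim <- generate_eeg(sim_config(duration = 900, seed = 29))
  bb <- compute_baseline(sim$record, c(0, 600))
  short <- inject_artifacts(sim$record, seq(700, 708, by = 0.25), 4,
                            amplitude_stat = bb$amplitude_stat)
  expect_null(detect_se_onset(short$record, bb, profile))
})

test_that("a spec-compliant seizure passes all five criteria", {
  sim <- fixture_one_seizure()
  det <- detect_srs(sim$record, sim$baseline)
  acc <- det[det$accepted, ]
  expect_equal(nrow(acc), 1L)
  expect_true(all(acc$quiet_before, acc$gradual_ramp, acc$sustained_spiking,
                  acc$abrupt_shutoff, acc$postictal_suppression))
  expect_gte(acc$suppression_duration, 30)
  # recovered duration close to the labelled detectable span
  expect_lt(abs(acc$duration - sim$truth$seizures$duration), 2)

  expect_error(
    detect_srs(eeg_record(rnorm(100 * 500), 500), sim$baseline),
    "shorter than the minimum")
})

test_that("rule boundaries reject short events and short suppression", {
  # 15-s event: sustained_spiking must fail (needs > 20 s)
  short_spec <- seizure_spec(onset = 400, ramp_duration = 4,
                             plateau_duration = 11, offset_duration = 0.5,
                             suppression_duration = 60)
  sim <- generate_eeg(sim_config(duration = 600,
                                 seizure_specs = list(short_spec), seed = 3))
  b <- compute_baseline(sim$record, c(0, 300))
  det <- detect_srs(sim$record, b)
  expect_false(any(det$accepted))
  expect_false(any(det$sustained_spiking))

  # 10-s suppression: postictal_suppression must fail (needs >= 30 s)
  supp_spec <- seizure_spec(onset = 400, suppression_duration = 10)
  sim2 <- generate_eeg(sim_config(duration = 600,
                                  seizure_specs = list(supp_spec), seed = 3))
  b2 <- compute_baseline(sim2$record, c(0, 300))
  det2 <- detect_srs(sim2$record, b2)
  expect_false(any(det2$accepted))
  cand <- det2[det2$sustained_spiking, ]
  expect_false(any(cand$postictal_suppression))
})

test_that("accepted events pass an independent brute-force criteria scan", {
  sim <- fixture_one_seizure()
  profile <- detection_profile("chronic")
  det <- detect_srs(sim$record, sim$baseline, profile)
  acc <- det[det$accepted, ]
  for (i in seq_len(nrow(acc))) {
    flags <- oracle_criteria(sim$record, sim$baseline, profile,
                             acc$onset[i], acc$offset[i],
                             quiet_end = acc$cand_onset[i])
    expect_true(all(flags), info = paste(names(flags)[!flags], collapse = ", "))
  }
})

test_that("seizure duration spans first to last spike", {
  event <- list(onset = 10, offset = 50)
  expect_equal(seizure_duration(event, c(10, 20, 46)), 36)
  expect_error(seizure_duration(event, c(12)), "at least two spikes")

  sim <- fixture_one_seizure()
  det <- detect_srs(sim$record, sim$baseline)
  acc <- det[det$accepted, ][1, ]
  spikes <- detect_spikes(sim$record, sim$baseline,
                          detection_profile("chronic"))
  expect_equal(seizure_duration(acc, spikes), acc$duration)
  expect_lt(abs(seizure_duration(acc, spikes) - sim$truth$seizures$duration), 2)
})
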