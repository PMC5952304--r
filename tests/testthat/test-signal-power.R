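fs <- 500

test_that("band-pass filter preserves the band and rejects out-of-band", {
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  spec <- filter_spec(20, 70)

  zero <- bandpass(eeg_record(rep(0, 5000), fs), spec)
  expect_equal(zero$samples, rep(0, 5000))

  in_band <- bandpass(eeg_record(sin(2 * pi * 40 * t), fs), spec)
  mid <- in_band$samples[1001:4000]      # away from edge transients
  expect_lt(abs(sqrt(mean(mid^2)) / sqrt(0.5) - 1), 0.05)

  out_band <- bandpass(eeg_record(sin(2 * pi * 5 * t), fs), spec)
  expect_lt(sqrt(mean(out_band$samples^2)) / sqrt(0.5), 0.10)

  # >= 20 dB one octave outside the band (10 Hz)
  oct <- bandpass(eeg_record(sin(2 * pi * 10 * t), fs), spec)
  expect_lt(sqrt(mean(oct$samples^2)) / sqrt(0.5), 10^(-20 / 20))

  expect_error(bandpass(eeg_record(rnorm(1000), fs), filter_spec(20, 260)),
               "Nyquist")
})

test_that("zero-phase filtering leaves a symmetric impulse centred", {
  x <- rep(0, 4001)
  x[2001] <- 1
  filtered <- bandpass(eeg_record(x, fs), filter_spec(20, 70))
  expect_lte(abs(which.max(abs(filtered$samples)) - 2001), 1)
})

test_that("epoch power follows the uV^2/min convention", {
  t <- seq(0, 300 - 1 / fs, by = 1 / fs)

  zero <- epoch_power(eeg_record(rep(0, 300 * fs), fs))
  expect_equal(zero$power, 0)

  # amplitude A sinusoid filling one epoch: power = 60 * A^2 / 2
  for (A in c(1, 3)) {
    ep <- epoch_power(eeg_record(A * sin(2 * pi * 40 * t), fs), 300)
    expect_equal(ep$power, 60 * A^2 / 2, tolerance = 1e-6)
  }

  # quadratic amplitude scaling
  noise <- rnorm(300 * fs)
  p1 <- epoch_power(eeg_record(noise, fs))$power
  p2 <- epoch_power(eeg_record(2 * noise, fs))$power
  expect_equal(p2 / p1, 4, tolerance = 1e-9)

  expect_error(epoch_power(eeg_record(rnorm(100), fs)), "shorter than one epoch")
  expect_message(epoch_power(eeg_record(rnorm(310 * fs), fs)),
                 "partial epoch")

  # additivity over disjoint epochs: total energy is the sum of epochs
  x <- rnorm(600 * fs)
  both <- epoch_power(eeg_record(x, fs), 300)
  whole <- epoch_power(eeg_record(x, fs), 600)
  expect_equal(sum(both$power) * 5, whole$power * 10, tolerance = 1e-9)
})

make_series <- function(power, epoch = 300) {
  rec <- eeg_record(rep(0, length(power) * epoch * 10), 10)
  s <- epoch_power(rec, epoch)
  s$power <- power
  s
}

test_that("baseline-relative power centres on the baseline window", {
  s <- make_series(c(10, 10, 30, 5))
  rel <- relative_power(s, c(0, 600))
  expect_equal(rel$power, c(0, 0, 20, -5))
  expect_true(attr(rel, "relative"))

  const <- relative_power(make_series(rep(7, 6)), c(0, 1800))
  expect_equal(const$power, rep(0, 6))

  whole <- relative_power(make_series(rnorm(8)), c(0, 2400))
  expect_equal(mean(whole$power), 0)

  expect_error(relative_power(s, c(5000, 6000)), "covers no epoch")
})

test_that("window means average the epochs starting inside the window", {
  s <- make_series(1:12)
  w <- window_mean_power(s, 0, 0.5)
  expect_equal(w$mean_power, mean(1:6))
  expect_equal(w$n_epochs, 6L)

  const <- make_series(rep(4.2, 12))
  expect_equal(window_mean_power(const, 0.25, 0.75)$mean_power, 4.2)

  expect_error(window_mean_power(s, 10, 24), "overlaps no epoch")
})

test_that("relative power of a quiet recording is near zero away from baseline", {
  sim <- generate_eeg(sim_config(duration = 7200, seed = 31))
  filtered <- bandpass(sim$record, filter_spec(20, 70))
  series <- suppressMessages(epoch_power(filtered, 300))
  rel <- relative_power(series, c(0, 1800))
  post <- rel$power[rel$epoch_start >= 1800]
  base <- series$power[series$epoch_start < 1800]
  # mean(post) carries both the post-window and the baseline-mean
  # estimation error
  se <- sqrt(stats::var(post) / length(post) +
               stats::var(base) / length(base))
  expect_lt(abs(mean(post)), 2 * se)
})

test_that("artifact removal deletes isolated transients only", {
  sim <- fixture_one_seizure(seed = 11)
  stat <- nominal_amplitude_stat(20)
  profile <- detection_profile("chronic")

  # clean trace -> unchanged
  quiet <- generate_eeg(sim_config(duration = 400, seed = 13))
  bq <- compute_baseline(quiet$record, c(0, 300))
  clean <- remove_artifact_transients(quiet$record, bq, profile)
  expect_identical(clean$record$samples, quiet$record$samples)
  expect_equal(nrow(clean$annotations), 0L)

  # 5 isolated artifacts + 1 seizure -> exactly 5 removals, seizure
  # interval bit-identical
  times <- c(50, 120, 200, 290, 360)
  inj <- inject_artifacts(sim$record, times, 6, amplitude_stat = stat)
  b <- compute_baseline(inj$record, c(0, 300))
  out <- remove_artifact_transients(inj$record, b, profile)
  expect_equal(nrow(out$annotations), 5L)
  expect_equal(out$annotations$onset, times, tolerance = 0.1)
  fs <- 500
  seiz <- (400 * fs):(439 * fs)
  expect_identical(out$record$samples[seiz], inj$record$samples[seiz])
  thr <- profile$multiplier * b$amplitude_stat
  for (tm in times) {
    win <- (floor((tm - 0.1) * fs)):(ceiling((tm + 0.1) * fs))
    expect_lt(max(abs(out$record$samples[win])), thr)
  }

  # power is altered only in epochs containing a removed transient
  before <- suppressMessages(epoch_power(inj$record, 100))
  after <- suppressMessages(epoch_power(out$record, 100))
  touched <- findInterval(times, before$epoch_start)
  expect_equal(before$power[-touched], after$power[-touched])
  expect_false(any(before$power[touched] == after$power[touched]))

  # two large transients 0.5 s apart are not isolated -> kept
  pair <- inject_artifacts(quiet$record, c(200, 200.5), 6,
                           amplitude_stat = stat)
  bp <- compute_baseline(pair$record, c(0, 150))
  kept <- remove_artifact_transients(pair$record, bp, profile)
  expect_equal(nrow(kept$annotations), 0L)
  expect_identical(kept$record$samples, pair$record$samples)
})
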