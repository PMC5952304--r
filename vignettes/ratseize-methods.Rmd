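---
title: "Methods: EEG quantification, rule-based seizure detection, and outcome statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EEG quantification, rule-based seizure detection, and outcome statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`ratseize` implements the computational workflow of a rodent
organophosphate status-epilepticus (SE) study: cortical EEG is recorded
at 500 Hz around a chemoconvulsant exposure, quantified as 20--70 Hz
band power in 300-s epochs, and screened for epileptiform spikes, SE
onset, and -- weeks later -- spontaneous recurrent seizures (SRS) with a
five-criterion rule set. Group outcomes are compared with exact Fisher
tests and Mann--Whitney tests, inflammatory gene expression with the
2^-ddCt method, and behavior with the modified Racine scale, the
modified Irwin test and the novel-object-recognition discrimination
index. Because raw recordings of such studies are rarely deposited, the
package ships a seeded synthetic-EEG generator with exact ground-truth
labels, so that every stage of the pipeline is validated end-to-end on
data whose answer is known.

# Band power

The analysis band is 20--70 Hz: this gamma band minimizes movement
artifact contamination while tracking ictal spiking. Filtering
(`bandpass()`) is a 4th-order Butterworth applied forward and backward
(`signal::filtfilt`), i.e. zero-phase, so epoch boundaries and event
times are not shifted by group delay. One octave outside the band the
attenuation of the two-pass filter exceeds 20 dB.

Per-epoch power (`epoch_power()`) integrates the squared filtered
signal over each 300-s epoch and divides by the epoch length in
minutes:

$$P_e = \frac{\sum_{t \in e} x_t^2\,\Delta t}{T_e / 60}
\qquad [\mu V^2/\mathrm{min}].$$

The field reports band power in uV^2/min without a standard
normalization; this package fixes the convention above and documents
it. For a sinusoid of amplitude $A$ filling an epoch the closed form is
$60\,A^2/2$, which the tests verify to well below 1%. Epochs are
anchored at the recording start and a trailing partial epoch is
dropped (and logged). Baseline-relative power (`relative_power()`)
subtracts the mean power of a pre-exposure window; quiet
post-treatment recordings then fluctuate around zero and small negative
window means are meaningful, which is why relative power is the default
for SE recordings.

# Baseline statistic and spike detection

All detectors reference a quiet-baseline window (10 min for the acute
profile, 5 min for the chronic profile). The amplitude statistic is the
95th percentile of the absolute band-filtered signal -- a robust stand-in
for "baseline amplitude", which the source rubric leaves unspecified;
the window RMS is kept alongside for envelope-level rules. A spike is a
contiguous excursion with $|x|$ *strictly* above `multiplier` times the
amplitude statistic (2x acute, 3x chronic), merged with a 50-ms
refractory rule and gated on sharpness (width at half peak below
200 ms, so slow high-amplitude waves do not count). The refractory
merge operates on peak-to-peak distance rather than on the gap between
supra-threshold runs: the two lobes of one biphasic transient sit
~15 ms apart and merge at any threshold, whereas neighbouring spikes at
ictal rates (~10/s) never do. Gap-based merging would make the spike
count non-monotone in the threshold (wide low-threshold excursions can
bridge between spikes); peak-based merging preserves the invariant
that raising the multiplier never increases the count.

# SE onset

SE onset is the first spike train (inter-spike gaps at most 2 s) that
persists for more than 10 s and is followed, within 60 s of its last
spike, by the 1-s RMS envelope dropping below 2x the baseline RMS --
the "rapid quieting" that separates the initial discrete seizure from
the continuous spiking that follows. The rubric's quieting threshold is
an amplitude-free phrase; 2x the baseline RMS is used for every
envelope-level comparison in the package (quieting, shutoff) for
internal consistency, while spike thresholds always use the amplitude
statistic.

# The five-criterion SRS detector

Candidates are spike trains with gaps at most 5 s. Each is scored on:

1. **quiet baseline**: no supra-threshold spike in the 300 s before the
   candidate's first spike, and pre-event RMS below 2x baseline RMS;
2. **gradual ramp**: at least 2 s from event onset until the 1-s RMS
   envelope first reaches 90% of its event maximum;
3. **sustained spiking**: duration above 20 s and at least 80% of the
   non-overlapping 1-s windows inside the event contain a spike;
4. **abrupt shutoff**: the envelope falls from its last crossing of 50%
   of the event maximum to below 2x baseline RMS within 2 s;
5. **post-ictal suppression**: envelope at or below 50% of baseline RMS
   for at least 30 s, starting within 5 s of offset.

An event is accepted iff all five flags hold; rejected candidates are
returned with their flags for audit. Three operationalizations deserve
comment.

*Ramp and shutoff bounds* (2 s each) quantify "gradual, typically over
several seconds" and "abrupt"; both are profile parameters.

*Event extent.* Onset and offset are anchored at the first and last
spike of the *sustained* run (at least 3 spikes within 1 s). Near the
detection threshold the background noise adds roughly +/-1 threshold
unit to a spike's realized peak, so during a gradual amplitude ramp a
lone early spike can cross threshold seconds before continuous
spiking is established; anchoring on the sustained run makes the
measured duration robust to such fringe crossings. The quiet-baseline
window (criterion 1) still ends at the candidate's very first spike,
so the build-up is never counted as "background".

*Suppression measurement.* The envelope crosses the suppression
threshold tangentially and can wiggle across it for a few samples;
the suppression duration is therefore the longest below-threshold run
starting within 5 s of offset, not the run at the first crossing.

Seizure duration follows the study convention -- first to last
detectable spike -- via `seizure_duration()`, or directly as the
accepted event's `duration`.

# Movement-artifact removal

Isolated movement artifacts are large single transients not of cerebral
origin. `remove_artifact_transients()` deletes a supra-threshold
excursion iff it is isolated (no other excursion within 2 s) and
shorter than 200 ms at half peak, replacing a padded 60-ms window by
linear interpolation; excursions inside supplied seizure intervals are
never touched, and ictal spikes protect themselves in any case because
they are never isolated at ictal rates. The isolation radius and width
bound operationalize a qualitative description; both matter, since the
chronic screening fixture deliberately places artifacts inside the
5-min pre-seizure windows, where an unremoved artifact correctly voids
criterion 1. Artifact removal is therefore a standard stage before
chronic detection in `run_pipeline()`.

# The synthetic generator

`generate_eeg()` emulates what the detectors need to be tested against,
not cortical physiology:

* **Background**: Gaussian noise, FFT-shaped to a 1/f spectrum
  band-limited to 1--100 Hz, with a soft saturation at 3.7x RMS
  (rescaled so the RMS is exact). The saturation bounds every
  event-free sample strictly below 4x RMS, making "no events implies
  no supra-threshold excursions" a provable property rather than a
  probabilistic one. Long traces are built from ~70-min chunks
  cross-faded over 1 s with variance-preserving weights; chunks are
  scaled by the theoretical process SD, not the empirical one, so band
  power stays statistically homogeneous across chunk boundaries.
* **Spikes**: biphasic derivative-of-Gaussian wavelets (sigma 10 ms,
  ~60 ms support), well inside the detector's 200-ms sharpness gate.
  Amplitudes are programmed as multiples of the background's nominal
  95th-percentile amplitude (`nominal_amplitude_stat()`).
* **Seizures** (`seizure_spec()` defaults): 8-s linear ramp to a 5x
  plateau, 30 s of sustained 10/s spiking, 0.5-s offset, then 60 s of
  suppression at 0.25x baseline RMS -- the shape of a typical ~40-s SRS
  with clear post-ictal depression, chosen once from the rule set's own
  magnitudes (3x threshold, >20 s, >=30 s suppression, 5-min quiet).
* **SE scenario**: an initial discrete seizure (2-s ramp to 4x, ~20 s
  of spiking, 30 s of quieting) followed by near-continuous 8/s
  spiking at 2.5--4.5x until the SE interval ends.
* **Artifacts**: isolated 8-ms-sigma transients at 6x, placed by a
  seeded Poisson process (or explicitly) at least 5 s from any other
  event, so artifact labels are unambiguous.

Ground truth records every spike, seizure interval and artifact time.
The labelled *detectable span* of a seizure is computed from the
realized trace: the first/last spike of the sustained run whose
realized peak (wavelet plus noise) exceeds the chronic 3x reference.
Labelling from programmed amplitudes instead would misstate the trace
the detector actually sees by 1--2 s at the ramp, because noise
genuinely pushes near-threshold spikes over the line.

The generator does **not** model spatial structure, physiological
rhythms (spindles, theta), state transitions, electrode drift, or
realistic artifact morphology. Detector validation on it therefore
demonstrates that the rules are implemented correctly and are robust
to stationary 1/f background at calibrated amplitudes -- not that the
detector generalizes to arbitrary recordings.

# Validation study conditions

The canonical chronic-screening fixture (`generate_srs_study()`) is a
2-h, 500-Hz recording holding 20 spec-compliant seizures (first onset
400 s, ~352-s spacing, so each event keeps >5 min of quiet baseline)
plus 20 artifacts placed in the inter-seizure gaps. Sensitivity,
precision and duration recovery are measured over ten seeds
(200 seizures, 200 artifacts); with artifact removal enabled the
detector attains sensitivity and precision 1.0 and duration errors
well under 1 s on these conditions. The test suite exercises the same
study at these sizes; a deployment against real recordings would use
the same code path on longer records.

# Outcome statistics

`fisher_exact_two_sided()` sums hypergeometric point probabilities of
all tables (at fixed margins) no more probable than the observed one --
the two-sided convention of mainstream statistical software; the suite
checks it against `stats::fisher.test` and against brute-force
enumeration over every table with total at most 40.
`mann_whitney()` uses midranks, an exact permutation distribution
(dynamic programming over doubled ranks, so ties are handled exactly)
when `min(n) <= 8` and the combined size is at most 25, and a normal
approximation with tie correction otherwise; it is cross-checked
against `stats::wilcox.test` and full enumeration.
`ddct_fold_change()` references each sample's target CT to the
geometric mean of the beta-actin/GAPDH/HPRT1 CTs and the control
group's arithmetic-mean dCt (the source wording does not fix the mean
type; the arithmetic mean on the CT scale is the field's standard and
makes the control-group mean fold exactly 1 under the
reference-to-control-mean convention). Reported percentages follow the
presentation conventions: incidence reductions round to integer
percent; frequency reductions are computed both as per-subject rates
and as total counts, since the headline number is compatible with
either arithmetic.

# Behavioral rubrics

`declare_se()` implements the Racine-scale SE rule: two or more
observations in stages 3, 4 or 6 within a 5-min window, with the window
sliding and endpoint-inclusive (the rubric does not say whether the
window is anchored; sliding is the conservative reading and declares SE
at the earliest defensible time). `irwin_total()` sums the 12 items
(0--2 each) and classifies 0 as normal, 1--11 as impaired, and >=12 as
a fail. The NOR discrimination index is
`(novel - familiar) / (novel + familiar)`, with training trials
excluded when either identical object received less than 30% of the
exploration time (exactly 30% is valid).

# Numerical and format choices

* Times are seconds from recording start; intervals are half-open
  `[onset, offset)`; epoch and window membership is by start time.
* Threshold crossings are strict (`>`), so boundary cases are
  deterministic and a transient at exactly the multiplier is not a
  spike.
* The envelope is the RMS in a centred 1-s sliding window, computed in
  O(n) from cumulative sums -- the simplest statistic supporting all
  five criteria.
* EDF output uses one data record per second, a symmetric physical
  range written to the header's 8-character precision and re-parsed by
  the writer itself, so reader and writer agree on the scale exactly
  and round-trips are within one 16-bit quantization step. A physical
  dimension of mV is converted to uV on read.
* JSON reports serialize with fixed field order and 10 significant
  digits; identical configuration and seed give byte-identical files.

# Known limitations

* The uV^2/min normalization is a documented convention; absolute group
  power values from other normalizations are not comparable.
* The five criteria are operationalized with explicit parameters where
  the rubric is qualitative (ramp >= 2 s, shutoff <= 2 s, suppression
  at 50% of baseline RMS); all are `detection_profile()` fields.
* Spike-count monotonicity in the threshold holds for the peak-based
  refractory merge on transient-like events; pathological waveforms
  (sustained oscillations just above threshold) are excluded by the
  sharpness gate rather than counted.
* The generator's noise is stationary; detector performance numbers on
  it are upper bounds for real recordings with state changes and
  richer artifacts.
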