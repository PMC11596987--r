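---
title: "Methods: cycle-by-cycle burst detection and lapse analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cycle-by-cycle burst detection and lapse analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burstlapse)
```

`burstlapse` links oscillatory bursts in multichannel EEG to behavioural
lapses in a sustained visual attention task. This vignette documents the
models and procedures, the tunable parameters and their defaults, the
synthetic-data generator the tests rely on, and the numerical and design
choices made where several reasonable options existed.

## 1. Data model and conventions

A recording is a channels x samples matrix in microvolts with a sampling
rate and a time origin; sample *i* sits at `t0 + (i - 1) / rate`. All
windows — trials, bursts, topography windows, frequency bands — are
half-open `[start, end)`, so a boundary value belongs to the following
interval (a reaction time of exactly 0.5 s is *slow*, a burst frequency
of exactly 8 Hz is alpha, a sample at exactly +0.3 s is in the Response
window). Channels are identified by label, never by index, when
recordings are combined. A *session block* pools the recordings of one
condition (e.g. baseline vs extended wakefulness); all normalisation
references (occupancy z-scoring, spectral baselines, amplitude
quantiles) are computed over every unmasked sample of the block, so that
event-locked values are expressed relative to that participant's own
typical activity.

Trial outcomes derive from reaction times alone: below 0.1 s a false
alarm (anticipatory press), `[0.1, 0.5)` s fast, `[0.5, 1)` s slow, and
absent (or >= 1 s) a lapse. False alarms are excluded from every EEG
analysis.

## 2. Preprocessing

The filter chain mirrors standard wake-EEG preprocessing: a 40 Hz
low-pass, decimation to 250 Hz, and a 0.5 Hz high-pass. All filters are
zero-phase (forward–backward Butterworth via `signal::filtfilt`), chosen
so that event-locked timing is not skewed by filter group delay. Two
numerical choices matter:

- The low-pass runs as two cascaded zero-phase passes of a 4th-order
  Butterworth. A single pass leaves ~28% of a 45 Hz tone's amplitude;
  the cascade brings stop-band leakage below 10% close to the cutoff
  while doubling as the anti-alias filter for the integer decimation.
- The high-pass at 0.5 Hz sits at a normalised frequency of 0.004,
  where a direct-form 4th-order filter is numerically fragile; it runs
  as two cascaded 2nd-order zero-phase sections instead.

Eye closures come from a pupil-tracker confidence trace in `[0, 1]`:
samples with confidence strictly below 0.5 count as closed. Closed
samples are masked exactly like EEG artifacts, and a trial whose
stimulus window is more than half closed is flagged (`ec_stimulus`) and
excluded from burst analyses — such a lapse is attributable to the eyes,
not the cortex. The "stimulus window" is taken as the 0.5 s stimulus
visibility duration rather than the 0.3 s topography window; both are
arguments (`flag_ec_trials(stim_window = )`), and 0.5 s is the default
because the exclusion rationale is about seeing the stimulus at all.

## 3. Cycle-by-cycle burst detection

Band power confounds sustained rhythmicity with isolated transients;
cycle-by-cycle detection instead demands several consecutive
well-formed oscillation cycles.

1. **Filter bank.** The broadband (0.5–40 Hz) signal is filtered in
   4 Hz wide bands stepped by 1 Hz from 2 to 16 Hz (`[2,6], [3,7], ...,
   [12,16]`; 11 bands). With a 1 Hz step every frequency in the 4–14 Hz
   range of interest lies within half a bandwidth of a band centre, so
   no oscillation falls between bands.
2. **Zero-crossings** of each narrowband signal are located with linear
   sub-sample interpolation; their signs alternate by construction.
3. **Cycles** are measured on the *broadband* signal: between an upward
   and the next downward crossing its maximum is a positive peak,
   between a downward and the next upward crossing its minimum is a
   trough (argmax ties resolve to the earliest sample). A cycle spans
   positive peak to next positive peak and contains one trough. The
   period is the trough-to-trough interval (the first cycle, lacking a
   preceding trough, uses its peak-to-peak span); the amplitude is the
   mean peak-to-trough excursion of the two flanks.
4. **Properties.** Monotonicity is the fraction of sample-to-sample
   differences with the expected sign along the descending and
   ascending flanks; period consistency and amplitude consistency are
   the worst shorter/longer ratio against each neighbouring cycle
   (boundary cycles have a single neighbour). All lie in `[0, 1]`.
5. **Criteria.** A maximal run of consecutive cycles that all meet
   every threshold, with run length >= `min_cycles`, becomes a burst.
6. **Merging and banding.** The overlapping bands detect each event
   several times; per channel, overlapping burst spans are merged, the
   representative cycles/period/amplitude taken from the constituent
   with the most cycles, and the band re-derived from the mean period:
   theta for `1/period` in `[4, 8)` Hz, alpha in `[8, 14)`, otherwise
   "other".

### Default criteria and why there is an amplitude criterion

Defaults (`burst_criteria()`): `min_cycles = 4`, monotonicity >= 0.6,
period consistency >= 0.5, amplitude consistency >= 0.3, and
`amp_fraction = 0.8` — a cycle qualifies only if its amplitude exceeds
the 0.8 quantile of all cycle amplitudes of its channel x band.

The amplitude criterion deserves comment. Narrowband filtering makes
*any* signal — including pure 1/f background — look locally rhythmic:
measured on spectrally shaped noise, the three shape properties of
filtered-noise cycles overlap almost completely with those of genuine
burst cycles, and no threshold setting on them alone yields both high
sensitivity and high precision. What does separate bursts from
background is that their cycles stand out in amplitude. A relative
(quantile-based) amplitude threshold is the standard solution in
cycle-by-cycle toolboxes, and it keeps the criterion adaptive to each
channel's overall amplitude level. With these defaults, synthetic
recordings with bursts of at least 6 cycles and peak amplitude at least
twice the background standard deviation are recovered with sensitivity
and precision both above 0.9 (50% temporal overlap counting as a hit),
band labels are correct for over 95% of off-boundary events, and pure
1/f background produces under 5% spurious occupancy. All thresholds are
arguments and should be revisited when porting to a different recording
setup.

## 4. Event-locked occupancy analysis

Burst *occupancy* is the boolean channel x time indicator of being
inside a burst. For each band:

- **Epoching**: occupancy is cut into trials over `[-2, +4]` s around
  stimulus onset. Masked samples (artifacts, closures) become missing;
  trials with more than 50% missing data are dropped; false-alarm and
  eye-closure trials are excluded.
- **Participant time course**: at each time point, the proportion of
  non-missing channels with a burst, averaged over trials with clean
  data, z-scored to the mean and SD of that proportion over the whole
  session block. Time points with fewer than 15 clean trials are
  linearly interpolated from their neighbours; if such gaps exceed 20%
  of the window, or the outcome has fewer than 15 trials in total, the
  outcome is excluded for that participant. The proportion denominator
  is the channels non-missing at that point, not the full montage.
- **Group statistics**: per outcome and time point, a two-sided
  one-sample t-test of the participants' z values against zero;
  Benjamini–Hochberg FDR across all time points and outcomes of the
  analysis call (the "per figure" family); Hedge's g per point. Display
  smoothing uses lowess (tricube local linear) over 0.2 s and is never
  applied before statistics.
- **Window topographies**: per channel, the proportion of trials with a
  burst at each time point, averaged within the four windows Pre
  `[-2,0)`, Stimulus `[0,0.3)`, Response `[0.3,1)`, Post `[2,4)` s,
  minus the channel's session-block average occupancy; group t-tests
  per channel with FDR applied within each window x outcome topography
  separately. Note the comparison must be point-probability against
  point-probability: comparing "window contains at least one burst"
  against the session point-average would be biased high for every
  window longer than a typical burst (we verified this inflates the
  null false-positive rate to ~0.7).

The channel-proportion measure does not distinguish one global burst
from several local ones; no disambiguation is attempted.

## 5. Amplitude quantiles

For each trial (eyes-open, non-false-alarm) and each burst whose span
intersects `[-1, 0)` s before onset, one record is emitted with the
burst's amplitude averaged over the cycles whose peak lies in the
window. A trial with several pre-stimulus bursts contributes one record
per burst, each carrying the trial's outcome (an argument switches to a
per-trial maximum-amplitude record instead). Records are sorted into 10
equal-count amplitude quantiles within the session block (ties broken
by stable order; bin sizes differ by at most one); the lapse proportion
per quantile is z-scored within participant; and all 45 quantile pairs
are compared with paired t-tests under one FDR family per band x
condition panel. Participants with fewer than 10 records are excluded.
The `[-1, 0)` s window is the default; it is an argument
(`prestim_burst_amplitudes(window = )`) for analyses that prefer a
longer pre-stimulus span.

## 6. Time–frequency control analysis

Complex Morlet wavelets on a 1 Hz grid from 1 to 35 Hz, with cycle
counts log-linearly interpolated from 3 at 1 Hz to 15 at 35 Hz. The
cycle mapping is anchored at 1 and 35 Hz, not at the ends of whatever
grid is requested, so a restricted grid (say 4–8 Hz) analyses each
frequency identically to the full grid. Power is magnitude-squared,
floored at 1e-12 of the recording's median power (so silent synthetic
segments cannot produce `-Inf`), and log10-transformed. Edges are
handled by reflection padding of one maximal wavelet length. The session
block's mean log-power per channel x frequency is subtracted from every
sample; no per-trial baseline correction is applied. Epoching follows
the occupancy rules, run both with and without eye-closure exclusion.
Outcome contrasts are one-sample t-tests on the participants'
channel-averaged frequency x time maps with FDR over the map; band
summaries average within delta (1–4), theta (4–8), alpha (8–14), beta
(15–25) and gamma (25–30 Hz) and the Pre/Stimulus windows, with FDR per
topography. The 30–35 Hz sliver above the printed gamma edge stays
unassigned by default; bands are arguments.

## 7. Statistics layer

- `one_sample_t` / `paired_t`: closed-form two-sided t; zero-variance
  inputs return an `undefined` flag and are never significant.
- `fdr_bh`: Benjamini–Hochberg step-up via `stats::p.adjust`;
  significance is `p_fdr <= q`. FDR families are always passed
  explicitly by the calling analysis.
- `hedges_g`: g = d · J with J = 1 − 3/(4·df − 1).
- `detectable_effect_size(alpha, power, n)`: smallest d such that a
  two-sided one-sample t-test with noncentrality d·sqrt(n) and df = n−1
  attains the requested power, by root finding on the exact noncentral-t
  power function; returned on both the d and the J-corrected g scale.
  At α = 0.05 and power 0.8 this gives d = 0.701 for n = 18 and
  d = 0.996 for n = 10.
- `lowess_smooth`: `stats::lowess` (tricube-weighted local linear,
  robustness iterations disabled), window expressed in seconds; exact on
  globally linear input away from the edges; NA positions preserved.

## 8. The synthetic-data generator

Because every downstream stage must be testable without recordings, the
generator produces data whose ground truth is known exactly:

- **Background**: spectrally shaped Gaussian noise with power
  proportional to f^(−exponent) (FFT-domain shaping, gain clamped below
  0.5 Hz), rescaled to a per-channel SD. Shaped noise gives direct
  control of the aperiodic exponent, unlike AR models. Defaults:
  exponent 1.5, 10 µV SD — a typical wake-EEG slope and amplitude scale.
- **Bursts**: each event is a sinusoid at a frequency drawn uniformly
  within its band, times a Hann envelope spanning the whole event
  (smooth onsets; cycle-mean amplitude ~= 0.64 of the peak), scaled so
  the configured amplitude is the peak-to-trough excursion at the
  envelope maximum, added identically to a block of adjacent channels
  (no leadfield mixing, keeping channel ground truth exact). Event
  counts are Poisson at a per-band, per-channel-per-minute rate; events
  overlapping an already placed event on a shared channel are rejected
  so the per-channel ground truth stays unambiguous. Amplitudes are
  log-normal (default meanlog log(30), sdlog 0.4 µV — median 30 µV
  peak-to-trough, giving quantile analyses realistic spread), with an
  optional lower truncation to pin a minimum signal-to-noise ratio.
  Default rates (theta 2, alpha 4 events/min/channel) produce the
  sparse-but-frequent occupancy typical of drowsy wake EEG.
- **Closures**: Poisson onsets (1/min), log-normal durations (median
  2 s); the confidence trace sits near 0.9 open / 0.1 closed with
  0.05 SD jitter at 120 Hz.
- **Trials**: onsets with uniform inter-stimulus intervals in
  `[2, 10]` s. Lapse probability is
  `plogis(beta0 + beta_amp * A + beta_ec * EC + beta_dist * D)` with A
  the maximum ground-truth burst amplitude in the second before onset
  (0 if none; optionally an indicator of exceeding the amplitude
  distribution's 90th percentile, for couplings confined to the largest
  events), EC the eyes-closed-during-stimulus flag (`beta_ec = Inf`
  forces those trials to lapse), and D the normalised stimulus
  distance. Given no lapse, RT is 0.1 s plus a log-normal draw
  truncated below 0.9 s, split into fast/slow at 0.5 s.
- **Determinism**: every stage reseeds from the master seed plus a
  fixed offset; per-participant seeds derive from the master seed, so
  identical configurations are bit-identical.

What the generator does *not* emulate: volume conduction and realistic
topographies, non-sinusoidal waveform shape, ECG/EMG artifact classes,
circadian drift, and amplitude distributions estimated from real data
(none are published for these events; the defaults are plausible
placeholders and deliberately config-exposed). Passing tests therefore
demonstrates correctness of the pipeline's logic and calibration of its
statistics under a faithful-but-idealised signal model — not
performance on any particular amplifier or population.

## 9. Verification studies and problem sizes

The acceptance suite runs five simulation studies, sized to finish in
minutes while keeping the relevant counts at realistic scale:

- *Detector recovery*: 20 recordings of 8 channels x 5 min, exponent
  1.5 background, events of >= 6 cycles truncated at 40 µV peak-to-trough
  (peak amplitude = 2x the 10 µV background SD).
- *Null calibration*: 100 datasets of 12 participants (8 channels,
  8 min sessions, ~75 trials each) with all couplings zero, run on
  ground-truth occupancy; FDR-significant time points, topography
  channels, and Q1-vs-Q10 quantile contrasts must stay at or below
  their nominal rates.
- *Effect recovery*: (a) a negative amplitude-to-lapse coupling
  (β_amp = −0.08/µV, baseline lapse odds logit(0.6)) whose signature is
  a pre-stimulus occupancy deficit before lapses, 12 participants;
  (b) a positive coupling (β_amp = +0.06/µV, baseline logit(0.06),
  amplitude sdlog 0.5, 10-min sessions) recovered as a significant
  Q1-vs-Q10 quantile contrast, 14 participants; each in >= 80% of 25
  seeds. (c) a coupling confined to the top amplitude decile of dense
  global theta events (25/min, boost +4 log-odds), which must show as a
  significant pre-stimulus mean-power effect while the occupancy time
  course shows none — the dissociation that motivates running both a
  burst-based and a power-based analysis: binary occupancy saturates
  and is blind to an amplitude-weighted effect.
- The statistical calibration and recovery studies use the simulator's
  exact ground-truth occupancy rather than re-running the detector for
  every dataset; detector fidelity is established separately by the
  recovery study, and decoupling the two keeps each property's failure
  mode interpretable.

## 10. Known limitations

- The burst criteria defaults were set against the synthetic signal
  model; real recordings (different montage, reference, artifact
  residue) will likely need retuned thresholds, which is why every
  criterion is exposed.
- Bursts shorter than `min_cycles` and oscillations outside 2–16 Hz are
  invisible to the detector by design.
- The occupancy measure confounds burst globality with burst count.
- Statistical maps use massive-univariate t-tests with BH-FDR; no
  cluster-based permutation inference is provided.
- The EDF writer stores one data record per file with per-channel
  symmetric physical ranges; amplitude resolution is 16-bit over the
  per-channel range.
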