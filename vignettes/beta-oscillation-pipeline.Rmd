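---
title: "Methods: vigilance-state-resolved beta-oscillation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vigilance-state-resolved beta-oscillation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(betasleep)
```

## The problem

R6/1 transgenic mice — a Huntington's-disease model carrying exon 1 of
human huntingtin with expanded CAG repeats — develop an abnormal β rhythm
(~25 Hz) in frontal cortical field potentials. The rhythm occurs in
discrete bursts whose prevalence depends on vigilance state: rare and small
during active waking, frequent during quiet waking and slow wave sleep
(SWS), and strongest during REM sleep. It appears weeks before the
hindlimb-clasping motor sign, which makes it interesting as an early
electrophysiological biomarker. This package implements the full analysis
chain needed to quantify that phenomenon in longitudinal multichannel sleep
recordings, together with a synthetic-data generator that reproduces its
statistical structure with known ground truth.

## Pipeline model and assumptions

The per-session pipeline (`run_session()`) assumes three synchronized
signal channels — frontal EEG, hippocampal LFP and neck EMG, in µV — plus a
video-tracked position stream in cm. Time is 0-based seconds from session
start; epochs are half-open intervals.

**Spectrogram.** FFTs on 4-s windows with 50 % overlap (2-s hop), each
tapered by a Gaussian with σ = window/6, so the taper is effectively
compact at ±3σ. With a 4-s window the resolution is 0.25 Hz. One-sided
power is scaled by `2 / (fs · Σw²)` (half at DC and Nyquist) so that
Parseval holds for the tapered window; all downstream quantities are
normalized, so this constant only matters for absolute-power readouts. A
session of duration `T` yields `floor((T−4)/2)+1` windows; the window
centered at `2i` seconds is paired one-to-one with the scoring epoch
`[2i−1, 2i+1)`, so hypnograms produced by the scorer start at `t = 1 s`.

**State-conditioned spectra.** Windows whose center falls in an epoch of
the requested state are averaged and the mean spectrum is divided by its
sum over 0.5–100 Hz. The normalization range excludes DC (electrode drift)
and the mains-adjacent high band; band edges are inclusive everywhere. The
normalization makes spectra unitless fractions, comparable across probes
and animals, and makes every band-power readout a fraction of total power.

**Vigilance scoring.** A fixed cascade per epoch, mirroring classical
criteria: (1) epoch mean speed > 2 cm/s → active waking; otherwise
(2) immobile (< 0.5 cm/s, the tracker noise floor), EMG RMS ≤ 8 µV and
hippocampal θ/δ ratio ≥ 2 → REM; otherwise (3) immobile, low EMG and
2–8 Hz fraction ≥ 0.45 of 0.5–100 Hz power → SWS; else (4) quiet waking.
A 3-epoch majority filter removes isolated labels; the center label wins
ties, so smoothing can never introduce a state absent from its window. EMG
RMS is computed in 0.5-s sub-windows and averaged per epoch; speed is the
1-s moving average of frame-to-frame displacement times the frame rate.

The θ/δ ratio uses *non-overlapping* bands: θ 5–9 Hz over δ 2–4 Hz. With
the superficially natural choice of θ 4–9 Hz over δ 2–8 Hz the ratio is
bounded near 1 whenever θ dominates — the 6.75–7.5 Hz θ peak lies inside
both bands — and no threshold can separate REM from SWS. Disjoint bands
restore the intended contrast (REM ratio well above 2, SWS well below).
All thresholds were calibrated once against per-epoch feature
distributions measured on the generator's default presets and are exposed
in `scoring_thresholds()`; they are operating points, not biology.

**β-peak detection.** The aperiodic background is modeled as a power law:
a straight line fitted to log10 power versus log10 frequency over 10–55 Hz
*excluding* 15–40 Hz, i.e. on the flanks of the β band. A peak is declared
present when observed/background power reaches 2.0 at a local maximum
inside 15–40 Hz. The spectrum is first smoothed with a 5-bin (1.25 Hz)
moving average: single-bin fluctuations of a tapered periodogram averaged
over a few dozen windows otherwise exceed the threshold by chance, while
genuine burst peaks are several hertz wide (burst envelope ~1 Hz,
between-burst center-frequency scatter ~1 Hz) and pass through unchanged.
`run_session()` additionally requires at least 15 windows (30 s) of a state
before estimating its spectrum — a "state spectrum" from a single window
carries no usable information and was the dominant source of spurious
detections in development runs. Ties in `peak_in_band()` break toward the
lowest frequency.

**Comodulogram.** Pearson correlation between per-frequency power time
series of two channels, restricted to windows of a state (the combined
active + quiet waking mask reproduces the "waking state" analysis). Power
is log10-transformed by default because window-wise power is heavy-tailed;
a flag switches to raw power. Frequencies are restricted to 1–55 Hz to
bound the matrix. p-values use the t transform of r with n−2 degrees of
freedom and are reported raw: whether any multiplicity correction should be
applied across the ~50 000 bin pairs is left to the analyst, and the
package deliberately does not hide that issue. At least 10 windows are
required; extrema searches break ties toward the lowest frequency pair.

**Cohort statistics.** A mouse's β-onset age is the age of the *first*
session whose REM spectrum yields a detection (REM being the state where
the rhythm is strongest); no persistence across sessions is required.
Precedence is clasping-onset age minus β-onset age; exact ties count as
neither β-first nor clasp-first. The genotype proportion test is the
Pearson χ² on the 2×2 table *without* continuity correction — the
uncorrected statistic is what a 10-of-10 versus 0-of-8 split yields as
exactly 18 (Yates' correction would give ≈ 14.2). The genotype × state
ANOVA uses Type II sums of squares on the unbalanced tables longitudinal
designs produce; on balanced designs Type I, II and III coincide, which
the test suite verifies. The repeated-measures structure of real cohorts
(the same animal contributes several states) is *not* modeled — both
factors are treated as fixed, a documented simplification.

## The synthetic generator

`generator_config()` defines the study conditions; `simulate_session()`
and `simulate_cohort()` draw from them.

* **Sleep architecture.** A semi-Markov chain with exponential dwell times
  (means: active waking 40 s, quiet waking 25 s, SWS 75 s, REM 50 s) and a
  transition graph in which REM is reachable only from SWS. Sessions start
  in SWS, as appropriate for light-phase recordings of a nocturnal animal.
  The exponential law is the simplest semi-Markov choice; real bout-length
  distributions are heavier-tailed.
* **Signals.** Each channel is 1/f² Gaussian background (flat below
  0.5 Hz), with state-dependent RMS (hippocampus 40/70/100/50 µV for
  AW/QW/SWS/REM; frontal half that — sleep states carry more low-frequency
  power, REM and active waking are "activated" states with less).
  Oscillations are gated by the hypnogram: a hippocampal θ sinusoid at
  7.5 Hz (wild-type) or 6.75 Hz (transgenic) with 5 % slow frequency
  jitter during REM (45 µV) and active waking (40 µV), half of it
  volume-conducted onto the frontal channel; SWS wide-band 2–8 Hz noise
  (PSD ∝ f^−1.4, "low ranges prevalent"; 100/50 µV RMS) on both channels;
  EMG as white noise at 30/15/6/3 µV RMS.
* **β bursts** (transgenic only) are Hann-enveloped sinusoids injected on
  the frontal channel (×0.6 on hippocampus). Rates 1/8/12/15 per minute,
  mean durations 0.3/0.7/1.0/1.8 s and amplitude factors 0.3/1.0/1.5/1.8
  for AW/QW/SWS/REM encode the qualitative ordering — rare and brief in
  active waking, long-lasting in REM. The age model is linear from 9 to
  26 weeks: center frequency 27 → 23 Hz (exactly 25 Hz at the default
  symptomatic age of 17.5 weeks) and base amplitude 15 → 45 µV (tripling).
  Per-burst center frequencies scatter with SD 1 Hz. No quantitative burst
  statistics are available to match, so these presets are calibrated only
  to reproduce the qualitative orderings and the published peak
  frequencies.
* **Waking δ–β coupling.** During quiet waking, each β burst is
  accompanied (probability 0.85) by a hippocampal 2.5–4.5 Hz event. Since
  active waking instead carries θ and almost no β, the waking comodulogram
  inherits the empirical sign pattern: frontal β power correlates
  positively with hippocampal δ and negatively with hippocampal θ.
* **Movement.** A heading random walk whose per-frame step follows the
  state speed (8/0.2/0.05/0.05 cm/s), folded into a 33 × 15 cm cage, plus
  50 µm tracker jitter. The jitter magnitude matters: apparent speed is a
  non-negative quantity, so smoothing cannot remove its mean, and a 0.2 mm
  jitter at 50 Hz would alone produce ~1.8 cm/s of phantom speed — above
  the stillness criterion.
* **Longitudinal design.** Per transgenic mouse, a β-onset age is drawn
  uniformly from 10–19 weeks and the clasping age is onset + 6.67 weeks.
  The onset range is chosen so that every clasping onset falls inside the
  9–26-week session grid; with a wider range some mice would clasp after
  the last session and the onset-precedence pattern would be truncated by
  the design rather than by the biology. Bursts appear only in sessions at
  or after onset; wild-types never burst and never clasp.

**What the generator does not emulate.** Electrode artifacts, micro-arousals
and state fragmentation, circadian structure, EMG leakage into EEG
channels, θ harmonics, non-sinusoidal burst waveforms, inter-animal
variability in background amplitude, and drowsiness as a distinct state
(it is absorbed into quiet waking). Passing tests on synthetic sessions
therefore demonstrates that the *analysis chain* is correct and
internally consistent under realistic signal statistics — not that the
scoring thresholds or the detection threshold would transfer unchanged to
any particular recording rig.

## Numerical choices and degenerate inputs

* Defaults for simulation speed: 500 Hz sampling and 10-minute sessions
  (2 kHz and multi-hour sessions are supported through the configuration).
  The test suite validates the spectral criteria on ten 10-minute sessions
  per genotype, the state-ordering property on ten 30-minute sessions
  (short snippets can lack active waking or REM entirely), and the cohort
  statistics on one full 18-mouse × 5-session cohort.
* EDF I/O uses classic 16-bit EDF with 1-s records and per-signal rates
  (position stored as two 50 Hz signals). Samples round-trip to the
  declared resolution, (physical range)/65535; physical min/max are
  quantized against the formatted 8-character header fields so a
  write–read cycle is exact with respect to the file's own declared
  scaling. Fixed header dates keep equal inputs byte-identical.
* All randomness flows through explicit seeds (`withr::with_seed`);
  cohort session seeds are derived deterministically from the cohort seed.
  Outputs are stamped with a configuration hash and seed in `#` header
  comments.
* Degenerate inputs fail with classed errors: traces shorter than one
  window, empty states, bands outside the frequency axis, comodulograms
  with fewer than 10 windows, contingency tables with a zero margin,
  ANOVA designs with an empty cell. An all-zero ANOVA response returns
  F = 0 by convention rather than 0/0. `run_cohort()` reports per-session
  failures and continues.

## Known limitations

* Scoring is threshold-based; no learned classifier, no micro-arousal or
  transition-epoch handling. Windows straddling a state change inherit the
  state at their center, which is the main source of residual scoring
  error at bout boundaries.
* The 1/f background fit is a single power law over 10–55 Hz; spectra with
  a knee in that range would bias the prominence ratio.
* The ANOVA ignores within-animal correlation; a mixed model would be the
  next step for real cohorts.
* Comodulogram p-values are uncorrected for multiple comparisons.
* β-onset estimation is limited by the monthly session grid: an onset is
  always detected at the first session at or after the true onset, so
  recovered precedence is quantized to the inter-session interval.
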