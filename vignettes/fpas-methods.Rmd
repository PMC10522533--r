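---
title: "Frequency-tagged auditory EEG: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-tagged auditory EEG: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fpas)
```

## The paradigm

Fast periodic auditory stimulation (FPAS) presents short vocalizations at a
fixed base rate and embeds a target emotion category at every third
position. With 350 ms stimuli and 50 ms inter-stimulus silences the base
rate is 1/(0.350 + 0.050) = 2.5 Hz and the target rate is 2.5/3 =
0.833 Hz. A brain response at the base rate and its harmonics indexes
general auditory processing; a response at the target rate and its
harmonics can only arise if the brain *discriminates* the target category
from the other categories and *generalizes* across its heterogeneous
exemplars. Because the response lives at frequencies known in advance, it
can be measured objectively with very high spectral resolution.

Two properties make the measurement interpretable:

* **Stimulus matching.** All stimuli are RMS-equalized and ramped, and the
  set is selected so that spectral centre of gravity, pitch and
  harmonicity-to-noise ratio (HNR) are comparable across categories.
* **A scrambled control.** Every sequence has a twin built from
  frequency-scrambled versions of the same stimuli in the same order.
  Scrambling permutes FFT coefficients within consecutive 200 Hz windows
  and then reapplies the original Hilbert envelope, preserving the coarse
  spectro-temporal profile while destroying harmonicity and
  intelligibility. A response that survives the subtraction
  intact − scrambled cannot be explained by the preserved acoustics.

The package implements the full chain: stimulus processing and scrambling
(`rms_equalize()`, `apply_ramps()`, `scramble_frequency()`, acoustic
features), sequence construction and rendering (`sequence_spec()`,
`build_sequence()`, `render_audio()`), acoustic controls
(`envelope_spectrum()`, `cochlear_response()`, `control_contrast()`), a
synthetic EEG generator (`simulation_spec()`, `simulate_recording()`), the
frequency-domain analysis (`preprocess()`, `crop_and_average()`,
`amplitude_spectrum()`, `harmonic_z()`, `select_harmonics()`,
`quantify()`, `contrast_intact_scrambled()`, `per_participant_response()`),
the time-domain ERP analysis (`notch_base()`, `extract_target_epochs()`,
`baseline_correct()`, `pointwise_test()`) and signal-detection scoring of
the behavioral tasks (`dprime()`, `group_test()`,
`categorization_matrix()`).

## The synthetic data generator

Real recordings for this paradigm are not publicly deposited, so the
package ships a generator that produces data with exactly the statistical
structure the analysis presumes. It is first-class, tested code — the
entire analysis stack is exercised end-to-end on its output.

A simulated trial is

$$x_c(t) = g_p\Big[\sum_k A^{(b)}_k\,w^{(b)}_c \cos(2\pi k f_b t + \phi_k)
        + g_s \sum_m A^{(t)}_m\,w^{(t)}_c \cos(2\pi h_m f_t t + \psi_m)
        + g_s\, w^{(t)}_c \,e(t)\Big] + n_c(t)$$

per channel $c$: a base steady state at harmonics of $f_b$ = 2.5 Hz, a
target steady state at the non-base-coincident harmonics
$h_m \in \{1, 2, 4, 5, 7\}$ of $f_t$ = 0.833 Hz, transient target-locked
ERP kernels $e(t)$ (raised-cosine bumps on the target onset train), and
spatially correlated $1/f^\alpha$ Gaussian noise. $w^{(b)}, w^{(t)}$ are
smooth random scalp topographies in $[0, 1]$; $g_p$ is a log-normal
per-participant gain; $g_s$ equals 1 for intact sequences and
`scrambled_gain` for scrambled ones — the scrambled control shares all
acoustic periodicity, so only the category-selective components (target
steady state and ERPs) are attenuated.

Defaults (all in µV): base amplitudes 1.2/0.6/0.3 at 2.5/5/7.5 Hz, target
amplitudes 0.6/0.4/0.3/0.25/0.2 at 0.83–5.83 Hz, ERP components of 3 µV
(150 ms latency, 60 ms width) and 4 µV (340 ms, 90 ms), broadband noise SD
10 µV with $\alpha = 1$, `scrambled_gain` 0.5, participant gain SD 0.2,
24 participants, 512 Hz. The steady-state amplitudes sit 3–10× above the
per-bin noise floor after modest trial averaging — the regime the paradigm
is designed for — while single trials at single channels remain
noise-dominated, as in real EEG.

Two phase conventions matter and are deliberate:

* Phases are fixed across a participant's trials, otherwise
  within-participant time-domain averaging would destroy the response.
* Phases are drawn once at the population level with a small
  per-participant jitter (SD 0.35 rad). Steady-state latencies are broadly
  shared across people; without this, the grand average across
  participants — the pipeline's central step — would cancel the signal.

What the generator does **not** emulate: eye-blink and muscle artifacts
(rejection is tested with synthetic amplitude spikes), volume-conducted
dipolar field patterns (topographies are arbitrary smooth maps, so tests
validate parameter recovery, not topography shapes), alpha rhythms and
other structured background, and electrode drift. Passing tests on this
generator therefore demonstrate that the analysis recovers what it assumes
from data satisfying those assumptions — not that the assumptions hold for
any particular laboratory's recordings.

The mastoid reference channels carry (mostly independent) noise like any
other channel. Subtracting the linked-mastoid average therefore injects
channel-common noise into every scalp channel, which makes whole
time-points flip jointly in the pointwise test. This is a real property of
mastoid-referenced analyses, and it is why the time-domain detection
checks are run at the powered end of the design (see below).

## The frequency-domain statistics

All spectra are single-sided FFT amplitudes with $2/N$ normalization (a
bin-centred sinusoid of amplitude $a$ µV reads $a$ µV). Trials are cropped
from 2 s after sequence onset (past the fade-in) to 52.8 s — an integer
number of target cycles (44) and base cycles (132) — giving a resolution
of 1/52.8 ≈ 0.0189 Hz.

The local-noise rule: for a bin of interest, the noise set comprises the
12 bins on each side after skipping the immediately adjacent bin (offsets
±2…±13), minus the single maximum and minimum of that 24-bin window — 22
bins. Then

* z-score: $z = (x - \hat\mu) / \hat\sigma$, computed on the
  channel-pooled (arithmetic mean) spectrum for harmonic selection;
* baseline-subtracted amplitude: $\mathrm{BSA} = x - \hat\mu$ (µV);
* SNR: $x / \hat\mu$.

Harmonics of the target rate that coincide with base-rate bins (every
third) are excluded. Consecutive harmonics with $z > 2.32$ (nominally
$p < 0.01$, one-tailed), counted from the first candidate, are selected;
the count is equalized across intact and scrambled by taking the maximum
(adding a non-significant harmonic adds zero on average). The per-channel
intact − scrambled contrast extracts a 25-bin chunk around each selected
harmonic from the difference spectrum, sums chunks across harmonics,
z-scores the central bin against the surrounding chunk bins under the same
noise rule (the chunk offers 11 usable bins per side after exclusions),
and corrects across the 128 channels with Benjamini–Hochberg at
$q = 0.05$ (the conventional level; only "FDR corrected" is standard in
this literature).

**Calibration caveat.** The "$z > 2.32 \Rightarrow p < 0.01$" reading
treats $\hat\mu, \hat\sigma$ as the true noise parameters. They are
estimates from 22 bins, and dropping the extremes biases $\hat\sigma$
low. A direct Monte-Carlo on Gaussian bins puts the true exceedance
probability of $z > 2.32$ near 3.5% (about 1.6% without the
extremes-exclusion). The test suite and the acceptance script measure this
exceedance on noise-only simulations; the measured rate should be read
against that analysis, not against the nominal 1%. This is a property of
the procedure as practised in the frequency-tagging literature, which the
package reproduces faithfully rather than corrects; the harmonic-selection
threshold is therefore mildly anticonservative, which is harmless for its
purpose (choosing how many harmonics to sum) and does not affect the
FDR-corrected channel-level inference, whose p-values inherit the same
(slightly heavy-tailed) null but are dominated by far smaller p-values in
practice.

## The time-domain analysis

The ERP pipeline runs at 512 Hz (the 25 ms ⇒ "more than 13 consecutive
points" rule pins the rate). Base-rate activity at 2.5/5/7.5 Hz is notched
out; 800 ms epochs run from one base cycle (400 ms) before each target
onset to target offset; the first and last 2 of the 48 target epochs are
dropped (fade-in/out), leaving 44; epochs with any |amplitude| > 100 µV
are rejected (the boundary value itself is kept); counts are equalized
across condition/type by seeded subsampling; baselines are the pre-target
400 ms. The paired one-tailed t-test runs per channel and time point with
BH-FDR across channels within each time point, and a channel's stretch of
significant points is a "window" only if it lasts strictly longer than
25 ms (> 13 points at 512 Hz).

A 60 ms raised-cosine difference bump is close to the smallest effect this
rule can report: its supra-threshold span at peak $t \approx 4$ is about
13 samples — exactly the boundary. The detection checks therefore inject a
5 µV difference (late-positivity scale) and use 24 participants with 4
trials per type, where the peak paired $t$ is ≈ 10 and the reported
windows span ≈ 35–40 ms; a 15 ms bump (≤ 8 points) is rejected at any
power. In these paired checks the band-pass and base-rate notches are
skipped: the synthetic noise is already band-limited and the base steady
state is *identical* in both sequence types (the scrambled gain touches
only category-selective components), so it cancels exactly in the paired
difference; the filters are exercised separately by their own tests.

## Numerical choices

* **Zero-phase filtering** is applied in the frequency domain: the
  spectrum is multiplied by the squared Butterworth magnitude response
  $|H(f)|^2$, the exact transfer function of forward–backward filtering,
  on a zero-padded (power-of-two) FFT. This is vectorized across 130
  channels and has no direction-dependent transient.
* **Down-sampling** 512 → 256 Hz is plain decimation after the 0.1–100 Hz
  band-pass: the signal is already band-limited below the new Nyquist
  (128 Hz), so no separate anti-alias stage is needed.
* **Sample counts** are `round(duration × rate)`: a 61.6 s trial at 256 Hz
  is 15 770 samples. The 52.8 s crop additionally picks, among the counts
  within two samples of `round(52.8 × rate)`, the one with the smoothest
  prime factorization (13 516 at 256 Hz) so the per-channel FFTs stay
  O(N log N) — `round` alone would give 13 517 = 7 × 1931 and a ~5×
  slower transform. The crop is therefore up to two samples (< 8 ms) away
  from an exact integer-cycle window; the resulting leakage is at the
  $10^{-4}$ relative level and far below every tolerance used in the
  statistics, and every tagged frequency keeps the same bin.
* **Pitch** uses the autocorrelation method with unbiased lag
  normalization, parabolic peak-value interpolation, a search range of
  75–600 Hz and a voicing threshold of 0.45 on the normalized peak
  (Praat-like conventions); HNR is $10\log_{10}(r/(1-r))$ capped at
  ±60 dB. COG weights frequency by spectral power. All features use a
  single rectangular window over the 350 ms stimulus — short enough to be
  treated as stationary.
* **Scrambling** permutes complex FFT coefficients jointly (magnitude and
  phase travel together) within 200 Hz windows aligned from 0 Hz, one
  seeded permutation per window; DC and Nyquist never move, and the
  negative-frequency half is mirrored so the output stays real. An
  `"independent"` mode shuffles magnitudes and phases with two separate
  permutations. "Applying the original envelope" afterwards *imposes* it
  by default: the scrambled carrier is first flattened by its own analytic
  magnitude, so the output's temporal envelope equals the original's
  exactly. Plain multiplication (available as `envelope = "multiply"`)
  leaves the carrier's Rayleigh-like magnitude fluctuations in place,
  which measurably dilutes the coherent envelope (~11% after RMS
  equalization) and would create a spurious intact-vs-scrambled envelope
  difference — the opposite of what the control stimuli are for. The two
  goals trade off: imposition whitens the carrier somewhat (spectral
  centre of gravity moves by ~10-20% on the synthetic set, versus < 10%
  under multiplication), a time-frequency uncertainty cost that cannot be
  iterated away. Scrambled items are then equalized to the *set's* shared
  RMS level and ramped, the identical path the intact items take.
* **Cochlear simulation** uses 4th-order gammatone filters in the Slaney
  parameterization (four cascaded second-order sections per band,
  ERB-spaced centre frequencies, 64 bands from 50 Hz), half-wave
  rectification per band, and summation across bands (RMS aggregation is
  available as an option).

## Design choices where the design was open

* *Non-target ordering*: "each sound once before any repeat" is enforced
  at the token level — all 48 unique non-targets appear before any second
  occurrence — with an equal number of unique items drawn from each
  non-target category (12 from each of the four, sampling 12 of the 24
  available for the frequent categories).
* *Attention probes* (6 per sequence, RMS ÷ 10) are placed outside the
  2 s fades and, by default, never on target slots, so the probe does not
  perturb the tagged response; a flag allows probes on targets.
* *Fades* are linear amplitude ramps over 2 s.
* *ERP scaling*: the transient target-locked components are
  category-selective by construction, so they scale with the same
  intelligibility gain `scrambled_gain` as the target steady state;
  otherwise the time-domain intact − scrambled contrast would have
  nothing to detect.
* *Empty harmonic selection* returns an explicit empty report flagged "no
  significant response" rather than defaulting to one harmonic.
* *Epoch rejection boundary*: exactly ±100.0 µV is kept; anything
  strictly above is rejected.
* *Rejection before baseline correction*, matching the order in which the
  artifacts occur in the raw signal.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` exercise the same computations
at different sizes, chosen as the smallest designs at which each check has
the power it needs: null calibration of the harmonic z over 60 (suite) or
200 (script) noise-only spectra at 256 Hz; parameter recovery over 8/24
participants at low noise (0.5 µV); group detection of
`scrambled_gain = 0.5` with 24 participants × 2 trials per type; ERP
window detection with 12 × 4 (suite) or 24 × 4 (script) participants ×
trials; time-domain nulls over 3/6 simulated datasets; acoustic controls
over 12–24 paired sequences (envelope) and 5–8 (cochlear). Oracle
equivalence checks (noise rule, BH step-up, neighbour selection) run on
10⁴ random instances.

## Limitations

* The generator's topographies are arbitrary smooth maps; nothing here
  validates source-space claims.
* The harmonic z-statistic's nominal 1% level is anticonservative (see
  the calibration caveat above); treat `z > 2.32` as a selection
  heuristic, not a calibrated test.
* Average referencing removes the spatial mean of a topography, so
  absolute amplitude recovery is only exact in the unreferenced pipeline
  (`reref = "none"`); the referenced pipeline recovers relative
  topography and contrasts.
* ICA-based artifact removal is out of scope: `analyze_frequency()` and
  `analyze_timedomain()` accept recordings that have already been cleaned
  (any function can stand in the loader slot).
* EDF files store neither positions nor sub-sample metadata; recordings
  read from EDF refuse interpolation until positions are supplied.
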