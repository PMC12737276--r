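---
title: "ecogsleep: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ecogsleep: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its methods: what each stage
assumes, which parameters matter and why their defaults are what they are,
what the synthetic-data generator does and does not emulate, and where the
design was genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. The analysis problem

Chronic micro-ECoG grids (here an 8×8 layout, 600 µm pitch, 64 channels)
record cortical surface potentials continuously across the sleep–wake
cycle in mice. Four analyses are standard: scoring vigilance states in 4-s
epochs; quantifying spectral power and its spatial distribution across the
grid; quantifying between-channel synchrony (coherence) per frequency
band; and detecting NREM sleep spindles with their amplitude, duration,
power and density. Because public reference recordings for this kind of
device are scarce, the package pairs every analysis with a synthetic
generator whose ground truth makes recovery measurable.

## 2. Sleep staging

An epoch showing motion in the video stream is wake, unconditionally.
Otherwise the decision is spectral: the in-epoch STFT (1-s Hann windows,
50% overlap — the window length is our choice; only "STFT" is inherent to
the method) yields summed power in three bands, wake 8–30 Hz, NREM
0.5–4 Hz, REM 6.25–9 Hz, and the largest wins.

Design choices that were open:

- **Channel support.** Whether staging should use one channel or many is
  not dictated by the method; band spectra are averaged over a
  configurable channel subset (default: all), which makes the hypnogram
  invariant to channel ordering (a tested property).
- **Band overlap and ties.** The REM and wake bands overlap at 8–9 Hz;
  the overlap is kept as defined and dominance is decided by summed
  in-band power with ties broken NREM > REM > WAKE. The tie-break favors
  the physiologically dominant low-frequency call and makes output
  deterministic.
- **Degenerate epochs.** All-zero band power (flat-lined channels) is
  labeled WAKE with a warning rather than erroring mid-recording.
- **Motion detection.** Consecutive-frame absolute difference inside the
  ROI, intensity threshold (default 20 on a 0–255-ish scale), 3×3 binary
  opening (the smallest useful structuring element), and a minimum
  connected-component size of 5 px. The first epoch has no preceding
  frame and inherits the second epoch's flag.

## 3. Spectra

`welch_psd()` uses 2-s Hann windows with 1.75-s overlap; the estimator is
the textbook average of modified periodograms with per-segment demeaning,
density-scaled so that white noise of variance σ² integrates to σ² over
the one-sided axis (a tested Parseval property). Mains interference at
50/100/150 Hz is removed by zero-phase IIR notches (quality factor 30,
≥ 20 dB at the line, ≤ 1 dB ripple beyond ±2 Hz). Band power integrates
the density trapezoidally over the closed band, so a flat density of 1
over 8–12 Hz gives 4.

The 8×8 per-electrode band-power map is interpolated to 100×100 with a
thin-plate spline (`r² log r` kernel plus a linear polynomial tail). A
thin-plate spline was chosen over Gaussian or multiquadric kernels because
it is parameter-free (no shape parameter to tune), exactly interpolates
the 64 nodes, and reproduces constants — both tested. Contour rendering is
left to the caller; the module returns the interpolated matrix.

## 4. Coherence

Magnitude-squared coherence is estimated per channel pair as
`|P_xy|²/(P_xx P_yy)` from segment-averaged spectra after a 1–150 Hz
4th-order Butterworth bandpass and the mains notches. Within a 15-s
analysis segment the estimator uses 2-s windows at 50% overlap; both are
config-exposed, since only the definition, the analysis band and the 15-s
segments are fixed by the method. Single-segment coherence is trivially 1,
so fewer than two windows is an error. The estimator is symmetric,
scale-invariant and biased upward by roughly 1/n_segments under
independence — the reason band means of independent channels sit near
0.015 at 64 segments rather than 0 (tested).

Band summaries are unweighted means over in-band bins (an integral
weighting differs only by the constant bin width here). Before/after
comparisons use the Wilcoxon matched-pairs signed-rank test per pair×band
cell — exact null distribution for ≤ 25 non-zero differences, continuity-
corrected normal approximation otherwise, zeros dropped (the usual
convention) — followed by Benjamini–Hochberg across all cells; the
direction call (`increase`/`decrease`/`none`) combines the FDR-adjusted p
with the sign of the median paired difference.

## 5. Spindles

The channel pipeline is: despike → resample to 1024 Hz → 0.5 Hz
second-order Butterworth high-pass → (optional ICA) → 10–16 Hz
fifth-order Butterworth bandpass → Hilbert envelope → NREM-baseline
threshold → duration gate → metrics. All filtering is zero-phase
(forward–backward over second-order sections), so event timestamps carry
no group delay.

- **Despiking.** Samples beyond 5 SD are excised and bridged by linear
  interpolation. The SD is robust (1.4826 × MAD about the median) so the
  spikes themselves cannot inflate the threshold, and the flagged region
  is widened by 2 ms per side to catch spike shoulders. More than 20%
  flagged triggers a channel-quality warning.
- **Threshold.** "Mean ± 1.5 SD of NREM baseline" is interpreted as a
  one-sided upper threshold μ + 1.5σ on the envelope — a lower envelope
  bound carries no information about bursts. Baseline statistics are
  global over all NREM samples of the recording (per-bout baselines were
  the alternative; global is simpler and stabler for short bouts), and
  they include whatever spindles are present, as any self-referential
  baseline must.
- **Event extent (hysteresis).** The detection threshold decides whether
  a burst exists; its temporal extent runs between the surrounding
  crossings of the baseline mean (the standard two-threshold envelope
  convention). With a single threshold the measured duration of a
  smooth-envelope burst is only ~60% of its true duration, which pushes
  legitimate short spindles under the 0.4-s gate; measuring extent at the
  baseline mean recovers ~80–90%. To keep background excursions from
  registering as events under this permissive extent, a kept event must
  also hold the envelope above the detection threshold for at least
  0.3 s contiguously (`min_core_s`). That default comes from measured
  excursion statistics: in clean sigma-band Gaussian noise, excursions
  with a ≥ 0.3-s core occur at under 0.005 events/s, while a Hann-shaped
  burst at the duration gate's lower edge retains a core well above it.
- **Merging and gating.** Regions closer than 0.1 s (`merge_gap`) merge;
  events are clipped to NREM support and kept if their duration is
  0.4–3 s.
- **Metrics.** Amplitude is max − min of the sigma-band signal over the
  event; power is the mean Welch density over 10–16 Hz computed on the
  event samples — a single Hann periodogram when the event is shorter
  than the 2-s window, since a 0.4-s event cannot host 2-s Welch
  segments. A band mean was chosen over band peak or total power (the
  definition of a per-spindle "PSD value" is otherwise open); both
  alternatives are one-line changes on the returned spectrum. Density is
  exactly `n_events / NREM seconds`.
- **ICA.** The decomposition (32 components by default, symmetric
  FastICA with a logcosh contrast on PCA-whitened data) is part of the
  pipeline, but how its output should feed detection is genuinely open.
  The default pipeline therefore detects in channel space; `use_ica =
  TRUE` detects on components and assigns each component's events to the
  channel with the largest absolute mixing weight. Both paths are tested.

## 6. Mixed models

Each spindle metric is compared Before vs After with
`value ~ time + (1 | mouse_id)` under REML, Before as the reference level,
Wald z and normal 95% CI for the time effect. With a single mouse the
random intercept is unidentifiable and the fit falls back to ordinary
least squares with a warning. Sign conventions of reported effects follow
the Before-reference coding; analyses that code time the other way will
flip signs, so magnitudes and p-values, not signs, are the comparable
quantities. Calibration (bias of the estimate, CI coverage, type-I rate
under a null) is verified by simulation in the acceptance suite.

## 7. The synthetic world

The generator is a stated world, not a tuning knob; its defaults are fixed
here and used by the tests as-is.

- **Hypnogram.** A Markov chain at the 4-s epoch step. Mean bout
  durations WAKE 100 s, NREM 120 s, REM 50 s (typical of adult mice in
  the light phase), with routing that forbids WAKE→REM in all but 2% of
  exits and sends most REM exits to wake. Continuous-time bout modeling
  was the alternative; the epoch-level chain matches the 4-s granularity
  of everything downstream.
- **Signals.** Unit-variance 1/f Gaussian background (spectral shaping,
  flat below 0.5 Hz) plus a stage-band oscillation of amplitude 2 (2 Hz
  NREM, 7.5 Hz REM, 20 Hz wake, ±5% frequency jitter). The amplitude is
  chosen so the stage band dominates the 1/f low-frequency mass; the
  wake oscillator sits at 20 Hz, outside both the REM band and the sigma
  band, so wake epochs do not masquerade as spindle activity.
- **Spindles.** Hann-windowed sinusoids (smooth envelope, so threshold
  crossings are clean) at 13 Hz, durations uniform on 0.5–2.0 s, planted
  only inside NREM epochs with Poisson rate 0.1 per NREM second (the
  upper end of reported mouse spindle densities), non-overlapping, with
  peak amplitude 3× the channel RMS by default.
- **Coupling.** A coupled pair is `x = s + n₁`, `y = a·s + n₂` with
  independent white noise; the expected coherence
  `a²P_s²/((P_s+P_n)(a²P_s+P_n))` is evaluated per frequency from the
  known source spectrum and stored as ground truth.
- **Artifacts.** Mains lines at 50/100/150 Hz with common phase across
  channels (amplitudes 0.2/0.1/0.05), and biphasic 5-ms transients at 8×
  the channel SD — guaranteed to trip the 5-SD excision rule — at 1 per
  minute per channel.
- **Motion.** One frame per epoch: a Gaussian blob over pixel noise that
  jumps to a new position exactly when the epoch is wake.

What the generator does **not** emulate: real electrode impedance drift,
EMG contamination, state-transition epochs containing two stages,
physiological spindle frequency chirps, volume-conduction coherence
profiles, or realistic video of an animal. A green recovery test
establishes that the pipeline implements its definitions correctly and
recovers structure under realistic SNR — not that it would score a real
recording at the same accuracy.

## 8. Numerical choices

- Butterworth filters are designed as analog zero-pole-gain prototypes,
  bilinear-transformed and paired into second-order sections; filtering
  is forward–backward with odd-reflection padding and steady-state
  initial conditions. The section cascade keeps the 10th-order sigma
  bandpass numerically stable where a flat `(b, a)` form would be
  marginal.
- Welch spectra demean each segment (removing DC leakage) and scale as
  one-sided densities; DC and Nyquist bins are not doubled.
- Resampling is rational polyphase with a Kaiser-windowed (β = 5) sinc,
  cutoff at the tighter of the two Nyquists; passband sinusoids survive
  within 1%.
- FastICA whitens to the leading principal subspace and uses symmetric
  decorrelation; it is deterministic given the R RNG state.
- The stationary distribution of the stage chain is computed by
  eigen-decomposition in the tests as an independent oracle. Because
  bouts last tens of epochs, stage frequencies mix slowly: the tests run
  the chain for 2×10⁴ epochs so the Monte Carlo error is safely below
  the 3-percentage-point recovery margin.
- Simulations in the acceptance suite are scaled for a single-CPU budget
  (16 channels at 512 Hz for the 1-h staging run; 4 channels at 1024 Hz
  for the 30-min spindle run); generator defaults themselves are
  unchanged.

## 9. Known limitations

- EDF export quantizes to 16 bits over each channel's observed range and
  pads the last second; it targets interoperability, not archival
  fidelity (the native bundle is bit-exact).
- The staging classifier has no artifact-epoch rejection beyond the
  zero-power guard, and no EMG channel (the recording modality has
  none).
- With very low spindle rates the NREM envelope baseline approaches
  clean noise, where a 1.5 SD detection threshold admits occasional
  background events; the 0.3-s core requirement suppresses most, but a
  higher `k` is advisable for sparse-spindle data.
- `compare_conditions` treats segments as exchangeable paired
  observations; serial correlation between adjacent 15-s segments is not
  modeled.
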