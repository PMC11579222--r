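---
title: "Models and methods for time-resolved brain-heart interaction analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for time-resolved brain-heart interaction analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bhi)
```

## The problem

During naturalistic emotional experiences — here, a 280-s immersive
virtual-rollercoaster session with two ride segments (153 s and 97 s) and a
30-s break — cortical activity and cardiac autonomic regulation change
together. `bhi` implements a complete, testable pipeline for asking three
questions about such sessions:

1. Does parasympathetically mediated heart-rate variability (HF-HRV) and
   parieto-occipital alpha power drop when self-reported arousal is high?
2. Is the cortical response to each heartbeat (the heartbeat-evoked
   potential, HEP) modulated by arousal?
3. Is there *directional* coupling between EEG band power and cardiac
   rhythms, over and above co-modulation?

Because raw human recordings for this paradigm are generally not shareable,
the package is built around a synthetic generator that produces coupled
ECG/EEG/rating sessions with known ground truth. Every downstream stage is
validated against that ground truth, against closed-form oracles, or against
exhaustive enumeration.

## The synthetic session generator

`generate_session()` simulates one participant-session from a
`session_config()` (geometry, rates, noise) and a `ground_truth()` (effect
sizes, couplings).

**Arousal ratings.** A step function over the three segments (defaults 22,
6, 34 dial units for ride 1, break, ride 2, emulating "second ride most
arousing, break least") plus a smooth AR(1) fluctuation (sd 7 units,
correlation time 8 s), rounded and clipped to the integer dial range 0-50.
The per-segment ordering break < ride 1 < ride 2 is a generator contract.

**Heart.** R-peaks come from an integral pulse frequency modulation (IPFM)
generator: a beat is emitted whenever the integral of the instantaneous rate
`(1 + m(t)) / T` crosses an integer. The modulation
`m(t) = C_LF(t) cos(omega_s t + phi) + C_HF(t) cos(omega_p t + phi')` carries
two oscillators at the LF and HF central frequencies (0.1 and 0.25 Hz).
The modulation depths are condition-dependent (defaults: HF 0.12 under low
and 0.05 under high arousal; LF 0.10/0.06), which injects the "lower HRV
under high arousal" effect. A small broadband modulation noise (sd 0.02,
generated at 4 Hz) keeps the spectrum realistic. `|C_LF| + |C_HF| < 1` is
enforced so the rate stays positive.

**EEG.** Each channel is a sum of five band-limited carriers (2, 6, 10, 20,
35 Hz) with 1-Hz amplitude envelopes, plus white noise (sd 1 microvolt) and
an optional shared 1/f background. Alpha amplitude at the parieto-occipital
ROI is condition-dependent (12 microvolt under low, 7 under high arousal),
injecting the alpha suppression; other bands are condition-flat by default.
Envelopes fluctuate with a shared AR(1) factor (relative sd 0.1,
persistence 0.9/s). When a heart-to-brain coupling is injected, the band's
envelope instead follows the adaptive Markov amplitude recursion
`a(k+1) = rho a(k) + gamma sigma_X(k) + eta(k)` driven by the cardiac band
amplitude.

**Heartbeat-evoked potential.** A fixed smooth biphasic template spanning
200-450 ms after each R-peak (windowed sine cycle, 10-ms smoothed, unit
peak) is added to five fronto-central channels (Fz, F3, FC1, FC5, C3),
scaled per beat by the arousal condition of the second containing the peak
(defaults 0 microvolt under low, -2 under high arousal). The template was
placed so the 250-450 ms cluster-test window covers it. The generator
assigns conditions with the same tertile rule the analysis uses, applied to
its own rating trace; the downstream split on the cropped trace therefore
recovers the injected contrast almost exactly, and exactly in noise-free
runs.

**What the generator does not emulate.** Real ECG waveform morphology,
respiration, eye/muscle artifacts, volume-conduction topographies and the
cardiac-field artifact (a config flag can add a small R-locked pulse outside
the baseline window for robustness checks). Passing tests on synthetic data
therefore demonstrates correctness of the *analysis chain*, not robustness
to real-world artifacts; real recordings must be cleaned before entering the
pipeline.

## Spectral estimation

All oscillatory quantities go through one variance-calibrated Morlet
transform (`morlet_cwt_power()`). The analytic wavelet at frequency `f` has
Gaussian envelope sd `sigma_t = n_cycles / (2 pi f)`; `n_cycles = 6` for the
cardiac analysis (the omega0 = 6 mother wavelet) and 7 for EEG. The
normalization is chosen so that the trapezoidal integral of the returned
power density over a band equals the variance of the corresponding signal
component: a sinusoid of amplitude A integrates to A^2/2. This keeps HRV
power in ms^2 and EEG band power in microvolt^2 and makes the forward and
inverse coupling models commensurable.

The cardiac chain is: interbeat intervals stamped at the terminating beat
(the causal convention), removal of the first beat after each break boundary,
natural cubic-spline resampling to 4 Hz, anti-symmetric ("inverted") mirror
padding of 70 s per end, wavelet power on a 64-point log grid over
0.01-0.5 Hz augmented with the exact band edges, 1-Hz downsampling by 2-s
windows with 50% overlap centred on integer seconds, band integration over
LF (0.04-0.15 Hz) and HF (0.15-0.4 Hz), and trimming of the padding down to
35 s per end (retained to initialize the coupling model). Anti-symmetric
padding (point reflection about the edge value) preserves value and slope at
the seam, which is what suppresses edge artifacts.

Grid frequencies whose wavelet envelope sd exceeds half the padding are
excluded (a cone-of-influence guard): at 0.01 Hz the envelope sd is ~95 s,
longer than the padding itself, so nothing about such components can be
estimated anywhere on a 280-s record and finite-length edge structure would
dominate the density there.

EEG band power uses the same machinery per segment (ride 1, break, ride 2),
with per-segment mirror padding of `min(35 s, half the segment)` at inner
seams and the full 35 s kept at the outer ends, then re-concatenation. This
stops wavelet support from spanning segment transitions. Band edges
(0.3/4/8/13/30/45 Hz) are grid points, so the five bands tile the spectrum
and band power is additive; integration is a closed-interval trapezoid
(a shared edge has zero measure, so no power is double-counted).

ROI alpha is averaged across electrodes first and log-transformed second
(mean-then-log): the quantity modelled downstream is the log of the ROI
mean power. Log-then-mean would instead model a geometric mean; the
arithmetic ROI mean is the conventional reading and is what the package
uses throughout.

## Timeline, cropping, binning

The analysis clock is 1 Hz; a sample at integer second `t` stands for
`[t, t+1)`. 2.5 s at each ride boundary are excluded (`crop_session()`),
which removes exactly 10 of 280 s; the break is never cropped. Cropping is
applied to the labelled timeline before binning and statistics rather than
by cutting the raw signals: spectral estimates at retained seconds are
unchanged either way, and the signals stay continuous for the wavelet
stages. Ratings are block-averaged to 1 Hz and split per participant into
tertiles by a stable sort-and-slice rule: the lowest third of seconds is
"low", the highest third "high", the middle discarded. Sort-and-slice
(rather than quantile thresholding) guarantees exactly balanced bins —
90/90/90 on a 270-s trace — even with heavily tied integer dial values; the
tie rank is time order. The empirical tertile boundaries are recorded in the
output for reproducibility.

## Heartbeat-evoked potentials and cluster inference

Epochs span -300 to +800 ms around each R-peak whose second carries a
low/high label, baseline-corrected by the per-epoch, per-channel mean over
[-125, -25] ms. Overlapping epochs (IBI < 1.1 s) are retained. Per
participant and condition, epochs are averaged pooling both movement
conditions; the high-minus-low difference maps enter a spatio-temporal
cluster-based permutation t test on the 250-450 ms window: pointwise paired
t values, thresholded two-tailed at the cluster-forming alpha (0.05),
clustered over channel neighbours (schematic 10-20 positions, distance
threshold 0.52 head radii, 4-8 neighbours per channel) and adjacent
timepoints with matching sign; cluster mass is the sum of t. The null
distribution of the maximum absolute cluster mass comes from random
per-participant sign flips (default 10,000; exhaustive enumeration is
available and used as the oracle at small n). Monte Carlo p uses the +1
correction so p is never exactly zero; both signs are tested against the
same max-|mass| null, which is the two-tailed convention. The companion
ECG-waveform control (`ecg_waveform_control()`) runs pointwise paired t
tests on R-locked ECG condition means across the window with
Benjamini-Yekutieli FDR correction across timepoints.

## Directional coupling (the SDG model)

The coupling model treats the heart as the IPFM generator above and each
EEG band as an adaptive Markov amplitude oscillator. Its inverse is
estimated window-wise (15-s windows, 1-s steps, timestamp at the window's
final second — the causal choice) on the shared 1-Hz clock, using the 35 s
of retained padding so estimates exist from the first session second (the
model consumes 30 s of initialization).

*Heart-to-brain*: the forward recursion is autoregressive, so the inverse
regresses the band amplitude `sqrt(2 P_b)` at `k+1` on an intercept, its own
lag (the AR nuisance term) and the cardiac band amplitude
`sigma_X = sqrt(P_X) / sinc(pi f_c T)`; the reported coupling is the
magnitude of the driver coefficient.

*Brain-to-heart*: the forward map is instantaneous
(`C_X(t) = gamma P_b(t) + C0`), so a lagged-target regressor would be
collinear with the driver and the coefficient split arbitrary; the inverse
therefore regresses the cardiac modulation depth
`sqrt(2 P_X) / (1000 T sinc(pi f_c T))` contemporaneously on the EEG band
power, pre-smoothed with a Gaussian of sd 2.5 s.

Two calibration constants deserve explanation. First, the `sinc(pi f_c T)`
factor: an IPFM heart samples the rate modulation by averaging it over each
interbeat interval, which attenuates a sinusoid at the band's central
frequency by exactly `sin(pi f_c T)/(pi f_c T)` (~0.935 for HF at
T = 0.8 s); dividing the measured modulation depth by it puts estimates back
on the forward model's scale. Second, the 2.5-s driver smoothing: because
band *integration* captures the modulation sidebands around the central
frequency, the temporal smearing of the estimated modulation envelope is set
by the 2-s downsampling window (plus spline and interval sampling), not by
the much wider wavelet ridge; smoothing the driver to the same resolution
makes the regression compare like with like. Both constants were fixed by
forward/inverse self-consistency — simulate with a known constant
coefficient, re-estimate through the full wavelet chain, require the median
ratio near 1 — which is the defining contract of this estimator. Magnitudes
are reported (they are log-transformed downstream); signed coefficients are
kept in the fit object.

Couplings are estimated for all 2 directions x 5 EEG bands x 2 HRV bands x
electrodes; the confirmatory pair (alpha and HF) is ROI-averaged and
log-transformed before condition-level modelling. Coupling magnitudes are
in model units; no attempt is made to compare their absolute scale with
other implementations, since the cited family of estimators fixes scale by
its own conventions.

## Condition-level inference

Per-second samples of each metric at low/high-labelled seconds enter a
linear mixed model `value ~ arousal * movement` with the same structure as
random slopes within participants, fitted by REML. HRV and coupling metrics
are natural-log-transformed; ROI alpha is already log scale. F tests are
type 3 with Satterthwaite denominator degrees of freedom; estimated marginal
means with 95% CIs and Tukey-corrected pairwise arousal contrasts within
movement level are derived from the fit. The full random structure is often
singular on per-second data; singular fits are accepted and flagged by
default, and a documented fallback ladder (drop interaction slope, movement
slope, arousal slope, intercept-only) is available and logged when
simplification is requested. Simulation at the package's own fixture noise
(200 null datasets, reported by the acceptance script) shows the arousal
test rejects at or below the nominal 5% rate and detects a 30%
multiplicative HF-HRV reduction essentially always at n = 12.
Exploratory whole-scalp maps use electrode-wise paired t tests on
movement-pooled participant means with Benjamini-Yekutieli correction across
electrodes — BY rather than BH to stay valid under the arbitrary dependence
between neighbouring electrodes.

## Numerical and design choices

- **1-Hz alignment.** All series share integer-second timestamps produced by
  the same 2-s/50%-overlap downsampling, so joins are exact, never
  interpolated.
- **Degenerate inputs.** All-identical ratings raise a "degenerate split"
  error; constant drivers make a coupling window rank-deficient and yield a
  missing estimate for that window; a constant LMM response returns the
  trivial zero model rather than dividing 0 by 0; zero-variance paired
  differences report p = 1 with a degeneracy flag.
- **Determinism.** A session is a pure function of (config, truth, seed);
  pipeline runs derive per-session seeds from the master seed and the
  participant/movement index, and the run manifest records file checksums so
  bit-identical re-runs are verifiable.
- **Problem sizes.** The package's own validation uses 280-s sessions, 20
  synthetic participants x 2 movement conditions for the end-to-end check,
  20 seeds for coupling recovery, 200 simulations for each calibration
  bound, and 500-10,000 permutations depending on context. These sizes give
  stable Monte Carlo estimates at interactive runtimes.
- **Known limitations.** The generator's carriers are single sinusoids per
  band (band power is concentrated, not spread); coupling scale is
  model-internal; the montage is schematic 2D, adequate for adjacency but
  not for source-level work; eLORETA-style source localization and
  artifact-removal pipelines for real data are out of scope.

## A minimal run

```{r example, eval = FALSE}
cfg <- run_config(n_participants = 8, seed = 42, n_permutations = 2000)
res <- run_all(cfg, out_dir = "bhi_out")
print(res)
```

The printout reports, per metric, the type-3 arousal F test and the HEP
cluster table; `res$samples` holds the per-second sample table and
`res$coupling` the full coupling grid for the ROI electrodes.
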