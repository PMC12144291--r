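---
title: "Measurement model, pipeline design, and validation strategy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement model, pipeline design, and validation strategy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`eegret` turns continuous multi-paradigm EEG sessions into a small set of
scalar measures — ERP component amplitudes, steady-state phase locking and
power, resting band power, task performance — and quantifies how reliably
those measures separate people across a repeated session. This vignette
describes the models and the design decisions behind each stage, and what
the validation suite does and does not establish.

## The measurement model

Every scored measure is treated through the two-facet generalizability
design

$$y_{ij} = \mu + p_i + o_j + e_{ij},$$

with persons $p_i \sim N(0, \sigma_p^2)$ the objects of measurement,
occasion $j$ (baseline, two-month follow-up) the single measurement facet,
and $e_{ij}$ the person-by-occasion interaction confounded with measurement
error. Reliability of relative decisions is the G-coefficient
$G = \sigma_p^2 / (\sigma_p^2 + \sigma_{po+e}^2/n_o)$; occasion variance is
excluded from the error because a shift common to everyone leaves ranks
unchanged. At $n_o = 1$ this is ICC(3,1), which the test suite verifies
numerically to $10^{-10}$ on random balanced tables.

For a balanced complete table the variance components have a closed form in
the two-way ANOVA mean squares
($\hat\sigma^2_{po+e} = MS_{res}$,
$\hat\sigma^2_p = (MS_P - MS_{res})/n_o$), which coincides with the REML
optimum; the package therefore uses the closed form (exact, testable)
rather than an iterative fit, dropping persons with incomplete pairs.
Negative estimates are truncated at zero, with the raw values retained.
The suite cross-checks the components against an independent REML fit
(`lme4`) away from the boundary.

Mean-level stability is tested with a two-tailed paired t-test per measure
and group; amplitude habituation with a Session × Run within-subject ANOVA.
Each effect is tested through orthonormal within-person contrast scores;
the Greenhouse–Geisser epsilon is the sample estimator
$\hat\varepsilon = \mathrm{tr}(S)^2/(q\,\mathrm{tr}(S^2))$ from the
contrast-score covariance $S$, clamped to $[1/q, 1]$ (Huynh–Feldt is not
implemented). One-degree linear and quadratic polynomial contrasts over
runs, and their session interactions, are the follow-up trend tests. The F
statistics are verified against `stats::aov` to $10^{-6}$; type-I error of
the paired t and GG-adjusted effects is calibrated to $[0.03, 0.07]$ at
nominal 0.05 under matched nulls.

## Paradigms and the synthetic-data generator

The generator reproduces the acquisition design exactly: five interleaved
MMN/visual-oddball runs (640 tones/run at 500 ms SOA, the first 20 always
standard; 160 visual stimuli/run with SOA uniform on a 1.6–2.4 s grid in
1/60 s steps, i.e. frame-quantized on a 60 Hz-class display), four auditory
oddball runs (200 stimuli at 1.1–1.4 s SOA in 25 ms steps), 150 click
trains (500 ms, clicks every 25 ms = 40 Hz, SOA 1.5 s), and 185 s of rest
per eye condition. "Pseudorandom" order is implemented as a constrained
shuffle forbidding consecutive rare stimuli — common oddball practice.
Visual onsets are re-drawn until every one is ≥ 50 ms from every tone
onset, making the two streams non-simultaneous while keeping the SOA on its
grid; onsets are snapped to the 1000 Hz sample grid only at the end.
`session_timeline()` carries the published block schedule (57:23 total); note
the printed steady-state block length is shorter than 150 trials at a
1.5 s SOA — the generator follows the stated trial count and SOA, the
timeline follows the printed schedule.

Runs are rendered as independent 63-channel, 1000 Hz recordings in the
FCz-referenced acquisition frame (the reference carries no data row and is
reconstructed as an explicit zero channel before re-referencing). A session
is therefore a `session_set` of per-run recordings rather than one
monolithic array — the run is the unit of acquisition and of processing,
and a full session at 1 kHz would be ~1.7 GB for no benefit.

**Amplitude convention.** A component kernel (temporal Gaussian at the
component's canonical peak latency; spatial Gaussian field on the unit
sphere centered on its peak electrode) is calibrated so that an ideal
pipeline — average reference over the included channels, difference wave,
±40 ms cluster-window mean — scores exactly the requested amplitude in
microvolts. Effect sizes are thus specified in measure units, and
end-to-end recovery tests have analytic targets. Session-level amplitudes
follow the measurement model above; within a session, run $r$ is scaled by
$(1-d)^{r-1}$ with a decay rate $d$ that may differ between sessions —
two interpretable parameters that reproduce the qualitative
baseline-vs-follow-up habituation pattern.

The background model is deliberately simple: twelve latent $1/f$ sources
mixed through smooth random scalp fields (yielding realistic inter-channel
correlations), a parieto-occipital alpha rhythm whose amplitude doubles
with eyes closed (4× power), independent sensor noise at ~10% of the
background, plus optional blinks (frontal 300 ms bumps, ~8/min), temporal
muscle bursts (high-pass noise, ~2/min), line noise, and designated bad
channels. Steady-state responses are amplitude-modulated 40 Hz sinusoids
with trial phase drawn from a von Mises distribution of concentration
$\kappa$ (expected coherence $I_1(\kappa)/I_0(\kappa)$, so ground truth is
analytic); click-level acoustics are not modeled because every scored
quantity lives in the 38–42 Hz band. Responses to targets are emitted with
a configured miss probability and log-normal reaction times. What the
generator does *not* emulate: volume-conduction head models, heartbeat and
slow electrode drift, non-stationary alpha reactivity, or the content of
novel sounds. Passing recovery tests therefore demonstrates correctness of
the measurement chain, not field realism of the simulation.

## Preprocessing chain

The task chain is fixed: 0.2 Hz high-pass → decimation to 250 Hz (0.4 ×
target-rate anti-alias low-pass) → robust common-average reference with
iterative bad-channel detection → spherical-spline interpolation of the
detected channels → epoching → BSS-CCA muscle removal → ±3 SD
epoch-statistic rejection → ocular proxy regression → −100–0 ms baseline
subtraction. Resting runs use a 0.5 Hz high-pass, the first 180 whole
1-second epochs, conservative (stricter-threshold) component removal, and
a final robust reference that keeps interpolated channels out of the mean.

Numerical and design choices worth knowing:

* **Filters** are 4th-order (high-pass) and 8th-order (anti-alias)
  Butterworth cascades of bilinear-transformed second-order sections,
  applied forward-backward with odd-reflection padding. The cascade form is
  essential at 0.2 Hz/1000 Hz, where the expanded polynomial is
  ill-conditioned; the per-sample loop is a small C++ kernel.
* **Bad channels** are flagged by robust-z amplitude deviation (> 5), best
  single-neighbor correlation (< 0.4; flat channels fail here), and
  robust-z high-frequency noisiness (> 5). Detection runs *inside* the
  reference iteration, in the average frame: against FCz, the channels
  nearest the reference carry almost no signal and any frame-dependent
  statistic misbehaves. The two frontopolar channels and both mastoids are
  excluded from the reference and never interpolated (they are kept for
  the blink proxy and for alternative referencing), and the steady-state
  chain re-references to the mean of P7/P8 before decomposition.
* **Epochs** are half-open `[start, end)` windows on the 0-based sample
  grid (−0.5–0.5 s for the mismatch stream, −1–2 s for oddballs,
  −1.248–1.752 s for click trains), removing ±1-sample ambiguities; events
  too close to an edge are dropped with a warning.
* **Rejection** z-scores three channel-mean epoch statistics once (mean
  amplitude, variance, peak-to-peak) with no re-iteration; a zero-spread
  statistic defines no rejections, so degenerate input cannot reject
  everything.
* **BSS-CCA** maximizes lag-1 autocorrelation in a PCA-whitened space
  (components are eigenvectors of the symmetrized lag-1 covariance; the
  eigenvalue *is* the autocorrelation). Components with autocorrelation
  < 0.6 *and* > 50% of power above 30 Hz are removed. Average-referenced
  data are structurally rank-deficient by one; only deeper deficiency is
  flagged. Thresholds are configurable defaults.
* **Ocular cleaning** replaces a trained component classifier with a
  deterministic regression: the blink proxy is the low-passed (≤ 8 Hz)
  mean of Fp1/Fp2, regression coefficients are estimated on samples where
  the proxy exceeds 4 robust SDs, and the fitted contribution is
  subtracted. Fully testable, no trained weights; it removes blink-band
  frontal power but will not separate lateral eye movements from frontal
  brain activity the way an ICA classifier can.
* **Artifact toggling.** `pipeline_config(artifact_stages = FALSE)` runs
  the pure measurement path (filter, reference, epoch, baseline). This is
  the configuration used with noise-free synthetic data: on such
  degenerate input the outlier detectors would flag the signal-carrying
  channels themselves (the robust amplitude median is ~0), so recovery
  tests disable both the simulated artifacts and the artifact-handling
  stages together. Stage order never changes when stages are enabled.

## Scoring

ERP components are scored on condition difference waves (deviant−standard,
target−standard, novel−standard) as the mean amplitude over a fixed ±40 ms
window centered on the component's canonical grand-average peak latency
(MMN 126 ms at FCz, auditory P3b 339 ms at Pz, auditory P3a 316 ms at Cz,
visual P3b 433 ms at Pz, visual P3a 372 ms at CPz), averaged over the
component's 6-electrode cluster. Window endpoints include samples whose
centers fall in the closed interval on the 4 ms grid. Scoring is linear,
and the session-level score equals the trial-count-weighted combination of
run-level sums — the pipeline exploits this identity to avoid materializing
pooled epoch arrays. Per-run scores reuse the fixed session windows (a
per-run peak search would confound latency and amplitude changes); an
optional peak re-derivation from a pooled grand average is available for
synthetic data with relocated kernels.

Time-frequency measures use Morlet wavelets with $\sigma_f = f/C$,
$\sigma_t = 1/(2\pi\sigma_f)$, where $C$ is 7 at ≤ 20 Hz, 14 at ≥ 40 Hz,
and linear in between — making the spectral bandwidth $6\sigma_f$ equal
(17.1429 Hz) across that transition. Kernels are truncated at
$\pm 3\sigma_t$ and L2-normalized so magnitudes are comparable across
frequencies (the normalization is not otherwise pinned down; ratios and
coherence are normalization-free). No padding is used: outputs are
restricted to −248–752 ms, which the −1248–1752 ms epochs guarantee valid
at every frequency down to 4 Hz. Inter-trial coherence is the mean
resultant length of trial phases (1 − circular variance); zero-magnitude
coefficients are excluded pointwise. Total power is trial-averaged squared
magnitude, 10log10-transformed, then baseline-corrected against
−200…−100 ms; evoked power is the squared magnitude of the trial-average
waveform, baseline-corrected in linear units — the dB transform is applied
to total power only, following the stated processing order literally.
Power below $10^{-12}$ is clipped before the log. Steady-state measures
average the 38/40/42 Hz bins over 100–500 ms on fronto-central (evoked) or
central (ITC, total) clusters.

Resting PSDs are per-epoch Hamming periodograms averaged across the 1 s
epochs (Welch with non-overlapping segments — the choice matches the epoch
structure; taper and normalization are config-exposed since the method is
otherwise unconstrained). Density normalization makes the one-sided
integral equal the signal variance (Parseval is a test). "Absolute band
power" is the mean density over the band's integer bins and cluster; the
band integral is available by flag — the G-coefficient is invariant to the
constant bandwidth factor. Behavioral scoring attributes each button press
to the most recent stimulus whose 0.1–1.0 s response window contains it
(the window sits below the minimum SOA, so double attribution is
impossible); the window is a package default, not a published constant.

## Validation strategy and problem sizes

The suite validates each stage against constructions with known answers:
planted outlier channels/epochs/bursts/blinks, analytic wavelet contracts,
closed-form circular statistics (uniform-phase resultant
$\sqrt{\pi}/(2\sqrt{N})$; von Mises coherence $I_1(\kappa)/I_0(\kappa)$),
Parseval identities, and independent oracles (brute-force z-scores, a
sort-based median, `stats::aov`, REML, an FFT-bandpass + Hilbert path for
time-frequency). End-to-end, eight noise-free synthetic persons are scored
through the full chain and compared with the calibrated kernel amplitudes
at 2% of the population amplitude — a per-person relative criterion would
be meaningless for a person whose trait draw happens to sit near 0 µV.

Statistical properties run at study-like sizes chosen to keep the full
suite in the tens of minutes on one core: reliability recovery at
n = 500 persons × 200 replicates per target G; calibration at n = 84
(the control-group size) × 2000 replicates; habituation detectability at
n = 546 (the complete-run sample) × 100 replicates, configured as a target
P3b declining little over baseline runs (2%/run) but clearly at follow-up
(8%/run) — the component and pattern for which the Session × Run
interaction is the expected positive; the mismatch response, whose
interaction is expected null, is not used as the power benchmark.
Full-session EEG-level simulations are reserved for signal-path tests at
small n; measure-level simulation carries the statistical suites.

## Known limitations

* The reliability machinery assumes a balanced two-occasion design;
  unbalanced or covariate-adjusted REML is out of scope.
* Ocular cleaning is a single-proxy regression; it does not model saccade
  topographies or cardiac artifact.
* The generator's topographies are idealized spherical Gaussians on
  geometric 10-10 positions, not digitized electrode locations or
  forward-modeled sources.
* BrainVision IO covers the multiplexed float32/int16 binary dialects
  only; EDF/BDF are out of scope.
* Evoked power is reported in linear units (no dB), mirroring the stated
  processing order; comparisons with dB-transformed evoked power from
  other toolchains require a transform.
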