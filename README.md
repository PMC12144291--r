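# eegret

Event-related EEG measures and their test-retest reliability.

`eegret` implements a complete measurement pipeline for the multi-paradigm
EEG batteries used in large longitudinal psychosis-risk studies, together
with the statistics needed to ask whether the resulting measures are stable
enough to serve as biomarkers. It covers:

* **Paradigms** — an interleaved mismatch-negativity / visual-oddball task
  (3200 tones at 90/10% standard/deviant, 800 visual stimuli at 80/10/10%),
  a 3-stimulus auditory oddball (800 stimuli), a 40-Hz auditory steady-state
  paradigm (150 click trains), and eyes-open/eyes-closed resting runs.
* **Preprocessing** — zero-phase Butterworth filtering, decimation to
  250 Hz, robust common-average referencing with iterative bad-channel
  detection, spherical-spline interpolation, stimulus-locked epoching,
  epoch-statistic (±3 SD) outlier rejection, BSS-CCA muscle removal, and
  blink-proxy ocular regression.
* **Scoring** — difference-wave ERP components (MMN, auditory/visual P3a
  and P3b) as ±40 ms cluster-window means; Morlet-wavelet inter-trial
  coherence, evoked and total power for the 40-Hz steady-state response;
  resting band power (delta–gamma) from Welch PSDs; oddball miss/false-alarm
  rates and median reaction time.
* **Reliability and stability** — generalizability-theory variance
  components for the fully crossed Persons × Occasion design, the
  G-coefficient

  $$G = \frac{\sigma_p^2}{\sigma_p^2 + \sigma_{po+e}^2 / n_o},$$

  which at $n_o = 1$ equals ICC(3,1), with the conventional
  poor/fair/good/excellent categories; paired t-tests of occasion
  stability; and Session × Run repeated-measures ANOVA with
  Greenhouse–Geisser correction and polynomial trend contrasts for
  habituation.
* **Synthetic sessions** — a paradigm-exact generator producing 63-channel,
  1000 Hz recordings (FCz-referenced) with known component amplitudes,
  phase-locking concentration, 1/f background, alpha, blinks, muscle
  bursts, and bad channels, so the entire chain can be validated against
  analytic ground truth.

## Worked example

Simulate a measure-level study (571 participants, baseline and two-month
follow-up) and estimate per-measure reliability:

```r
library(eegret)
truth <- study_truth()
mt  <- simulate_measures(truth, n_persons = 571, seed = 1, group = "CHR")
rep <- reliability_report(mt, group = "CHR")
print(rep[, c("measure", "n", "g", "category", "t", "p")], digits = 3)
```

```
             measure   n     g  category      t        p
1      mmn_amplitude 571 0.762 excellent  5.327 1.44e-07
2  aod_p3b_amplitude 571 0.725      good -4.422 1.17e-05
3  aod_p3a_amplitude 571 0.709      good  0.182 8.56e-01
4  vod_p3b_amplitude 571 0.737      good -4.182 3.35e-05
5  vod_p3a_amplitude 571 0.696      good -9.135 1.14e-18
...
```

Each row is one measure: `g` is the test-retest G-coefficient over the two
occasions (here good-to-excellent by design of the simulation truth), and
`t`/`p` test the baseline → follow-up amplitude change — the significant
declines for MMN and target P3b reflect the session-level habituation
built into the generator defaults.

The same report can be computed from fully synthesized EEG: `run_pipeline()`
draws person effects, renders every paradigm run as a 63-channel recording,
pushes each through the preprocessing and scoring chain, and returns the
measure table plus its reliability report:

```r
out <- run_pipeline(n_persons = 4, seed = 1, paradigms = "rest_open")
out$measures          # long measure table (person x occasion x measure)
```

Signal-level validation uses the generator's analytic ground truth: with
noise disabled, a synthesized session's scored MMN amplitude matches the
injected kernel amplitude to well under 2%:

```r
truth <- study_truth(); truth$habituation$run_decay <- 0
sess <- synthesize_session(truth, occasion = 1, seed = 7,
                           paradigms = "mmn_vod",
                           include_noise = FALSE, include_artifacts = FALSE)
cfg  <- pipeline_config(artifact_stages = FALSE)
m <- process_session(sess, cfg, list(subject_id = "s1", group = "CON",
                                     occasion = "baseline"))$measures
m$value[m$measure_name == "mmn_amplitude" & m$run_index == "all"]
#> [1] -2.492798      # injected: -2.5
```

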