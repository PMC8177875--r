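---
title: "Spectral slowing analysis for resting-state MEG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral slowing analysis for resting-state MEG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megalpha)
```

## The scientific problem

Thalamocortical dysrhythmia predicts that chronic pain (and several other
neurological conditions) shifts the dominant resting-state cortical rhythm
toward lower frequencies: alpha-band power moves down toward the
theta/alpha boundary. Three spectral signatures — increased theta power,
decreased alpha power, and a lowered individual alpha peak frequency — are
all captured by a single summary, the **slow-to-fast alpha power ratio**

$$
\mathrm{APR} \;=\;
\frac{\overline{P}(7\!-\!9\ \mathrm{Hz})}{\overline{P}(9\!-\!11\ \mathrm{Hz})},
$$

the mean Welch power spectral density in the low alpha band divided by the
mean in the middle alpha band. A slowed rhythm raises the numerator and
drains the denominator, so patients are expected to show a higher ratio
than controls.

`megalpha` implements the complete analysis chain for this biomarker on
multichannel resting-state recordings: preprocessing (powerline notch,
band-pass, bad-channel and bad-segment exclusion, signal-space projection
of cardiac/ocular artifacts), Welch spectral estimation, extraction of
seven spectral features per sensor or brain region, and group statistics
(two-sample permutation *t* tests with Benjamini–Hochberg FDR control,
Pearson correlations with clinical covariates, and a lateralization
index). Because raw clinical MEG of this kind is generally not shareable,
the package also contains a first-class synthetic cohort generator that
reproduces the statistical structure the analysis assumes, so the entire
chain is testable end to end.

## The seven spectral features

PSDs are estimated with Welch's method: 4-second Hamming windows, 50 %
overlap, per-window constant detrend, one-sided density normalization
(`sum(power) * delta_f` approximates the signal variance). The 4-second
window fixes the frequency resolution at exactly 0.25 Hz, which places all
band edges on bin centers. Per signal we extract:

* mean power in **theta** (4–7.5 Hz), **alpha** (8–12.5 Hz), **beta**
  (13–30 Hz), **low gamma** (30.5–60 Hz) and **high gamma** (60.5–90 Hz) —
  closed intervals over bin centers; the mean (not the sum) keeps bands of
  different widths comparable;
* the **alpha peak frequency**: the frequency of the maximal bin in the
  7–13 Hz search range, ties broken toward the lower frequency;
* the **alpha power ratio** defined above.

Two conventions deserve comment because the verbal definitions do not fix
them:

**The 9 Hz bin.** "7 to 9" over "9 to 11" leaves the shared edge
ambiguous. We use half-open bins: `[7, 9)` in the numerator and `[9, 11)`
in the denominator, so the 9.00 Hz bin is counted exactly once. The rule
is configurable in `band_scheme()` and recorded in outputs.

**No clear peak.** Some patients show no discernible alpha peak; the
analysis flags such signals and excludes them from peak-frequency
averages. A naive criterion (raw maximum < 1.2 × median in the search
range) can never flag a peakless 1/f spectrum, because the aperiodic
slope itself makes the 7 Hz bin ~1.4 × the median. We therefore first
divide out a per-signal log–log linear fit over the search range (so a
pure aperiodic spectrum becomes flat), lightly smooth (3-bin moving
average) to suppress periodogram noise, and then apply the
max < 1.2 × median rule to the compensated spectrum. The reported peak
location itself always comes from the raw spectrum. With this rule an
exactly flat spectrum and a pure 1/f background are both flagged, while
any visible alpha peak (a few times the local background) never is.

DC and Nyquist bins are excluded from every band. Whether sensors flagged
"no clear peak" should enter the whole-head average peak frequency is not
decidable from verbal descriptions; `sensor_average()` excludes them and
reports the count.

## The synthetic cohort generator

`simulate_subject()` realizes a generative model with three ingredients:

* **Aperiodic background**: Gaussian noise shaped in the frequency domain
  to a one-sided PSD $10^{\mathrm{offset}} / f^{\mathrm{exponent}}$,
  independent per channel (defaults: offset −1, exponent 1). A straight
  line fit to the log-PSD over 20–80 Hz recovers the exponent to ±0.3 at
  300 s.
* **Oscillators**: narrowband-filtered Gaussian noise with a
  Gaussian-shaped PSD around `center_freq` with FWHM `bandwidth`
  (default 1.5 Hz), scaled to RMS `amplitude` and projected to channels
  through a nonnegative topography (default: posterior-weighted on the
  circular layout). Filtered noise, not a sinusoid, so simulated peaks
  have realistic width.
* **Artifacts**: a stereotyped cardiac waveform repeated at a jittered
  inter-beat interval with a fixed random topography; a slow biphasic
  blink transient with a frontal topography; a powerline sinusoid. Clean
  copies of the cardiac/ocular trains are exposed as `ecg`/`eog`
  reference channels so event detection and SSP can be exercised.

Cohort templates mirror the reported group structure: controls carry one
alpha oscillator near 10.25 Hz; patients draw from a four-way mixture —
8.25 Hz only, 9.25 Hz only, both peaks, or no clear peak — with default
proportions 4/21, 11/21, 4/21, 2/21. Subjects with "no clear peak" simply
have oscillator amplitude 0, the simplest mechanism consistent with the
description. Between-subject variability is not reported for the source
study, so the generator exposes it as parameters with defaults chosen
once as physiologically plausible: peak-frequency SD 0.4 Hz and lognormal
amplitude spread (`sdlog` 0.25). Under these defaults the groups separate
on the sensor-average ratio with an effect size broadly comparable to the
reported contrast (standardized difference on the order of 1–1.5,
depending on recording length) while overlapping substantially at the
individual level.

Covariates (pain VAS before/24 h before the session, a depression score)
are drawn per subject; `pain_link` sets the correlation between a
patient's alpha slowing and the pain score (default 0, a true null, so
correlation analyses are testable under both hypotheses).

The default sampling rate is 600 Hz rather than an acquisition-grade
2400 Hz: every analysis frequency is ≤ 90 Hz, and acquisition hardware
anti-aliasing sits below 600 Hz anyway; 2400 Hz remains available via
`cohort_spec()`. The default layout is a 64-sensor circular disc with
hemisphere labels — topography statistics need a layout, not a
proprietary helmet geometry.

What the generator does **not** emulate: biophysical forward fields and
sensor covariance (no head model), non-stationarity over minutes,
movement, muscle artifacts, or realistic regional coupling. Region time
series are generated directly (standing in for a source-imaging inverse
solution); the region-retention rule (keep regions backed by **more
than 20** source grid points) is applied to region metadata exactly as at
sensor level. Consequently, green tests demonstrate correctness of the
pipeline's algorithms and statistics under the assumed generative model —
not clinical validity on real recordings.

## Preprocessing choices

* Filters are zero-phase (forward–backward) IIR: per-line second-order
  Butterworth band-stops with quality factor 30, and a band-pass realized
  as cascaded order-4 high- and low-pass sections, which is numerically
  stable even for a 1 Hz edge. Reflection padding covers ~3 time
  constants of the slowest pole; edge samples within the settling zone of
  a finite record remain imperfect, as with any zero-phase scheme.
* SSP bases come from the SVD of the event-locked average epoch
  (channels × epoch time), one component per artifact kind by default.
  The averaged epoch cancels non-phase-locked background, so the leading
  singular vector aligns with the true artifact topography
  (|cosine| > 0.99 in simulation). Component counts and epoch windows are
  configuration, and are reported in the preprocessing log.
* Bad channels are excluded, never interpolated. Bad segments are
  annotations (visual inspection in practice; inputs here); spectra are
  estimated per good segment and pooled with window-count weights, which
  avoids stitching discontinuities. Segments shorter than one Welch
  window are discarded and counted.

## Statistics

The group test is a two-tailed two-sample permutation *t* test
(pooled-variance Student statistic; the permutation null makes the
statistic's flavor a labelling choice, and it is configurable). With
`n_perm` random relabelings, `p = (1 + #{|t*| ≥ |t|}) / (1 + n_perm)`, so
p is never zero; when the number of distinct label splits is ≤ `n_perm`
the null is enumerated exhaustively and the identity split is included in
the count. `group_compare()` uses **one shared permutation schedule**
across all signal × feature cells, preserving their dependence structure,
and applies Benjamini–Hochberg FDR at level 0.05 over the joint family
(all signals × all 7 features, the default; per-feature families are
available since the original correction family cannot be pinned down
beyond "signals × bands").

Post hoc Pearson correlations between the whole-head ratio and covariates
are reported uncorrected, matching their descriptive role. The
lateralization index for a positive feature on a homologous region pair
is $(L - R)/(L + R) \in (-1, 1)$.

## Acceptance-scale study designs

The statistical acceptance checks run Monte Carlo studies that would take
hours at acquisition scale, so they use scaled designs (recordings remain
≥ 2 Welch windows; all frequencies of interest are below Nyquist at
300 Hz):

* Type-I error: 1,000 null cohorts, 8 + 8 subjects, 12 s × 2 sensors,
  999 permutations, single feature (whole-head alpha ratio).
* FDR control: 200 global-null cohorts, 8 + 8 subjects, 64 sensors × 7
  features, 8 s records. Power: 20 cohorts, 16 + 16 subjects, 60 s
  records, with the default slowed oscillator injected on 6 of 64
  sensors (~10 % of signals); "true effect" cells are the injected
  sensors' peak-frequency and ratio features — the two features the
  slowing manipulation moves by construction — and at least 80 % must be
  recovered.
* Paper-analogue recovery: 100 cohorts of 25 controls vs 21 patients
  (default mixture), 24 s × 8 sensors with artifacts and full
  preprocessing; the patient mean sensor-average ratio must exceed the
  control mean in ≥ 95 cohorts and the permutation test must reject in
  ≥ 90.
* Lateralization: slowing confined to right-hemisphere regions (with a
  normal-speed alpha on the spared hemisphere) must yield predominantly
  right-sided rejections; hemispherically symmetric slowing must keep the
  mean alpha-ratio LI below 0.05 in magnitude while rejections persist.

## Worked example

```{r example, eval = FALSE}
co <- cohort_spec(n_control = 10, n_patient = 10,
                  duration = 60, sampling_rate = 300, n_channels = 16,
                  master_seed = 1)
cfg <- analysis_config(cohort = co,
                       preprocess = preprocess_config(
                         notch_freqs = c(50, 100), bandpass = c(1, 140)),
                       n_permutations = 999, seed = 1)
report <- run_sensor_analysis(cfg)
report$group_means
report$avg_ratio_test
write_report(report, "report")
```

## Known limitations

* Artifact event detection assumes reference channels; no reference-free
  (ICA-style) decomposition is provided.
* Automatic bad-segment detection is out of scope; annotations are
  inputs.
* The generator's artifact model is stereotyped by design — sufficient to
  exercise SSP, not to benchmark artifact-removal methods.
* No parametric separation of periodic and aperiodic spectral components;
  the aperiodic compensation inside the peak-prominence rule is a local
  linear fit, not a model fit.
* Statistical results on synthetic cohorts characterize the pipeline, not
  patients; no clinical claims follow from them.
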