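---
title: "Simulating and recovering qEEG brain-age effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and recovering qEEG brain-age effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qeegage)
```

## The model

The package implements a quantitative-EEG brain-age workflow. Its scoring
model is deliberately simple and fully linear:

1. **Feature.** Resting-state EEG is notch- and band-pass filtered
   (50 Hz; 0.5–30 Hz), cut into 2-s segments with 50% overlap,
   artifact-rejected, Hann-windowed and Fourier transformed; the
   segment-averaged power spectra give, per channel, the alpha-band
   (7–13 Hz) center-of-gravity frequency, averaged over a posterior
   electrode set (`O1 O2 P3 P4 Pz T5 T6`). The center of gravity is the
   standard robust estimator of the individual alpha frequency (IAF) and
   degrades gracefully when the alpha peak is split; the extractor is a
   plain function of a `power_spectrum`, so peak-frequency variants can be
   swapped in.
2. **Calibration.** Ordinary least squares of chronological age (CA) on
   the feature, fitted on a normative reference cohort. The regression is
   run in the prediction-ready direction (CA on feature) because the brain
   biological age (BBA) is *defined* as a predicted age; the alternative
   (invert a feature-on-CA fit) is noted but not implemented.
3. **Scores.** `BBA = intercept + slope × feature`, clamped to the
   meaningful age range 16–100 y (flagged, never an error: the bounds mark
   EEG maturation and a practical maximum age, not invalid data). The
   brain-age gap is `BBA − CA`; the brain-resources index is
   `BR = 100 · (CA − BBA) / 84` percent, i.e. the gap normalized to the
   16–100 y span, positive when the brain is younger than its CA. The
   84-year denominator is an interpretation reconciling the verbal
   definition with the published group means (e.g. a 54.1/46.3 pair gives
   9.29%, within rounding of the printed 9.89%; a CA−16 denominator would
   give 20.5%, which is inconsistent).

Because the study's registry data are private, every claim the package
makes is established by **parameter recovery on synthetic cohorts**: the
generator encodes known truths, the pipeline must get them back.

## The cohort generator

`paper_profile()` encodes the study conditions: a nutraceuticals arm
(n = 42, CA 54.1 ± 13 y truncated to 25–77, 73.8% female, follow-up
13 ± 1.13 months truncated to 6–18) and a lifestyle arm (n = 47, CA
45.2 ± 7.3 y, 53.2% female, follow-up 13.5 ± 1.10 months). Post-visit CA
is exactly `CA + followup/12`.

**Baseline gap.** The published baseline numbers over-determine a single
normal distribution: the arm-mean gaps (−7.86 / −7.49 y) together with the
observed older-brain counts (15/42 and 13/47 subjects with BBA > CA) would
force sd ≈ 21 y, which puts over 10% of subjects below the BBA = 16 floor
and distorts every downstream mean. The generator therefore makes the
stratum structure first-class: a fixed `round(n · p_older)` subjects draw
a positive gap and the rest a non-positive one, each from a truncated
normal whose *location is solved numerically* (`uniroot` over the
closed-form truncated-normal mean) so that the realized stratum mean
equals the configured one despite per-subject bounds that keep
`BBA ∈ [16, 100]`. Older-stratum moments (+8.82 ± 7.73 y) come from the
published pooled stratified table (BR −10.5 ± 9.2% on the 84-y scale); the
younger-stratum mean is then solved per arm from the arm-level mean, e.g.
`(−7.86 − (15/42)·8.82)/(27/42) = −17.13` y. This reproduces arm means,
stratum counts and the age floor simultaneously.

**Intervention effect.** The true post−pre BBA change is drawn per subject
from `N(effect_mean_stratum, effect_sd)` with the published
stratum-conditional means (−6.77 y for older-brain and −0.64 y for
younger-brain subjects in the nutraceuticals arm; +0.25 / −0.13 y in the
lifestyle arm). The arm-level effects are therefore *emergent mixtures*:
(15·(−6.77) + 27·(−0.64))/42 = −2.83 y and
(13·0.25 + 34·(−0.13))/47 = −0.025 y. `effect_sd = 2.5` y is the package's
choice for response heterogeneity: large enough that single replicates
show realistic spread, small enough that the published effect is reliably
detectable at n = 42 (measured detection rate ≈ 0.98 within-arm, ≈ 0.87
between arms).

**Measurement model.** The alpha–age mapping is
`f(bba) = 10.8 − 0.03 · (bba − 16)` Hz, spanning ≈10.8→8.3 Hz over ages
16–100, safely inside the 7–13 Hz analysis band. The source study reports only
that the feature is alpha-based, so anchor and slope are configurable; the
defaults follow the well-replicated slowing of the IAF with age. Per-visit
feature noise is `sd · (√ρ · u_subject + √(1−ρ) · z_visit)` with
`sd = 0.075` Hz and `ρ = 0.6`: each visit has marginal noise sd 0.075 Hz
(≈2.5 y of BBA at the −33.3 y/Hz slope, consistent with the high but
imperfect test–retest stability of the IAF), visits of one subject
correlate at ρ, and ρ = 1 makes paired differences noise-free. The binary
"current health symptoms" covariate uses the published per-arm visit rates
(33.3→4.7% and 40.2→32%) and feeds the chi-square leg of the battery.

**Two fidelities.** `fidelity = "feature"` emits the noisy feature
directly and supports thousands of replicates in seconds;
`fidelity = "signal"` synthesizes 19-channel, 256 Hz EEG around the *same*
feature draw — an amplitude-modulated alpha oscillation (posterior 20 µV,
anterior 8 µV), a 1/f background (5 µV RMS), a 50 Hz mains line (2 µV) and
Poisson artifact events (blinks: 0.5–2 Hz half-sines of 150–300 µV on
frontal channels; muscle: 20–30 Hz bursts of ≈50 µV on temporal/frontal
channels) — and the full signal chain re-measures it. A bridging test
checks that matched-seed arm means from the two fidelities agree within
0.5 y.

## Numerical choices

* **Zero-phase filtering** (forward–backward 4th-order Butterworth
  band-pass; biquad notch with ≈2 Hz bandwidth) so the feature band
  carries no group delay; odd-reflection padding suppresses edge
  transients. Filtering twice changes passband RMS by <1%.
* **Hann window, window-power normalization, no zero-padding**: 2-s
  segments give exactly 0.5 Hz bins, so the 7 and 13 Hz band edges fall on
  bins and the band sum is unambiguous; the spectrum sums to the
  time-domain variance within 2% (Parseval test).
* **Artifact rejection** is a documented stand-in for the study's
  unpublished algorithm: a segment is dropped when any channel exceeds
  100 µV peak-to-peak, jumps >50 µV between samples, or flatlines
  (<0.5 µV range). Thresholds are config; recordings with fewer than 30
  retained segments are flagged low-confidence; a fully rejected recording
  is a hard error. Equivalence with the original algorithm is not claimed —
  the criteria are validated against the generator's injected-event log
  (≥80% of event-center segments rejected).
* **Rank tests**: exact two-sided p by full enumeration for n ≤ 12
  (signed-rank) / n₁+n₂ ≤ 12 (Mann–Whitney), mid-ranks for ties,
  zero differences dropped (Pratt behind a flag), tie-corrected normal
  approximation otherwise, no continuity correction. The reported z is
  `(min(T⁺,T⁻) − μ)/σ`, the convention of the source tables (always ≤ 0
  for the signed-rank). Note the exact null distributions are discrete: the
  approximate p matches the exact p well on average but can differ by >0.05
  pointwise at these n.
* **Calibration attenuation**: regressing CA on a noisy feature shrinks
  the slope by the reliability `λ = var(f_true)/(var(f_true)+σ²)`
  (≈0.99 at the default noise over a uniform 16–100 y reference). This
  biases recovered *gaps* toward zero by ≈0.15–0.35 y (visible in
  `recover_effects()` output); change scores are affected only via λ
  itself (≈1%). This is a property of the chosen, prediction-ready
  calibration direction, not a bug, and is left visible rather than
  corrected.
* **Clamping**: estimated and true post BBA are clamped to [16, 100] with
  flags; under the study profile the clamp touches <1% of subjects.
* **Strata at analysis time** use the *estimated* pre-visit gap (as the
  study did), so stratum-level recoveries carry a small
  regression-to-the-mean bias relative to the generator truths; a gap of
  exactly 0 counts as "younger".

## Problem sizes

The recovery analyses use 200 replicates of the full two-arm profile
(≈8,400 subject-visits per quantity) and 1,000 replicates for the
lifestyle change, whose true value (−0.025 y) is an order of magnitude
below the per-replicate standard error; the type-I-error check uses 1,000
zero-effect replicates; signal-fidelity checks use 60–120 s recordings and
a handful of subjects. These sizes give Monte-Carlo standard errors a
factor ≈3–10 below the effects being checked.

## What the synthetic data do not show

The generator emulates the *statistical* structure of the study — arm
demographics, stratum mixture, effect sizes, follow-up drift, feature
noise — and the *spectral* structure needed by the signal chain. It does
not emulate real EEG microstructure (spindles, transients, non-stationary
alpha reactivity), electrode artifacts beyond the two stylized waveforms,
dropout/missingness, or any pharmacology of the interventions. Passing
recovery tests therefore demonstrates that the pipeline measures what it
claims under its own assumptions; it cannot validate the published
regression coefficients (never printed) or the original artifact
algorithm, and it cannot rule out biases absent from the simulation (e.g.
drowsiness-induced alpha slowing at the post visit). The published test
statistics themselves (z-values, χ²) are not recovery targets: several are
not reproducible even from the published summary tables themselves, and the
private registry data they summarize are unavailable.
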