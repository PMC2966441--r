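---
title: "Simulating and decoding eye-of-origin signals: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and decoding eye-of-origin signals: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(utrocular)
```

## The scientific problem

Utrocular discrimination is the ability to report which eye a monocularly
presented stimulus was shown to. Behaviorally this ability is weak and
variable, yet the eye of origin is encoded in primary visual cortex, where
neurons are organized into ocular-dominance columns roughly 0.8 mm wide.
Conventional 3 T fMRI voxels (1.5 mm here) are too coarse to resolve single
columns, but each voxel samples an idiosyncratic mix of left- and right-eye
columns, leaving a small net eye preference per voxel. Multivoxel pattern
analysis (MVPA) can aggregate these weak biases across a region of interest
and decode the stimulated eye above chance.

This package provides a complete in-silico counterpart of such a study:

1. a **forward simulator** of a columnar cortical sheet sampled into
   BOLD-like voxel time series with known ground truth,
2. the **decoding pipeline** — per-run z-normalization, block-averaged
   pattern samples, training-only T-statistic voxel selection,
   template-correlation classification, leave-one-run-out cross-validation,
3. an **inference layer** — within-run permutation tests with Bonferroni
   correction, plus the analytic t and correlation tests used for group
   summaries, and
4. a **behavioral module** — generation and equal-variance signal-detection
   analysis of utrocular discrimination sessions.

Because no raw scanner data accompany the study this package models, the
simulator is not a convenience: it is the substrate on which every claim
about the pipeline (no selection circularity, calibrated false-positive
rates, recovery of the spatial-frequency contrast) is made testable.

## The cortical sheet model

### Ocular-dominance map

`generate_od_map()` draws Gaussian white noise on a mm-resolution grid,
band-passes it with a log-Gaussian annular filter centred on the columnar
frequency `1/od_period_mm` (default period 1.6 mm, i.e. two 0.8 mm columns),
and passes the unit-variance result through `tanh(sharpness * z)`. This is
the standard minimal generative model for stripe-like columnar layouts: the
band-pass sets the spatial scale, the saturation sharpens the field toward
binary left/right stripes while keeping it in [-1, 1]. With `sharpness = 0`
the linear field is returned, rescaled by its maximum. The radially averaged
power spectrum of the generated maps peaks at the columnar frequency
(verified within half an octave across seeds in the test suite).

```{r odmap}
oc <- generate_od_map(seed = 1)
ps <- radial_power_spectrum(oc)
ps$freq[which.max(ps$power)]  # cycles/mm; columnar frequency is 1/1.6 = 0.625
```

### Spatial-frequency preference map

Low spatial-frequency domains tend to sit at the centres of ocular-dominance
columns, where neurons are most monocular. `generate_sf_map()` encodes this
as a mixture: a standardized `(1 - |ocularity|)` field (low preference at
column centres) is combined with independent band-passed noise using weight
`coupling_rho`, and the mixture is rank-mapped to a uniform marginal on
[0, 1]. One parameter therefore controls the whole association:
`coupling_rho = 0` gives an independent map, `coupling_rho = 1` a
deterministic function of ocularity, and the correlation between
`1 - sf_pref` and `|ocularity|` grows monotonically in between. The rank
transform guarantees the [0, 1] range and a scale-free preference axis.

### Response model

`neural_response()` maps a stimulus (eye `e` with sign `s = ±1`, spatial
frequency `f` on the unit preference axis, low = 0, high = 1) to the
noise-free response of every sheet location:

    r = base_gain * (1 + eye_selectivity * s * ocularity)
        * exp(-(f - sf_pref)^2 / (2 * sf_tuning_width^2))
        + left_eye_offset_delta * [e == L]

The multiplicative term is monocular gain; the Gaussian term is unimodal
spatial-frequency tuning; the additive term reproduces the global left-eye
mean-signal advantage seen in group data. Because `eye_selectivity <= 1` and
`|ocularity| <= 1` the response is non-negative everywhere, and with
`eye_selectivity = 0` and zero offset the left- and right-eye responses are
identical — the construction used by all null suites.

The decisive interaction: a low-sf stimulus drives locations with low
`sf_pref`, which under positive coupling are the most monocular ones, so the
eye signal available to a voxel is strongest for low spatial frequencies.
This is the mechanism behind the headline contrast (eye decoding succeeds
for low but not high spatial frequency), and the simulator reproduces it
without any dedicated switch.

### Voxel sampling

`sample_voxels()` smooths the response field with a Gaussian kernel
(default FWHM 4 mm, edge-renormalized so constants are preserved) and
averages it inside each voxel footprint (default 1.5 mm isotropic). A point
worth stating explicitly: 4 mm smoothing attenuates the columnar frequency
itself essentially to zero (the Gaussian transfer function at 0.625
cycles/mm is ~e^-22), so decoding in this regime rides on *low-frequency
imbalances* in the ocularity field — chance local excesses of left- or
right-eye territory — rather than on resolved columns. That smoothing does
not abolish eye decoding is thus a property the simulation reproduces, not
an assumption.

### Run simulation

`simulate_run()` lays out each run as fixation (19.2 s) followed by each of
the four conditions (eye × spatial frequency) once in a pseudo-random order,
each 19.2 s block followed by 19.2 s fixation; at TR 3.2 s every block spans
exactly 6 volumes (54 volumes/run). The noise-free expectation of a
stimulation volume is the condition's voxel response vector modulated by a
canonical double-gamma hemodynamic response (peak ~6 s, undershoot ~16 s,
unit peak) convolved with the block boxcar; a pure-boxcar mode exists for
exact tests. Noise is stationary AR(1) Gaussian per voxel (default marginal
SD 0.25 response units, lag-one correlation 0.3), independent across voxels;
spatially correlated noise is a known omission. Condition order and noise
take separate seeds so label sequences can be held fixed while noise varies.

## Preprocessing

`znormalize_run()` standardizes each voxel's time course over the full run
(stimulation and fixation) to mean 0, SD 1. The population-SD convention
(denominator n) is used — the choice is immaterial to correlation-based
decoding, which is scale-invariant, but must be fixed for bit-exact tests.
Normalizing over the whole time course centres responses against the
fixation baseline, so "responsive" voxels have positive sample means.
Whether normalization should instead be per volume-pattern is ambiguous in
principle; per-voxel is the default and the alternative was deliberately not
implemented as a claimed-faithful option.

`extract_samples()` identifies blocks as maximal constant-label stretches,
shifts each block's window forward by `lag_volumes` (default 1 volume =
3.2 s) to absorb hemodynamic lag, and averages the window into one pattern
sample per block. Volumes shifted past the end of the run are dropped; a
window that disappears entirely is an error. Volumes falling between
shifted windows are unused by design.

## Decoding

For a binary problem (e.g. `L_low` vs `R_low`) `loro_cv()` iterates over
runs: all other runs form the training set, on which

1. voxels are ranked by the absolute pooled-variance two-sample T statistic
   between the two conditions (ranking *ignores the sign*), and the top
   `n_voxels_cutoff` (default 100) are retained. Degenerate voxels follow
   deterministic conventions: zero variance with zero mean difference gets
   |T| = 0 (ranked last); zero variance with a nonzero difference gets
   +Inf (ranked first). Ties at the cutoff break by lowest voxel index;
2. per-condition templates are the element-wise means over training
   samples, restricted to the selected voxels;
3. each held-out sample is assigned to the condition whose template has the
   larger Pearson correlation with it. Pearson (not rank) correlation
   implements "linear correlation", and its affine invariance makes the
   classifier insensitive to per-sample gain and offset.

The univariate variant (`classifier = "univariate_difference"`) mirrors the
mean-signal analysis: voxels are ranked by mean response across all training
stimulation samples ("most visually responsive"), samples and templates are
reduced to their mean across the selected voxels, and the nearer template
(smaller absolute difference) wins. Exact ties in either classifier resolve
to the first problem condition and are counted in the result — ties have
measure zero with continuous data, but the rule makes runs bit-reproducible.

Voxel selection is re-run inside **every** fold, never on the full dataset.
The test suite certifies the payoff: across 200 pure-noise datasets the
cross-validated accuracy stays at chance and the permutation test's type-I
error stays at its nominal level, i.e. training-only selection introduces no
circularity. Within cross-validation the responsiveness ranking for the
univariate decoder is likewise computed from training folds only; when used
merely to summarize mean signal outside any CV, all data may be used.

## Inference

`permutation_test()` builds the null by independently permuting the two
problem labels within each run (with one sample per condition per run this
is a fair coin flip per run, a space of 2^12 relabelings) and re-running the
full pipeline — selection, templates, cross-validation — per permutation.
The add-one estimator `p = (1 + #{null >= observed}) / (1 + N)` never
returns zero and counts ties against significance; the default N = 1000
resolves p < 0.01 with margin, and N = 199 is used in the large calibration
suites. Within-run flips respect the run structure that the cross-validation
unit is built on, so exchangeability holds exactly under the null. The
Bonferroni family defaults to 3 (the three visual areas tested together) and
is configurable; no claim is made that this matches any particular published
family.

The analytic layer (`t_pvalue()`, `one_sample_t()`, `paired_t()`,
`pearson_test()`, `bonferroni()`) implements the textbook formulas with
`stats::pt` as the tail primitive, and is cross-checked in the tests against
both numerical integration of the t density and `stats::t.test` /
`stats::cor.test`.

## Behavioral model and analysis

`simulate_behavior()` generates a 624-trial session (156 per eye × spatial
frequency condition, 350 ms stimuli) under two ordering constraints: no
condition repeats on adjacent trials anywhere, and within each consecutive
series of 8 trials the spatial frequency never repeats on adjacent trials.
The series reading (624 = 78 × 8, boundaries reset) is adopted because a
sliding-window reading would make the spatial-frequency rule subsume the
condition rule entirely. Sequences are drawn by sequential constrained
sampling from the balanced deck, with probabilities proportional to
remaining counts and a restart on dead-ends (budget 10^5 restarts); the
result is verified against an exhaustive scan of both rules in the tests.

Responses follow the equal-variance Gaussian signal-detection model with
"dominant eye stimulated" as the signal class: evidence ~ N(+d'/2, 1) on
dominant-eye trials and N(-d'/2, 1) otherwise, response "dominant" when the
evidence exceeds the criterion for that trial's spatial frequency. Positive
criterion is a conservative bias against reporting the dominant eye. The
default generative parameters are the group estimates this package models
(d' = -0.13 low / 0.96 high; criterion 0.07 / 0.16; dominant eye left —
the majority in the modelled sample), so the default simulated observer *is*
the study's average observer.

`sdt_analysis()` estimates d' = z(hit) - z(fa) and criterion
c = -(z(hit)+z(fa))/2 with the log-linear correction (add 0.5 to each count,
1 to each denominator) applied always — a continuous estimator that never
produces infinities — with a flag for sessions where a raw rate was 0 or 1.
A consequence of the corrected rates' exact complement identity is worth
recording: relabeling the dominant eye leaves d' invariant and flips the
sign of the criterion (swapping the stimulus classes while keeping responses
is what flips d'). Parameter recovery from 100 sessions × 624 trials returns
generative d' and criterion to within ±0.05, and an unbiased observer's
accuracy converges to Φ(d'/2).

## The study orchestrator

`run_study()` chains everything per subject and region of interest. Regions
are simulated as independent sheets with decreasing coupling and monocular
gain (defaults: V1 0.8/0.8, V2 0.5/0.5, V3 0.1/0.1 for
coupling/eye-selectivity), mirroring the qualitative hierarchy in which
eye-of-origin information weakens from V1 to V3; no quantitative cross-area
forward model is claimed. Each subject receives one out-of-scanner session
(624 trials) and one in-scanner judgement per stimulation block (48 trials),
both driven by the same generative observer, which yields the in/out
accuracy correlation over subjects × spatial frequencies. Reports carry the
master seed and an FNV-1a hash of the config in every artifact name.

## Parameter defaults and how they were chosen

Protocol parameters (12 runs, 4 conditions, 19.2 s blocks and fixations,
TR 3.2 s, 1.5 mm voxels, 4 mm FWHM smoothing, 100-voxel cutoff, 1-volume
lag, 624 trials, 0.8 mm columns) are the modelled study's own design and are
not tuning knobs.

Voxel-level eye-bias effect sizes have no published quantitative anchor, so
they were fixed once, by forward simulation of the generator alone, to land
in the qualitative regime the study reports — low-spatial-frequency eye
decoding clearly above chance, high near chance — and then frozen:

| parameter | default | role |
|---|---|---|
| `eye_selectivity` | 0.8 | monocular gain modulation |
| `sf_tuning_width` | 0.2 | width of sf tuning on the unit axis |
| `left_eye_offset_delta` | 0.05 | global left-eye mean advantage |
| `noise_sd` | 0.25 | per-volume noise SD (response units) |
| `ar1_phi` | 0.3 | temporal noise autocorrelation |
| `coupling_rho` | 0.8 | sf-preference / ocularity association |
| `sharpness` | 2 | saturation of the columnar map |

Under these defaults low-sf eye decoding averages ~0.85–0.9 and high-sf
~0.5, with low > high in ~90% of simulated subjects. These are *chosen*
effect sizes, documented as tunable — the simulation demonstrates the
mechanism and calibrates the pipeline; it does not estimate cortical
parameters from data.

## Numerical choices and degenerate inputs

- Z-scoring uses the population-SD denominator; zero-variance voxels map to
  zeros rather than NaN.
- Undefined correlations (zero-variance test vectors or templates) are
  treated as losing scores; if all scores are undefined the tie-break fires
  and the tie is flagged.
- The permutation p-value is the add-one estimator, bounded below by
  1/(N+1).
- `pearson_test` reports |r| = 1 as p below the double floor rather than 0.
- The behavioral sampler fails with a diagnostic after its restart budget
  instead of hanging on infeasible constraint sets.
- All randomness flows through per-call seeds; child streams are derived
  with a fixed multiplicative scheme, so every artifact is bit-reproducible
  from one master seed.

## Problem sizes used by the checks

The calibration suites use 200 simulated null datasets (12 runs × 144
voxels, 199 permutations each), 50 simulated subjects for the
spatial-frequency contrast, and 100 sessions × 624 trials for
signal-detection recovery; these sizes give Monte-Carlo margins a few times
smaller than the effects being checked while keeping the whole suite fast
on a single CPU.

## What passing tests do and do not show

The simulator emulates: columnar spatial structure at a controlled period,
coupling between preference maps, partial-volume voxel sampling, smoothing,
hemodynamic block responses, temporally correlated noise, and a
signal-detection observer with ordering-constrained trial sequences. It does
not emulate: 3D folded cortical geometry, spatially correlated noise, head
motion or distortion, binocular rivalry dynamics, non-stationary arousal, or
any scanner physics. Passing tests therefore certify the *pipeline* —
its selection logic is non-circular, its inference calibrated, its
estimators consistent — and the *mechanistic sufficiency* of biased columnar
sampling for the decoding contrast; they do not certify that real cortical
effect sizes equal the defaults.

## Known limitations

- The 2D flattened-sheet geometry ignores through-depth partial voluming.
- AR(1) noise is independent across voxels; real fMRI noise is spatially
  correlated, which would reduce the effective number of independent voxel
  biases.
- The univariate decoder's "most responsive" ranking is defined on training
  folds within CV; other conventions exist and are not claimed equivalent.
- The Bonferroni family size and the permutation scheme are reasonable
  defaults, not reconstructions of any specific published analysis.
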