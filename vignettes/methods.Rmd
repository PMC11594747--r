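---
title: "Models and methods: macular structure-function analysis with the mfPhNR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: macular structure-function analysis with the mfPhNR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfphnr)
library(dplyr)
```

## The scientific problem

Open-angle glaucoma kills retinal ganglion cells (RGCs). Roughly half of
all RGCs sit within the central 16° of the macula, so the question of
*where* in the macula dysfunction appears first — and whether functional
loss tracks structural thinning — is central to early detection. Two
measurements address it from opposite sides:

* **Function.** The multifocal photopic negative response (mfPhNR) is the
  negative deflection that follows the positive P1 peak of a localized
  cone-driven ERG response; it originates mainly in RGC activity. With a
  multifocal paradigm, 60 dart-shaped stimulus elements covering the
  central 20° are modulated independently, and each element's local
  response is recovered from a single recorded channel.
* **Structure.** Spectral-domain OCT segments the ganglion cell layer
  (GCL) and reports its thickness over an 8 × 8 superpixel grid covering
  the central 30° × 25° of the posterior pole.

The package implements the full chain from raw (here: simulated) traces
to the case–control statistics: kernel extraction, the response amplitude
density (RAD) statistic, regional aggregation on both maps, normative
classification, and the group/correlation analyses. A 21-eye glaucoma
cohort table and the matching 20-eye control summaries are bundled so the
statistical layer can be exercised on real published numbers.

## Stimulus geometry and the OCT grid

The stimulated field is a disc of 20° eccentricity divided into four
annuli with boundaries at 5, 10, 15, 20° (rings R1–R4). The exact
dart-element tessellation of the commercial system is not public; any
60-element tiling honouring the annuli is admissible, and we chose 12
wedges in each of R1 and R2 and 18 in each of R3 and R4 (12+12+18+18 =
60), so angular element size shrinks with eccentricity as in a scaled
dartboard. Wedge boundaries are aligned to the horizontal and vertical
meridians (30° and 20° both divide 90°), which makes every element lie
wholly inside one quadrant and renders sector aggregation exact rather
than approximate.

Coordinates are visual-space degrees with the fovea at the origin, in a
right-eye (OD) anatomical frame: temporal = negative x, superior =
positive y. Left eyes are handled by mirroring x before quadrant lookup,
so sector labels (ST, SN, IN, IT) are anatomical rather than
screen-sided. Points exactly on the vertical midline are assigned to the
temporal side and points on the horizontal midline to the superior side;
with the chosen wedge alignment no element centroid falls on a midline,
so the tie-break never actually fires for the dartboard.

The OCT grid is 8 × 8 superpixels over 30° × 25°; the device's exact
pitch is not published, so each superpixel is 30/8 × 25/8 = 3.75° ×
3.125°, centred on the fovea. Three concentric areas are defined on the
superpixel-centre distance: Area 1 inside 6.35°, Area 2 from 6.35° to
9.37°, Area 3 from 9.37° to 12.5°. (The source material states the Area 3
inner bound once as 9.31° and once as 9.37°; we adopt 9.37°, consistent
with Area 2's outer bound.) Intervals are half-open, `[inner, outer)`, so
boundary cases are deterministic. Each quadrant of the grid holds 16
superpixels, and its sector set is defined as those 16 minus the 3
nearest the fovea — the central region is analysed separately as Area 1 —
leaving the 13 superpixels per sector that the device's regional report
uses. Which 3 superpixels the device excludes is not documented; ties in
our foveal-distance ranking are broken by (row, column) order, though
none occur on this grid.

## The synthetic recording model

No raw recordings are deposited anywhere, so the signal chain is
validated by construction against a simulator whose defaults are the
study conditions:

* **Stimulation.** Every element follows the same binary maximum-length
  sequence (m-sequence) of order 12 (4095 steps), cyclically shifted by a
  distinct lag per element (lags spaced ⌊4095/60⌋ = 68 steps apart).
  M-sequences are generated by a Fibonacci linear-feedback shift register
  with tabulated primitive polynomials for orders 2–16; in ±1 coding the
  sequence is balanced up to one step and its periodic autocorrelation at
  every nonzero lag is exactly −1.
* **Step timing.** The stimulation rate is 7 Hz and one m-sequence step
  is presented per period; at the default 1 kHz sampling this is 143
  samples per step (quantized to the sample grid). The analysed epoch
  runs from 10 ms before the step onset to the end of the step, which
  covers the 50–90 ms trough window with margin. The relation between
  the step rate and possible epoch overlap in the commercial system is
  not published; the simulator treats steps as non-overlapping.
* **Response.** An element contributes its response template whenever its
  state is white. The template is a positive Gaussian bump at the P1 time
  (default 35 ms) minus a negative Gaussian bump at the trough time
  (default 70 ms, constrained to 50–90 ms), each with an 8 ms width,
  scaled by the element's area so the *density* equals the nominal
  amplitudes (defaults 30 and 25 nV/deg²), and anchored to zero at t = 0.
* **Noise.** Additive white Gaussian noise on the recorded channel. Real
  recordings also contain line interference, drift, blinks and saccades;
  none of these are modelled by default (a spike can be injected to test
  the artifact gate). Passing tests therefore demonstrate correctness of
  the *computations*, not robustness to every ocular artifact.
* **Seeding.** All randomness flows through one explicit seed per call,
  so every simulated object is exactly reproducible.

## Kernel extraction

The preprocessing chain is a 3–100 Hz band-pass and an automatic artifact
gate. The band-pass is realized as a cascade of a 2nd-order Butterworth
high-pass at 3 Hz and a 6th-order Butterworth low-pass at 100 Hz, applied
forward–backward (zero phase, so implicit times are not shifted) with
reflection padding so end transients are settled. The orders were chosen
from the Butterworth magnitude response so that the doubled
(forward–backward) attenuation stays below 1 dB across 6–80 Hz; measured
worst case is −0.50 dB, with 50 Hz passed at gain 0.9998 and a constant
input suppressed below 10⁻⁶ of its level. The artifact criterion is a
peak-to-peak amplitude gate (default 100 µV — far above any multifocal
response); the recording is declared unusable if fewer than
`min_valid_fraction` of epochs survive. The commercial system's
proprietary rejection rule is unknown; at realistic SNR the results are
insensitive to this choice.

Per-element responses are recovered with the m-transform: the recording
is cross-correlated with each element's ±1 sequence and scaled by
2/(N+1), N = 4095. Because an element responds on its white
presentations and the m-sequence cross-moments satisfy
Σₜ sⱼ(t) = +1 and Σₜ sⱼ(t)sₖ(t) = −1 for j ≠ k, the cross-terms from all
other elements cancel *exactly*: a noise-free simulation is recovered to
machine precision (measured ≲ 10⁻¹³ relative). The textbook "halved
difference of state means" estimator is also provided
(`method = "state_diff"`); it leaves a residual cross-contamination of
order 60/4095 ≈ 1.4% because one full period is unbalanced by one step,
which is why the cross-correlation form is the default. When epochs have
been rejected, the two state-group means are computed over surviving
epochs and recombined with the same (N±1)/2 weights, which reduces to the
exact form when nothing was rejected.

## The RAD statistic and regional aggregation

The mfPhNR RAD of a kernel is (baseline − trough)/area in nV/deg²: the
baseline is the mean over the 10 ms before stimulus onset (the exact
pre-stimulus window is a package choice; it is configurable), and the
trough is the minimum over the 50–90 ms window, earliest sample on ties.
RAD is positive when the trough lies below baseline; negative values can
arise in pure noise and are flagged.

Ring values are area-weighted means of member-element densities (the
ring value then equals total amplitude over total area); the combined
R3+R4 value is the unweighted mean of the R3 and R4 ring values,
following the stated averaging rule for combined regions. Sector values
average each quadrant's R2, R3 and R4 portions (area-weighted within a
portion) and then take the unweighted mean of the three portion values;
S1 equals R1. Whether the device weights element densities by area
within a region is not documented; both modes are implemented
(`weighting = "area"` default, `"unweighted"` alternative).

## Cohort statistics

* **Summaries** are means and SDs (n−1).
* **Group comparison** is the classical one-way ANOVA with groups as
  factor, df (1, n₁+n₂−2). Because control individuals are not published,
  the comparison against the bundled cohort uses the summary-statistics
  form F = (n₁n₂/(n₁+n₂))(m₁−m₂)²/s²ₚ, which is algebraically identical
  to the raw-data F (an identity the tests verify on random instances).
  Recomputing from summaries printed to 3 decimals perturbs F by ~0.01.
* **Normative limits.** The classification limit is the control-derived
  one-sided lower 95% bound. Computed mode uses mean − t₀.₉₇₅,ₙ₋₁·SD/√n;
  this reproduces most of the published limits to ~0.1 but not all (the
  published R1 and R2 RAD limits follow no rule we could recover), so the
  default for the bundled cohort is supplied mode, which uses the
  published limit row verbatim. A value is abnormal iff strictly below
  the limit.
* **Structure-function regression** is OLS with RAD as dependent and GCL
  thickness as independent variable — the direction is fixed by the fact
  that the published estimates equal r·SD(RAD)/SD(GCL) for every region —
  with t-based 95% CIs and R² equal to the squared Pearson correlation.
* **Eccentricity trends** code the ordered regions 0, 1, 2 (slopes are
  invariant to a coding shift; intercepts refer to the first level) and
  fit per-group OLS plus a pooled model with a group × index interaction.
  For balanced complete data the individual-level and mean-level fits
  coincide exactly. The patient thickness trend uses the 21 × 3
  individual values; the control trend uses the three published area
  means, since control individuals are unavailable.
* Significance is declared at p < 0.01, mirroring the study's threshold;
  no multiplicity correction is applied beyond it.

The full pipeline (`run_full_analysis()`) also emits a reconciliation
table comparing every recomputed quantity with its published counterpart
at printed precision. Three quantities do not reconcile, and should not:
the published ST-sector thickness abnormal count (19) is inconsistent
with the published individual values against the published limit (18
recomputable), and two published percentages are off by one rounding
unit. The published mfPhNR ring-trend coefficients are likewise not
reproducible from the printed ring means under any linear coding we
tried; the package computes and reports its own trend fit but treats
those printed coefficients as not independently verifiable.

## Simulated cohorts

`simulate_cohort()` draws, per region pair and group, (RAD, thickness)
from a bivariate normal with the bundled group moments and a prescribed
correlation — by default √R² of the published structure-function
regressions, applied to both groups because control correlations were
not published. Regions are drawn independently of one another; the
dependence of interest, and the one the statistics estimate, is between
the two measures of the same region. At n = 2000 the simulator recovers
R² = 0.80 within sampling error (±0.03); at the study's own n = 21 the
across-seed SD of
R² is ≈ 0.08 (200 replicates), a useful reminder of how dispersed a
determination coefficient is at that sample size.

`simulate_gcl_grid()` constructs superpixel thicknesses whose regional
means hit given area and/or sector targets exactly: the deterministic
part is the minimum-norm deviation from a uniform baseline subject to
the regional-mean constraints (a 64-unknown least-squares system with at
most 7 constraints), after which independent Gaussian noise is added, so
targets hold in expectation under noise.

## Problem sizes and numerical choices

The test suite runs the full 60-element, 4095-step, 1 kHz noise-free
chain once (≈ 600k samples) and keeps every brute-force oracle on
order-4/5 sequences with 2–3 elements; the correlation-recovery checks
use one n = 2000 draw and 200 replicates at n = 21. The whole suite
completes in under a minute on one core. Exactness claims (kernel
recovery, grid targets, round-trips) are asserted at 10⁻⁶–10⁻¹² relative;
statistical claims are asserted at tolerances derived from the printed
precision of the reference values (0.01–0.02 for F, slopes and R²) or
from sampling error (±0.03 for the n = 2000 R²).

Degenerate inputs are defined, not accidental: zero pooled variance with
equal means gives F = 0 and with unequal means an explicit infinite F
with a warning; a perfect regression fit returns R² = 1 with a zero-width
CI; a value exactly at a normative limit is normal; ties in the trough
search take the earliest sample; the all-zero LFSR state, the foveal
origin point, empty rings/portions, and missing superpixel thicknesses
raise typed errors naming the offender.

## Known limitations

* The dart tessellation, OCT grid pitch and sector superpixel identities
  are reconstructions of undocumented device internals; all regional
  rules are exact with respect to *this* geometry.
* The waveform model is a two-bump caricature adequate for validating
  extraction and measurement, not a biophysical retina model; artifact
  modelling is limited to injectable spikes.
* The recording-level results of the bundled study cannot be reproduced
  (no deposited traces); the signal chain is verified by construction
  against the simulator instead.
* Control-side analyses that require individual control values (raw
  ANOVA, control trend on individuals, computed limits reproducing the
  published ones exactly) necessarily run on summaries.
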