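# mfphnr

Macular structure–function analysis for glaucoma with the **multifocal
photopic negative response (mfPhNR)** and OCT **ganglion cell layer (GCL)**
thickness.

Open-angle glaucoma destroys retinal ganglion cells (RGCs), and about half
of them live in the central macula. This package is for visual
electrophysiologists and glaucoma researchers who want to quantify *where*
in the macula RGC dysfunction appears and how tightly it tracks structural
thinning. It implements, end to end and fully testable without any
recordings:

- **m-sequence multifocal ERG signal chain** — maximal-length sequence
  generation (LFSR, primitive polynomials for orders 2–16), simulation of
  raw multi-element trace sets, zero-phase 3–100 Hz band-pass filtering,
  peak-to-peak artifact rejection, and first-order kernel extraction by the
  m-transform. For an element *j* with state sequence *sⱼ(t) ∈ {±1}* over
  *N = 2ᵏ−1* steps, the kernel is

  ```
  Kⱼ = 2/(N+1) · Σₜ sⱼ(t) · x(epoch t)
  ```

  under which the cross-terms from all other elements cancel exactly.

- **The RAD statistic** — the mfPhNR response amplitude density,
  `RAD = (baseline − trough)/area` in nV/deg², with the trough searched in
  the 50–90 ms implicit-time window, aggregated over a 60-element dartboard
  into concentric rings (R1, R2, R3+R4) and quadrant sectors (S1, ST, SN,
  IN, IT).

- **OCT posterior-pole mapping** — an 8×8 superpixel thickness grid mapped
  into three concentric areas (6.35° / 9.37° / 12.5°) and four 13-superpixel
  quadrant sectors, plus a synthetic grid generator that hits regional
  targets exactly.

- **Cohort statistics** — group summaries, one-way ANOVA (raw and
  summary-statistics forms, `F = (n₁n₂/(n₁+n₂))(m₁−m₂)²/s²ₚ`), normative
  one-sided lower limits with strict abnormality classification,
  structure–function OLS regressions (RAD on GCL-T) with 95% CIs and R²,
  Pearson correlations, and eccentricity trend fits with a group
  interaction.

- **A bundled cohort** — a published 21-eye open-angle glaucoma table
  (per-region RAD and GCL thickness), 20-eye control summaries, normative
  limits, and the published comparison results, wired into a
  reconciliation report.

All user-facing functions take and return tibbles, so the pieces compose
with the pipe; fitted objects support `tidy()`/`glance()` and results plot
via `autoplot()` / `plot_*()`.

## Worked example

```r
library(mfphnr)

cohort <- load_cohort(mfphnr_example("oag_cohort.csv"))
report <- run_full_analysis(cohort)
report
```

```
Macular structure-function analysis report
  cohort: 21 patient eyes; 0 control eyes in table
  normative limits: supplied

Group comparison (per region):
   region measure    control_mean patient_mean     f        p n_abnormal
 1 Area1  GCL_T             45.2         26.8  128.  6.75e-14         21
 3 Area3  GCL_T             24.0         20.2   53.2 8.45e- 9         20
 4 R1     mfPhNR_RAD        30.0         15.9   84.5 2.63e-11         21
...

Structure-function regressions (patients):
  rad_region gcl_region estimate ci_low ci_high    r2            p
1 R1         Area1          0.75   0.58    0.93  0.81 0.0000000304
4 ST         ST             0.1    0.06    0.14  0.54 0.000158
...

Eccentricity trends:
  GCL_T
  group    slope intercept     n
1 control -10.6       44.7     3
2 patient  -3.32      27.0    63

Reconciliation vs published values: 53 of 56 quantities match at printed precision
```

Reading this: every region shows a significant (p < 0.01) patient deficit —
e.g. central-ring RAD drops from 30.0 to 15.9 nV/deg² (F = 84.5) and
central-area GCL from 45.2 to 26.8 µm. Functional loss tracks structure:
RAD rises 0.75 nV/deg² per µm of GCL in the central region (R² = 0.81).
Thickness falls 3.32 µm per area step in patients versus 10.60 in controls
— the central macula has the most to lose. The three unreconciled
quantities are internal inconsistencies of the published table itself (an
abnormal count that does not match its own limit, and two rounding slips);
the reconciliation surfaces them rather than hiding them.

The simulation side works the same way:

```r
els <- build_dartboard()                       # 60 elements, rings + sectors
ts  <- simulate_trace_set(els, generate_mseq(12),
                          waveform_params(trough_amp = 25),
                          noise_sd = 50, seed = 1)
ks  <- ts |> bandpass() |> reject_artifacts() |> first_order_kernel()
rad_by_element(ks) |> aggregate_rings(els)
#>   eye_id region_type region measure    value units
#> 1 sim    ring        R1     mfPhNR_RAD  23.6 nV_per_deg2
#> 2 sim    ring        R2     mfPhNR_RAD  23.5 nV_per_deg2
#> 3 sim    ring        R3+R4  mfPhNR_RAD  23.5 nV_per_deg2
```

(The nominal 25 nV/deg² trough reads ≈ 23.5 after the 3 Hz high-pass
shaves the kernel's slow content; skip `bandpass()` on noise-free input
and the recovery is exact.)

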