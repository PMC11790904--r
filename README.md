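# neuromech

Quantitative analysis of the mechanochemical cycle that drives saltatory
neuronal migration. Migrating neurons (e.g. olfactory interneurons moving
through 3D matrix) alternate two strokes: extension of the leading process,
and translocation of the soma toward it. `neuromech` implements, as one
tested R package, the measurement pipelines that connect the two strokes:

- **SICM stiffness mapping** — hopping-mode scanning ion conductance
  microscopy approach curves; per-pixel Young's modulus from the
  normalized-current window slope via

  `E = p0 * A * (s_inf / s - 1)^-1`

  with applied pressure `p0 = 10` kPa, pipette geometry factor `A = 0.4`,
  `s` the slope of the normalized approach curve between 98.5% and 99% of
  the reference current on the cell, and `s_inf` the same slope on the
  rigid substrate. Includes a forward simulator of full scans over phantom
  neurons with known stiffness fields.
- **FLIM lifetime fitting** — bi-exponential photon-decay fits
  (`a1*exp(-t/tau1) + a2*exp(-t/tau2)`, no cutoff); the long lifetime is
  the membrane-tension readout of lipid tension probes.
- **Calcium transient detection** — ratiometric 525/650 nm traces,
  whole-trace baseline `F0`, and the rule that a transient is an excursion
  with `(F - F0)/F0 > 0.40`; frequencies overall and by
  leading-process-length-deviation bin (edges at -4, 0, +4 um around the
  mean).
- **Migration metrics** — leading-process length, the somal-translocation
  phase ("moved any distance" between 2-min frames, operationalized as
  > 0.2 um), migration speed (path/total time), translocation speed
  (phase distance/phase time), and stretch-orientation classification
  (0-30 degrees parallel, 60-90 degrees perpendicular).
- **Rear myosin quantification** — posterior-half-of-soma masks and the
  pMLC/MLC intensity ratio.
- **Statistics** — the normality-gated decision tree
  (D'Agostino-Pearson for n > 7, Shapiro-Wilk for 3-7; F-test-gated
  Student/Welch; Mann-Whitney; paired t / Wilcoxon; ANOVA+Tukey vs
  Kruskal-Wallis+Dunn) and Spearman correlation with exact permutation
  p values for n <= 7.
- **Synthetic cohorts** — a seeded generator of whole cells implementing
  the feedback model: extension raises membrane tension (affine in
  length), tension gates the transient rate (logistic gate +4 um above
  the mean length), each transient charges a leaky rear-myosin
  integrator, and the myosin level sets the somal step that shortens the
  process. Wild-type, knockdown (rate factor `kappa`), and 20%-stretch
  variants.

## Worked example

```r
library(neuromech)
cfg <- default_config()
cfg$seed <- 1L
cfg$cohort$n_cells <- 20
cfg$cohort$n_stretch <- 8
rep <- run_pipeline(cfg)
print(rep)
```

```
neuromech pipeline report
  cells: 40 (20 WT / 20 KD)
  spearman_rho_tension_length        0.9759
  wt_mean_length_um                  35.74
  kd_mean_length_um                  50.03
  wt_migration_speed_um_min          1.297
  kd_migration_speed_um_min          0.7498
  wt_translocation_speed_um_min      2.764
  kd_translocation_speed_um_min      2.407
  wt_transient_freq_per_min          0.1217
  kd_transient_freq_per_min          0.08167
  top_bin_freq_per_min               0.3455
  bottom_bin_freq_per_min            0
```

Reading the report: membrane tension (lifetime proxy) correlates strongly
with process length across cells (`rho = 0.98`); knocking the
mechanosensitive channel down (`kappa = 0.2`) lengthens the process
(50.0 vs 35.7 um) while slowing both somal translocation (2.41 vs 2.76
um/min) and overall migration (0.75 vs 1.30 um/min); and the transient
frequency climbs with length deviation — 0.35/min when the process is more
than 4 um longer than its mean versus 0/min in the bottom bin:

```r
print(rep$length_bins)
#         bin  time_min n_events freq_per_min
# 1 [-Inf,-4)  94.33333        0    0.0000000
# 2    [-4,0) 181.75000       11    0.0605227
# 3     [0,4) 237.08333       32    0.1349736
# 4   [4,Inf)  86.83333       30    0.3454894
```

Single-assay entry points: `simulate_scan()`/`stiffness_map()` (SICM),
`simulate_decay()`/`biexp_fit()` (FLIM), `ratio_series()` /
`normalize_f0()` / `detect_transients()` (calcium), `migration_metrics()`
(tracks), `posterior_half_mask()`/`myosin_activity_ratio()` (myosin),
`compare_two()`/`compare_multi()`/`spearman_test()` (statistics). A thin
CLI wrapper lives at `inst/cli/neuromech.R`.

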