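---
title: "neuromech: models, methods, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{neuromech: models, methods, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuromech)
```

## The scientific problem

Neurons migrating through 3D matrix move saltatorily: the leading process
extends first, then the soma translocates toward it. The package implements
the quantitative chain that links the two strokes — process extension
raises plasma-membrane tension, tension opens a mechanosensitive channel,
the resulting Ca2+ transients activate rear myosin II, and myosin
contraction drives the somal step — as (i) analysis pipelines for the four
measurement modalities involved and (ii) a generative model that produces
ground-truth synthetic cells for end-to-end testing.

## SICM stiffness mapping

### Measurement model

In hopping-mode SICM a nanopipette approaches the surface at every grid
pixel while the ion current `I` is recorded against the vertical position
`z`. Far from the surface the current equals the reference `I_ref`
(averaged over the waiting plateau); as the probe approaches, `I` falls.
With an applied pressure `p0` the local slope of the normalized current
carries the surface stiffness:

`E = p0 * A * (s_inf / s - 1)^-1`

where `s` is the slope magnitude of `I/I_ref` vs `z` fitted between 98.5%
and 99% of the reference, `s_inf` the same slope on the rigid substrate,
and `A = 0.4` the pipette geometry factor. Defaults: `p0 = 10` kPa, set
point 0.98, window (0.985, 0.99).

### The forward generator

The true functional form of an approach curve is instrument-specific; the
generator defines the noise-free normalized curve as exactly 1 above an
interaction onset and exactly linear (slope `s` from the inverted stiffness
equation) below it. This makes the inverse analysis well-posed and the
round trip exactly testable: the linear window guarantees that a correct
window fit recovers `s` to machine precision, and the onset is placed so
that the set-point crossing sits exactly at the phantom surface height, so
topography is recovered exactly too. Both the generator and the fitter work
with slope magnitudes (sign conventions differ between instruments).

Sampling emulates the published acquisition: approach speed 20 nm/ms with a
~1 MHz digitizer gives one sample per 0.02 nm near the surface (parameter
`dz_fine_nm`), coarser sampling (5 nm) during the free fall, and a waiting
plateau of 1000 samples (1 ms at the same rate) that defines `I_ref`.
Current noise is i.i.d. Gaussian per recorded sample with sd
`noise_sd * I_ref`.

### Numerical choices

* **Window localization under noise.** With 1% current noise the noise sd
  (0.01) is twice the height of the fit window (0.005), so selecting
  samples by their raw noisy values is ill-posed — samples far outside the
  true window enter and destroy the fit. `window_slope()` therefore
  localizes the window on a boxcar-smoothed copy of the curve (width about
  one fifth of the expected in-window sample count) and then fits the
  *raw* samples within the selected range by ordinary least squares. For
  noise-free data this reduces exactly to the literal rule.
* **Error budget.** For a least-squares line over a window of height 0.005
  containing `n` samples with per-sample noise `sigma`, the relative slope
  error is `sigma * sqrt(12) / (0.005 * sqrt(n))` — independent of
  `s_inf`. At `sigma = 0.01` the ~5,000-20,000 in-window samples provided
  by the 0.02-nm sampling give median modulus errors of 8-9% on the 32x32
  protocol grid; meeting a 10% error bound is impossible at this noise
  level with substantially coarser sampling, which is why the fine default
  matters.
* **Set-point crossing** is linearly interpolated between the two
  bracketing samples (smoothed localization under noise, raw otherwise).
* **Substrate slope.** `s_inf` comes from, in order: an explicit argument,
  the median window slope over a user-supplied substrate mask, or the
  pipette parameters. Fitted slopes within 2% of `s_inf` are flagged rigid
  (the modulus diverges there); failed pixels are flagged invalid, never
  imputed.
* The recorded `z` is treated as probe position; the container stores a
  single z axis.

## FLIM lifetime fitting

Decays are modelled as ideal bi-exponentials from `t = 0` with no
instrument-response deconvolution and no cutoff — every bin enters the
unweighted least-squares fit. Initialization is a log-linear fit to the
tail (slow component) and to the early-time residual (fast component);
optimization uses `nls` (port algorithm, positivity bounds) with a
Nelder-Mead fallback. Components are sorted so `tau_long >= tau_short`;
the long lifetime is the tension readout. Fits whose lifetimes collapse
within 1% are flagged degenerate (mono-exponential data) but still
reported. Photon counts, bin widths and the per-region vs per-pixel choice
are configuration, not assertions about any particular instrument; tests
use region-pooled decays of 1e5 photons over 250 bins spanning 25 ns.

## Calcium transient detection

The ratio `R = F525/F650` cancels joint intensity changes; the baseline
`F0` is the whole-trace mean of `R` (faithful to the published rule even
though transients inflate it slightly), and a transient is a contiguous run
of frames with `(F - F0)/F0` strictly above 0.40. The threshold rule
"F/F0 > 40%" is interpreted as a 40% excursion above baseline
(`F/F0 > 1.4`); the literal reading (ratio > 0.4) would flag essentially
every frame. Runs separated by less than 10 s (two frames at the 5-s
protocol) merge into one event — a minimal anti-double-counting rule; the
source protocol states no run/merge convention. Frequencies by
length-deviation bin use half-open bins `(-Inf,-4) [-4,0) [0,4) [4,Inf)`
um around the trace-mean length; events are assigned by onset frame, time
by frame occupancy, and unvisited bins are reported missing rather than 0.

## Migration metrics

The somal-translocation phase is "moved any distance between 2-min
frames"; against tracking jitter this is a displacement threshold
`eps = 0.2` um (about one camera pixel, configurable). Migration speed is
soma path length over total observation time. For translocation speed the
protocol wording is ambiguous between dividing by total time (which would
duplicate the migration speed up to the sub-threshold remainder) and by
time in phase; the package defaults to phase time — making the two speeds
distinct quantities — and exposes `denominator = "total"` for the other
reading. With the phase-time denominator
`translocation_speed >= migration_speed` on every track where both are
defined, since non-phase intervals contribute at most `eps` each. Speeds
are reported in um/min (`um_min_to_um_h()` converts).

## Rear myosin quantification

The posterior half of the soma is the set of soma pixels whose offset from
the nucleus centroid projects negatively on the polarity axis (unit vector
toward the leading process). Myosin activity is the ratio of mean pMLC to
mean MLC intensity over the mask: mean-of-means rather than the mean of
pixelwise ratios, which is robust to near-zero pixels; the two halves can
differ in pixel count, so means rather than sums are compared. Inputs are
assumed background-corrected; nucleus segmentation is out of scope.

## The statistics tree

Two dependent groups: paired t (differences normal) or Wilcoxon
signed-rank. Two independent groups: if both pass normality
(D'Agostino-Pearson when n > 7, Shapiro-Wilk for 3-7, alpha = 0.05), an F
test gates Student's vs Welch's t; otherwise Mann-Whitney U. Three or more
groups: ANOVA + Tukey when all normal, else Kruskal-Wallis + Dunn with
Bonferroni adjustment (the post hoc adjustment is not specified upstream;
Bonferroni is the conservative convention). The normality and F-test gate
level (0.05) is likewise an assumption. Spearman's rho uses average ranks;
p values are exact by full enumeration for n <= 7, seeded Monte-Carlo
permutation for n of 8-10, and the t approximation beyond. The
D'Agostino-Pearson K^2 statistic is implemented from the standard skewness
and kurtosis transformations and validated against an independent
implementation on frozen fixtures.

## The synthetic cohort generator

No equations for the feedback loop are published; the generator is the
minimal quantitative model consistent with every qualitative arrow, with
all functional forms exposed in `cohort_params()`:

* **Length dynamics.** `L(t)` on a 5-s grid: constant extension drive
  `v_ext = 1.2` um/min (typical of leading-process growth), mean reversion
  to a per-cell baseline (`tau_L = 20` min), Gaussian innovations, and
  step resets. A 30-min burn-in is discarded so records start in the
  stationary extension/step cycle (without it, early-trace rates are
  biased by the initial condition). Per-cell baselines are
  `N(39.0, 12)` um — the printed cohort mean, with between-cell spread
  wide enough to emulate cohorts of visibly different process lengths.
* **Tension.** Affine in length, `T = T0_i + 0.02 * (L - 39)` ns on the
  lifetime scale, with a per-cell baseline spread (sd 0.05 ns) and small
  per-frame noise. Without between-cell baseline variability the
  cohort-level tension-length correlation is trivially 1.
* **Transient rate.** `lambda(L) = kappa * (0.05 + 0.5 *
  logistic((L - L_bar - 4)/2))` per minute: a low basal rate and a gate
  that engages about 4 um above the cell's mean length, matching the
  observed rate increase threshold. `kappa` in [0,1] is the knockdown
  factor.
* **Myosin and steps.** Each transient adds 1 to a leaky integrator
  (`tau_m = 6` min). The somal step triggered by a transient has size
  `11.3 um * (m / 1.6) * lognormal(cv = 0.15)` — 11.3 um is the printed
  extension/retraction amplitude, and 1.6 is the typical wild-type
  integrator level at an event, so wild-type steps average the printed
  amplitude. Because sparser transients leave the integrator lower,
  knockdown cells take smaller steps as well as fewer of them; this is the
  mechanism by which the knockdown arm shows slower translocation even
  with the phase-time denominator. The step plays out over a 2-min
  refractory window during which the soma advances and the process
  shortens by the step size.
* **Fluorescence.** Anti-correlated channels (525 up by 35%, 650 down by
  20% per unit kernel) with a 15-s decay kernel and 1% multiplicative
  noise; a transient peaks near `dF/F0 = 0.65`, comfortably above the 0.40
  threshold, so clean detection recall is high by construction.
* **Stretch.** `apply_stretch()` scales the length by 1.2 from a mid-trace
  onset for parallel orientation, re-evaluates the rate on the scaled
  length, and regenerates transients and fluorescence after onset;
  perpendicular orientation returns the record unchanged. The soma track
  and myosin series are left untouched because the stretch assay reads out
  calcium only.

### What a green test does and does not establish

The generator reproduces printed *summary* statistics (mean length,
excursion amplitude, the +4 um gate) and the *directions* of every
cohort-level effect; printed per-figure effect sizes (absolute speeds,
per-bin frequencies, lifetimes) are not machine-readable and are not
calibration targets. Green end-to-end tests therefore establish that the
analysis code recovers what the model puts in and orders cohort arms
correctly — not that the model's absolute rates match any particular
biological dataset. Real data additionally contain features the phantom
world omits: instrument response functions and dark counts (FLIM),
approach-curve nonlinearity and drift (SICM), motion artifacts and focus
drift (imaging), and segmentation error (tracks).

## External formats

Scan grids round-trip through an HDF5 container (`/z`, `/current`,
`/plateau`, `/n_samples`, `/meta`; NaN-padded rectangular layout) via
`rhdf5`. Traces, tracks, events and per-cell tables use snake_case CSV
with unit suffixes (`_um`, `_ns`, `_min`, `_s`). Image outputs (stiffness,
topography, lifetime maps) are written as plain CSV matrices rather than
32-bit TIFF: no TIFF writer is assumed in the target environment, and the
CSV matrices carry identical information. Configurations are YAML or JSON,
validated against `default_config()` with unknown keys rejected by name.

## Known limitations

* The SICM noise model is white; correlated (1/f) current noise would
  degrade the window fit faster than the sqrt(n) budget above.
* `F0` from the whole-trace mean is biased upward by the transients it
  normalizes; a percentile baseline would be more robust but less faithful
  to the published rule (the detection threshold absorbs the few-percent
  bias at realistic transient densities).
* The exact permutation Spearman test enumerates n! orderings and is
  limited to n <= 7 by design; ties are handled by average ranks in both
  the statistic and its permutation distribution.
* `simulate_cell()` advances frame by frame in R; cohorts of hundreds of
  cells simulate in seconds, but the loop is not vectorized for much
  larger studies.
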