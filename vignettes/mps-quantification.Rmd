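---
title: "Quantifying membrane periodic skeleton order from single-molecule localizations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying membrane periodic skeleton order from single-molecule localizations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpsquant)
```

## The measurement problem

Axons carry a membrane-associated periodic skeleton (MPS): rings of actin
spaced about 190 nm apart, connected by spectrin tetramers, directly under
the plasma membrane. Single-molecule localization microscopy (STORM) of a
spectrin subunit resolves this lattice as a quasi-1D comb of localizations
along the axon shaft. During axon degeneration — for example after trophic
deprivation of sensory neurons — the lattice disassembles, and the question
"how ordered is the MPS in this axon?" needs a number.

`mpsquant` computes the standard answer, the **autocorrelation amplitude**,
and everything around it: a synthetic-data generator with tunable lattice
disorder, localization I/O and axis projection, an occupancy-ratio measure
for wide-field image pairs, and per-condition group statistics.

## The statistic

For one axon the pipeline is:

1. **Project** each localization onto the axon axis. For straight
   stretches the first principal axis of the (x, y) cloud is used; a
   polyline backbone (arc-length projection) is available for curved
   axons. Localizations farther than a 500 nm corridor half-width from
   the axis are dropped and counted; the corridor default covers the
   700 nm diameter ceiling used when selecting unbundled distal axons. z
   is ignored — the analysis is one-dimensional.
2. **Bin** the axial positions into a histogram with 10 nm bins,
   half-open `[k·10, (k+1)·10)` from the projection origin.
3. **Segment** the profile into adjacent, non-overlapping 1900 nm
   windows (ten lattice periods). A trailing remainder is discarded;
   segments holding fewer than `min_locs_per_segment = 50` localizations
   are dropped and counted, since near-empty segments contain shot noise
   but no usable lattice signal.
4. **Autocorrelate** each segment: with `d = counts − mean(counts)`,
   `acf[k] = Σ_i d_i d_{i+k} / Σ_i d_i²`, the numerator over the
   overlapping range and the denominator from the full segment. This
   Pearson-style normalization fixes `acf[0] = 1` and makes the curve
   invariant to labeling density, so axons with different staining
   efficiency are comparable. The normalization convention (mean
   subtraction, biased denominator) is a package choice; it keeps
   amplitudes dimensionless and of order 0–1.
5. **Average** the per-segment curves lag-wise, and read off the
   **amplitude**: the curve maximum within the 150–230 nm window (around
   the 190 nm period) minus the minimum within the 50–150 nm window
   (around the 95 nm half-period). Extrema are window-global; exact ties
   resolve toward the window center, then the smaller lag. Negative
   amplitudes are reported as-is.

On the 10 nm lag grid the 95 nm half-period falls between two lags. The
amplitude always uses the on-grid minimum; a separate reporting helper,
`lag_min_midpoint()`, exploits the symmetry of a periodic curve about its
half-period and reports the midpoint of the adjacent lag pair with the
smallest summed value — 95 nm for a clean lattice.

```{r one-axon}
params <- lattice_params(periodic_fraction = 1, jitter_nm = 5,
                         loc_precision_xy_nm = 10, axon_length_um = 38)
axon <- simulate_axon(params, seed = 1)
res <- quantify_axon(axon)
res
lag_min_midpoint(result_curve(res))
```

## What the generator emulates

No public repository of raw MPS localization tables exists, so every
claim the package makes is exercised against simulated axons whose
ground truth is known. `simulate_axon()` draws
`N ~ Poisson(density · length)` localizations for an axon modeled as a
ring comb plus disorder:

* **`period_nm = 190`** — the MPS lattice constant.
* **`periodic_fraction` (f)** — fraction of localizations bound to the
  comb; the remainder is uniform along the axon. `f = 0` is complete
  spatial randomness; declining f is how disassembly time courses are
  emulated.
* **`jitter_nm`** — Gaussian displacement of each *ring's* phase, drawn
  once per ring and shared by its localizations: lattice disorder.
* **`ring_width_nm = 35`** — Gaussian axial spread of each *label*
  around its ring center. Immunolabeled spectrin bands are not planes:
  the epitope position along the tetramer plus two antibodies of
  ~10–15 nm each spread labels over tens of nanometers, which is why
  measured 1D profiles look sinusoidal rather than comb-like. Without
  this term the autocorrelation of a low-jitter lattice is flat between
  its 190 nm peaks and has no defined half-period minimum; with it, the
  fundamental dominates and the 95 nm minimum exists, as in measured
  curves. The 35 nm default corresponds to ~80 nm FWHM bands.
* **`loc_precision_xy_nm = 10`, `loc_precision_z_nm = 20`** — fitted
  localization error, applied per coordinate.
* **`density_per_um = 500`** — localizations per micron; with 10 nm bins
  this gives ~5 counts per bin, a realistic STORM labeling regime. The
  density and precision defaults are placeholders chosen at typical
  reported values, exposed in the configuration.
* **Geometry** — transverse and z coordinates are uniform across the
  diameter (default 400 nm, constrained to ≤ 700 nm, the selection
  ceiling for unbundled axons). Ring occupancy around the circumference
  is collapsed since the statistic is 1D.

Deliberate simplifications: per-ring labeling is independent (no epitope
clustering), there is no frame-level blinking or drift model, and no
astigmatic z PSF. Passing tests therefore demonstrate correctness of the
*statistic* under a faithful point-process model, not robustness to every
artifact of real acquisitions.

Cohorts are reproducible: per-axon seeds derive from one top-level seed by
a counter-based scheme (`derive_seeds()`), so simulation order never
matters. `td_timecourse_preset()` encodes a four-condition deprivation
time course with f declining 1.0 → 0.75 → 0.45 → 0.2 at 20 axons per
condition, the cohort scale of typical per-condition axon counts.

## Occupancy ratio

For wide-field spectrin/tubulin image pairs the package measures how much
of the axon shaft still carries spectrin signal. Both channels are
binarized (Otsu by default; fixed and percentile thresholds available and
recorded in the result). The tubulin mask is thinned to a 1-pixel
skeleton with a topology-preserving Zhang–Suen pass and dilated by 2 px
into thin "strokes", so the measure reads coverage of the axon midline
corridor rather than of the diffraction-broadened silhouette. The
spectrin mask is registered to the tubulin channel — translation by
exhaustive integer search by default, since the purpose is drift
correction; a full affine least-squares refinement (Gauss–Newton on the
sum of squared differences under bilinear interpolation) is opt-in — and
the ratio is covered stroke pixels over all stroke pixels. Spectrin
signal outside the strokes never contributes. Sub-pixel refinement is
most meaningful on intensity images; binarized masks quantize sub-pixel
shifts.

`simulate_widefield_pair()` builds matching synthetic pairs: a ribbon
axon, Gaussian PSF of σ = 250 nm, 160 nm pixels (typical microscope
scale), Poisson shot noise, and a ground-truth covered fraction realized
over 1900 nm blocks and recorded in the metadata.

## Group statistics

Per condition the package reports mean ± SEM (n−1 sample standard
deviation over √n) and n, and compares conditions with the two-sided
two-sample Kolmogorov–Smirnov test: D is computed exactly over the pooled
order statistics (ties handled by evaluating both one-sided suprema at
every pooled point), and the p-value uses the asymptotic Kolmogorov
distribution at `sqrt(nm/(n+m))·D`. The asymptotic rather than exact
small-sample distribution is appropriate at the cohort sizes involved
(~20 axons and up per condition). Raw p-values are reported per contrast
without multiplicity correction, with the usual star annotation
(`*` ≤ 0.05, `**` ≤ 0.01, `***` ≤ 0.001).

```{r groups}
specs <- td_timecourse_preset(n_axons = 8, seed = 7,
                              params = lattice_params(axon_length_um = 7.6))
amps <- lapply(specs, function(sp)
  vapply(simulate_cohort(sp)$tables,
         function(tab) quantify_axon(tab)$amplitude, numeric(1)))
names(amps) <- vapply(specs, function(sp) sp$label, character(1))
summarize_groups(amps, contrasts = list(c("NGF", "TD_12h")))
```

## Numerical choices and degenerate inputs

* Lags run 0–600 nm in bin-width steps; windows must lie inside the lag
  range, checked at configuration time, as is the requirement that the
  segment length be an integer multiple of the bin width.
* The principal-axis sign is fixed (positive correlation with +x, ties
  toward +y) so projections are deterministic; the projected origin is
  the minimum retained position.
* A flat segment (zero count variance) cannot be normalized and is
  dropped with the sparse segments; an axon with no usable segment is
  flagged `"unquantifiable"` rather than scored, and the pipeline counts
  such axons per condition instead of letting them enter summaries.
* Writing localization tables uses 17 significant digits, so a
  write/read round trip reproduces doubles bit-exactly and repeated
  writes are byte-identical.
* The per-segment-amplitude variant (average the per-segment amplitudes
  instead of taking the amplitude of the averaged curve) is exposed as
  `per_segment_amplitude = TRUE` but is not the default: the averaged
  curve reading follows the standard definition of the statistic.

## Known limitations

* **The amplitude has a positive floor under randomness.** Because the
  statistic takes a window-global maximum minus a window-global minimum
  of a noisy curve, its expectation under complete spatial randomness is
  a small positive number (an extreme-value range), not zero — about
  0.07 for 19 µm axons at 500 localizations/µm, shrinking with the
  number of averaged segments. Fully disordered conditions should be
  compared against this floor, not against zero. The distribution-level
  comparisons (KS) are unaffected: under identical conditions the test
  rejects at its nominal rate.
* Whether localizations should be filtered by z before the 1D analysis
  is left to the caller; the projection ignores z.
* Curved axons are handled by the polyline axis, but the package does
  not straighten axons automatically.
* The KS p-value is asymptotic; for groups of fewer than ~10 axons an
  exact test would be preferable.

## Problem sizes used in the test suite

The suite validates the estimator against an independent double-loop
oracle (100 random 190-bin segments, agreement to 1e-10), recovers the
190 nm period and 95 nm half-period on clean 38 µm axons, checks
monotonicity of the mean amplitude in jitter and periodic fraction with
50 paired-seed axons per grid point, measures the KS type-I rate over
500 replicate pairs of 20-axon cohorts (3.8 µm axons, two segments
each), and recovers wide-field coverage 0.6 within ±0.1 over 10 seeded
pairs. These sizes were chosen so the whole suite exercises every claim
at cohort scales comparable to real experiments while remaining quick to
run on a laptop.
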