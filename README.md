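# mpsquant

Quantification of axonal **membrane periodic skeleton (MPS)** order from
single-molecule localization microscopy data.

The MPS is a quasi-1D lattice under the axonal membrane: actin rings
spaced ~190 nm apart, linked by spectrin tetramers. STORM imaging of
spectrin renders it as a periodic comb of localizations along the axon,
and its disassembly (e.g. during trophic-deprivation-induced
degeneration) shows up as a loss of that periodicity. `mpsquant`
implements the field's standard periodicity score and the surrounding
analysis:

* **Autocorrelation amplitude** — the 1D axial localization profile is
  binned at 10 nm, cut into adjacent non-overlapping 1900 nm segments,
  each segment's normalized spatial autocorrelation
  `acf[k] = Σ_i d_i d_{i+k} / Σ_i d_i²` (with `d` the mean-subtracted
  counts) is computed and averaged, and the amplitude is
  `acf(lag_max) − acf(lag_min)` with the maximum searched in the
  150–230 nm window (around the 190 nm period) and the minimum in the
  50–150 nm window (around the 95 nm half-period).
* **Occupancy ratio** — for two-channel wide-field images: binarize,
  skeletonize the tubulin channel into thin axon "strokes"
  (topology-preserving thinning + dilation), register the spectrin
  channel (translation or affine), and report the fraction of stroke
  pixels covered by spectrin signal.
* **Group statistics** — per-condition mean ± SEM and n, pairwise
  two-sided Kolmogorov–Smirnov comparisons with star annotations.
* **Synthetic data** — a generator of localization tables (ring comb +
  phase jitter + label spread + uniform background, Poisson counts,
  Gaussian localization error) and matched wide-field image pairs, with
  a preset emulating a four-condition deprivation time course. All
  package claims are tested against it.
* **Pipeline** — `run_pipeline()` (and a thin CLI) drives
  simulate → quantify → compare reproducibly from one YAML config and
  one seed.

## Worked example

```r
library(mpsquant)

# a clean synthetic axon: intact lattice, 38 um, 500 localizations/um
params <- lattice_params(periodic_fraction = 1, jitter_nm = 5,
                         loc_precision_xy_nm = 10, axon_length_um = 38)
axon <- simulate_axon(params, seed = 1)
res  <- quantify_axon(axon)
res
#> acf_result [axon]: amplitude 1.266 (max at 190 nm, min at 90 nm)
#>   18913 localizations, 19 segments used, 0 dropped
lag_min_midpoint(result_curve(res))
#> [1] 95
```

The averaged autocorrelation peaks at 190 nm (the lattice period); the
minimum sits at the half-period — on the 10 nm lag grid it falls between
90 and 100 nm, and the bracketing-lag midpoint reports 95 nm. The
amplitude (curve maximum minus minimum) is the axon's periodicity score;
disordered axons score near the small positive noise floor instead.

A full time-course comparison from the shipped demo configuration:

```r
cfg <- system.file("extdata/td_demo.yaml", package = "mpsquant")
run_pipeline(cfg, out_dir = "td_run")
read.csv("td_run/summary.csv")
#>    label  n      mean       sem
#> 1    NGF 20 1.1784921 0.0066504
#> 2  TD_3h 20 0.9712445 0.0076998
#> 3  TD_6h 20 0.5457416 0.0116155
#> 4 TD_12h 20 0.1759673 0.0055361
```

Mean amplitude declines strictly as the generator's periodic fraction
falls across conditions; `td_run/comparisons.csv` holds the pairwise KS
results (all contrasts `***` here). The CLI equivalent:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts/mps.R", package="mpsquant"))') \
    run --config inst/extdata/td_demo.yaml --out td_run
```

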