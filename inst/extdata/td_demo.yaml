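# Demo run configuration: four-condition trophic-deprivation time course.
# Periodic fraction declines from the intact lattice (NGF) to a mostly
# disordered one (12 h of deprivation); 20 axons per condition.
seed: 2026
out_dir: mps_td_demo
conditions:
  - label: NGF
    n_axons: 20
    params:
      periodic_fraction: 1.0
  - label: TD_3h
    n_axons: 20
    params:
      periodic_fraction: 0.75
  - label: TD_6h
    n_axons: 20
    params:
      periodic_fraction: 0.45
  - label: TD_12h
    n_axons: 20
    params:
      periodic_fraction: 0.2
analysis:
  bin_nm: 10
  segment_nm: 1900
  min_locs_per_segment: 50
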