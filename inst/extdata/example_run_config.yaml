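# Example run configuration for read_run_config(). Paths are relative to
# where the pipeline is run; every section is optional and falls back to
# the package defaults.
paths:
  counts: results/sim/counts_shoot.tsv
  sample_sheet: results/sim/samples_shoot.tsv
  annotation: results/sim/annotation.tsv
  output_dir: results/run
de:
  sdeg_alpha: 0.01
  high_lfc_threshold: 2
  min_detected_reps: 3
classifier:
  tolerance: 0.5
  interval_closed: true
universes:
  - mode: all_hs_sdegs
  - mode: high_hs_sdegs
  - mode: unique_hs
enrichment:
  min_bin_size: 5
  level: 1
seed: 1
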