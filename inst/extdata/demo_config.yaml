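# Bundled demonstration study: a 2-Mb genome, three mutant lineages with one
# causative lesion each (an intergenic SNP, a splice-donor SNP, a stop-loss
# SNP), 40 background mutations per lineage segregating 1:1, and four
# 40-isolate pools mirroring the published crossing scheme.
mode: simulate
seed: 42
simulate:
  genome_length: 2000000
  n_contigs: 1
  gc: 0.5
  n_background: 40
  n_isolates: 40
  coverage: 50
  read_len: 76
  insert_mean: 2000
  insert_sd: 200
  error_rate: 0.005
  n_rate: 0.001
screen:
  coverage_fraction: 0.4
  # relaxation knobs for error-prone reads: full penetrance up to sequencing
  # error, absence up to two stray error reads (see the methods vignette)
  penetrance_min: 0.9
  absence_max_alt: 2
  min_absent_depth: 1
  homopolymer_min_run: 3
structural:
  min_len: 500
  other_min_depth: 5
  gap_join: 50
  window: 50
  z_threshold: 6
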