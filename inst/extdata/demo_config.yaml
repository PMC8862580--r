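# Demo configuration for run_pipeline(); any omitted key takes the default
# from default_pipeline_config(), and any sv_config() threshold may be set
# here too (e.g. anchor_min_len, merge_dist).
seed: 1
n_chrom: 2
chrom_length: 1000000
n_genes: 150
te_families: 3
te_density: 0.08
edits:
  insertion: 12
  deletion: 12
  repeat_expansion: 10
  repeat_contraction: 10
  tandem_expansion: 10
  tandem_contraction: 10
  te_insertion: 6
  inversion: 1
translocate: true
bin_size: 100000
hic_delta: 0.4
switch_frac: 0.45
n_samples: 10
support_rate: 5
fp_count: 20
sr_jitter: 50
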