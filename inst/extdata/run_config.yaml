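# Example pipeline configuration (paths relative to the working directory).
references: inst/extdata/synthetic_amplicons.fa
amplicon_config: inst/extdata/amplicon_config.yaml
sample_sheet: inst/extdata/sample_sheet.tsv
fastq:
  - r1: sim/wt_R1.fastq.gz
    r2: sim/wt_R2.fastq.gz
layout:
  umi_len: 15
  delimiter: CTAG
  index_len: 6
  max_index_mismatch: 1
  max_delim_mismatch: 1
  index_source: header
  min_mean_q: 20
window: 80
max_mismatch_rate: 0.05
min_anchor: 10
max_end_trim: 0
tolerance: 0
dedup_mode: exact
out_dir: tailrace_out
seed: 1
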