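# demo pipeline configuration: four multiplexed samples, two conditions with
# two replicates each, default analysis parameters
gene_model: model.yaml
fastq: demo.fastq   # produce with: racetss simulate --model model.yaml --sim sim.yaml --fastq demo.fastq
samples:
  - {id: s1, condition: A, replicate: 1}
  - {id: s2, condition: A, replicate: 2}
  - {id: s3, condition: B, replicate: 1}
  - {id: s4, condition: B, replicate: 2}
params:
  min_suffix: 8
  cutoff_pct: 0.1
  cutoff_mode: per_sample
  max_gap: 1
  depth_factor: 50
  alpha: 0.05
  k_discriminatory: 30
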