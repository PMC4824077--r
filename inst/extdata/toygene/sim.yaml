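# demo simulator configuration for the synthetic gene: three loci (two
# spliced through donors F and B, one unspliced) with a realistic 5'-RACE
# regime: 90% capped input, 40% label retention after shearing to
# 200-350 nt, indel-dominated errors
tss:
  "-800": 0.20
  "-799": 0.11
  "-798": 0.055
  "-660": 0.165
  "-659": 0.11
  "-658": 0.055
  "-657": 0.02
  "-300": 0.165
  "-299": 0.11
  "-250": 0.01
splice:
  "-800": [F, ex2]
  "-799": [F, ex2]
  "-798": [F, ex2]
  "-660": [B, ex2]
  "-659": [B, ex2]
  "-658": [B, ex2]
  "-657": [B, ex2]
depth: 20000
seed: 11
capped_fraction: 0.9
degraded_fraction: 0.1
label_retention: 0.4
shear_min: 200
shear_max: 350
insertion_rate: 0.02
deletion_rate: 0.004
substitution_rate: 0
homopolymer_indel_multiplier: 4
samples: [s1, s2, s3, s4]
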