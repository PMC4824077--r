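# synthetic demo gene: a 1.2 kb plus-strand region with two annotated
# first-exon splice donors (F, B), one downstream acceptor, an ATG anchor
# and four MID barcodes. The reference (ref.fa) is synthetic random sequence.
name: synthetic_demo
fasta: ref.fa
chrom: chrT
region_start: 1001
region_end: 2200
strand: "+"
anchor:
  kind: ATG
  pos: 1900
donors:
  F: 1350
  B: 1520
acceptors:
  ex2: 1850
oligo: CGACUGGAGCACGAGGACACUGACAUGGACUGAAGGAGUAGAAA
mids:
  s1: ACGAGTGCGT
  s2: ACGCTCGACA
  s3: AGACGCACTC
  s4: AGCACTGTAG
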