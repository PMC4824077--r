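# Annotation template for the human glucocorticoid receptor (NR3C1/GR)
# 5' region on hg19, as published: region chr5:142,657,496-142,850,254,
# minus strand, TSSs annotated against the ATG(+1) translation initiation
# codon in exon 2. To use it, point `fasta:` at an hg19 chr5 slice covering
# the region (not distributed with this package) and fill in the genomic
# donor/acceptor coordinates for your exon set.
#
# Two cautions inherited from the published annotation:
#   * exon 1F is described as 62 nt long but its stated bounds (-3208 to
#     -3146) span 63 positions; both readings are kept below under distinct
#     names (F_62nt drops the downstream bound by one).
#   * the donor attributions of exons 1F and 1B appear swapped in part of
#     the source text (1F "sharing the -3536 splice donor site" vs 1B
#     "(-3640 to -3536) ... common splice donor site at -3146"); both
#     readings are retained under distinct names rather than guessing.
# Coordinates below are gene-relative (ATG = +1); convert to genomic with
# to_genomic() once the anchor position is set, or enter genomic values
# directly.
name: NR3C1
fasta: FILL_ME_hg19_chr5_slice.fa
chrom: chr5
region_start: 142657496
region_end: 142850254
strand: "-"
anchor:
  kind: ATG
  pos: FILL_ME  # genomic position of the A of the exon-2 ATG
# donors (gene-relative, reading 1: 1F ends at -3146, 1B at -3536):
#   F_63nt: -3146   (exon 1F -3208..-3146, 63 positions)
#   F_62nt: -3147   (62 nt reading)
#   B: -3536        (exon 1B -3640..-3536)
# donors (reading 2, as in the locus description text):
#   F_alt: -3536
#   B_alt: -3146
donors: {}
acceptors: {}
oligo: CGACUGGAGCACGAGGACACUGACAUGGACUGAAGGAGUAGAAA
mids: {}
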