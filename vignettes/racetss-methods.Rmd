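---
title: "Methods: TSS microvariability from 5'-RACE sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TSS microvariability from 5'-RACE sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement problem

RNA-ligase-mediated 5′-RACE coupled to deep amplicon sequencing measures
where transcription of one gene actually starts, at single-nucleotide
resolution and at depths that resolve start sites used by a fraction of a
percent of transcripts. The chemistry is what makes the readout
trustworthy: phosphatase (CIP) treatment removes the ligatable
5′-monophosphate from degraded RNA, pyrophosphatase (TAP) then converts
only the m⁷G cap of intact mRNA into a ligatable end, and a known RNA
oligo is ligated in its place. A sequencing read that begins with the 3′
end of that oligo therefore marks a genuine transcript 5′ end, and the
first template base after the trimmed oligo is the transcription start
site (TSS).

`racetss` implements the full computational path from multiplexed FASTQ to
TSS loci and differential TSS usage, plus a library simulator with exact
ground truth that stands in for deposited data in all tests.

# Coordinate conventions

Gene-relative coordinates use the skip-zero convention common in promoter
annotation: the anchor base (the A of the translation-initiation ATG, or
the first mRNA nucleotide for mono-exonic genes annotated against a
reference mRNA) is +1, the base immediately 5′ of it is −1, and no
position 0 exists. Minus-strand genes are reverse-complemented once at
model load; everything downstream is gene-forward, which removes strand
branching from every stage. `to_relative()`/`to_genomic()` are exact
inverses over the whole region.

The gene model is a small YAML schema rather than GFF3: donor/acceptor-only
splice annotation plus MID barcodes and the cap-oligo sequence has no
faithful GFF3 encoding. A GFF3 export of the region and splice sites is
provided for genome-browser interoperability; deliberately, no fixed exon
intervals are exported, because the 5′ exon boundary is exactly what TSS
microvariability makes variable. The bundled `NR3C1_hg19_template.yaml`
records the published glucocorticoid-receptor annotation with two known
ambiguities preserved verbatim: exon 1F's stated bounds span 63 positions
although it is described as 62 nt long, and the donor attributions of
exons 1F and 1B appear swapped between two passages of the source
annotation; both readings are kept under distinct names rather than
resolved by guesswork.

# Capture: MID sorting and cap-oligo selection

A read is accepted as oligo-labelled iff a 3′-terminal suffix of the
44-nt cap-oligo, at least `min_suffix = 8` nt long, occurs in the read's
5′ region with at most `max_mismatch = 0` substitutions and at least one
template base after it. Two design points deserve explanation:

* **Strict matching by default.** A falsely accepted label fabricates a
  TSS, whereas a rejected read only costs depth; mismatch tolerance is
  exposed but off.
* **The window bounds the match's end, not its start.** The match must end
  within `search_window + oligo length` bases of the read start (default
  window 5). Bounding the start instead looks equivalent but is not:
  an indel *inside* the oligo shifts the terminal suffix rightward by up
  to (oligo length − suffix length), and under realistic indel rates a
  start-bounded window rejects a large fraction of genuinely labelled
  reads. An end-bounded window tolerates both 5′ adapter remnants and
  in-oligo indels, while still refusing oligo hits deep inside a read
  (which would mislabel re-capped or chimeric fragments). Among qualifying
  hits the longest suffix wins, then the smallest offset.

The capture funnel (total → MID-assigned → oligo-labelled →
length-filtered) is conserved exactly and reported per sample by
`qc_reads()`.

# Mapping: spliced placement and the first-matched-base rule

Reads are placed by a seed-and-extend search over the contiguous
gene-forward reference and one concatenated "layout" per annotated
(donor, acceptor) pair — only single splices at annotated sites are
considered, since microvariant transcripts use established sites, and a
novel-junction read is better surfaced as unaligned-for-review than
silently misplaced. For a read of length *m* and edit budget
*e* = ⌊`max_edit_frac` · *m*⌋ (default 0.1, chosen to tolerate observed
indel rates of a few percent with margin), *e*+1 non-overlapping *k*-mers
with *k* = ⌊*m*/(*e*+1)⌋ are looked up in per-layout indexes. By the
pigeonhole principle, any placement within the edit budget leaves at least
one chunk exact, so the seeded search is provably equivalent to exhaustive
search — the test suite verifies this against an independent full-scan
dynamic-programming oracle on a thousand randomized reads.

The TSS of a placement is the **first matched reference base** of a
canonical optimal alignment (traceback preference: diagonal, then
deletion, then insertion; smallest optimal end column). This rule exists
because plain edit distance cannot distinguish "k extraneous bases
inserted before the TSS" from "k mismatches starting k bases upstream":
both placements cost k. Defining the TSS by the first matched base
collapses these boundary shift-variants onto a single call, which makes
TSS assignment robust to leading non-reference bases. Placements that
still disagree after this normalisation (and after folding
non-junction-crossing spliced placements onto the contiguous layout) are
rejected as ambiguous rather than assigned arbitrarily — a wrong placement
fabricates a TSS, exclusion only costs depth. The known cost of the rule:
a substitution in the very first template base shifts the call one base
downstream; substitution rates in the targeted data are ≈ 0, and the
noise cut-off absorbs the residue.

`profile_errors()` reports per-nt substitution/insertion/deletion rates
over aligned bases, flags edits within ±2 nt of each TSS, and gives the
reference homopolymer run length at each TSS — the three artefact checks
that matter for semiconductor (indel-dominated) sequencing.

# Quantification

**Frequencies.** The denominator of the percent frequencies is the
per-sample count of mapped oligo-labelled reads (the count-table column
sums). Raw frequencies sum to 100 % per sample by construction.

**TMM.** Between-sample factors follow the published trimmed mean of
M-values: M and A values over positions nonzero in both sample and
reference, 30 %/5 % trims, a precision-weighted mean with inverse
delta-method binomial variances, reference chosen by the 75th-percentile
relative frequency closest to the mean, factors rescaled to geometric
mean 1. The implementation is validated against an independent reference
implementation to 1e−8. One subtlety: with precision weights the factors
are invariant to a pure depth change only to ~0.1–0.5 % (the reference
sample's variance term does not rescale); the unweighted trimmed mean is
exactly invariant. This matches the behaviour of the established
implementation and is asserted at that tolerance in the tests.

**Noise cut-off.** TSSs below a frequency cut-off are removed as noise of
the labelling/sequencing process; the boundary is inclusive (exactly
0.1 % survives, matching the "below cut-off removed" phrasing). The
default `per_sample` mode validates each (position, sample)
independently; `all_replicates` mode requires the cut-off in *every*
replicate of a condition — the stricter reading under which a TSS ranging
0.02–0.14 % across replicates is excluded even though one replicate
clears 0.1 %. Both modes are implemented because the source analyses are
consistent with either; neither is asserted as the original intent.

**Cut-off estimation.** `estimate_cutoff()` counts surviving TSSs along a
log-spaced cut-off grid and fits a continuous two-segment linear model to
(log₁₀ cut-off, survivors) by exhaustive breakpoint search; the segment
intersection is the recommended cut-off — the point where removing more
depth stops removing many positions (noise exhausted). A curve with
constant survivors is degenerate and errors out.

**Loci.** Adjacent valid TSSs chain greedily into loci with gap ≤
`max_gap`; the default is strict adjacency (`max_gap = 1`), with 5 as a
looser preset — the literature never pins the inter-locus gap
numerically, so both are exposed and the default is the conservative one.
Adjacency is evaluated on a linearised scale in which −1 and +1 are
neighbours (the relative scale has no zero). Locus ids use the nearest
annotated donor's exon name plus an ordinal (`F1`, `B4`, …), falling back
to `L1`, `L2`, … for unannotated regions.

**Depth rule.** Detecting microvariable TSSs reliably needs about 50
labelled mapped reads per nt of variable region; `depth_check()` passes
or warns with the deficit. In the pipeline the variable-region length is
the span of the valid TSS positions.

# Differential TSS usage

The test follows the empirical-noise ("NOISeq-style") idea rather than a
parametric model: the distribution of (|M|, D) across within-condition
replicate pairs defines what technical plus sampling noise can do, and a
between-condition contrast is called significant when it is jointly more
extreme than essentially all of that null.

* Zeros are replaced by a pseudo-frequency (default half the cut-off,
  0.05 %) rather than dropped, so condition-unique TSSs — a key class of
  findings — remain testable.
* `p_raw` is the plain fraction of null points with |M| and D both at
  least the observed values, with no +1 continuity correction. The
  empirical null bounds the smallest nonzero p at 1/(null size); a
  contrast beyond every null point gets p = 0. With a continuity
  correction, the BH-adjusted p of even an overwhelming effect (30 % vs
  1 %) could never reach 0.05 at realistic null sizes (hundreds of
  positions × a few replicate pairs), so the correction would destroy all
  power by construction. The cost is that p-values are resolution-limited;
  the type-I behaviour of the whole procedure is therefore verified by
  simulation (200 seeded null datasets; empirical false-positive fraction
  ≈ 2 × 10⁻⁴ at α = 0.05, comfortably below the 1.2 × α bound asserted in
  the tests) rather than assumed from theory.
* BH adjustment across positions; significance at adjusted p ≤ 0.05.
* The exact proprietary variant and version of the original tooling is
  not recoverable; this module is validated by its own calibration and
  power simulations, not by output-identity to any external package.

Discriminatory TSSs are the positions significant in ≥ 1 contrast, ranked
by across-condition variance of log₁₀(frequency + pseudo-frequency); the
top 30 (configurable) are clustered with Euclidean distance and complete
linkage over both positions and samples, the defaults of the heatmap
tooling this display imitates.

# The simulator: what it emulates, and what it does not

`simulate_transcripts()`/`simulate_library()` generate libraries with
exact per-read ground truth:

* a multinomial draw over the configured TSS distribution, with optional
  single splices at annotated sites;
* cap status: only capped transcripts are ligation-eligible; degraded
  transcripts are 5′-truncated at a point drawn uniformly over the
  transcript body (keeping ≥ 25 nt) and enter the library unlabelled, so
  the capture stage's rejection path is exercised end-to-end;
* shearing to a 200–350 nt window with a `label_retention` probability
  (default 0.4) that a fragment keeps the oligo–TSS junction — the
  literature gives this only as an average, so it is a modelling knob,
  not a fixed constant. Labelled fragments carry the full oligo;
* per-cycle Phred qualities from a linear decay profile that stays above
  Q20 through cycle 200 (defaults q_start 36, q_decay 0.08/nt, floor 12);
* errors: independent per-nt substitution/insertion/deletion, with indel
  probabilities multiplied (default ×4) inside homopolymer runs ≥ 2 nt —
  the character of semiconductor sequencing without a flow-space model;
* `clean_junction = TRUE`: indels are not injected in the last 3 oligo nt
  or the first 3 template nt of labelled reads. This emulates a measured
  property of real libraries — junction regions are observed indel-free —
  and matters because a junction indel is the one error that shifts the
  called TSS: at realistic deletion rates it would fabricate neighbour
  positions at ~0.1–0.3 % of a major TSS's frequency, a regime the
  observed data exclude. Substitutions are not shielded.

Deliberately **not** simulated: PCR amplification bias (counts are
treated as semi-quantitative by the method itself; uniform amplification
keeps ground truth exact), flow-space signal artefacts and polyclonal
beads, RT/PCR chimeras, and antisense reads. Consequently, a green test
suite shows the *pipeline* is correct under the stated error model; it
does not certify behaviour under ligation bias or amplification
artefacts, which the wet-lab protocol controls for.

Seeds are mandatory and all randomness is scoped with `withr::with_seed`;
a configuration reproduces its FASTQ byte-for-byte.

# Numerical and engineering choices

* Genomic coordinates are 1-based inclusive internally; BED/bedGraph
  exports are converted to 0-based half-open by `rtracklayer`.
* The aligner rejects reads shorter than 20 nt and placements whose edit
  count exceeds 10 % of read length; equal-cost placement ties are
  rejected as ambiguous after first-matched-base normalisation.
* TMM falls back to unit factors (with a warning path in the pipeline)
  when fewer than 10 positions are nonzero in both sample and reference.
* Breakpoint search is exhaustive over interior grid points; ties keep
  the first (smallest) candidate.
* Pipeline outputs are byte-identical across reruns for all TSV, BED,
  bedGraph and JSON analysis files; the manifest additionally records a
  wall-clock timestamp and input/output MD5 digests, so it is the one
  file excluded from byte-identity.

Problem sizes in the test suite (chosen so the whole suite runs in a few
minutes on one core): simulator round trips and recovery at 10⁵ reads on
a 1.2 kb synthetic gene with 10 TSSs in 4 loci; aligner-vs-oracle
equivalence on 1 000 randomized reads; differential calibration on 200
null datasets of 500 positions; locus invariants on 1 000 random position
sets. The acceptance script (`scripts/acceptance.R`) re-runs the study
design at 2 × 30 000 reads with the error regime set to the observed
per-nt component rates (insertions 0.007, deletions 0.004, substitutions
0, homopolymer ×4 — an effective indel rate of ≈ 2.3 %).

# Known limitations

* Only single-splice placements at annotated sites; novel junctions land
  in the unaligned bin (categorized) for manual review.
* The empirical differential test is resolution-limited by the null size
  and is conservative for condition means of many replicates (means are
  less variable than the single-replicate contrasts forming the null).
* Base qualities are carried and summarised but do not enter alignment
  scoring.
* The depth rule and the 0.1 % default cut-off are calibrated for deep
  single-gene amplicon data; genome-wide or shallow data need their own
  calibration via `estimate_cutoff()`.
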