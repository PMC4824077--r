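# toy gene models and simulator configurations used across the suite

RACE_OLIGO <- "CGACUGGAGCACGAGGACACUGACAUGGACUGAAGGAGUAGAAA"

TOY_MIDS <- c(s1 = "ACGAGTGCGT", s2 = "ACGCTCGACA",
              s3 = "AGACGCACTC", s4 = "AGCACTGTAG")

random_dna <- function(len, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), len,
                                      replace = TRUE), collapse = ""))
}

# plus-strand toy gene: region chrT:1001-(1000+len), ATG anchor near the 3'
# end, two first-exon donors (F upstream of B) and one exon-2 acceptor
toy_model <- function(len = 1200L, seed = 42L, strand = "+",
                      donor_f = 350L, donor_b = 520L, acceptor = 850L,
                      anchor = 900L, mids = TOY_MIDS,
                      reference = NULL) {
  # ref_gf is the gene-forward sequence, identical across strands so that
  # strand reflection leaves every gene-forward quantity unchanged
  ref_gf <- reference %||% random_dna(len, seed)
  # gene-forward index i maps to genomic 1000+i (+) or 1000+len+1-i (-)
  g <- function(idx) if (strand == "+") 1000L + idx else 1000L + len + 1L - idx
  ref_plus <- if (strand == "+") ref_gf else {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(ref_gf)))
  }
  gene_model(
    name = "toygene", chrom = "chrT",
    region_start = 1001L, region_end = 1000L + len,
    strand = strand, anchor_kind = "ATG", anchor_pos = g(anchor),
    donor_sites = c(F = g(donor_f), B = g(donor_b)),
    acceptor_sites = c(ex2 = g(acceptor)),
    oligo_seq = RACE_OLIGO, mids = mids,
    reference = ref_plus)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# gene-relative coordinate of a gene-forward index in a toy model
toy_rel <- function(model, idx) {
  g <- if (model$strand == "+") model$region_start + idx - 1L else
    model$region_end - idx + 1L
  to_relative(g, model)
}

# a 10-TSS distribution over the toy gene: 2 spliced loci (via F and B) and
# one unspliced cluster straddling positions upstream of the anchor
toy_tss_distribution <- function(model) {
  idx <- c(100L, 101L, 102L, 240L, 241L, 242L, 243L, 600L, 601L, 650L)
  rel <- vapply(idx, function(i) toy_rel(model, i), integer(1))
  probs <- c(0.20, 0.10, 0.05, 0.15, 0.10, 0.05, 0.02, 0.15, 0.10, 0.08)
  probs <- probs / sum(probs)
  splice <- stats::setNames(
    rep(list(c("F", "ex2")), 3), as.character(rel[1:3]))
  splice <- c(splice, stats::setNames(rep(list(c("B", "ex2")), 4),
                                      as.character(rel[4:7])))
  list(tss = stats::setNames(probs, rel), splice = splice, idx = idx)
}

toy_sim_config <- function(model, depth = 2000L, seed = 7L, ...) {
  d <- toy_tss_distribution(model)
  sim_config(tss = d$tss, splice = d$splice, depth = depth, seed = seed, ...)
}

# clean libraries: no errors, every capped fragment keeps its label
clean_sim_config <- function(model, depth = 2000L, seed = 7L, ...) {
  toy_sim_config(model, depth = depth, seed = seed,
                 capped_fraction = 1, label_retention = 1,
                 insertion_rate = 0, deletion_rate = 0,
                 substitution_rate = 0, ...)
}

# build a tss_counts table directly from a matrix (positions x samples)
counts_table <- function(m, positions = seq_len(nrow(m))) {
  colnames(m) <- colnames(m) %||% paste0("s", seq_len(ncol(m)))
  wide <- tibble::as_tibble(as.data.frame(m))
  wide <- dplyr::bind_cols(tibble::tibble(tss_rel = as.integer(positions)), wide)
  racetss:::new_tss_counts(wide)
}
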