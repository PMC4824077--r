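#' Gene model for a 5'-RACE target region
#'
#' A gene model bundles everything downstream stages need to interpret reads
#' from a single-gene 5'-RACE library: the genomic window, strand, the
#' coordinate anchor used for reporting (the A of the ATG start codon, or the
#' first nucleotide of the reference mRNA), annotated first-exon splice donor
#' sites and downstream acceptor site(s), the cap-oligo sequence that labels
#' genuine m7G-capped 5' ends, and the per-sample MID barcodes.
#'
#' The reference sequence is stored gene-forward: for minus-strand genes it is
#' reverse-complemented once at construction, so that every downstream stage
#' (simulation, tagging, alignment, counting) works in a single orientation.
#' Genomic coordinates remain on the plus strand of the assembly, 1-based
#' inclusive.
#'
#' @param name Gene/region name.
#' @param chrom Chromosome or sequence name of the reference.
#' @param region_start,region_end 1-based inclusive genomic bounds of the
#'   region.
#' @param strand `"+"` or `"-"`.
#' @param anchor_kind `"ATG"` (coordinates reported relative to the
#'   translation initiation codon, anchor base = +1, no zero) or
#'   `"MRNA_START"` (first mRNA nucleotide = +1).
#' @param anchor_pos Genomic coordinate of the anchor base.
#' @param donor_sites Named integer vector of genomic coordinates, each the
#'   last exonic base of an annotated first exon. Names (e.g. `"F"`, `"B"`)
#'   label the exons and seed locus naming; may be empty for mono-exonic
#'   genes.
#' @param acceptor_sites Named integer vector of genomic coordinates, each the
#'   first exonic base of a downstream exon.
#' @param oligo_seq Cap-oligo sequence (RNA or DNA alphabet; `U` is converted
#'   to `T` at load since reads are DNA-space).
#' @param mids Named character vector of sample-id -> MID barcode.
#' @param reference Plus-strand genomic sequence covering exactly
#'   `region_start:region_end` (character or [Biostrings::DNAString]).
#'
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(name, chrom, region_start, region_end, strand,
                       anchor_kind = c("ATG", "MRNA_START"), anchor_pos,
                       donor_sites = integer(), acceptor_sites = integer(),
                       oligo_seq, mids = character(), reference) {
  anchor_kind <- match.arg(anchor_kind)
  region_start <- as.integer(region_start)
  region_end <- as.integer(region_end)
  anchor_pos <- as.integer(anchor_pos)
  donor_sites <- stats::setNames(as.integer(donor_sites), names(donor_sites))
  acceptor_sites <- stats::setNames(as.integer(acceptor_sites), names(acceptor_sites))

  check <- function(ok, field, msg) {
    if (!ok) stop("invalid gene model field '", field, "': ", msg, call. = FALSE)
  }
  check(is.character(name) && nzchar(name), "name", "must be a non-empty string")
  check(!is.na(region_start) && !is.na(region_end) && region_start <= region_end,
        "region_start/region_end", "need region_start <= region_end")
  check(strand %in% c("+", "-"), "strand", "must be '+' or '-'")
  check(!is.na(anchor_pos) && anchor_pos >= region_start && anchor_pos <= region_end,
        "anchor_pos", "anchor must lie inside the region")
  check(all(donor_sites >= region_start & donor_sites <= region_end),
        "donor_sites", "all donor sites must lie inside the region")
  check(all(acceptor_sites >= region_start & acceptor_sites <= region_end),
        "acceptor_sites", "all acceptor sites must lie inside the region")
  check(is.character(oligo_seq) && nzchar(oligo_seq), "oligo_seq", "must be non-empty")
  if (length(mids)) {
    check(!is.null(names(mids)) && all(nzchar(names(mids))), "mids",
          "barcodes must be named by sample id")
    check(!anyDuplicated(mids), "mids", "barcodes must be unique")
    check(!anyDuplicated(names(mids)), "mids", "sample ids must be unique")
  }

  oligo_seq <- toupper(gsub("U", "T", toupper(oligo_seq), fixed = TRUE))
  check(grepl("^[ACGT]+$", oligo_seq), "oligo_seq", "alphabet must be A/C/G/U/T")

  ref <- toupper(as.character(reference))
  len <- region_end - region_start + 1L
  check(nchar(ref) == len, "reference",
        sprintf("length %d does not match region length %d", nchar(ref), len))
  check(grepl("^[ACGTN]*$", ref), "reference", "alphabet must be A/C/G/T/N")
  if (strand == "-") ref <- revcomp(ref)

  model <- structure(
    list(name = name, chrom = chrom,
         region_start = region_start, region_end = region_end,
         strand = strand, anchor_kind = anchor_kind, anchor_pos = anchor_pos,
         donor_sites = donor_sites, acceptor_sites = acceptor_sites,
         oligo_seq = oligo_seq, mids = mids, ref = ref, length = len),
    class = "gene_model")

  # gene-forward ordering: donors ascending, all acceptors downstream of at
  # least one donor, no interleaving of an acceptor upstream of every donor
  di <- gf_index(model, donor_sites)
  ai <- gf_index(model, acceptor_sites)
  if (is.unsorted(di)) {
    o <- order(di)
    model$donor_sites <- donor_sites[o]
    di <- di[o]
  }
  if (is.unsorted(ai)) {
    o <- order(ai)
    model$acceptor_sites <- acceptor_sites[o]
    ai <- ai[o]
  }
  if (length(ai) && length(di)) {
    check(all(ai > min(di)), "acceptor_sites",
          "acceptor upstream of all donor sites in gene-forward order")
  }
  if (length(ai) && !length(di)) {
    check(FALSE, "acceptor_sites", "acceptor sites given without donor sites")
  }
  model
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s  %s:%d-%d (%s)\n", x$name, x$chrom,
              x$region_start, x$region_end, x$strand))
  cat(sprintf("  anchor: %s at %d; %d donor site(s), %d acceptor site(s)\n",
              x$anchor_kind, x$anchor_pos, length(x$donor_sites),
              length(x$acceptor_sites)))
  cat(sprintf("  cap oligo: %s (%d nt); %d MID(s)\n", x$oligo_seq,
              nchar(x$oligo_seq), length(x$mids)))
  invisible(x)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Gene-forward index of a genomic coordinate
#'
#' Maps genomic coordinates to 1-based positions along the gene-forward
#' reference (1 = 5'-most base of the gene region).
#'
#' @param model A [gene_model()].
#' @param pos Genomic coordinate(s).
#' @return Integer vector of gene-forward indices.
#' @keywords internal
gf_index <- function(model, pos) {
  if (model$strand == "+") as.integer(pos - model$region_start + 1L)
  else as.integer(model$region_end - pos + 1L)
}

# inverse of gf_index
gf_genomic <- function(model, idx) {
  if (model$strand == "+") as.integer(model$region_start + idx - 1L)
  else as.integer(model$region_end - idx + 1L)
}

#' Convert genomic coordinates to gene-relative coordinates
#'
#' Gene-relative coordinates follow the skip-zero convention used for
#' annotating TSSs against a translation start: the anchor base is +1, the
#' base immediately 5' (gene-forward upstream) of it is -1, and there is no
#' position 0. Positions increase in the gene-forward direction, so the
#' mapping is strand-aware.
#'
#' @param pos Genomic coordinate(s), inside the model's region.
#' @param model A [gene_model()].
#' @return Integer vector of nonzero gene-relative coordinates.
#' @seealso [to_genomic()] for the exact inverse.
#' @export
to_relative <- function(pos, model) {
  idx <- gf_index(model, pos)
  if (any(idx < 1L | idx > model$length)) {
    stop("position outside gene region [", model$region_start, ", ",
         model$region_end, "]", call. = FALSE)
  }
  d <- idx - gf_index(model, model$anchor_pos)
  as.integer(ifelse(d >= 0L, d + 1L, d))
}

#' Convert gene-relative coordinates to genomic coordinates
#'
#' Exact inverse of [to_relative()]. Relative coordinate 0 does not exist
#' under the skip-zero convention and is an error.
#'
#' @param rel Nonzero gene-relative coordinate(s).
#' @param model A [gene_model()].
#' @return Integer vector of genomic coordinates.
#' @export
to_genomic <- function(rel, model) {
  rel <- as.integer(rel)
  if (any(rel == 0L, na.rm = TRUE)) {
    stop("gene-relative coordinate 0 does not exist (skip-zero convention)",
         call. = FALSE)
  }
  d <- ifelse(rel > 0L, rel - 1L, rel)
  idx <- gf_index(model, model$anchor_pos) + d
  if (any(idx < 1L | idx > model$length)) {
    stop("relative coordinate maps outside the gene region", call. = FALSE)
  }
  gf_genomic(model, idx)
}

#' Load a gene model from a YAML configuration file
#'
#' The configuration is a small documented key/value schema rather than GFF3,
#' because donor/acceptor-only splice annotation together with MIDs and the
#' cap-oligo has no faithful GFF3 encoding. Keys:
#'
#' \preformatted{
#' name: mygene
#' fasta: reference.fa        # path, relative to the config file
#' chrom: chr5
#' region_start: 142657496
#' region_end:   142850254
#' strand: "-"
#' anchor: {kind: ATG, pos: 142780000}
#' donors:    {F: 142783000, B: 142783400}   # last exonic base of first exons
#' acceptors: {ex2: 142779000}               # first exonic base downstream
#' oligo: CGACUGGAGCACGAGGACACUGACAUGGACUGAAGGAGUAGAAA
#' mids: {sampleA: ACGAGTGCGT, sampleB: ACGCTCGACA}
#' }
#'
#' The FASTA record named `chrom` must cover the region; the region is
#' extracted and, for minus-strand genes, reverse-complemented once so all
#' downstream processing is gene-forward.
#'
#' @param config_path Path to the YAML config.
#' @return A validated [gene_model()].
#' @export
read_gene_model <- function(config_path) {
  if (!file.exists(config_path)) {
    stop("gene model config not found: ", config_path, call. = FALSE)
  }
  cfg <- yaml::read_yaml(config_path)
  need <- c("name", "fasta", "chrom", "region_start", "region_end", "strand",
            "anchor", "oligo")
  missing <- setdiff(need, names(cfg))
  if (length(missing)) {
    stop("gene model config missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!is.list(cfg$anchor) || is.null(cfg$anchor$kind) || is.null(cfg$anchor$pos)) {
    stop("invalid gene model field 'anchor': needs 'kind' and 'pos'", call. = FALSE)
  }
  for (f in c("region_start", "region_end")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] != as.integer(cfg[[f]])) {
      stop("invalid gene model field '", f, "': malformed coordinate", call. = FALSE)
    }
  }
  fasta <- cfg$fasta
  if (!file.exists(fasta)) {
    fasta <- file.path(dirname(config_path), cfg$fasta)
  }
  if (!file.exists(fasta)) {
    stop("reference FASTA not found: ", cfg$fasta, call. = FALSE)
  }
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (!cfg$chrom %in% names(seqs)) {
    stop("FASTA has no record named '", cfg$chrom, "'", call. = FALSE)
  }
  rec <- seqs[[cfg$chrom]]
  # the record either spans the region coordinates directly, or (common for
  # single-region files) is exactly the region
  len <- cfg$region_end - cfg$region_start + 1
  if (length(rec) == len) {
    ref <- as.character(rec)
  } else if (length(rec) >= cfg$region_end) {
    ref <- as.character(Biostrings::subseq(rec, cfg$region_start, cfg$region_end))
  } else {
    stop("FASTA record '", cfg$chrom, "' (", length(rec),
         " nt) does not cover the region", call. = FALSE)
  }
  gene_model(
    name = cfg$name, chrom = cfg$chrom,
    region_start = cfg$region_start, region_end = cfg$region_end,
    strand = cfg$strand,
    anchor_kind = toupper(cfg$anchor$kind), anchor_pos = cfg$anchor$pos,
    donor_sites = unlist(cfg$donors %||% integer()),
    acceptor_sites = unlist(cfg$acceptors %||% integer()),
    oligo_seq = cfg$oligo,
    mids = unlist(cfg$mids %||% character()),
    reference = ref)
}

#' Export the splice annotation of a gene model as GFF3
#'
#' Writes the gene region plus each annotated splice donor and acceptor site
#' as single-base features. Fixed exon intervals are deliberately not
#' emitted: the 5' boundary of each first exon is exactly what TSS
#' microvariability makes variable.
#'
#' @param model A [gene_model()].
#' @param path Output GFF3 path.
#' @return `path`, invisibly.
#' @export
export_gff3 <- function(model, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = model$chrom,
    ranges = IRanges::IRanges(
      start = c(model$region_start, unname(model$donor_sites),
                unname(model$acceptor_sites)),
      end = c(model$region_end, unname(model$donor_sites),
              unname(model$acceptor_sites))),
    strand = model$strand,
    type = c("region", rep("splice_donor", length(model$donor_sites)),
             rep("splice_acceptor", length(model$acceptor_sites))),
    ID = c(model$name,
           paste0("donor_", names(model$donor_sites)),
           paste0("acceptor_", names(model$acceptor_sites))))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
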