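#' Splice layouts of a gene model
#'
#' The contiguous gene-forward reference plus one concatenated layout per
#' annotated (donor, acceptor) pair with donor upstream of acceptor. Each
#' layout records the junction position so aligned coordinates can be mapped
#' back to gene-forward indices.
#'
#' @param model A [gene_model()].
#' @return A list of layouts: `seq`, `junction` (1-based layout position of
#'   the donor base; -1 for contiguous), `delta` (index shift past the
#'   junction), `donor`, `acceptor` (names), `donor_g`, `acceptor_g`
#'   (genomic coordinates).
#' @keywords internal
#' @export
splice_layouts <- function(model) {
  L <- model$length
  layouts <- list(list(seq = model$ref, junction = -1L, delta = 0L,
                       donor = NA_character_, acceptor = NA_character_,
                       donor_g = NA_integer_, acceptor_g = NA_integer_))
  for (dn in names(model$donor_sites)) {
    d_idx <- gf_index(model, model$donor_sites[[dn]])
    for (an in names(model$acceptor_sites)) {
      a_idx <- gf_index(model, model$acceptor_sites[[an]])
      if (d_idx >= a_idx) next
      layouts[[length(layouts) + 1L]] <- list(
        seq = paste0(substr(model$ref, 1L, d_idx),
                     substr(model$ref, a_idx, L)),
        junction = d_idx, delta = a_idx - d_idx - 1L,
        donor = dn, acceptor = an,
        donor_g = model$donor_sites[[dn]],
        acceptor_g = model$acceptor_sites[[an]])
    }
  }
  layouts
}

#' Align tagged reads and call one TSS per read
#'
#' Each oligo-trimmed read is placed on the gene region by a seed-and-extend
#' search over the contiguous layout and every single-splice layout at
#' annotated donor/acceptor sites. The called TSS is the reference base
#' aligned to the first read base (the first matched base when the read
#' starts with an insertion). Placements needing more than
#' `max_edit_frac * read length` edits are rejected; reads whose optimal
#' placement is not unique are rejected as ambiguous rather than assigned at
#' random, since a wrong placement fabricates a TSS while exclusion only
#' costs depth.
#'
#' @param tagged A `tagged_reads` tibble from [tag_reads()] (or any tibble
#'   with `read_id`, `sample_id`, `sequence`).
#' @param model A [gene_model()].
#' @param max_edit_frac Maximum edits as a fraction of read length (default
#'   0.1, tolerating the indel-dominated error rates of semiconductor
#'   sequencing with margin).
#' @param min_read_len Minimum read length attempted (default 20 nt).
#' @return A `tss_calls` tibble with one row per read:
#'   `read_id`, `sample_id`, `status` (`aligned`, `too_short`,
#'   `too_many_edits`, `ambiguous`), `tss_genomic`, `tss_rel`, `donor`,
#'   `acceptor`, `donor_site`, `acceptor_site`, `n_mismatch`, `n_insertion`,
#'   `n_deletion`, `edits`, `aligned_len`, `read_len`, `tss_clean` (no edit
#'   within +-2 nt of the TSS).
#' @export
align_reads <- function(tagged, model, max_edit_frac = 0.1, min_read_len = 20L) {
  layouts <- splice_layouts(model)
  if (nrow(tagged) == 0L) {
    return(empty_calls())
  }
  res <- cpp_align_batch(tagged$sequence,
                         vapply(layouts, `[[`, character(1), "seq"),
                         vapply(layouts, `[[`, integer(1), "junction"),
                         vapply(layouts, `[[`, integer(1), "delta"),
                         max_edit_frac, as.integer(min_read_len))

  status <- c("aligned", "too_short", "too_many_edits", "ambiguous")[res$status + 1L]
  lay <- res$layout + 1L  # 1-based into layouts; NA when unaligned
  donor_nm <- vapply(layouts, `[[`, character(1), "donor")
  acc_nm <- vapply(layouts, `[[`, character(1), "acceptor")
  donor_g <- vapply(layouts, `[[`, integer(1), "donor_g")
  acc_g <- vapply(layouts, `[[`, integer(1), "acceptor_g")

  aligned <- status == "aligned"
  tss_genomic <- rep(NA_integer_, nrow(tagged))
  tss_rel <- rep(NA_integer_, nrow(tagged))
  tss_genomic[aligned] <- gf_genomic(model, res$tss_idx[aligned])
  tss_rel[aligned] <- to_relative(tss_genomic[aligned], model)

  out <- tibble::tibble(
    read_id = tagged$read_id,
    sample_id = tagged$sample_id,
    status = status,
    tss_genomic = tss_genomic,
    tss_rel = tss_rel,
    donor = ifelse(aligned, donor_nm[lay], NA_character_),
    acceptor = ifelse(aligned, acc_nm[lay], NA_character_),
    donor_site = ifelse(aligned, donor_g[lay], NA_integer_),
    acceptor_site = ifelse(aligned, acc_g[lay], NA_integer_),
    n_mismatch = res$n_mismatch, n_insertion = res$n_insertion,
    n_deletion = res$n_deletion, edits = res$edits,
    aligned_len = res$aligned_ref_len,
    read_len = nchar(tagged$sequence),
    tss_clean = ifelse(aligned, res$min_edit_offset < 0 | res$min_edit_offset > 2, NA))
  class(out) <- c("tss_calls", class(out))
  out
}

empty_calls <- function() {
  out <- tibble::tibble(
    read_id = character(), sample_id = character(), status = character(),
    tss_genomic = integer(), tss_rel = integer(), donor = character(),
    acceptor = character(), donor_site = integer(), acceptor_site = integer(),
    n_mismatch = integer(), n_insertion = integer(), n_deletion = integer(),
    edits = integer(), aligned_len = integer(), read_len = integer(),
    tss_clean = logical())
  class(out) <- c("tss_calls", class(out))
  out
}

#' Align a batch of tagged reads and summarise mapping
#'
#' Runs [align_reads()] and attaches a per-sample mapping summary (mapped
#' fraction, unaligned category counts). Calls are sorted by `read_id` so the
#' output is independent of input order.
#'
#' @inheritParams align_reads
#' @return A `tss_calls` tibble of aligned calls only, with attribute
#'   `mapping_summary` (per sample: reads attempted, mapped, mapped_fraction,
#'   counts per rejection category) and attribute `all_calls` retaining the
#'   per-read status table.
#' @export
call_tss <- function(tagged, model, max_edit_frac = 0.1, min_read_len = 20L) {
  all <- align_reads(tagged, model, max_edit_frac, min_read_len)
  all <- dplyr::arrange(all, .data$read_id)
  summ <- dplyr::summarise(
    dplyr::group_by(all, .data$sample_id),
    attempted = dplyr::n(),
    mapped = sum(.data$status == "aligned"),
    too_short = sum(.data$status == "too_short"),
    too_many_edits = sum(.data$status == "too_many_edits"),
    ambiguous = sum(.data$status == "ambiguous"),
    mapped_fraction = ifelse(dplyr::n() > 0, mapped / dplyr::n(), NA_real_),
    .groups = "drop")
  out <- dplyr::filter(all, .data$status == "aligned")
  attr(out, "mapping_summary") <- summ
  attr(out, "all_calls") <- all
  class(out) <- c("tss_calls", class(out))
  out
}

#' Profile sequencing errors over aligned reads
#'
#' Per-nt substitution, insertion and deletion rates over the aligned bases,
#' a per-TSS flag for edits within +-2 nt of the TSS (edits there would
#' compromise TSS identification), and the reference homopolymer run length
#' at each called TSS.
#'
#' @param calls A `tss_calls` tibble of aligned calls.
#' @param model A [gene_model()].
#' @return An `error_profile` list: `rates` (tibble with
#'   substitution/insertion/deletion per aligned nt), `tss` (per TSS:
#'   reads, clean fraction, `tss_region_clean` flag, homopolymer length).
#' @export
profile_errors <- function(calls, model) {
  calls <- dplyr::filter(calls, .data$status == "aligned")
  total_nt <- sum(calls$read_len)
  rates <- tibble::tibble(
    substitution_rate = ifelse(total_nt > 0, sum(calls$n_mismatch) / total_nt, 0),
    insertion_rate = ifelse(total_nt > 0, sum(calls$n_insertion) / total_nt, 0),
    deletion_rate = ifelse(total_nt > 0, sum(calls$n_deletion) / total_nt, 0),
    total_nt = total_nt)
  tss <- dplyr::summarise(
    dplyr::group_by(calls, .data$tss_rel),
    reads = dplyr::n(),
    clean_fraction = mean(.data$tss_clean),
    tss_region_clean = all(.data$tss_clean),
    .groups = "drop")
  if (nrow(tss)) {
    idx <- gf_index(model, to_genomic(tss$tss_rel, model))
    tss$homopolymer_len <- vapply(idx, function(i) homopolymer_at(model$ref, i),
                                  integer(1))
  } else {
    tss$homopolymer_len <- integer()
  }
  structure(list(rates = rates, tss = tss), class = "error_profile")
}

# length of the homopolymer run containing position i of seq
homopolymer_at <- function(seq, i) {
  b <- substr(seq, i, i)
  n <- nchar(seq)
  lo <- i
  while (lo > 1 && substr(seq, lo - 1L, lo - 1L) == b) lo <- lo - 1L
  hi <- i
  while (hi < n && substr(seq, hi + 1L, hi + 1L) == b) hi <- hi + 1L
  as.integer(hi - lo + 1L)
}

#' @export
print.error_profile <- function(x, ...) {
  cat("<error_profile>\n")
  print(x$rates)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.error_profile <- function(x, ...) x$tss

#' @exportS3Method generics::glance
glance.error_profile <- function(x, ...) x$rates

#' Write accepted alignments' TSS calls as TSV
#'
#' @param calls A `tss_calls` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tss_calls <- function(calls, path) {
  readr::write_tsv(calls, path)
  invisible(path)
}
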