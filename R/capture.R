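#' Demultiplex reads by MID barcode
#'
#' Assigns each read to at most one sample by prefix match against the gene
#' model's MID barcodes, allowing up to `max_mid_mismatch` substitutions.
#' Reads matching no barcode, or more than one at the configured radius, are
#' binned as unassigned with the reason recorded. Matched MIDs are trimmed
#' from sequence and quality.
#'
#' @param reads Tibble with `read_id`, `sequence`, `quality` (e.g. from
#'   [read_fastq()] or [simulate_library()]).
#' @param model A [gene_model()] carrying the MIDs.
#' @param max_mid_mismatch Maximum substitutions tolerated in the barcode
#'   (default 0).
#' @return The reads tibble with a `sample_id` column (`NA` = unassigned) and
#'   an `assign_status` column (`assigned`, `no_match`, `ambiguous`,
#'   `too_short`); MID trimmed where assigned. Attribute `demux_counts`
#'   summarises the bins.
#' @export
demultiplex <- function(reads, model, max_mid_mismatch = 0L) {
  mids <- model$mids
  if (!length(mids)) stop("gene model has no MIDs", call. = FALSE)
  # barcodes must be mutually distinguishable at the configured radius
  if (length(mids) > 1) {
    cmb <- utils::combn(length(mids), 2)
    for (j in seq_len(ncol(cmb))) {
      a <- mids[[cmb[1, j]]]; b <- mids[[cmb[2, j]]]
      l <- min(nchar(a), nchar(b))
      d <- hamming(substr(a, 1, l), substr(b, 1, l))
      if (d <= 2L * max_mid_mismatch) {
        stop("MID barcodes '", names(mids)[cmb[1, j]], "' and '",
             names(mids)[cmb[2, j]], "' are within mutual mismatch radius ",
             max_mid_mismatch, call. = FALSE)
      }
    }
  }

  n <- nrow(reads)
  if (n == 0L) {
    out <- reads
    out$sample_id <- character()
    out$assign_status <- character()
    attr(out, "demux_counts") <- tibble::tibble(sample_id = character(),
                                                status = character(),
                                                n = integer())
    return(out)
  }
  nmm <- matrix(NA_integer_, nrow = n, ncol = length(mids))
  for (i in seq_along(mids)) {
    len <- nchar(mids[[i]])
    ok <- nchar(reads$sequence) >= len
    if (any(ok)) {
      nmm[ok, i] <- hamming_vec(substr(reads$sequence[ok], 1, len), mids[[i]])
    }
  }
  hit <- !is.na(nmm) & nmm <= max_mid_mismatch
  nhit <- rowSums(hit)
  which_hit <- apply(hit, 1, function(z) if (any(z)) which(z)[1] else NA_integer_)

  status <- dplyr::case_when(
    nchar(reads$sequence) < min(nchar(mids)) ~ "too_short",
    nhit == 1 ~ "assigned",
    nhit > 1 ~ "ambiguous",
    TRUE ~ "no_match")
  sample_id <- ifelse(status == "assigned", names(mids)[which_hit], NA_character_)
  mid_len <- ifelse(status == "assigned", nchar(mids)[which_hit], 0L)

  out <- reads
  out$sample_id <- sample_id
  out$assign_status <- status
  out$sequence <- substr(reads$sequence, mid_len + 1L, nchar(reads$sequence))
  out$quality <- substr(reads$quality, mid_len + 1L, nchar(reads$quality))
  attr(out, "demux_counts") <- dplyr::count(
    tibble::tibble(sample_id = sample_id, status = status),
    .data$sample_id, .data$status, name = "n")
  out
}

hamming <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# mismatches of each string in x (all nchar >= nchar(pattern)) vs pattern
hamming_vec <- function(x, pattern) {
  l <- nchar(pattern)
  if (!length(x)) return(integer())
  m <- matrix(unlist(strsplit(substr(x, 1, l), "", fixed = TRUE), use.names = FALSE),
              nrow = l)
  p <- strsplit(pattern, "", fixed = TRUE)[[1]]
  as.integer(colSums(m != p))
}

#' Detect and trim the 5' cap-oligo label
#'
#' A read is accepted as a genuine oligo-labelled 5' end iff a 3'-terminal
#' suffix of the cap-oligo, of length at least `min_suffix` (default 8 nt),
#' matches entirely within the first `search_window + oligo length` bases of
#' the read with at most `max_mismatch` substitutions, and at least one
#' template base follows the match. Bounding the match's end (rather than
#' its start) tolerates both 5' adapter remnants and indels inside the
#' oligo, which shift the terminal suffix rightward, while still refusing
#' internal oligo hits deep in the read. The longest qualifying suffix is
#' chosen (smallest offset on ties) and everything through the oligo's last
#' base is trimmed, so the first retained base is the putative TSS base.
#'
#' @param reads Tibble with `sequence` and `quality` columns (MID already
#'   removed, e.g. from [demultiplex()]).
#' @param oligo_seq Cap-oligo in DNA alphabet (the gene model applies U->T at
#'   load).
#' @param min_suffix Minimum oligo suffix length accepted (default 8).
#' @param max_mismatch Substitutions allowed in the suffix match (default 0:
#'   a false label fabricates a TSS).
#' @param search_window Extra bases beyond the oligo length within which the
#'   suffix match must end (default 5).
#' @return The input tibble with columns `tag_status` (`labelled`,
#'   `no_match`, `match_at_read_end`), `oligo_match_len`, `oligo_mismatches`,
#'   and sequence/quality trimmed for labelled reads.
#' @export
detect_and_trim_oligo <- function(reads, oligo_seq, min_suffix = 8L,
                                  max_mismatch = 0L, search_window = 5L) {
  olen <- nchar(oligo_seq)
  if (min_suffix > olen) stop("min_suffix exceeds oligo length", call. = FALSE)
  n <- nrow(reads)
  seqs <- reads$sequence
  rlen <- nchar(seqs)
  match_len <- integer(n)
  match_off <- integer(n)
  match_mm <- integer(n)
  found <- logical(n)
  at_end <- logical(n)

  # with exact matching, any qualifying hit must contain the terminal
  # min_suffix oligo bases within the searchable prefix: cheap prefilter
  searchable <- rep(TRUE, n)
  if (max_mismatch == 0L) {
    min_suf <- substr(oligo_seq, olen - min_suffix + 1L, olen)
    prefix <- substr(seqs, 1L, search_window + olen)
    searchable <- grepl(min_suf, prefix, fixed = TRUE)
  }

  for (L in seq(olen, min_suffix)) {
    suffix <- substr(oligo_seq, olen - L + 1L, olen)
    for (off in 0:(search_window + olen - L)) {
      todo <- which(searchable & !found & rlen >= off + L)
      if (!length(todo)) next
      cand <- substr(seqs[todo], off + 1L, off + L)
      if (max_mismatch == 0L) {
        mm <- ifelse(cand == suffix, 0L, NA_integer_)
      } else {
        mm <- hamming_vec(cand, suffix)
        mm[mm > max_mismatch] <- NA_integer_
      }
      hit <- !is.na(mm)
      if (!any(hit)) next
      idx <- todo[hit]
      has_template <- rlen[idx] > off + L
      ok <- idx[has_template]
      found[ok] <- TRUE
      match_len[ok] <- L
      match_off[ok] <- off
      match_mm[ok] <- mm[hit][has_template]
      # suffix flush with the read end: no template base follows, so the hit
      # is categorized but the search continues for shorter qualifying hits
      endhit <- idx[!has_template]
      newend <- endhit[!at_end[endhit]]
      match_len[newend] <- L
      at_end[endhit] <- TRUE
    }
  }

  out <- reads
  out$tag_status <- dplyr::case_when(found ~ "labelled",
                                     at_end ~ "match_at_read_end",
                                     TRUE ~ "no_match")
  out$oligo_match_len <- ifelse(found | at_end, match_len, NA_integer_)
  out$oligo_mismatches <- ifelse(found, match_mm, NA_integer_)
  trim_from <- match_off + match_len + 1L
  out$sequence <- ifelse(found, substr(seqs, trim_from, rlen), seqs)
  out$quality <- ifelse(found, substr(reads$quality, trim_from, rlen),
                        reads$quality)
  out
}

#' Demultiplex and cap-oligo-select a read stream
#'
#' Convenience wrapper running [demultiplex()] then [detect_and_trim_oligo()]
#' on the assigned reads. The result carries the full read funnel so that
#' [qc_reads()] can report per-sample conservation
#' (total = assigned + unassigned; assigned = labelled + rejected).
#'
#' @inheritParams demultiplex
#' @inheritParams detect_and_trim_oligo
#' @return A `tagged_reads` tibble of labelled reads (`read_id`, `sample_id`,
#'   `sequence` trimmed to start at the putative TSS base, `quality`,
#'   `oligo_match_len`, `oligo_mismatches`), with attribute `funnel`.
#' @export
tag_reads <- function(reads, model, max_mid_mismatch = 0L, min_suffix = 8L,
                      max_mismatch = 0L, search_window = 5L) {
  dm <- demultiplex(reads, model, max_mid_mismatch)
  assigned <- dplyr::filter(dm, .data$assign_status == "assigned")
  det <- detect_and_trim_oligo(assigned, model$oligo_seq, min_suffix,
                               max_mismatch, search_window)

  funnel <- dplyr::summarise(
    dplyr::group_by(det, .data$sample_id),
    assigned = dplyr::n(),
    labelled = sum(.data$tag_status == "labelled"),
    rejected_no_match = sum(.data$tag_status == "no_match"),
    rejected_match_at_read_end = sum(.data$tag_status == "match_at_read_end"),
    .groups = "drop")
  # samples with zero assigned reads still appear in the funnel
  all_samples <- tibble::tibble(sample_id = names(model$mids))
  funnel <- dplyr::left_join(all_samples, funnel, by = "sample_id")
  funnel[is.na(funnel)] <- 0L
  funnel$total_input <- nrow(reads)
  funnel$unassigned_total <- sum(dm$assign_status != "assigned")

  out <- dplyr::select(
    dplyr::filter(det, .data$tag_status == "labelled"),
    dplyr::any_of(c("read_id", "sample_id", "sequence", "quality",
                    "oligo_match_len", "oligo_mismatches")))
  attr(out, "funnel") <- funnel
  attr(out, "demux_counts") <- attr(dm, "demux_counts")
  class(out) <- c("tagged_reads", class(out))
  out
}

#' Summarise the capture funnel and read quality
#'
#' Reports per-sample read counts at each funnel stage (total input,
#' MID-assigned, oligo-labelled, length-filtered), the labelled fraction, and
#' mean Phred quality by cycle of the labelled reads.
#'
#' @param tagged A `tagged_reads` object from [tag_reads()].
#' @param min_len Minimum retained-sequence length for the length-filtered
#'   stage (default 20, matching the aligner's minimum).
#' @return A `race_qc` object (list with `funnel`, `quality_by_cycle`,
#'   `labelled_fraction`).
#' @export
qc_reads <- function(tagged, min_len = 20L) {
  funnel <- attr(tagged, "funnel")
  if (is.null(funnel)) {
    funnel <- dplyr::count(tagged, .data$sample_id, name = "labelled")
    funnel$assigned <- funnel$labelled
    funnel$rejected_no_match <- 0L
    funnel$rejected_match_at_read_end <- 0L
    funnel$total_input <- nrow(tagged)
    funnel$unassigned_total <- 0L
  }
  lf <- dplyr::count(
    dplyr::filter(tagged, nchar(.data$sequence) >= min_len),
    .data$sample_id, name = "length_filtered")
  funnel <- dplyr::left_join(funnel, lf, by = "sample_id")
  funnel$length_filtered[is.na(funnel$length_filtered)] <- 0L
  funnel$labelled_fraction <- ifelse(funnel$assigned > 0,
                                     funnel$labelled / funnel$assigned, NA_real_)

  qbc <- quality_by_cycle(tagged$quality)
  structure(list(funnel = funnel, quality_by_cycle = qbc,
                 labelled_fraction = stats::setNames(funnel$labelled_fraction,
                                                     funnel$sample_id)),
            class = "race_qc")
}

quality_by_cycle <- function(quals) {
  quals <- quals[nzchar(quals)]
  if (!length(quals)) {
    return(tibble::tibble(cycle = integer(), mean_q = double(), n = integer()))
  }
  ints <- utf8ToInt(paste(quals, collapse = "")) - 33L
  cyc <- sequence(nchar(quals))
  tibble::tibble(cycle = sort(unique(cyc)),
                 mean_q = as.numeric(tapply(ints, cyc, mean)),
                 n = as.integer(tapply(ints, cyc, length)))
}

#' @export
print.race_qc <- function(x, ...) {
  cat("<race_qc> capture funnel\n")
  print(x$funnel)
  invisible(x)
}

#' @importFrom generics tidy
#' @exportS3Method generics::tidy
tidy.race_qc <- function(x, ...) x$funnel

#' @importFrom generics glance
#' @exportS3Method generics::glance
glance.race_qc <- function(x, ...) {
  tibble::tibble(
    total_input = x$funnel$total_input[1],
    assigned = sum(x$funnel$assigned),
    labelled = sum(x$funnel$labelled),
    labelled_fraction = sum(x$funnel$labelled) / max(1, sum(x$funnel$assigned)))
}
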