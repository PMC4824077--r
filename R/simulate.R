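#' Configuration for the synthetic 5'-RACE library simulator
#'
#' The simulator emulates the molecular stages that shape a 5'-RACE NGS
#' library: transcripts start from a configured TSS distribution (optionally
#' spliced at annotated sites), a fraction are m7G-capped (only those are
#' eligible for cap-oligo ligation; degraded/uncapped molecules are
#' 5'-truncated and never ligated), libraries are sheared so only a fraction
#' of fragments retains the oligo-TSS junction, and reads acquire
#' MID-barcoded, indel-dominated sequencing errors with indels boosted inside
#' homopolymer runs.
#'
#' @param tss Named numeric vector: gene-relative TSS -> probability
#'   (must sum to 1 within 1e-9).
#' @param splice Named list mapping a gene-relative TSS (as character) to a
#'   length-2 character vector `c(donor, acceptor)` of annotated site names in
#'   the gene model. TSSs absent from the list are unspliced.
#' @param capped_fraction Proportion of transcripts carrying the m7G cap.
#' @param degraded_fraction Proportion degraded/uncapped; must equal
#'   `1 - capped_fraction`.
#' @param shear_min,shear_max Fragment-size selection bounds in nt (default
#'   200-350, the size window selected during library preparation).
#' @param label_retention Probability that a sheared fragment retains the 5'
#'   oligo-TSS junction (default 0.4; shearing makes the label survive in
#'   only a minority of fragments).
#' @param insertion_rate,deletion_rate,substitution_rate Per-nt error
#'   probabilities.
#' @param homopolymer_indel_multiplier Factor (>= 1) applied to indel
#'   probabilities inside homopolymer runs of length >= 2, giving the
#'   indel-dominated, homopolymer-biased error character of semiconductor
#'   sequencing.
#' @param clean_junction Suppress indel injection in the oligo-TSS junction
#'   window (last 3 oligo nt + first 3 template nt) of labelled reads
#'   (default TRUE). Deep 5'-RACE data shows this window to be indel-free in
#'   practice, and junction indels are the one error class that would shift
#'   the called start site; substitutions are still injected there.
#' @param depth Number of reads to simulate (0 gives a valid empty library).
#' @param seed Mandatory integer seed; the simulator never touches global RNG
#'   state outside [withr::with_seed()].
#' @param samples Character vector of sample ids to multiplex (default: all
#'   MIDs of the gene model); reads are assigned uniformly.
#' @param q_start,q_decay,q_min Per-cycle Phred quality profile:
#'   `q(cycle) = max(q_min, round(q_start - q_decay * (cycle - 1)))`. The
#'   defaults stay above Q20 through cycle 200.
#'
#' @return A `sim_config` list.
#' @export
sim_config <- function(tss, splice = list(),
                       capped_fraction = 0.9,
                       degraded_fraction = 1 - capped_fraction,
                       shear_min = 200L, shear_max = 350L,
                       label_retention = 0.4,
                       insertion_rate = 0, deletion_rate = 0,
                       substitution_rate = 0,
                       homopolymer_indel_multiplier = 4,
                       clean_junction = TRUE,
                       depth = 10000L, seed,
                       samples = NULL,
                       q_start = 36, q_decay = 0.08, q_min = 12) {
  if (missing(seed) || !is.numeric(seed)) {
    stop("sim_config requires an explicit integer seed", call. = FALSE)
  }
  if (abs(sum(tss) - 1) > 1e-9) {
    stop("tss probabilities must sum to 1 (tolerance 1e-9)", call. = FALSE)
  }
  if (is.null(names(tss)) || any(!nzchar(names(tss)))) {
    stop("tss must be named by gene-relative coordinate", call. = FALSE)
  }
  stopifnot(capped_fraction >= 0, capped_fraction <= 1,
            degraded_fraction >= 0, degraded_fraction <= 1)
  if (abs(capped_fraction + degraded_fraction - 1) > 1e-9) {
    stop("capped_fraction + degraded_fraction must equal 1", call. = FALSE)
  }
  stopifnot(shear_min >= 1, shear_min <= shear_max,
            label_retention >= 0, label_retention <= 1,
            insertion_rate >= 0, insertion_rate < 1,
            deletion_rate >= 0, deletion_rate < 1,
            substitution_rate >= 0, substitution_rate < 1,
            homopolymer_indel_multiplier >= 1,
            depth >= 0)
  structure(
    list(tss = tss, splice = splice,
         capped_fraction = capped_fraction,
         degraded_fraction = degraded_fraction,
         shear_min = as.integer(shear_min), shear_max = as.integer(shear_max),
         label_retention = label_retention,
         insertion_rate = insertion_rate, deletion_rate = deletion_rate,
         substitution_rate = substitution_rate,
         homopolymer_indel_multiplier = homopolymer_indel_multiplier,
         clean_junction = isTRUE(clean_junction),
         depth = as.integer(depth), seed = as.integer(seed),
         samples = samples,
         q_start = q_start, q_decay = q_decay, q_min = q_min),
    class = "sim_config")
}

#' Draw transcript templates from a simulator configuration
#'
#' Performs the multinomial TSS draw and the cap/degradation assignment.
#' Capped transcripts begin exactly at their drawn TSS; degraded transcripts
#' are 5'-truncated at a position drawn uniformly over the transcript body
#' (keeping at least 25 nt) and are flagged ineligible for oligo ligation,
#' mirroring the phosphatase treatment that removes them from the ligation
#' pool.
#'
#' @param model A [gene_model()].
#' @param cfg A [sim_config()].
#' @return A tibble with one row per transcript (`transcript_id`, `tss_rel`,
#'   `tss_idx`, `capped`, `donor`, `acceptor`, `trunc_offset`, `length`) and
#'   attribute `true_counts` (realized TSS counts among capped transcripts).
#' @export
simulate_transcripts <- function(model, cfg) {
  stopifnot(inherits(model, "gene_model"), inherits(cfg, "sim_config"))
  tss_rel <- as.integer(names(cfg$tss))
  tss_g <- to_genomic(tss_rel, model)  # errors if outside region
  tss_idx <- gf_index(model, tss_g)

  donor_idx <- rep(NA_integer_, length(tss_rel))
  acc_idx <- rep(NA_integer_, length(tss_rel))
  donor_nm <- rep(NA_character_, length(tss_rel))
  acc_nm <- rep(NA_character_, length(tss_rel))
  for (nm in names(cfg$splice)) {
    i <- match(as.integer(nm), tss_rel)
    if (is.na(i)) stop("splice map names TSS ", nm, " absent from tss", call. = FALSE)
    ch <- cfg$splice[[nm]]
    if (length(ch) != 2 || !ch[1] %in% names(model$donor_sites) ||
        !ch[2] %in% names(model$acceptor_sites)) {
      stop("splice chain for TSS ", nm,
           " must name an annotated donor and acceptor", call. = FALSE)
    }
    donor_nm[i] <- ch[1]; acc_nm[i] <- ch[2]
    donor_idx[i] <- gf_index(model, model$donor_sites[[ch[1]]])
    acc_idx[i] <- gf_index(model, model$acceptor_sites[[ch[2]]])
    if (tss_idx[i] > donor_idx[i]) {
      stop("TSS ", nm, " lies downstream of its splice donor", call. = FALSE)
    }
  }

  withr::with_seed(cfg$seed, {
    k <- sample.int(length(tss_rel), cfg$depth, replace = TRUE, prob = cfg$tss)
    capped <- stats::runif(cfg$depth) < cfg$capped_fraction

    L <- model$length
    seg1 <- ifelse(is.na(donor_idx[k]), L - tss_idx[k] + 1L,
                   donor_idx[k] - tss_idx[k] + 1L)
    seg2 <- ifelse(is.na(acc_idx[k]), 0L, L - acc_idx[k] + 1L)
    tlen <- as.integer(seg1 + seg2)

    trunc <- integer(cfg$depth)
    if (any(!capped)) {
      room <- pmax(1L, tlen[!capped] - 25L)
      trunc[!capped] <- as.integer(floor(stats::runif(sum(!capped)) * room)) + 1L
    }
  })

  out <- tibble::tibble(
    transcript_id = seq_len(cfg$depth),
    tss_rel = tss_rel[k], tss_idx = tss_idx[k],
    capped = capped,
    donor = donor_nm[k], acceptor = acc_nm[k],
    donor_idx = donor_idx[k], acceptor_idx = acc_idx[k],
    trunc_offset = trunc,
    length = tlen - trunc)
  true_counts <- dplyr::count(dplyr::filter(out, capped), .data$tss_rel,
                              name = "count")
  attr(out, "true_counts") <- true_counts
  attr(out, "model_name") <- model$name
  out
}

# materialize the sequence of one or more transcripts (transcript coordinates,
# truncation applied); vectorized over rows
transcript_sequence <- function(model, tss_idx, donor_idx = NA_integer_,
                                acceptor_idx = NA_integer_, trunc_offset = 0L) {
  L <- model$length
  n <- max(length(tss_idx), 1L)
  donor_idx <- rep_len(donor_idx, n); acceptor_idx <- rep_len(acceptor_idx, n)
  trunc_offset <- rep_len(trunc_offset, n)
  start1 <- tss_idx + trunc_offset
  end1 <- ifelse(is.na(donor_idx), L, donor_idx)
  seg1len <- end1 - tss_idx + 1L
  # truncation can run past the splice junction
  in2 <- !is.na(donor_idx) & start1 > end1
  s1 <- substring(model$ref, pmin(start1, end1 + 1L), end1)
  s2 <- ifelse(is.na(acceptor_idx), "",
               substring(model$ref,
                         ifelse(in2, acceptor_idx + (start1 - end1 - 1L), acceptor_idx),
                         L))
  paste0(s1, s2)
}

#' Simulate a multiplexed 5'-RACE sequencing library
#'
#' Turns transcript templates into FASTQ-ready reads: ligation-eligible
#' (capped) templates receive the full cap-oligo at the 5' end, fragments are
#' drawn from the configured shear-size window, only a `label_retention`
#' fraction of capped fragments keeps the oligo-TSS junction, each read gets
#' its sample's MID prefix, sequencing errors are injected at the configured
#' per-nt rates (indels multiplied inside homopolymer runs), and per-cycle
#' Phred qualities follow the configured decay profile.
#'
#' @param transcripts Output of [simulate_transcripts()].
#' @param model A [gene_model()].
#' @param cfg The same [sim_config()].
#' @return A `race_reads` tibble (`read_id`, `sample_id`, `sequence`,
#'   `quality`) with attributes `truth` (per-read ground truth: true TSS, cap
#'   and label status, splice chain, injected edit counts) and
#'   `true_counts` (realized per-sample TSS counts over capped, labelled
#'   reads).
#' @export
simulate_library <- function(transcripts, model, cfg) {
  stopifnot(inherits(model, "gene_model"), inherits(cfg, "sim_config"))
  samples <- cfg$samples %||% names(model$mids)
  if (!length(samples)) stop("no samples: gene model has no MIDs", call. = FALSE)
  if (!all(samples %in% names(model$mids))) {
    stop("samples absent from gene model MIDs", call. = FALSE)
  }
  n <- nrow(transcripts)
  olen <- nchar(model$oligo_seq)

  if (n == 0L) {
    out <- tibble::tibble(read_id = character(), sample_id = character(),
                          sequence = character(), quality = character())
    attr(out, "truth") <- tibble::tibble(
      read_id = character(), sample_id = character(), tss_rel = integer(),
      capped = logical(), labelled = logical(), donor = character(),
      acceptor = character(), n_sub = integer(), n_ins = integer(),
      n_del = integer())
    attr(out, "true_counts") <- tibble::tibble(
      sample_id = character(), tss_rel = integer(), count = integer())
    class(out) <- c("race_reads", class(out))
    return(out)
  }

  withr::with_seed(cfg$seed + 1L, {
    sample_id <- sample(samples, n, replace = TRUE)
    labelled <- transcripts$capped & (stats::runif(n) < cfg$label_retention)
    frag_len <- sample(cfg$shear_min:cfg$shear_max, n, replace = TRUE)

    full_len <- transcripts$length + ifelse(transcripts$capped, olen, 0L)
    start <- integer(n)
    start[labelled] <- 1L
    lost <- transcripts$capped & !labelled
    if (any(lost)) {
      lo <- olen + 1L
      hi <- pmax(lo, full_len[lost] - cfg$shear_min)
      start[lost] <- lo + as.integer(floor(stats::runif(sum(lost)) * (hi - lo + 1L)))
    }
    if (any(!transcripts$capped)) {
      hi <- pmax(1L, full_len[!transcripts$capped] - cfg$shear_min)
      start[!transcripts$capped] <- 1L +
        as.integer(floor(stats::runif(sum(!transcripts$capped)) * hi))
    }
    start <- pmin(start, full_len)
    end <- pmin(start + frag_len - 1L, full_len)

    # fragment sequence in template space: [oligo | transcript]
    o_part <- ifelse(transcripts$capped & start <= olen,
                     substring(model$oligo_seq, start, pmin(end, olen)), "")
    t_start <- pmax(1L, start - ifelse(transcripts$capped, olen, 0L))
    t_end <- end - ifelse(transcripts$capped, olen, 0L)
    t_part <- character(n)
    has_t <- t_end >= t_start
    if (any(has_t)) {
      tx <- transcripts[has_t, ]
      c1 <- tx$tss_idx + tx$trunc_offset + t_start[has_t] - 1L  # transcript->region, segment 1
      e1 <- ifelse(is.na(tx$donor_idx), model$length, tx$donor_idx)
      seg1_left <- e1 - c1 + 1L  # bases available before the junction
      want <- t_end[has_t] - t_start[has_t] + 1L
      take1 <- pmax(0L, pmin(seg1_left, want))
      s1 <- substring(model$ref, pmin(c1, e1 + 1L), c1 + take1 - 1L)
      rem <- want - take1
      off2 <- pmax(0L, c1 - e1 - 1L)  # fragment starts past the junction
      s2 <- ifelse(rem > 0L & !is.na(tx$acceptor_idx),
                   substring(model$ref, tx$acceptor_idx + off2,
                             pmin(tx$acceptor_idx + off2 + rem - 1L, model$length)),
                   "")
      t_part[has_t] <- paste0(s1, s2)
    }
    seqs <- paste0(unname(model$mids[sample_id]), o_part, t_part)

    protect <- NULL
    if (isTRUE(cfg$clean_junction)) {
      mid_len <- nchar(model$mids[sample_id])
      protect <- list(
        start = ifelse(labelled, mid_len + olen - 2L, 0L),
        end = ifelse(labelled, mid_len + olen + 3L, -1L))
    }
    err <- inject_errors(seqs, cfg$insertion_rate, cfg$deletion_rate,
                         cfg$substitution_rate,
                         cfg$homopolymer_indel_multiplier, protect)
  })

  quality <- quality_strings(nchar(err$seqs), cfg$q_start, cfg$q_decay, cfg$q_min)
  read_id <- sprintf("r%07d", seq_len(n))
  out <- tibble::tibble(read_id = read_id, sample_id = sample_id,
                        sequence = err$seqs, quality = quality)
  truth <- tibble::tibble(
    read_id = read_id, sample_id = sample_id,
    tss_rel = transcripts$tss_rel, capped = transcripts$capped,
    labelled = labelled, donor = transcripts$donor,
    acceptor = transcripts$acceptor,
    n_sub = err$n_sub, n_ins = err$n_ins, n_del = err$n_del)
  attr(out, "truth") <- truth
  attr(out, "true_counts") <- dplyr::count(
    dplyr::filter(truth, .data$capped, .data$labelled),
    .data$sample_id, .data$tss_rel, name = "count")
  class(out) <- c("race_reads", class(out))
  out
}

#' Simulate a complete 5'-RACE library in one call
#'
#' @inheritParams simulate_transcripts
#' @return As [simulate_library()].
#' @export
simulate_race_library <- function(model, cfg) {
  simulate_library(simulate_transcripts(model, cfg), model, cfg)
}

# vectorized error injection over a character vector of reads; returns new
# sequences plus per-read injected edit counts. `protect` optionally gives
# per-read 1-based [start, end] windows shielded from indels (the oligo-TSS
# junction of labelled reads).
inject_errors <- function(seqs, ins_rate, del_rate, sub_rate, hp_mult,
                          protect = NULL) {
  n <- length(seqs)
  zero <- integer(n)
  if ((ins_rate + del_rate + sub_rate) == 0 || n == 0L || all(!nzchar(seqs))) {
    return(list(seqs = seqs, n_sub = zero, n_ins = zero, n_del = zero))
  }
  chars <- strsplit(seqs, "", fixed = TRUE)
  lens <- lengths(chars)
  rid <- rep.int(seq_len(n), lens)
  x <- unlist(chars, use.names = FALSE)
  m <- length(x)

  same_prev <- c(FALSE, x[-1] == x[-m] & rid[-1] == rid[-m])
  in_hp <- same_prev | c(same_prev[-1], FALSE)
  boost <- ifelse(in_hp, hp_mult, 1)
  if (!is.null(protect)) {
    pos <- sequence(lens)
    shielded <- pos >= protect$start[rid] & pos <= protect$end[rid]
    boost[shielded] <- 0
  }

  del <- stats::runif(m) < pmin(0.5, del_rate * boost)
  sub <- !del & stats::runif(m) < sub_rate
  ins <- stats::runif(m) < pmin(0.5, ins_rate * boost)

  alpha <- c("A", "C", "G", "T")
  if (any(sub)) {
    shift <- sample.int(3L, sum(sub), replace = TRUE)
    x[sub] <- alpha[((match(x[sub], alpha) - 1L + shift) %% 4L) + 1L]
  }
  ins_base <- if (any(ins)) alpha[sample.int(4L, sum(ins), replace = TRUE)] else character()

  emit <- as.integer(!del) + as.integer(ins)  # original (if kept), then inserted base
  idx_rep <- rep.int(seq_len(m), emit)
  out <- x[idx_rep]
  if (any(ins)) {
    slot <- cumsum(emit)[ins]  # last emitted slot of each inserting position
    out[slot] <- ins_base
  }
  rid_out <- rid[idx_rep]
  pieces <- vapply(split(out, factor(rid_out, levels = seq_len(n))),
                   paste, character(1), collapse = "")
  list(seqs = unname(pieces),
       n_sub = as.integer(tabulate(rid[sub], nbins = n)),
       n_ins = as.integer(tabulate(rid[ins], nbins = n)),
       n_del = as.integer(tabulate(rid[del], nbins = n)))
}

quality_strings <- function(lens, q_start, q_decay, q_min) {
  if (!length(lens)) return(character())
  maxlen <- max(lens, 1L)
  q <- pmax(q_min, round(q_start - q_decay * (seq_len(maxlen) - 1)))
  full <- intToUtf8(pmin(q, 93) + 33L)
  substring(full, 1L, lens)
}

#' Read and write FASTQ as tibbles
#'
#' Thin wrappers around [Biostrings] FASTQ support, converting between the
#' on-disk format (Sanger/Phred+33) and the tibble representation used
#' throughout the package.
#'
#' @param reads A tibble with columns `read_id`, `sequence`, `quality`.
#' @param path FASTQ file path.
#' @return `read_fastq()` returns a tibble (`read_id`, `sequence`,
#'   `quality`); `write_fastq()` returns `path` invisibly.
#' @export
write_fastq <- function(reads, path) {
  if (nrow(reads) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  dna <- Biostrings::DNAStringSet(stats::setNames(reads$sequence, reads$read_id))
  qs <- Biostrings::QualityScaledDNAStringSet(
    dna, Biostrings::PhredQuality(reads$quality))
  Biostrings::writeQualityScaledXStringSet(qs, path)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  if (file.size(path) == 0) {
    return(tibble::tibble(read_id = character(), sequence = character(),
                          quality = character()))
  }
  qs <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  tibble::tibble(read_id = sub("\\s.*$", "", names(qs)),
                 sequence = unname(as.character(qs)),
                 quality = unname(as.character(Biostrings::quality(qs))))
}

#' Write simulator ground truth as a TSV sidecar
#'
#' @param reads A `race_reads` object from [simulate_library()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(reads, path) {
  truth <- attr(reads, "truth")
  if (is.null(truth)) stop("reads carry no ground truth", call. = FALSE)
  readr::write_tsv(truth, path)
  invisible(path)
}
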