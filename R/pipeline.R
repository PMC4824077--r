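#' Run the full 5'-RACE TSS pipeline
#'
#' Orchestrates capture (MID demultiplexing + cap-oligo selection), mapping
#' (spliced TSS alignment), quantification (count table, TMM normalisation,
#' noise cut-off, locus clustering, replicate concordance, depth check) and,
#' when the design has conditions with replicates, differential TSS usage.
#' All intermediate tables are persisted in standard formats and a run
#' manifest records configuration, input digests, the read funnel and output
#' digests. Reruns with identical config and inputs produce byte-identical
#' TSV/BED/bedGraph/JSON analysis outputs (the manifest additionally carries
#' a timestamp).
#'
#' The configuration (YAML file or list) names the gene model, the
#' multiplexed FASTQ file(s), the sample sheet and the numeric parameters:
#'
#' \preformatted{
#' gene_model: model.yaml
#' fastq: library.fastq
#' samples:
#'   - {id: s1, condition: A, replicate: 1}
#'   - {id: s2, condition: A, replicate: 2}
#' params: {min_suffix: 8, cutoff_pct: 0.1, max_gap: 1, alpha: 0.05}
#' }
#'
#' @param config Path to a YAML run configuration, or an equivalent list.
#' @param out_dir Output directory (default: `out_dir` from the config, or
#'   `"racetss_out"`).
#' @return A `race_run` list: `model`, `qc`, `calls`, `counts`, `validity`,
#'   `loci`, `concordance`, `depth`, `diff`, `discriminatory`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    cfg_dir <- dirname(config)
    config <- yaml::read_yaml(config)
  } else {
    cfg_dir <- "."
  }
  if (is.null(config$gene_model)) {
    stop("pipeline config must name a gene_model", call. = FALSE)
  }
  if (is.null(config$fastq)) stop("pipeline config must name fastq input", call. = FALSE)
  if (is.null(config$samples)) stop("pipeline config must list samples", call. = FALSE)

  p <- pipeline_params(config$params)
  out_dir <- out_dir %||% config$out_dir %||% "racetss_out"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  resolve <- function(f) if (file.exists(f)) f else file.path(cfg_dir, f)
  model_path <- resolve(config$gene_model)
  fastq_paths <- vapply(unlist(config$fastq), resolve, character(1))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  model <- stage("gene_model", read_gene_model(model_path))
  sheet <- dplyr::bind_rows(lapply(config$samples, tibble::as_tibble))
  if (!all(c("id", "condition") %in% names(sheet))) {
    stop("each sample needs at least 'id' and 'condition'", call. = FALSE)
  }
  if (!all(sheet$id %in% names(model$mids))) {
    stop("sample id(s) without MID in the gene model: ",
         paste(setdiff(sheet$id, names(model$mids)), collapse = ", "),
         call. = FALSE)
  }
  groups <- stats::setNames(sheet$condition, sheet$id)

  reads <- stage("read_fastq",
                 dplyr::bind_rows(lapply(fastq_paths, read_fastq)))
  tagged <- stage("capture", tag_reads(
    reads, model, max_mid_mismatch = p$max_mid_mismatch,
    min_suffix = p$min_suffix, max_mismatch = p$oligo_max_mismatch,
    search_window = p$search_window))
  tagged <- dplyr::filter(tagged, .data$sample_id %in% sheet$id)
  qc <- qc_reads(tagged, min_len = p$min_read_len)

  calls <- stage("mapping", call_tss(
    tagged, model, max_edit_frac = p$max_edit_frac,
    min_read_len = p$min_read_len))
  counts <- stage("quantify", count_tss(calls))

  multi <- length(sample_names(counts)) >= 2
  if (multi) {
    counts <- stage("tmm", tryCatch(
      tmm_normalize(counts),
      error = function(e) {
        # degenerate overlap: fall back to unit factors, as recommended
        attr(counts, "tmm_factors") <-
          stats::setNames(rep(1, length(sample_names(counts))),
                          sample_names(counts))
        counts
      }))
  }
  validity <- stage("cutoff", apply_cutoff(
    counts, cutoff_pct = p$cutoff_pct, mode = p$cutoff_mode, groups = groups))
  valid_pos <- attr(validity, "valid_positions")
  loci <- stage("loci", call_loci(valid_pos, max_gap = p$max_gap,
                                  model = model, table = counts))
  concord <- if (multi) stage("concordance", replicate_concordance(validity))
  region_len <- if (length(valid_pos) > 1) {
    diff(range(gf_index(model, to_genomic(valid_pos, model)))) + 1L
  } else {
    model$length
  }
  depth <- depth_check(sum(attr(counts, "library_sizes")), region_len,
                       factor = p$depth_factor)

  diffs <- NULL; disc <- NULL
  conds <- split(sheet$id, sheet$condition)
  if (length(conds) >= 2 && any(lengths(conds) >= 2) && multi) {
    null <- stage("diff", build_null(counts, groups,
                                     pseudo_freq = p$pseudo_freq))
    pairs <- utils::combn(names(conds), 2)
    diffs <- lapply(seq_len(ncol(pairs)), function(j) {
      test_pairwise(counts, groups, null, pairs[, j], alpha = p$alpha,
                    pseudo_freq = p$pseudo_freq)
    })
    names(diffs) <- apply(pairs, 2, paste, collapse = "_vs_")
    disc <- stage("discriminatory", select_discriminatory(
      diffs, counts, groups, k = p$k_discriminatory,
      pseudo_freq = p$pseudo_freq))
  }

  paths <- write_outputs(out_dir, model, qc, calls, counts, validity, loci,
                         concord, depth, diffs, disc)
  manifest <- list(
    tool = "racetss",
    version = as.character(utils::packageVersion("racetss")),
    generated = format(Sys.time(), tz = "UTC", usetz = TRUE),
    config = config,
    params = p,
    inputs = as.list(tools::md5sum(c(model_path, fastq_paths))),
    funnel = qc$funnel,
    mapping = attr(calls, "mapping_summary"),
    outputs = as.list(tools::md5sum(unlist(paths))))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  structure(list(model = model, qc = qc, calls = calls, counts = counts,
                 validity = validity, loci = loci, concordance = concord,
                 depth = depth, diff = diffs, discriminatory = disc,
                 manifest = manifest, out_dir = out_dir,
                 output_paths = paths),
            class = "race_run")
}

pipeline_params <- function(params) {
  defaults <- list(
    min_suffix = 8L, max_mid_mismatch = 0L, oligo_max_mismatch = 0L,
    search_window = 5L, max_edit_frac = 0.1, min_read_len = 20L,
    cutoff_pct = 0.1, cutoff_mode = "per_sample", max_gap = 1L,
    depth_factor = 50, alpha = 0.05, k_discriminatory = 30L,
    pseudo_freq = 0.05)
  if (!is.null(params)) {
    unknown <- setdiff(names(params), names(defaults))
    if (length(unknown)) {
      stop("unknown pipeline parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    defaults[names(params)] <- params
  }
  defaults
}

write_outputs <- function(out_dir, model, qc, calls, counts, validity, loci,
                          concord, depth, diffs, disc) {
  fp <- function(...) file.path(out_dir, ...)
  paths <- list()

  jsonlite::write_json(list(funnel = qc$funnel,
                            quality_by_cycle = qc$quality_by_cycle),
                       fp("qc.json"), auto_unbox = TRUE, digits = NA)
  paths$qc <- fp("qc.json")

  readr::write_tsv(calls, fp("tss_calls.tsv"))
  paths$calls <- fp("tss_calls.tsv")

  readr::write_tsv(tibble::as_tibble(counts), fp("counts_raw.tsv"))
  paths$counts <- fp("counts_raw.tsv")
  readr::write_tsv(tss_frequencies(counts), fp("frequencies.tsv"))
  paths$frequencies <- fp("frequencies.tsv")

  readr::write_tsv(tibble::as_tibble(validity), fp("validity.tsv"))
  paths$validity <- fp("validity.tsv")

  for (s in sample_names(counts)) {
    f <- dplyr::filter(tss_frequencies(counts), .data$sample_id == s,
                       .data$count > 0)
    gr <- GenomicRanges::GRanges(
      seqnames = model$chrom,
      ranges = IRanges::IRanges(start = to_genomic(f$tss_rel, model), width = 1),
      score = f$frequency)
    gr <- GenomicRanges::sort(gr)
    path <- fp(paste0(s, ".bedGraph"))
    rtracklayer::export(gr, path, format = "bedGraph")
    paths[[paste0("bedgraph_", s)]] <- path
  }

  if (nrow(loci)) {
    g1 <- to_genomic(loci$start_rel, model)
    g2 <- to_genomic(loci$end_rel, model)
    lf <- attr(loci, "locus_frequencies")
    score <- if (!is.null(lf)) {
      mean_tot <- dplyr::summarise(dplyr::group_by(lf, .data$locus_id),
                                   f = mean(.data$total_frequency),
                                   .groups = "drop")
      pmin(1000L, as.integer(round(
        10 * mean_tot$f[match(loci$locus_id, mean_tot$locus_id)])))
    } else rep(0L, nrow(loci))
    gr <- GenomicRanges::GRanges(
      seqnames = model$chrom,
      ranges = IRanges::IRanges(start = pmin(g1, g2), end = pmax(g1, g2)),
      strand = model$strand, name = loci$locus_id, score = score)
    gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
    rtracklayer::export(gr, fp("loci.bed"), format = "BED")
  } else {
    file.create(fp("loci.bed"))
  }
  paths$loci_bed <- fp("loci.bed")
  readr::write_tsv(dplyr::select(tibble::as_tibble(loci), -"members"),
                   fp("loci.tsv"))
  paths$loci_tsv <- fp("loci.tsv")

  if (!is.null(concord)) {
    jsonlite::write_json(
      list(shared = concord$shared,
           unique_counts = as.list(concord$unique_counts),
           shared_mass = as.list(concord$shared_mass)),
      fp("concordance.json"), auto_unbox = TRUE, digits = NA)
    paths$concordance <- fp("concordance.json")
  }
  readr::write_tsv(depth, fp("depth_check.tsv"))
  paths$depth <- fp("depth_check.tsv")

  if (!is.null(diffs)) {
    for (nm in names(diffs)) {
      path <- fp(paste0("diff_", nm, ".tsv"))
      readr::write_tsv(tibble::as_tibble(diffs[[nm]]), path)
      paths[[paste0("diff_", nm)]] <- path
    }
  }
  if (!is.null(disc) && nrow(disc$positions)) {
    mat <- tibble::as_tibble(disc$matrix)
    mat <- dplyr::bind_cols(tibble::tibble(tss_rel = rownames(disc$matrix)), mat)
    readr::write_tsv(mat, fp("discriminatory.tsv"))
    paths$discriminatory <- fp("discriminatory.tsv")
    trees <- export_newick(disc, fp("discriminatory_tss.nwk"),
                           fp("discriminatory_samples.nwk"))
    for (t in trees) paths[[basename(t)]] <- t
  }
  paths
}

#' @export
print.race_run <- function(x, ...) {
  cat("<race_run>", x$model$name, "\n")
  cat(sprintf("  %d labelled read(s), %d aligned call(s), %d valid TSS(s), %d locus/loci\n",
              sum(x$qc$funnel$labelled), nrow(x$calls),
              length(attr(x$validity, "valid_positions")), nrow(x$loci)))
  cat("  outputs in", x$out_dir, "\n")
  invisible(x)
}

#' @exportS3Method generics::glance
glance.race_run <- function(x, ...) {
  tibble::tibble(
    labelled = sum(x$qc$funnel$labelled),
    mapped = nrow(x$calls),
    valid_tss = length(attr(x$validity, "valid_positions")),
    loci = nrow(x$loci),
    depth_status = x$depth$status)
}

#' Read a simulator configuration from YAML
#'
#' Keys mirror the [sim_config()] arguments; `tss` is a map of gene-relative
#' position to probability and `splice` a map of position to
#' `[donor, acceptor]` site names, e.g.:
#'
#' \preformatted{
#' tss: {"-701": 0.4, "-650": 0.35, "-300": 0.25}
#' splice: {"-701": [F, ex2]}
#' depth: 20000
#' seed: 11
#' capped_fraction: 0.9
#' }
#'
#' @param path YAML file.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$tss)) stop("sim config needs a 'tss' map", call. = FALSE)
  tss <- unlist(y$tss)
  splice <- lapply(y$splice %||% list(), unlist)
  extra <- y[setdiff(names(y), c("tss", "splice"))]
  do.call(sim_config, c(list(tss = tss, splice = splice), extra))
}

#' Simulate a library and write FASTQ plus ground truth
#'
#' Convenience wrapper for the command-line `simulate` subcommand: runs the
#' simulator and writes the multiplexed FASTQ and the ground-truth TSV
#' sidecar.
#'
#' @param model A [gene_model()] or path to a gene model YAML.
#' @param cfg A [sim_config()].
#' @param fastq_path,truth_path Output paths.
#' @return The `race_reads` tibble, invisibly.
#' @export
simulate_to_files <- function(model, cfg, fastq_path, truth_path = NULL) {
  if (is.character(model)) model <- read_gene_model(model)
  reads <- simulate_race_library(model, cfg)
  write_fastq(reads, fastq_path)
  if (!is.null(truth_path)) write_truth(reads, truth_path)
  invisible(reads)
}
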