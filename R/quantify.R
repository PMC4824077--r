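#' Build a TSS count table from per-read calls
#'
#' Counts reads per (gene-relative TSS position, sample). The table is dense
#' on observed positions: every called position appears for every sample,
#' with zeros where unobserved. Library sizes are the per-sample totals of
#' mapped oligo-labelled reads (the column sums), which is also the
#' denominator of the percent frequencies used throughout.
#'
#' @param calls A `tss_calls` tibble (aligned calls) from [call_tss()].
#' @return A `tss_counts` tibble: `tss_rel` plus one count column per sample,
#'   with attributes `library_sizes` and (after [tmm_normalize()])
#'   `tmm_factors`.
#' @export
count_tss <- function(calls) {
  calls <- dplyr::filter(calls, is.na(.data$status) | .data$status == "aligned")
  long <- dplyr::count(calls, .data$tss_rel, .data$sample_id, name = "count")
  wide <- tidyr::pivot_wider(long, names_from = "sample_id",
                             values_from = "count", values_fill = 0L,
                             names_sort = TRUE)
  wide <- dplyr::arrange(wide, .data$tss_rel)
  new_tss_counts(wide)
}

new_tss_counts <- function(wide, tmm_factors = NULL) {
  samples <- setdiff(names(wide), "tss_rel")
  lib <- vapply(wide[samples], sum, numeric(1))
  structure(wide,
            library_sizes = lib,
            tmm_factors = tmm_factors,
            class = c("tss_counts", class(tibble::as_tibble(wide))))
}

#' @export
print.tss_counts <- function(x, ...) {
  cat(sprintf("<tss_counts> %d position(s) x %d sample(s)\n",
              nrow(x), length(sample_names(x))))
  lib <- attr(x, "library_sizes")
  cat("  library sizes:", paste(names(lib), lib, sep = "=", collapse = ", "), "\n")
  tf <- attr(x, "tmm_factors")
  if (!is.null(tf)) {
    cat("  TMM factors:", paste(names(tf), signif(tf, 4), sep = "=",
                                collapse = ", "), "\n")
  }
  NextMethod()
}

sample_names <- function(table) setdiff(names(table), "tss_rel")

counts_matrix <- function(table) {
  m <- as.matrix(table[sample_names(table)])
  rownames(m) <- table$tss_rel
  m
}

#' Per-sample TSS frequencies
#'
#' Raw frequencies are `count / library size * 100` and sum to 100% per
#' sample. Normalised frequencies divide by the TMM-scaled effective library
#' size (`library size * factor`).
#'
#' @param table A `tss_counts` table.
#' @param normalized Use TMM-scaled library sizes (requires
#'   [tmm_normalize()]).
#' @return Long tibble: `tss_rel`, `sample_id`, `count`, `frequency` (%).
#' @export
tss_frequencies <- function(table, normalized = FALSE) {
  lib <- attr(table, "library_sizes")
  if (normalized) {
    tf <- attr(table, "tmm_factors")
    if (is.null(tf)) stop("table has no TMM factors; run tmm_normalize()",
                          call. = FALSE)
    lib <- lib * tf[names(lib)]
  }
  long <- tidyr::pivot_longer(tibble::as_tibble(table), -"tss_rel",
                              names_to = "sample_id", values_to = "count")
  long$frequency <- 100 * long$count / unname(lib[long$sample_id])
  long
}

#' @exportS3Method generics::tidy
tidy.tss_counts <- function(x, normalized = !is.null(attr(x, "tmm_factors")),
                            ...) {
  tss_frequencies(x, normalized = normalized)
}

#' @exportS3Method generics::glance
glance.tss_counts <- function(x, ...) {
  tibble::tibble(n_positions = nrow(x), n_samples = length(sample_names(x)),
                 total_reads = sum(attr(x, "library_sizes")),
                 normalized = !is.null(attr(x, "tmm_factors")))
}

#' Trimmed mean of M-values (TMM) normalisation
#'
#' Computes between-sample scaling factors from trimmed log2 ratios of
#' relative TSS frequencies, following the published TMM recipe: M-values
#' (log2 relative-frequency ratios versus a reference sample) and A-values
#' (mean log2 relative frequency) over positions nonzero in both samples;
#' the 30% most extreme M and 5% most extreme A are trimmed; the factor is
#' 2 to the precision-weighted mean of the surviving M-values, with inverse
#' asymptotic (delta-method binomial) variances as weights; factors are
#' rescaled to geometric mean 1. Unless given, the reference sample is the
#' one whose 75th-percentile relative frequency is closest to the
#' across-sample mean.
#'
#' @param table A `tss_counts` table with at least 2 samples.
#' @param ref_sample Optional reference sample id.
#' @param logratio_trim,sum_trim Trim fractions for M and A (defaults 0.30
#'   and 0.05, the published defaults).
#' @param min_common Minimum number of positions nonzero in both the sample
#'   and the reference (default 10); below it normalisation fails with a
#'   suggestion to fall back to factors of 1.
#' @return The table with a `tmm_factors` attribute (geometric mean 1).
#' @export
tmm_normalize <- function(table, ref_sample = NULL, logratio_trim = 0.30,
                          sum_trim = 0.05, min_common = 10L) {
  m <- counts_matrix(table)
  lib <- attr(table, "library_sizes")
  samples <- colnames(m)
  if (length(samples) < 2) stop("TMM needs at least 2 samples", call. = FALSE)
  if (any(lib <= 0)) stop("every sample needs a positive library size", call. = FALSE)

  if (is.null(ref_sample)) {
    f75 <- apply(m, 2, stats::quantile, probs = 0.75) / lib
    ref_sample <- samples[which.min(abs(f75 - mean(f75)))]
  }
  if (!ref_sample %in% samples) stop("unknown ref_sample", call. = FALSE)
  refc <- m[, ref_sample]
  nR <- lib[[ref_sample]]

  factors <- vapply(samples, function(s) {
    obs <- m[, s]; nO <- lib[[s]]
    common <- sum(obs > 0 & refc > 0)
    if (common < min_common) {
      stop("only ", common, " position(s) nonzero in both '", s, "' and '",
           ref_sample, "' (need ", min_common,
           "); consider factors of 1 instead", call. = FALSE)
    }
    logR <- log2((obs / nO) / (refc / nR))
    absE <- (log2(obs / nO) + log2(refc / nR)) / 2
    v <- (nO - obs) / (nO * obs) + (nR - refc) / (nR * refc)
    fin <- is.finite(logR) & is.finite(absE)
    logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
    if (!length(logR) || max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * logratio_trim) + 1; hiL <- n + 1 - loL
    loS <- floor(n * sum_trim) + 1; hiS <- n + 1 - loS
    keep <- (rank(logR) >= loL & rank(logR) <= hiL) &
      (rank(absE) >= loS & rank(absE) <= hiS)
    f <- sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
    if (!is.finite(f)) f <- 0
    2^f
  }, numeric(1))

  factors <- factors / exp(mean(log(factors)))
  attr(table, "tmm_factors") <- stats::setNames(factors, samples)
  table
}

#' Apply the noise cut-off to a TSS frequency table
#'
#' TSSs below the frequency cut-off are background noise of the 5' labelling
#' technique and are removed. The boundary is inclusive: a TSS at exactly
#' the cut-off survives ("below cut-off removed"). Two modes:
#' `per_sample` (default) validates each (position, sample) independently;
#' `all_replicates` validates a position for a condition only when it meets
#' the cut-off in every replicate of that condition, which is the stricter
#' replicate-wise reading.
#'
#' @param table A `tss_counts` table.
#' @param cutoff_pct Frequency cut-off in percent (default 0.1).
#' @param mode `"per_sample"` or `"all_replicates"`.
#' @param groups Named character vector sample id -> condition (needed for
#'   `all_replicates`; defaults to a single condition).
#' @return A `tss_validity` long tibble: `tss_rel`, `sample_id`, `count`,
#'   `frequency`, `valid`; attributes `cutoff_pct`, `mode`,
#'   `noise_fraction` (% of read mass removed per sample) and
#'   `valid_positions` (union of valid positions).
#' @export
apply_cutoff <- function(table, cutoff_pct = 0.1,
                         mode = c("per_sample", "all_replicates"),
                         groups = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(cutoff_pct) || cutoff_pct <= 0 || cutoff_pct >= 100) {
    stop("cutoff_pct must be in (0, 100)", call. = FALSE)
  }
  long <- tss_frequencies(table)
  if (mode == "per_sample") {
    long$valid <- long$frequency >= cutoff_pct
  } else {
    samples <- sample_names(table)
    if (is.null(groups)) groups <- stats::setNames(rep("all", length(samples)), samples)
    long$condition <- groups[long$sample_id]
    long <- dplyr::mutate(
      dplyr::group_by(long, .data$tss_rel, .data$condition),
      valid = all(.data$frequency >= cutoff_pct))
    long <- dplyr::select(dplyr::ungroup(long), -"condition")
  }
  noise <- dplyr::summarise(
    dplyr::group_by(long, .data$sample_id),
    noise_fraction = sum(.data$frequency[!.data$valid]),
    .groups = "drop")
  out <- long
  attr(out, "cutoff_pct") <- cutoff_pct
  attr(out, "mode") <- mode
  attr(out, "noise_fraction") <- stats::setNames(noise$noise_fraction,
                                                 noise$sample_id)
  attr(out, "valid_positions") <- sort(unique(long$tss_rel[long$valid]))
  class(out) <- c("tss_validity", class(out))
  out
}

#' Estimate the noise cut-off from the survivors curve
#'
#' Counts how many TSSs survive each candidate cut-off, then fits a
#' continuous two-segment linear model to (log10 cut-off, survivors) by
#' exhaustive breakpoint search minimising total SSE. The steep phase at low
#' cut-offs is noise being removed; the flat phase is genuine TSSs; the
#' recommended cut-off is the abscissa where the two regression phases
#' intersect.
#'
#' @param table A `tss_counts` table.
#' @param grid Candidate cut-offs in percent; at least 6 points spanning at
#'   least 2 decades (default: 25 log-spaced points over 0.001%-10%).
#' @return A `cutoff_estimate`: list with `curve` (tibble `cutoff_pct`,
#'   `survivors`), `breakpoint` (recommended cut-off, %), `fit_sse`, and the
#'   fitted segment slopes.
#' @export
estimate_cutoff <- function(table, grid = 10^seq(-3, 1, length.out = 25)) {
  if (length(grid) < 6) stop("grid needs at least 6 cut-off values", call. = FALSE)
  if (log10(max(grid) / min(grid)) < 2) {
    stop("grid must span at least 2 decades", call. = FALSE)
  }
  grid <- sort(grid)
  long <- tss_frequencies(table)
  maxf <- dplyr::summarise(dplyr::group_by(long, .data$tss_rel),
                           f = max(.data$frequency), .groups = "drop")$f
  survivors <- vapply(grid, function(ct) sum(maxf >= ct), integer(1))
  est <- fit_breakpoint(log10(grid), as.numeric(survivors))
  structure(list(curve = tibble::tibble(cutoff_pct = grid, survivors = survivors),
                 breakpoint = 10^est$xb, fit_sse = est$sse,
                 slopes = est$slopes),
            class = "cutoff_estimate")
}

# continuous two-phase linear fit by exhaustive breakpoint search over the
# interior grid points; returns the breakpoint abscissa and total SSE
fit_breakpoint <- function(x, y) {
  if (diff(range(y)) == 0) {
    stop("survivors constant across the grid: degenerate curve, no breakpoint",
         call. = FALSE)
  }
  n <- length(x)
  cand <- x[2:(n - 1)]
  best <- NULL
  for (xb in cand) {
    left <- pmin(x - xb, 0)
    right <- pmax(x - xb, 0)
    fit <- stats::lm(y ~ left + right)
    sse <- sum(stats::resid(fit)^2)
    if (is.null(best) || sse < best$sse - 1e-12) {
      best <- list(xb = xb, sse = sse,
                   slopes = stats::setNames(stats::coef(fit)[2:3],
                                            c("left", "right")))
    }
  }
  best
}

#' @export
print.cutoff_estimate <- function(x, ...) {
  cat(sprintf("<cutoff_estimate> recommended cut-off %.4g%% (SSE %.4g)\n",
              x$breakpoint, x$fit_sse))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cutoff_estimate <- function(x, ...) x$curve

#' @exportS3Method generics::glance
glance.cutoff_estimate <- function(x, ...) {
  tibble::tibble(breakpoint_pct = x$breakpoint, fit_sse = x$fit_sse,
                 slope_left = x$slopes[["left"]],
                 slope_right = x$slopes[["right"]])
}

#' Cluster adjacent valid TSSs into loci
#'
#' A locus (the unit of TSS microvariability) is a maximal run of valid TSSs
#' in which consecutive members are at most `max_gap` nt apart. Positions
#' are chained greedily left to right. Locus ids are formed from the nearest
#' annotated first-exon donor's name plus an ordinal (e.g. `F1`, `F2`)
#' when a model with named donors is supplied, otherwise `L1`, `L2`, ...
#'
#' @param positions Integer vector of valid gene-relative TSS positions
#'   (e.g. `attr(validity, "valid_positions")`), or a `tss_validity` object.
#' @param max_gap Maximum gap (nt) between consecutive members of one locus.
#'   Default 1 (strict adjacency); 5 is a useful looser preset.
#' @param model Optional [gene_model()] for exon-aware locus naming and
#'   correct adjacency across the anchor (the relative scale has no zero).
#' @param table Optional `tss_counts` to attach per-sample locus frequency
#'   totals.
#' @return A `tss_loci` tibble: `locus_id`, `start_rel`, `end_rel`, `span`,
#'   `n_members`, `members` (list column). With `table`, attribute
#'   `locus_frequencies` holds per-sample total frequencies.
#' @export
call_loci <- function(positions, max_gap = 1L, model = NULL, table = NULL) {
  if (inherits(positions, "tss_validity")) {
    positions <- attr(positions, "valid_positions")
  }
  positions <- sort(unique(as.integer(positions)))
  if (!length(positions)) {
    out <- tibble::tibble(locus_id = character(), start_rel = integer(),
                          end_rel = integer(), span = integer(),
                          n_members = integer(), members = list())
    class(out) <- c("tss_loci", class(out))
    return(out)
  }
  # linear scale without the skip over zero, so -1 and +1 are adjacent
  lin <- ifelse(positions > 0, positions - 1L, positions)
  gap <- diff(lin)
  locus <- cumsum(c(1L, as.integer(gap > max_gap)))

  out <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(pos = positions, locus = locus), .data$locus),
    start_rel = min(.data$pos), end_rel = max(.data$pos),
    span = max(.data$pos) - min(.data$pos) + 1L -
      as.integer(min(.data$pos) < 0 & max(.data$pos) > 0),
    n_members = dplyr::n(), members = list(.data$pos), .groups = "drop")
  out$locus_id <- locus_ids(out, model)
  out <- dplyr::select(out, "locus_id", dplyr::everything(), -"locus")
  if (!is.null(table)) {
    freqs <- tss_frequencies(table)
    memb <- tidyr::unnest(dplyr::select(out, "locus_id", "members"),
                          cols = "members")
    lf <- dplyr::summarise(
      dplyr::group_by(dplyr::inner_join(freqs, memb,
                                        by = c(tss_rel = "members")),
                      .data$locus_id, .data$sample_id),
      total_frequency = sum(.data$frequency), .groups = "drop")
    attr(out, "locus_frequencies") <- lf
  }
  class(out) <- c("tss_loci", class(out))
  out
}

locus_ids <- function(loci, model) {
  n <- nrow(loci)
  if (is.null(model) || !length(model$donor_sites) ||
      is.null(names(model$donor_sites))) {
    return(sprintf("L%d", seq_len(n)))
  }
  donor_rel <- to_relative(unname(model$donor_sites), model)
  mid <- (loci$start_rel + loci$end_rel) / 2
  nearest <- names(model$donor_sites)[
    vapply(mid, function(p) which.min(abs(donor_rel - p)), integer(1))]
  stats::ave(seq_len(n), nearest, FUN = seq_along) -> ord
  paste0(nearest, ord)
}

#' Replicate concordance of valid TSS sets
#'
#' Intersects the valid TSS sets of replicate samples and reports, for each
#' replicate, the fraction of its read mass carried by the shared set,
#' together with a membership matrix suitable for Venn-style reporting.
#'
#' @param validity A `tss_validity` object (cut-off applied).
#' @param samples Samples to compare (default: all, needs >= 2).
#' @return A `race_concordance` list: `shared` (positions valid in every
#'   replicate), `membership` (tibble position x sample logical),
#'   `unique_counts`, `shared_mass` (% of reads per replicate on shared
#'   TSSs).
#' @export
replicate_concordance <- function(validity, samples = NULL) {
  stopifnot(inherits(validity, "tss_validity"))
  samples <- samples %||% sort(unique(validity$sample_id))
  if (length(samples) < 2) stop("need at least 2 replicates", call. = FALSE)
  v <- dplyr::filter(validity, .data$sample_id %in% samples)
  memb <- tidyr::pivot_wider(
    dplyr::select(v, "tss_rel", "sample_id", "valid"),
    names_from = "sample_id", values_from = "valid", values_fill = FALSE)
  memb <- memb[rowSums(as.matrix(memb[samples])) > 0, , drop = FALSE]
  shared <- memb$tss_rel[rowSums(as.matrix(memb[samples])) == length(samples)]
  only_one <- vapply(samples, function(s) {
    m <- as.matrix(memb[samples])
    sum(m[, s] & rowSums(m) == 1L)
  }, integer(1))
  mass <- vapply(samples, function(s) {
    sum(v$frequency[v$sample_id == s & v$tss_rel %in% shared])
  }, numeric(1))
  structure(list(shared = sort(shared), membership = memb,
                 unique_counts = stats::setNames(only_one, samples),
                 shared_mass = stats::setNames(mass, samples)),
            class = "race_concordance")
}

#' @export
print.race_concordance <- function(x, ...) {
  cat(sprintf("<race_concordance> %d shared TSS(s); shared mass: %s\n",
              length(x$shared),
              paste(names(x$shared_mass),
                    sprintf("%.1f%%", x$shared_mass), sep = "=",
                    collapse = ", ")))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.race_concordance <- function(x, ...) x$membership

#' @exportS3Method generics::glance
glance.race_concordance <- function(x, ...) {
  tibble::tibble(n_shared = length(x$shared),
                 mean_shared_mass = mean(x$shared_mass))
}

#' Check sequencing depth against the variable-region rule
#'
#' Adequate depth for detecting microvariable TSSs is a total number of
#' oligo-labelled reads of at least `factor` (default 50) times the length
#' of the variable region.
#'
#' @param labelled_mapped_reads Total labelled mapped reads.
#' @param variable_region_len Length of the variable TSS region in nt.
#' @param factor Required reads per nt of variable region (default 50).
#' @return A tibble: `status` (`"pass"`/`"warn"`), `reads`, `required`,
#'   `deficit`.
#' @export
depth_check <- function(labelled_mapped_reads, variable_region_len,
                        factor = 50) {
  if (variable_region_len <= 0) stop("region length must be positive", call. = FALSE)
  required <- factor * variable_region_len
  tibble::tibble(
    status = ifelse(labelled_mapped_reads >= required, "pass", "warn"),
    reads = labelled_mapped_reads,
    required = required,
    deficit = pmax(0, required - labelled_mapped_reads))
}
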