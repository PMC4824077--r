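#' Build the empirical noise distribution from replicate contrasts
#'
#' For every within-condition replicate pair and every TSS position, records
#' the absolute log2 ratio |M| and the absolute difference D of normalised
#' frequencies (zeros replaced by the pseudo-frequency). Pooled across pairs
#' this is the empirical null against which between-condition contrasts are
#' judged: how large (|M|, D) gets when nothing but technical and sampling
#' noise is at work.
#'
#' @param table A TMM-normalised `tss_counts` table.
#' @param groups Named character vector sample id -> condition; at least one
#'   condition needs >= 2 replicates.
#' @param pseudo_freq Pseudo-frequency (in %) replacing zeros, default half
#'   the standard 0.1% noise cut-off, so condition-unique TSSs remain
#'   testable.
#' @return A `tss_null` tibble (`abs_m`, `d`, `condition`, `pair`) with
#'   attribute `pseudo_freq`.
#' @export
build_null <- function(table, groups, pseudo_freq = 0.05) {
  freqs <- tss_frequencies(table, normalized = TRUE)
  freqs$condition <- groups[freqs$sample_id]
  wide <- tidyr::pivot_wider(
    dplyr::select(freqs, "tss_rel", "sample_id", "frequency"),
    names_from = "sample_id", values_from = "frequency", values_fill = 0)

  conds <- split(names(groups), unname(groups))
  conds <- conds[lengths(conds) >= 2]
  if (!length(conds)) {
    stop("no condition has >= 2 replicates; supply technical-replicate ",
         "tables to estimate the noise distribution", call. = FALSE)
  }
  rows <- list()
  for (cn in names(conds)) {
    reps <- conds[[cn]]
    cmb <- utils::combn(reps, 2)
    for (j in seq_len(ncol(cmb))) {
      a <- pmax(wide[[cmb[1, j]]], pseudo_freq)
      b <- pmax(wide[[cmb[2, j]]], pseudo_freq)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        abs_m = abs(log2(a / b)), d = abs(a - b),
        condition = cn, pair = paste(cmb[, j], collapse = "|"))
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "pseudo_freq") <- pseudo_freq
  class(out) <- c("tss_null", class(out))
  out
}

#' Test differential TSS usage between two conditions
#'
#' For each position the contrast statistic is the (|M|, D) pair computed on
#' condition-mean normalised frequencies (zeros replaced by the
#' pseudo-frequency). The raw probability is the fraction of the empirical
#' null that is jointly at least as extreme (|M| and D both >= observed),
#' adjusted across positions by Benjamini-Hochberg. The empirical null
#' bounds the smallest attainable raw p at 1/(null size); observed contrasts
#' beyond every null point get p = 0.
#'
#' @param table A TMM-normalised `tss_counts` table.
#' @param groups Named character vector sample id -> condition.
#' @param null A `tss_null` from [build_null()].
#' @param pair Character vector of the two condition names to contrast.
#' @param alpha Significance level on the adjusted p (default 0.05).
#' @param pseudo_freq Zero replacement (%); defaults to the null's.
#' @return A `tss_diff` tibble: `tss_rel`, `mean_a`, `mean_b`, `m` (signed
#'   log2 ratio), `d`, `p_raw`, `p_adj`, `significant`; attribute `skipped`
#'   lists positions absent from both conditions.
#' @export
test_pairwise <- function(table, groups, null, pair, alpha = 0.05,
                          pseudo_freq = attr(null, "pseudo_freq")) {
  stopifnot(inherits(null, "tss_null"), length(pair) == 2)
  samples_a <- names(groups)[groups == pair[1]]
  samples_b <- names(groups)[groups == pair[2]]
  if (!length(samples_a) || !length(samples_b)) {
    stop("conditions not found in groups: ", paste(pair, collapse = ", "),
         call. = FALSE)
  }
  freqs <- tss_frequencies(table, normalized = TRUE)
  wide <- tidyr::pivot_wider(
    dplyr::select(freqs, "tss_rel", "sample_id", "frequency"),
    names_from = "sample_id", values_from = "frequency", values_fill = 0)
  mean_a <- rowMeans(wide[samples_a])
  mean_b <- rowMeans(wide[samples_b])

  present <- mean_a > 0 | mean_b > 0
  skipped <- wide$tss_rel[!present]

  fa <- pmax(mean_a[present], pseudo_freq)
  fb <- pmax(mean_b[present], pseudo_freq)
  m <- log2(fa / fb)
  d <- abs(fa - fb)

  nm <- null$abs_m; nd <- null$d
  p_raw <- vapply(seq_along(m), function(i) {
    mean(nm >= abs(m[i]) & nd >= d[i])
  }, numeric(1))
  p_adj <- stats::p.adjust(p_raw, method = "BH")

  out <- tibble::tibble(
    tss_rel = wide$tss_rel[present],
    condition_a = pair[1], condition_b = pair[2],
    mean_a = mean_a[present], mean_b = mean_b[present],
    m = m, d = d, p_raw = p_raw, p_adj = p_adj,
    significant = p_adj <= alpha)
  attr(out, "skipped") <- skipped
  attr(out, "alpha") <- alpha
  class(out) <- c("tss_diff", class(out))
  out
}

#' @exportS3Method generics::tidy
tidy.tss_diff <- function(x, ...) tibble::as_tibble(x)

#' @exportS3Method generics::glance
glance.tss_diff <- function(x, ...) {
  tibble::tibble(n_tested = nrow(x), n_significant = sum(x$significant),
                 n_skipped = length(attr(x, "skipped")),
                 alpha = attr(x, "alpha"))
}

#' Select and cluster the most discriminatory TSSs
#'
#' Candidates are positions significant in at least one pairwise contrast;
#' they are ranked by the across-condition variance of log10(frequency +
#' pseudo-frequency) and the top `k` (default 30) are retained.
#' Agglomerative hierarchical clustering (Euclidean distance, complete
#' linkage) is performed over the selected positions and over the samples on
#' the log10 percent scale.
#'
#' @param results A `tss_diff` or list of `tss_diff` objects (one per
#'   contrast).
#' @param table A TMM-normalised `tss_counts` table.
#' @param groups Named character vector sample id -> condition.
#' @param k Number of TSSs retained (default 30).
#' @param pseudo_freq Zero replacement on the log scale (default 0.05%).
#' @return A `tss_discriminatory` list: `positions` (ranked tibble),
#'   `matrix` (log10 % frequencies, positions x samples), `tss_clust` and
#'   `sample_clust` ([stats::hclust] trees; NULL when fewer than 3 leaves).
#' @export
select_discriminatory <- function(results, table, groups, k = 30L,
                                  pseudo_freq = 0.05) {
  if (inherits(results, "tss_diff")) results <- list(results)
  sig <- sort(unique(unlist(lapply(results, function(r) {
    r$tss_rel[r$significant]
  }))))
  if (!length(sig)) {
    return(structure(list(positions = tibble::tibble(tss_rel = integer(),
                                                     variance = numeric()),
                          matrix = NULL, tss_clust = NULL, sample_clust = NULL),
                     class = "tss_discriminatory"))
  }
  freqs <- tss_frequencies(table, normalized = TRUE)
  freqs <- dplyr::filter(freqs, .data$tss_rel %in% sig)
  freqs$logf <- log10(freqs$frequency + pseudo_freq)
  freqs$condition <- groups[freqs$sample_id]

  cond_means <- dplyr::summarise(
    dplyr::group_by(freqs, .data$tss_rel, .data$condition),
    logf = mean(.data$logf), .groups = "drop")
  ranks <- dplyr::arrange(dplyr::summarise(
    dplyr::group_by(cond_means, .data$tss_rel),
    variance = stats::var(.data$logf), .groups = "drop"),
    dplyr::desc(.data$variance))
  top <- utils::head(ranks, k)

  mat <- tidyr::pivot_wider(
    dplyr::select(dplyr::filter(freqs, .data$tss_rel %in% top$tss_rel),
                  "tss_rel", "sample_id", "logf"),
    names_from = "sample_id", values_from = "logf")
  m <- as.matrix(mat[-1])
  rownames(m) <- mat$tss_rel

  tss_clust <- if (nrow(m) >= 3) {
    stats::hclust(stats::dist(m, method = "euclidean"), method = "complete")
  }
  sample_clust <- if (ncol(m) >= 3) {
    stats::hclust(stats::dist(t(m), method = "euclidean"), method = "complete")
  }
  structure(list(positions = top, matrix = m,
                 tss_clust = tss_clust, sample_clust = sample_clust),
            class = "tss_discriminatory")
}

#' @export
print.tss_discriminatory <- function(x, ...) {
  cat(sprintf("<tss_discriminatory> %d TSS(s) selected\n", nrow(x$positions)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.tss_discriminatory <- function(x, ...) x$positions

#' @exportS3Method generics::glance
glance.tss_discriminatory <- function(x, ...) {
  tibble::tibble(n_selected = nrow(x$positions),
                 n_samples = if (is.null(x$matrix)) 0L else ncol(x$matrix))
}

#' Export linkage trees of a discriminatory set as Newick
#'
#' @param disc A `tss_discriminatory` object.
#' @param tss_path,sample_path Output paths (either may be NULL to skip).
#' @return Invisibly, the paths written.
#' @export
export_newick <- function(disc, tss_path = NULL, sample_path = NULL) {
  written <- character()
  if (!is.null(tss_path) && !is.null(disc$tss_clust)) {
    ape::write.tree(ape::as.phylo(disc$tss_clust), file = tss_path)
    written <- c(written, tss_path)
  }
  if (!is.null(sample_path) && !is.null(disc$sample_clust)) {
    ape::write.tree(ape::as.phylo(disc$sample_clust), file = sample_path)
    written <- c(written, sample_path)
  }
  invisible(written)
}
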