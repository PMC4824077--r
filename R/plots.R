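#' Plot a TSS frequency profile
#'
#' Per-sample TSS frequencies along the gene-relative coordinate, the
#' standard way of displaying start-site microvariability around loci.
#'
#' @param object A `tss_counts` table.
#' @param log_y Show frequencies on a log10 axis (default TRUE; individual
#'   TSS frequencies span several orders of magnitude).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.tss_counts <- function(object, log_y = TRUE, ...) {
  long <- dplyr::filter(tss_frequencies(object), .data$count > 0)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$tss_rel,
                                          y = .data$frequency,
                                          colour = .data$sample_id)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$tss_rel, yend = 0),
                          alpha = 0.6) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "TSS (gene-relative position)", y = "frequency (%)",
                  colour = "sample") +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot the survivors curve of a cut-off estimate
#'
#' Number of surviving TSSs against the candidate cut-off (log scale) with
#' the fitted two-phase breakpoint: the recommended noise cut-off.
#'
#' @param object A `cutoff_estimate`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cutoff_estimate <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$cutoff_pct,
                                             y = .data$survivors)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = object$breakpoint, linetype = "dashed",
                        colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "cut-off (%)", y = "surviving TSSs",
                  title = sprintf("recommended cut-off: %.3g%%",
                                  object$breakpoint)) +
    ggplot2::theme_minimal()
}

#' Plot a differential TSS contrast
#'
#' (M, D) scatter of the contrast: log2 frequency ratio against absolute
#' frequency difference, coloured by significance under the empirical noise
#' distribution.
#'
#' @param object A `tss_diff`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.tss_diff <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$m, y = .data$d,
                               colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7, size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = "M (log2 frequency ratio)",
                  y = "D (absolute frequency difference, %)",
                  title = paste(object$condition_a[1], "vs",
                                object$condition_b[1])) +
    ggplot2::theme_minimal()
}

#' Heatmap of the discriminatory TSS set
#'
#' log10 percent frequencies of the selected TSSs across samples, ordered by
#' the hierarchical clusterings.
#'
#' @param object A `tss_discriminatory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.tss_discriminatory <- function(object, ...) {
  if (is.null(object$matrix)) stop("empty discriminatory set", call. = FALSE)
  m <- object$matrix
  row_ord <- if (!is.null(object$tss_clust)) object$tss_clust$order else seq_len(nrow(m))
  col_ord <- if (!is.null(object$sample_clust)) object$sample_clust$order else seq_len(ncol(m))
  df <- tibble::as_tibble(m[row_ord, col_ord, drop = FALSE], rownames = "tss_rel")
  long <- tidyr::pivot_longer(df, -"tss_rel", names_to = "sample_id",
                              values_to = "logf")
  long$tss_rel <- factor(long$tss_rel, levels = rownames(m)[row_ord])
  long$sample_id <- factor(long$sample_id, levels = colnames(m)[col_ord])
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = .data$tss_rel,
                                     fill = .data$logf)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "log10 % freq") +
    ggplot2::labs(x = NULL, y = "TSS") +
    ggplot2::theme_minimal()
}

#' Plot the capture read funnel
#'
#' Per-sample read counts at each capture stage (assigned, labelled,
#' length-filtered).
#'
#' @param qc A `race_qc` from [qc_reads()].
#' @return A ggplot object.
#' @export
plot_funnel <- function(qc) {
  long <- tidyr::pivot_longer(
    dplyr::select(qc$funnel, "sample_id", "assigned", "labelled",
                  "length_filtered"),
    -"sample_id", names_to = "stage", values_to = "reads")
  long$stage <- factor(long$stage,
                       levels = c("assigned", "labelled", "length_filtered"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$stage, y = .data$reads,
                                     fill = .data$sample_id)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "reads", fill = "sample") +
    ggplot2::theme_minimal()
}
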