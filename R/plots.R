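# ggplot2 views of the result objects. Each autoplot() returns a ggplot
# the caller can restyle.

#' @method autoplot leakage_report
#' @export
autoplot.leakage_report <- function(object, ...) {
  pw <- object$pairwise_shared
  ggplot2::ggplot(pw, ggplot2::aes(x = .data$relation, y = .data$fraction)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.7) +
    ggplot2::labs(
      x = "well-pair relation on the chip",
      y = "shared-sequence fraction  |shared| / min(|a|,|b|)",
      title = "Cross-well sequence sharing by chip geometry",
      subtitle = sprintf("row enrichment %.2f, column enrichment %.2f",
                         object$row_enrichment, object$col_enrichment)
    )
}

#' @method autoplot tss_profile
#' @export
autoplot.tss_profile <- function(object, binwidth = 250, ...) {
  d <- object$distances %>% filter(is.finite(.data$distance))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$distance)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0) +
    ggplot2::geom_vline(xintercept = c(-object$window, object$window),
                        linetype = "dashed") +
    ggplot2::labs(
      x = "read midpoint distance to nearest TSS (bp, signed by strand)",
      y = "reads",
      title = sprintf("TSS profile: %.1f%% of reads within +/-%d bp",
                      100 * object$fraction_within, object$window)
    )
}

#' @method autoplot access_matrix
#' @export
autoplot.access_matrix <- function(object, ...) {
  counts <- tibble(cell = rownames(object$values),
                   n_peaks = rowSums(object$values))
  p <- ggplot2::ggplot(counts, ggplot2::aes(x = .data$n_peaks)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::labs(x = "positive peaks per cell", y = "cells",
                  title = sprintf("Per-cell peak counts (%s matrix)",
                                  if (object$filtered) "filtered" else "unfiltered"))
  if (!is.null(object$thresholds)) {
    p <- p + ggplot2::geom_vline(
      xintercept = c(object$thresholds$min_peaks_per_cell,
                     object$thresholds$max_peaks_per_cell),
      linetype = "dashed"
    )
  }
  p
}

#' @method autoplot covnorm_track
#' @export
autoplot.covnorm_track <- function(object, ...) {
  d <- tidy(object) %>%
    group_by(.data$window_id, .data$chrom, .data$start, .data$arm) %>%
    summarise(mean_covnorm = mean(.data$covnorm), .groups = "drop") %>%
    arrange(.data$chrom, .data$start) %>%
    mutate(idx = dplyr::row_number())
  ggplot2::ggplot(d, ggplot2::aes(x = .data$idx, y = .data$mean_covnorm,
                                  color = .data$arm)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_hline(yintercept = -log(2), linetype = "dashed") +
    ggplot2::labs(
      x = "window (genomic order)", y = "mean normalized coverage",
      title = "GC-matched normalized coverage per window",
      subtitle = "dashed line: hemizygous-loss expectation -ln 2"
    )
}

#' @method autoplot coaccess_result
#' @export
autoplot.coaccess_result <- function(object, top_n = 30, ...) {
  d <- tidy(object) %>%
    slice(seq_len(min(top_n, dplyr::n()))) %>%
    mutate(peak_id = factor(.data$peak_id, levels = rev(.data$peak_id)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$r, y = .data$peak_id)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = "dashed") +
    ggplot2::labs(
      x = sprintf("Pearson r with '%s'", object$query), y = NULL,
      title = sprintf("Co-accessible regions (%d hits at r > %g)",
                      nrow(object$hits), object$threshold)
    )
}
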