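# broom-style tidiers: tidy() returns the per-element table of a result,
# glance() its one-row summary.

#' @method tidy access_matrix
#' @export
tidy.access_matrix <- function(x, ...) {
  tibble(
    peak_id = colnames(x$values),
    n_cells_open = unname(colSums(x$values)),
    fraction_open = unname(colMeans(x$values))
  )
}

#' @method glance access_matrix
#' @export
glance.access_matrix <- function(x, ...) {
  tibble(
    n_cells = nrow(x$values),
    n_peaks = ncol(x$values),
    n_genes = if (is.null(x$gene_view)) NA_integer_ else ncol(x$gene_view),
    density = mean(x$values),
    filtered = x$filtered,
    max_peak_percentile = x$max_peak_percentile
  )
}

#' @method tidy leakage_report
#' @export
tidy.leakage_report <- function(x, ...) {
  x$pairwise_shared
}

#' @method glance leakage_report
#' @export
glance.leakage_report <- function(x, ...) {
  tibble(
    n_wells = x$n_wells,
    n_pairs = nrow(x$pairwise_shared),
    row_enrichment = x$row_enrichment,
    col_enrichment = x$col_enrichment,
    removed_count = x$removed_count,
    removed_fraction = x$removed_fraction
  )
}

#' @method tidy tss_profile
#' @export
tidy.tss_profile <- function(x, ...) {
  x$distances
}

#' @method glance tss_profile
#' @export
glance.tss_profile <- function(x, ...) {
  tibble(
    n_reads = x$n_reads,
    window = x$window,
    fraction_within = x$fraction_within
  )
}

#' @method tidy covnorm_track
#' @export
tidy.covnorm_track <- function(x, ...) {
  as_tibble(x$normalized, rownames = "cell") %>%
    tidyr::pivot_longer(-"cell", names_to = "window_id", values_to = "covnorm") %>%
    left_join(x$windows %>% select("window_id", "chrom", "start", "end", "arm"),
              by = "window_id")
}

#' @method glance covnorm_track
#' @export
glance.covnorm_track <- function(x, ...) {
  tibble(
    n_cells = nrow(x$normalized),
    n_windows = ncol(x$normalized),
    n_masked = length(x$mask),
    n_arms = dplyr::n_distinct(x$windows$arm)
  )
}

#' @method tidy coaccess_result
#' @export
tidy.coaccess_result <- function(x, ...) {
  x$correlations %>% arrange(dplyr::desc(.data$r), .data$peak_id)
}

#' @method glance coaccess_result
#' @export
glance.coaccess_result <- function(x, ...) {
  tibble(
    query = x$query,
    n_cells = x$n_cells,
    n_tested = nrow(x$correlations),
    n_hits = nrow(x$hits),
    threshold = x$threshold
  )
}

#' @method tidy chip_sim
#' @export
tidy.chip_sim <- function(x, ...) {
  x$truth$wells
}

#' @method glance chip_sim
#' @export
glance.chip_sim <- function(x, ...) {
  st <- x$truth$wells$status
  tibble(
    n_wells = length(st),
    n_empty = sum(st == "empty"),
    n_singlet = sum(st == "singlet"),
    n_doublet = sum(st == "doublet"),
    n_reads = nrow(x$reads),
    n_leaked = nrow(x$truth$leaks),
    seed = x$config$rng_seed
  )
}

#' @method tidy pipeline_report
#' @export
tidy.pipeline_report <- function(x, ...) {
  x$attrition
}

#' @method glance pipeline_report
#' @export
glance.pipeline_report <- function(x, ...) {
  tibble(
    seed = x$seed,
    cells = x$matrix$cells_post,
    peaks = x$matrix$peaks_post,
    genes = x$matrix$genes,
    row_enrichment = x$leakage$row_enrichment,
    col_enrichment = x$leakage$col_enrichment,
    leak_removed_fraction = x$leakage$removed_fraction,
    tss_fraction_within_2kb = x$tss_fraction_within_2kb,
    cnv_sensitivity = x$cnv$sensitivity,
    cnv_specificity = x$cnv$specificity,
    coaccess_hits = x$coaccessibility$n_hits
  )
}
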