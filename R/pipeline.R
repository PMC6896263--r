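#' Run the full chip analysis pipeline on a simulated experiment
#'
#' Orchestrates every stage in fixed order on one synthetic chip:
#' simulate, deduplicate within wells, purge cross-well leakage, TSS
#' profile, build the cell x peak matrix against the reference peaks,
#' filter cascade, collapse to genes, marker ranking per true subtype,
#' GC-matched coverage normalization with arm-loss calls, and a
#' co-accessibility query. Because the simulator's ground truth is known,
#' the report also scores the pipeline against it (purge precision/recall,
#' doublet removal, arm-call sensitivity/specificity).
#'
#' All randomness flows from `config$rng_seed`; rerunning with the same
#' configuration gives a byte-identical report.
#'
#' @param config A [chip_config()].
#' @param min_overlap_bp Minimum peak/reference overlap (default 50).
#' @param min_cells_per_peak,min_peaks_per_cell,max_peaks_per_cell Filter
#'   cascade thresholds, scaled to the simulated peak count (defaults 5,
#'   15, 45 for the default 100-peak chip; the canonical full-genome
#'   values are 5, 50, 3000).
#' @param max_substitutions Within-well dedup Hamming radius (default 0).
#' @param promoter_window Peak-to-TSS assignment window (default 2000).
#' @param window_bp,overlap_bp CNV window tiling (defaults 20 kb / 4 kb,
#'   scaled to the simulator's genome; canonical values are 10 Mb / 2 Mb).
#' @param n_background GC-matched background windows per window
#'   (default 15 on the small demo genome; canonical value 100).
#' @param cnv_threshold Arm-loss call threshold (default -0.3).
#' @param coaccess_query Gene to query for co-accessible regions; `NULL`
#'   picks the top specificity-ranked marker of the first group.
#' @param coaccess_threshold Correlation threshold (default 0.2).
#' @param gate Marker gate on `x_pos` (default 10).
#' @param out_dir Optional directory; when given, the report JSON and the
#'   main tables are written there.
#' @return A list of class `pipeline_report`.
#' @export
run_pipeline <- function(config = chip_config(),
                         min_overlap_bp = 50L,
                         min_cells_per_peak = 5L,
                         min_peaks_per_cell = 15L,
                         max_peaks_per_cell = 45L,
                         max_substitutions = 0L,
                         promoter_window = 2000L,
                         window_bp = 20000L,
                         overlap_bp = 4000L,
                         n_background = 15L,
                         cnv_threshold = -0.3,
                         coaccess_query = NULL,
                         coaccess_threshold = 0.2,
                         gate = 10L,
                         out_dir = NULL) {
  ## --- simulate ---------------------------------------------------------
  sim <- simulate_chip(config)
  n_raw <- nrow(sim$reads)

  ## --- clean-up ---------------------------------------------------------
  deduped <- dedup_within_well(sim$reads, max_substitutions)
  purged <- purge_cross_well(deduped)
  cleaned <- purged$reads
  leak_report <- purged$report

  removed_ids <- setdiff(deduped$read_id, cleaned$read_id)
  affected <- union(sim$truth$leaks$read_id, sim$truth$leaks$source_read_id)
  purge_eval <- list(
    precision = if (length(removed_ids)) {
      length(intersect(removed_ids, affected)) / length(removed_ids)
    } else NA_real_,
    recall = if (length(affected)) {
      length(intersect(removed_ids, affected)) / length(affected)
    } else NA_real_
  )

  tssprof <- tss_profile(cleaned, sim$genes)

  ## --- accessibility matrix ---------------------------------------------
  mat <- overlap_with_reference(sim$cell_peaks, sim$peaks, min_overlap_bp)
  filtered <- filter_cascade(
    mat,
    min_cells_per_peak = min_cells_per_peak,
    min_peaks_per_cell = min_peaks_per_cell,
    max_peaks_per_cell = max_peaks_per_cell
  )
  filtered <- collapse_to_genes(filtered, sim$genes, promoter_window)

  doublet_wells <- sim$truth$wells$well[sim$truth$wells$status == "doublet"]
  doublet_eval <- if (length(doublet_wells)) {
    mean(!doublet_wells %in% rownames(filtered$values))
  } else NA_real_

  ## --- markers ----------------------------------------------------------
  grouping <- sim$truth$wells %>%
    filter(.data$well %in% rownames(filtered$values)) %>%
    transmute(cell = .data$well, group = .data$subtype)
  markers <- rank_markers(filtered, grouping, gate = gate)

  ## --- CNV ---------------------------------------------------------------
  windows <- window_gc(tile_windows(config$genome_model, window_bp, overlap_bp))
  excluded_arms <- unique(unlist(config$deleted_arms_by_subtype, use.names = FALSE))
  cellreads <- cleaned %>% filter(.data$well %in% rownames(filtered$values))
  covw <- window_coverage(cellreads, windows)
  bg <- suppressWarnings(
    match_gc_background(windows, n_background, excluded_arms = excluded_arms)
  )
  track <- covnorm(covw, bg)
  calls <- call_arm_loss(track, arms = excluded_arms, threshold = cnv_threshold)

  truth_del <- sim$truth$deleted_arms %>% mutate(truth = TRUE)
  call_eval <- calls %>%
    left_join(truth_del, by = c(cell = "well", "arm")) %>%
    mutate(truth = !is.na(.data$truth))
  cnv_eval <- list(
    sensitivity = if (any(call_eval$truth)) {
      mean(call_eval$loss[call_eval$truth], na.rm = TRUE)
    } else NA_real_,
    specificity = if (any(!call_eval$truth)) {
      mean(!call_eval$loss[!call_eval$truth], na.rm = TRUE)
    } else NA_real_
  )

  ## --- co-accessibility ---------------------------------------------------
  if (is.null(coaccess_query)) {
    top <- markers %>%
      filter(.data$rank_specific == 1) %>%
      arrange(.data$group)
    coaccess_query <- if (nrow(top)) top$gene[1] else NA_character_
  }
  coaccess <- if (!is.na(coaccess_query) &&
                  coaccess_query %in% colnames(filtered$gene_view %||% matrix(0))) {
    coaccessible_regions(filtered, coaccess_query, coaccess_threshold)
  } else {
    NULL
  }

  ## --- report -------------------------------------------------------------
  attrition <- tibble(
    stage = c("simulated reads", "after within-well dedup",
              "after cross-well purge",
              "cells on chip", "occupied wells", "cells after filter cascade"),
    unit = c("reads", "reads", "reads", "wells", "cells", "cells"),
    count = c(n_raw, nrow(deduped), nrow(cleaned),
              nrow(sim$truth$wells),
              sum(sim$truth$wells$status != "empty"),
              nrow(filtered$values))
  )

  report <- structure(
    list(
      seed = config$rng_seed,
      attrition = attrition,
      leakage = list(
        row_enrichment = leak_report$row_enrichment,
        col_enrichment = leak_report$col_enrichment,
        removed_count = leak_report$removed_count,
        removed_fraction = leak_report$removed_fraction,
        purge_precision = purge_eval$precision,
        purge_recall = purge_eval$recall
      ),
      tss_fraction_within_2kb = tssprof$fraction_within,
      matrix = list(
        cells_pre = nrow(mat$values), peaks_pre = ncol(mat$values),
        cells_post = nrow(filtered$values), peaks_post = ncol(filtered$values),
        genes = ncol(filtered$gene_view %||% matrix(0, 0, 0)),
        max_peak_percentile = filtered$max_peak_percentile,
        doublet_removal_recall = doublet_eval
      ),
      top_markers = markers %>%
        filter(!is.na(.data$rank_specific), .data$rank_specific <= 5) %>%
        arrange(.data$group, .data$rank_specific) %>%
        select("group", "gene", "rank_specific", "specific_score", "top_score"),
      cnv = list(
        arms_called = excluded_arms,
        n_losses = sum(calls$loss, na.rm = TRUE),
        sensitivity = cnv_eval$sensitivity,
        specificity = cnv_eval$specificity
      ),
      coaccessibility = if (!is.null(coaccess)) {
        list(query = coaccess$query, n_hits = nrow(coaccess$hits),
             threshold = coaccess$threshold)
      } else {
        list(query = NA_character_, n_hits = 0L,
             threshold = coaccess_threshold)
      },
      results = list(markers = markers, calls = calls, matrix = filtered,
                     track = track, leak_report = leak_report, sim = sim)
    ),
    class = "pipeline_report"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_run_report(report, file.path(out_dir, "run_report.json"))
    readr::write_tsv(attrition, file.path(out_dir, "attrition.tsv"))
    readr::write_tsv(markers, file.path(out_dir, "markers.tsv"))
    readr::write_tsv(calls, file.path(out_dir, "arm_calls.tsv"))
  }
  report
}

#' Serialize a pipeline report to JSON
#'
#' Writes the machine-readable part of a [run_pipeline()] report (the
#' embedded R objects under `$results` are omitted). Output is
#' deterministic: the same report serializes to identical bytes.
#'
#' @param report A `pipeline_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path) {
  out <- report[setdiff(names(report), "results")]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(path)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> seed %d\n", x$seed))
  cat(sprintf(
    "  reads %d -> dedup %d -> purge %d | cells %d -> filtered %d (%d peaks, %d genes)\n",
    x$attrition$count[1], x$attrition$count[2], x$attrition$count[3],
    x$matrix$cells_pre, x$matrix$cells_post, x$matrix$peaks_post, x$matrix$genes
  ))
  cat(sprintf(
    "  leakage: row enr %.2f, col enr %.2f, removed %.1f%% | purge P/R %.2f/%.2f\n",
    x$leakage$row_enrichment, x$leakage$col_enrichment,
    100 * x$leakage$removed_fraction,
    x$leakage$purge_precision, x$leakage$purge_recall
  ))
  cat(sprintf(
    "  CNV (%s): %d losses, sens %.2f, spec %.2f | coaccess '%s': %d hits\n",
    paste(x$cnv$arms_called, collapse = ","), x$cnv$n_losses,
    x$cnv$sensitivity, x$cnv$specificity,
    x$coaccessibility$query, x$coaccessibility$n_hits
  ))
  invisible(x)
}
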