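#' @noRd
new_access_matrix <- function(values, peaks, gene_view = NULL, gene_map = NULL,
                              filtered = FALSE, thresholds = NULL,
                              max_peak_percentile = NA_real_) {
  structure(
    list(
      values = values, peaks = peaks, gene_view = gene_view,
      gene_map = gene_map, filtered = filtered, thresholds = thresholds,
      max_peak_percentile = max_peak_percentile
    ),
    class = "access_matrix"
  )
}

#' @export
print.access_matrix <- function(x, ...) {
  cat(sprintf(
    "<access_matrix> %d cells x %d peaks (%s)%s\n",
    nrow(x$values), ncol(x$values),
    if (x$filtered) "filtered" else "unfiltered",
    if (!is.null(x$gene_view)) sprintf(", gene view: %d genes", ncol(x$gene_view)) else ""
  ))
  invisible(x)
}

# Standardize the cell identifier column of a per-cell peak table.
#' @noRd
cell_column <- function(df) {
  for (cand in c("cell", "well")) {
    if (cand %in% names(df)) return(cand)
  }
  abort("per-cell peaks need a `cell` or `well` column",
        class = "atacwell_input_error")
}

#' Build a binary cell-by-peak matrix against a reference peak set
#'
#' Overlaps each cell's called peaks with a bulk reference peak set; entry
#' (cell, peak) is 1 when some peak of the cell overlaps the reference
#' peak by at least `min_overlap_bp` bases. Constraining single-cell peaks
#' to bulk-supported regions suppresses the spurious peaks that plague
#' sparse single-nucleus libraries.
#'
#' All coordinates are 0-based half-open; overlap length is
#' `max(0, min(ends) - max(starts))`.
#'
#' @param cell_peaks Tibble of per-cell peaks with a `cell` (or `well`)
#'   column plus `chrom`, `start`, `end`.
#' @param reference Reference peak tibble (`chrom`, `start`, `end`,
#'   optional `peak_id` and `gene`). Must be non-empty.
#' @param min_overlap_bp Minimum overlap in bases (default 50).
#' @return An unfiltered `access_matrix` whose rows are cells and whose
#'   columns are the reference peaks.
#' @export
#' @examples
#' cp <- tibble::tibble(cell = "c1", chrom = "chr1", start = 100L, end = 200L)
#' ref <- tibble::tibble(chrom = "chr1", start = 150L, end = 300L)
#' overlap_with_reference(cp, ref, min_overlap_bp = 50)$values
overlap_with_reference <- function(cell_peaks, reference, min_overlap_bp = 50L) {
  if (nrow(reference) == 0) {
    abort("reference peak set must be non-empty", class = "atacwell_input_error")
  }
  stopifnot(min_overlap_bp >= 1)
  cellcol <- cell_column(cell_peaks)

  reference <- reference %>% arrange(.data$chrom, .data$start)
  if (!"peak_id" %in% names(reference)) {
    reference <- reference %>% mutate(peak_id = sprintf("refpeak%05d", row_number()))
  }

  unknown <- !cell_peaks$chrom %in% unique(reference$chrom)
  if (any(unknown)) {
    warn(sprintf("ignoring %d cell peak(s) on chromosomes absent from the reference",
                 sum(unknown)))
  }
  cells <- sort(unique(cell_peaks[[cellcol]]))
  cp <- cell_peaks[!unknown, , drop = FALSE]

  values <- matrix(0L, nrow = length(cells), ncol = nrow(reference),
                   dimnames = list(cells, reference$peak_id))
  if (nrow(cp) > 0) {
    hits <- GenomicRanges::findOverlaps(
      as_granges0(cp), as_granges0(reference),
      minoverlap = min_overlap_bp
    )
    if (length(hits) > 0) {
      ri <- match(cp[[cellcol]][S4Vectors::queryHits(hits)], cells)
      ci <- S4Vectors::subjectHits(hits)
      values[cbind(ri, ci)] <- 1L
    }
  }
  new_access_matrix(values, peaks = reference)
}

#' Apply the peak/cell filter cascade
#'
#' A single ordered pass: (1) drop reference peaks positive in fewer than
#' `min_cells_per_peak` cells, (2) drop cells with fewer than
#' `min_peaks_per_cell` positive peaks, (3) drop cells with more than
#' `max_peaks_per_cell` positive peaks (the doublet guard — inflated peak
#' counts betray wells holding two nuclei). The realized percentile of
#' `max_peaks_per_cell` in the cascade's entry distribution of per-cell
#' peak counts is reported, since a fixed count threshold corresponds to a
#' dataset-specific percentile.
#'
#' The default is one pass in this order (removing cells can push peaks
#' back below `min_cells_per_peak`; that is accepted). `iterate = TRUE`
#' repeats the pass until a fixpoint, which always terminates because each
#' pass can only shrink the matrix.
#'
#' @param m An `access_matrix`.
#' @param min_cells_per_peak,min_peaks_per_cell,max_peaks_per_cell Integer
#'   thresholds (defaults 5, 50, 3000).
#' @param iterate Repeat the cascade to a fixpoint (default `FALSE`).
#' @return The filtered `access_matrix`.
#' @export
filter_cascade <- function(m, min_cells_per_peak = 5L, min_peaks_per_cell = 50L,
                           max_peaks_per_cell = 3000L, iterate = FALSE) {
  stopifnot(inherits(m, "access_matrix"))
  v <- m$values
  entry_counts <- rowSums(v)
  pctile <- if (nrow(v)) 100 * mean(entry_counts <= max_peaks_per_cell) else NA_real_

  one_pass <- function(v) {
    keep_peaks <- colSums(v) >= min_cells_per_peak
    v <- v[, keep_peaks, drop = FALSE]
    keep_cells <- rowSums(v) >= min_peaks_per_cell
    v <- v[keep_cells, , drop = FALSE]
    keep_cells2 <- rowSums(v) <= max_peaks_per_cell
    v[keep_cells2, , drop = FALSE]
  }

  v <- one_pass(v)
  if (iterate) {
    repeat {
      v2 <- one_pass(v)
      if (identical(dim(v2), dim(v))) break
      v <- v2
    }
  }
  if (nrow(v) == 0) {
    abort("filter cascade removed every cell", class = "atacwell_empty_error")
  }
  peaks <- m$peaks %>% filter(.data$peak_id %in% colnames(v))
  new_access_matrix(
    v, peaks = peaks, filtered = TRUE,
    thresholds = list(min_cells_per_peak = min_cells_per_peak,
                      min_peaks_per_cell = min_peaks_per_cell,
                      max_peaks_per_cell = max_peaks_per_cell),
    max_peak_percentile = pctile
  )
}

#' Collapse the peak matrix to gene level
#'
#' Assigns every retained peak to at most one gene — the gene with the
#' nearest TSS, provided the peak lies within `promoter_window` bp of that
#' TSS — and ORs the member peaks of each gene into a binary cells x genes
#' view. Peaks assigned to no gene form an intergenic bucket that is
#' excluded from the gene view (but kept in `gene_map` with gene `NA`).
#'
#' @param m An `access_matrix`.
#' @param annotation TSS table with `gene`, `chrom`, `tss` (and optionally
#'   `strand`).
#' @param promoter_window Maximum distance in bp between peak and TSS for
#'   assignment (default 2000, i.e. a TSS -2000/+2000 promoter).
#' @return The `access_matrix` with `gene_view` and `gene_map` filled in.
#' @export
collapse_to_genes <- function(m, annotation, promoter_window = 2000L) {
  stopifnot(inherits(m, "access_matrix"))
  peaks <- m$peaks
  miss <- setdiff(unique(peaks$chrom), unique(annotation$chrom))
  if (length(miss)) {
    warn(sprintf("annotation lacks chromosome(s): %s", paste(miss, collapse = ", ")))
  }
  assign_one <- function(chrom, start, end) {
    ann <- annotation[annotation$chrom == chrom, , drop = FALSE]
    if (nrow(ann) == 0) return(NA_character_)
    # distance from the half-open interval [start, end) to the TSS point
    d <- pmax(start - ann$tss, ann$tss - (end - 1L), 0L)
    if (min(d) > promoter_window) return(NA_character_)
    cand <- which(d == min(d))
    ann$gene[cand[order(ann$gene[cand])][1]]
  }
  gene_map <- peaks %>%
    mutate(gene = purrr::pmap_chr(list(.data$chrom, .data$start, .data$end),
                                  assign_one)) %>%
    select("peak_id", "gene")

  genes <- sort(unique(gene_map$gene[!is.na(gene_map$gene)]))
  gv <- matrix(0L, nrow = nrow(m$values), ncol = length(genes),
               dimnames = list(rownames(m$values), genes))
  for (g in genes) {
    member <- gene_map$peak_id[!is.na(gene_map$gene) & gene_map$gene == g]
    gv[, g] <- as.integer(
      rowSums(m$values[, member, drop = FALSE]) > 0
    )
  }
  m$gene_view <- gv
  m$gene_map <- gene_map
  m
}

#' Fraction of a cell group with an open promoter for a gene
#'
#' Counts, within a group of cells, how many have at least one accessible
#' peak collapsed to the gene, and reports the percentage rounded to one
#' decimal — the statistic used to contrast promoter accessibility between
#' molecular subgroups (e.g. an open CYTOR promoter in 101/145 = 70% of
#' non-codeleted vs 20/191 = 10.5% of codeleted nuclei).
#'
#' @param m An `access_matrix` with a gene view (see
#'   [collapse_to_genes()]).
#' @param gene Gene identifier present in the gene view.
#' @param cells Character vector of cell identifiers forming the group;
#'   `NULL` means all cells.
#' @return A one-row tibble: `gene`, `positives`, `group_size`,
#'   `percentage` (one decimal).
#' @export
open_promoter_fraction <- function(m, gene, cells = NULL) {
  stopifnot(inherits(m, "access_matrix"))
  if (is.null(m$gene_view)) {
    abort("matrix has no gene view; run collapse_to_genes() first",
          class = "atacwell_input_error")
  }
  if (!gene %in% colnames(m$gene_view)) {
    abort(sprintf("gene '%s' not in gene view", gene),
          class = "atacwell_input_error")
  }
  cells <- cells %||% rownames(m$gene_view)
  cells <- intersect(cells, rownames(m$gene_view))
  if (length(cells) == 0) {
    abort("cell group is empty; fraction undefined",
          class = "atacwell_empty_error")
  }
  pos <- sum(m$gene_view[cells, gene])
  tibble(
    gene = gene,
    positives = pos,
    group_size = length(cells),
    percentage = round(100 * pos / length(cells), 1)
  )
}
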