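#' Marker counts for a gene within a cell group
#'
#' Tabulates the four counts the marker scores are built from, over the
#' gene-level accessibility view:
#' * `x_pos` — nuclei in the group with peak(s) for the gene,
#' * `y_pos` — all nuclei with peak(s) for the gene,
#' * `x_neg` — nuclei in the group with no peaks for the gene,
#' * `y_neg` — all nuclei with no peaks for the gene.
#'
#' Invariants: `x_pos + x_neg` equals the group size and
#' `y_pos + y_neg` the total cell count.
#'
#' @param m An `access_matrix` with a gene view.
#' @param group Character vector of cell identifiers (non-empty subset of
#'   the matrix rows).
#' @param gene Gene identifier in the gene view.
#' @return A one-row tibble: `gene`, `x_pos`, `y_pos`, `x_neg`, `y_neg`.
#' @export
marker_counts <- function(m, group, gene) {
  stopifnot(inherits(m, "access_matrix"))
  if (is.null(m$gene_view)) {
    abort("matrix has no gene view; run collapse_to_genes() first",
          class = "atacwell_input_error")
  }
  if (!gene %in% colnames(m$gene_view)) {
    abort(sprintf("gene '%s' not in gene view", gene),
          class = "atacwell_input_error")
  }
  group <- intersect(group, rownames(m$gene_view))
  if (length(group) == 0) {
    abort("cell group is empty", class = "atacwell_empty_error")
  }
  v <- m$gene_view[, gene]
  tibble(
    gene = gene,
    x_pos = sum(v[group]),
    y_pos = sum(v),
    x_neg = sum(v[group] == 0L),
    y_neg = sum(v == 0L)
  )
}

#' Marker enrichment score (difference form)
#'
#' `x_pos / y_pos - (x_neg + 1) / y_neg`: the group's share of all
#' peak-positive nuclei for the gene, penalized by its share of the
#' peak-negative nuclei (with a +1 pseudocount on the negative count).
#' Genes also carry a gate `x_pos > 10` (strict), below which a score is
#' not considered for ranking. `y_neg = 0` (gene open in every nucleus) is
#' guarded by `max(y_neg, 1)`.
#'
#' @param x_pos,y_pos,x_neg,y_neg Marker counts (vectorized).
#' @return Numeric score(s) in `[-(y_neg + 1) / y_neg, 1)`.
#' @seealso [specific_score()], [rank_markers()]
#' @export
#' @examples
#' top_score(12, 15, 2, 20)  # 12/15 - 3/20 = 0.65
top_score <- function(x_pos, y_pos, x_neg, y_neg) {
  if (any(y_pos < 1)) {
    abort("top_score undefined when y_pos = 0 (gene open in no nucleus)",
          class = "atacwell_undefined_error")
  }
  x_pos / y_pos - (x_neg + 1) / pmax(y_neg, 1)
}

#' Marker specificity score (ratio form)
#'
#' `(x_pos / y_pos) / ((x_neg + 1) / y_neg)`: the same two terms as
#' [top_score()] composed as a ratio, so a gene scores highly only when
#' the group captures many of the peak-positive nuclei *and* few of the
#' peak-negative ones. The +1 pseudocount keeps the denominator positive;
#' `y_neg = 0` is guarded by `max(y_neg, 1)`.
#'
#' @inheritParams top_score
#' @return Positive numeric score(s); `> 0` whenever `x_pos >= 1`.
#' @export
#' @examples
#' specific_score(12, 15, 2, 20)  # 0.8 / 0.15 = 5.33
specific_score <- function(x_pos, y_pos, x_neg, y_neg) {
  if (any(y_pos < 1)) {
    abort("specific_score undefined when y_pos = 0 (gene open in no nucleus)",
          class = "atacwell_undefined_error")
  }
  (x_pos / y_pos) / ((x_neg + 1) / pmax(y_neg, 1))
}

#' Rank marker genes per cell group
#'
#' Computes [marker_counts()], [top_score()] and [specific_score()] for
#' every gene and every group of a cell grouping, gates genes at
#' `x_pos > gate` (strict), and ranks the gated genes per group by
#' descending score (ties broken by gene identifier). Gated-out genes stay
#' in the table with `passes_gate = FALSE` and no rank. Genes open in no
#' nucleus (`y_pos = 0`) get `NA` scores.
#'
#' @param m An `access_matrix` with a gene view.
#' @param grouping Tibble with columns `cell` and `group`, partitioning a
#'   subset of the matrix cells.
#' @param gate Minimum `x_pos` (exclusive) for a gene to be ranked
#'   (default 10).
#' @return A tibble of class `marker_table`: one row per (group, gene)
#'   with counts, both scores, `passes_gate`, `rank_top`, `rank_specific`.
#' @export
rank_markers <- function(m, grouping, gate = 10L) {
  stopifnot(inherits(m, "access_matrix"))
  if (is.null(m$gene_view)) {
    abort("matrix has no gene view; run collapse_to_genes() first",
          class = "atacwell_input_error")
  }
  stopifnot(all(c("cell", "group") %in% names(grouping)))
  gv <- m$gene_view
  grouping <- grouping %>% filter(.data$cell %in% rownames(gv))
  if (nrow(grouping) == 0) {
    abort("no grouped cells found in the matrix", class = "atacwell_empty_error")
  }
  if (anyDuplicated(grouping$cell)) {
    abort("grouping must assign each cell to a single group",
          class = "atacwell_input_error")
  }

  y_pos_all <- colSums(gv)
  y_neg_all <- nrow(gv) - y_pos_all

  tab <- grouping %>%
    group_by(.data$group) %>%
    group_split() %>%
    purrr::map(function(gd) {
      sub <- gv[gd$cell, , drop = FALSE]
      x_pos <- colSums(sub)
      tibble(
        group = gd$group[1],
        gene = colnames(gv),
        x_pos = as.integer(x_pos),
        y_pos = as.integer(y_pos_all),
        x_neg = as.integer(nrow(sub) - x_pos),
        y_neg = as.integer(y_neg_all)
      )
    }) %>%
    bind_rows() %>%
    mutate(
      top_score = ifelse(.data$y_pos >= 1,
                         .data$x_pos / .data$y_pos -
                           (.data$x_neg + 1) / pmax(.data$y_neg, 1),
                         NA_real_),
      specific_score = ifelse(.data$y_pos >= 1,
                              (.data$x_pos / .data$y_pos) /
                                ((.data$x_neg + 1) / pmax(.data$y_neg, 1)),
                              NA_real_),
      passes_gate = .data$x_pos > gate
    ) %>%
    group_by(.data$group) %>%
    arrange(dplyr::desc(.data$top_score), .data$gene, .by_group = TRUE) %>%
    mutate(rank_top = ifelse(.data$passes_gate & !is.na(.data$top_score),
                             cumsum(.data$passes_gate & !is.na(.data$top_score)),
                             NA_integer_)) %>%
    arrange(dplyr::desc(.data$specific_score), .data$gene, .by_group = TRUE) %>%
    mutate(rank_specific = ifelse(.data$passes_gate & !is.na(.data$specific_score),
                                  cumsum(.data$passes_gate & !is.na(.data$specific_score)),
                                  NA_integer_)) %>%
    arrange(dplyr::desc(.data$top_score), .data$gene, .by_group = TRUE) %>%
    ungroup()
  class(tab) <- c("marker_table", class(tab))
  tab
}
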