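#' Find regions co-accessible with a query peak or promoter
#'
#' Pearson-correlates the query's binary accessibility vector with every
#' other peak's vector across all retained cells. On binary vectors the
#' Pearson coefficient is the phi coefficient of the 2x2 presence table,
#' so the search reads directly off the peak-presence data model without
#' smoothing. Hits are peaks with coefficient strictly greater than
#' `threshold`, sorted descending; the query never appears in its own hit
#' list, and peaks constant across cells (undefined coefficient) are
#' excluded.
#'
#' @param m An `access_matrix` (filtered).
#' @param query A peak identifier, or a gene identifier if the matrix has
#'   a gene map — then the query vector is the OR over the gene's peaks
#'   (its promoter-level accessibility).
#' @param threshold Correlation threshold, exceeded strictly (default
#'   0.2).
#' @return A list of class `coaccess_result`: `query`, `correlations`
#'   tibble (`peak_id`, `r`), `hits` tibble (subset with `r > threshold`),
#'   `threshold`, `n_cells`.
#' @export
#' @examples
#' v <- matrix(c(1, 1, 1, 0, 0, 0,
#'               1, 1, 0, 0, 0, 1), ncol = 2,
#'             dimnames = list(paste0("c", 1:6), c("q", "p")))
#' m <- atacwell:::new_access_matrix(
#'   v, peaks = tibble::tibble(peak_id = c("q", "p"))
#' )
#' coaccessible_regions(m, "q")$correlations
coaccessible_regions <- function(m, query, threshold = 0.2) {
  stopifnot(inherits(m, "access_matrix"))
  v <- m$values
  if (query %in% colnames(v)) {
    qvec <- v[, query]
    drop_cols <- query
  } else if (!is.null(m$gene_map) && query %in% m$gene_map$gene) {
    member <- m$gene_map$peak_id[!is.na(m$gene_map$gene) &
                                   m$gene_map$gene == query]
    qvec <- as.integer(rowSums(v[, member, drop = FALSE]) > 0)
    drop_cols <- member
  } else {
    abort(sprintf("query '%s' is neither a peak nor a mapped gene", query),
          class = "atacwell_input_error")
  }
  if (stats::var(qvec) == 0) {
    abort("query vector is constant across cells; correlation undefined",
          class = "atacwell_undefined_error")
  }
  cand <- setdiff(colnames(v), drop_cols)
  r <- suppressWarnings(as.vector(cor(qvec, v[, cand, drop = FALSE])))
  correlations <- tibble(peak_id = cand, r = r) %>%
    filter(!is.na(.data$r))
  hits <- correlations %>%
    filter(.data$r > threshold) %>%
    arrange(dplyr::desc(.data$r), .data$peak_id)
  structure(
    list(query = query, correlations = correlations, hits = hits,
         threshold = threshold, n_cells = nrow(v)),
    class = "coaccess_result"
  )
}

#' @export
print.coaccess_result <- function(x, ...) {
  cat(sprintf(
    "<coaccess_result> query '%s' over %d cells: %d correlated region(s) with r > %g\n",
    x$query, x$n_cells, nrow(x$hits), x$threshold
  ))
  invisible(x)
}
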