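#' Deduplicate reads within each well
#'
#' Collapses PCR duplicates (and, with `max_substitutions > 0`, mutant
#' amplicons) independently in every well. Reads of equal length whose
#' sequences differ by at most `max_substitutions` bases are grouped into
#' connected components; one representative per component is kept: the read
#' with the lexicographically smallest sequence, and among equal sequences
#' the smallest read identifier. Wells never interact at this stage.
#'
#' @param reads Read tibble with at least `read_id`, `well`, `sequence`.
#' @param max_substitutions Maximum Hamming distance for two equal-length
#'   reads to be considered duplicates (default 0: exact duplicates only).
#' @return The read tibble with duplicates removed.
#' @export
#' @examples
#' r <- tibble::tibble(read_id = c("a", "b", "c"), well = "R01C01",
#'                     sequence = c("ACGT", "ACGT", "TTTT"))
#' dedup_within_well(r)$sequence
dedup_within_well <- function(reads, max_substitutions = 0L) {
  stopifnot(max_substitutions >= 0)
  if (nrow(reads) == 0) return(reads)
  if (anyNA(reads$sequence)) {
    abort("reads must carry sequences for deduplication",
          class = "atacwell_sequence_error")
  }
  if (max_substitutions == 0L) {
    return(
      reads %>%
        arrange(.data$well, .data$sequence, .data$read_id) %>%
        distinct(.data$well, .data$sequence, .keep_all = TRUE) %>%
        arrange(.data$well, .data$read_id)
    )
  }
  kept <- reads %>%
    mutate(.len = nchar(.data$sequence)) %>%
    group_by(.data$well, .data$.len) %>%
    group_split() %>%
    purrr::map(function(grp) {
      comp <- hamming_components(grp$sequence, max_substitutions)
      grp %>%
        mutate(.comp = comp) %>%
        arrange(.data$.comp, .data$sequence, .data$read_id) %>%
        distinct(.data$.comp, .keep_all = TRUE)
    }) %>%
    bind_rows() %>%
    select(-".len", -".comp") %>%
    arrange(.data$well, .data$read_id)
  kept
}

# Connected components of the <= k substitutions graph over equal-length
# sequences (union-find; exact-duplicate groups are merged up front so the
# pairwise scan runs on distinct sequences only).
#' @noRd
hamming_components <- function(seqs, k) {
  uniq <- unique(seqs)
  n <- length(uniq)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (find(i) != find(j) && hamming(uniq[i], uniq[j]) <= k) {
          parent[find(i)] <- find(j)
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  roots[match(seqs, uniq)]
}

#' Remove reads whose exact sequence occurs in two or more wells
#'
#' The cross-well purge: any sequence present in at least two distinct
#' wells is treated as contamination and removed from *all* wells carrying
#' it (no donor attribution is attempted). The accompanying report is
#' computed on the pre-purge store, so its pairwise sharing statistics
#' describe the contamination that was removed.
#'
#' Run [dedup_within_well()] first so within-well PCR copies do not count
#' as cross-well evidence.
#'
#' @param reads Read tibble (deduplicated within wells).
#' @return A list with `reads` (the purged store) and `report` (a
#'   [leakage_diagnostics()] report with `removed_count` and
#'   `removed_fraction` filled in).
#' @export
#' @examples
#' r <- tibble::tibble(
#'   read_id = c("a1", "a2", "b1", "b2"),
#'   well = c("R01C01", "R01C01", "R01C02", "R01C02"),
#'   row = c(1L, 1L, 1L, 1L), col = c(1L, 1L, 2L, 2L),
#'   sequence = c("AAAA", "CCCC", "CCCC", "GGGG")
#' )
#' purge_cross_well(r)$reads$sequence
purge_cross_well <- function(reads) {
  if (nrow(reads) == 0) {
    rep0 <- leakage_diagnostics(reads)
    rep0$removed_count <- 0L
    rep0$removed_fraction <- NaN
    return(list(reads = reads, report = rep0))
  }
  if (anyNA(reads$sequence)) {
    abort("reads must carry sequences for the cross-well purge",
          class = "atacwell_sequence_error")
  }
  report <- leakage_diagnostics(reads)
  shared_seqs <- reads %>%
    distinct(.data$sequence, .data$well) %>%
    count(.data$sequence) %>%
    filter(.data$n >= 2) %>%
    pull(.data$sequence)
  cleaned <- reads %>% filter(!.data$sequence %in% shared_seqs)
  report$removed_count <- nrow(reads) - nrow(cleaned)
  report$removed_fraction <- report$removed_count / nrow(reads)
  list(reads = cleaned, report = report)
}

#' Quantify cross-well sequence sharing and its chip geometry
#'
#' For every pair of non-empty wells, computes the shared-sequence
#' fraction `|shared| / min(|a|, |b|)` over distinct sequences (the `min`
#' denominator makes a small contaminated well register strongly).
#' Pairs are classified as same-row, same-column, or neither;
#' `row_enrichment` is the ratio of the mean shared fraction among
#' same-row pairs to the mean among non-row non-column pairs
#' (`col_enrichment` analogously). A ratio of empty or all-zero classes is
#' reported as 1 by convention (no evidence of structure).
#'
#' @param reads Read tibble with `well`, `row`, `col`, `sequence`.
#' @return A list of class `leakage_report`: `pairwise_shared` tibble
#'   (`well_a`, `well_b`, `size_a`, `size_b`, `shared`, `fraction`,
#'   `relation`), `row_enrichment`, `col_enrichment`, `n_wells`,
#'   `removed_count`/`removed_fraction` (NA until a purge fills them).
#' @export
leakage_diagnostics <- function(reads) {
  empty_pairs <- tibble(
    well_a = character(), well_b = character(),
    size_a = integer(), size_b = integer(), shared = integer(),
    fraction = double(), relation = character()
  )
  res <- structure(
    list(pairwise_shared = empty_pairs, row_enrichment = 1,
         col_enrichment = 1, n_wells = 0L,
         removed_count = NA_integer_, removed_fraction = NA_real_),
    class = "leakage_report"
  )
  if (nrow(reads) == 0) return(res)

  layout <- reads %>% distinct(.data$well, .data$row, .data$col)
  seq_sets <- split(reads$sequence, reads$well)
  seq_sets <- lapply(seq_sets, unique)
  wells <- sort(names(seq_sets))
  res$n_wells <- length(wells)
  if (length(wells) < 2) return(res)

  # restrict the intersection scan to sequences seen in >= 2 wells
  multi <- reads %>%
    distinct(.data$sequence, .data$well) %>%
    count(.data$sequence) %>%
    filter(.data$n >= 2) %>%
    pull(.data$sequence)
  small_sets <- lapply(seq_sets, function(s) s[s %in% multi])

  pairs <- utils::combn(wells, 2)
  shared <- vapply(seq_len(ncol(pairs)), function(i) {
    sum(small_sets[[pairs[1, i]]] %in% small_sets[[pairs[2, i]]])
  }, integer(1))
  sizes <- vapply(seq_sets, length, integer(1))
  rowcol <- layout %>% arrange(.data$well)
  rw <- setNames(rowcol$row, rowcol$well)
  cl <- setNames(rowcol$col, rowcol$well)

  pw <- tibble(
    well_a = pairs[1, ], well_b = pairs[2, ],
    size_a = unname(sizes[pairs[1, ]]), size_b = unname(sizes[pairs[2, ]]),
    shared = shared
  ) %>%
    mutate(
      fraction = .data$shared / pmin(.data$size_a, .data$size_b),
      relation = unname(
        ifelse(rw[.data$well_a] == rw[.data$well_b], "row",
               ifelse(cl[.data$well_a] == cl[.data$well_b], "col", "other"))
      )
    )

  class_mean <- function(rel) {
    x <- pw$fraction[pw$relation == rel]
    if (length(x) == 0) 0 else mean(x)
  }
  ratio <- function(num, den) {
    if (den == 0) {
      if (num == 0) 1 else Inf
    } else {
      num / den
    }
  }
  other <- class_mean("other")
  res$pairwise_shared <- pw
  res$row_enrichment <- ratio(class_mean("row"), other)
  res$col_enrichment <- ratio(class_mean("col"), other)
  res
}

#' @export
print.leakage_report <- function(x, ...) {
  cat(sprintf(
    "<leakage_report> %d wells, %d pairs | row enrichment %.3g, col enrichment %.3g",
    x$n_wells, nrow(x$pairwise_shared), x$row_enrichment, x$col_enrichment
  ))
  if (!is.na(x$removed_count)) {
    cat(sprintf(" | purged %d reads (%.1f%%)",
                x$removed_count, 100 * x$removed_fraction))
  }
  cat("\n")
  invisible(x)
}

#' Read-midpoint distance profile around transcription start sites
#'
#' Measures, for every read, the signed distance from its midpoint to the
#' nearest TSS (positive downstream of the TSS with respect to gene
#' strand), and the fraction of reads falling within +/- `window` bp — the
#' usual promoter-proximality QC for ATAC libraries.
#'
#' Reads on chromosomes absent from the annotation stay in the
#' denominator with infinite distance.
#'
#' @param reads Read tibble with `read_id`, `chrom`, `start`, `end`.
#' @param tss_table Annotation tibble with `gene`, `chrom`, `tss`,
#'   `strand`.
#' @param window Half-width of the promoter window in bp (default 2000).
#' @return A list of class `tss_profile`: `distances` tibble (`read_id`,
#'   `distance`, `gene`), `fraction_within`, `window`, `n_reads`.
#' @export
tss_profile <- function(reads, tss_table, window = 2000L) {
  if (nrow(tss_table) == 0) {
    abort("tss_table must be non-empty", class = "atacwell_input_error")
  }
  mid <- floor((reads$start + reads$end) / 2)
  dist <- rep(Inf, nrow(reads))
  gene <- rep(NA_character_, nrow(reads))
  for (ch in unique(reads$chrom)) {
    idx <- which(reads$chrom == ch)
    ann <- tss_table %>% filter(.data$chrom == ch) %>% arrange(.data$tss, .data$gene)
    if (nrow(ann) == 0) next
    pos <- ann$tss
    m <- mid[idx]
    lo <- findInterval(m, pos)
    hi <- pmin(lo + 1L, length(pos))
    lo <- pmax(lo, 1L)
    d_lo <- abs(m - pos[lo])
    d_hi <- abs(m - pos[hi])
    pick <- ifelse(d_hi < d_lo, hi, lo)  # tie -> lower position
    signed <- m - pos[pick]
    signed[ann$strand[pick] == "-"] <- -signed[ann$strand[pick] == "-"]
    dist[idx] <- signed
    gene[idx] <- ann$gene[pick]
  }
  structure(
    list(
      distances = tibble(read_id = reads$read_id, distance = dist, gene = gene),
      fraction_within = mean(abs(dist) <= window),
      window = window,
      n_reads = nrow(reads)
    ),
    class = "tss_profile"
  )
}

#' @export
print.tss_profile <- function(x, ...) {
  cat(sprintf(
    "<tss_profile> %d reads | %.1f%% within +/-%d bp of a TSS\n",
    x$n_reads, 100 * x$fraction_within, x$window
  ))
  invisible(x)
}
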