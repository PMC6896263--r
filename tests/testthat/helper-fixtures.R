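# Shared fixtures, built in code.

# A small leak-prone chip matching the geometry used throughout the QC
# narrative: 8x8 wells with the default leakage design.
leak_chip_config <- function(seed = 101L) {
  chip_config(n_rows = 8L, n_cols = 8L, rng_seed = seed)
}

# Minimal read tibble constructor for hand-placed toys.
toy_reads <- function(read_id, well, sequence = NA_character_,
                      row = 1L, col = 1L,
                      chrom = "chr1", start = 0L, end = 50L) {
  tibble::tibble(
    read_id = read_id, well = well,
    row = rep_len(row, length(read_id)), col = rep_len(col, length(read_id)),
    chrom = rep_len(chrom, length(read_id)),
    start = rep_len(as.integer(start), length(read_id)),
    end = rep_len(as.integer(end), length(read_id)),
    sequence = rep_len(sequence, length(read_id)),
    origin = "peak"
  )
}

# Brute-force filter cascade on a plain matrix: the independent oracle for
# filter_cascade().
brute_filter <- function(v, min_cells, min_peaks, max_peaks) {
  keep_p <- colSums(v) >= min_cells
  v <- v[, keep_p, drop = FALSE]
  keep_c <- rowSums(v) >= min_peaks
  v <- v[keep_c, , drop = FALSE]
  v[rowSums(v) <= max_peaks, , drop = FALSE]
}

# Phi coefficient from the 2x2 contingency table: the independent oracle
# for binary Pearson correlation.
phi_from_table <- function(a, b) {
  n11 <- sum(a == 1 & b == 1)
  n10 <- sum(a == 1 & b == 0)
  n01 <- sum(a == 0 & b == 1)
  n00 <- sum(a == 0 & b == 0)
  num <- n11 * n00 - n10 * n01
  den <- sqrt((n11 + n10) * (n01 + n00) * (n11 + n01) * (n10 + n00))
  num / den
}

# Wrap a plain binary matrix as an access_matrix.
as_access_matrix <- function(v, filtered = FALSE) {
  if (is.null(rownames(v))) rownames(v) <- sprintf("c%03d", seq_len(nrow(v)))
  if (is.null(colnames(v))) colnames(v) <- sprintf("p%03d", seq_len(ncol(v)))
  atacwell:::new_access_matrix(
    v, peaks = tibble::tibble(peak_id = colnames(v)), filtered = filtered
  )
}

# Gene-view access_matrix straight from a binary cells x genes matrix.
as_gene_view <- function(gv) {
  m <- as_access_matrix(gv, filtered = TRUE)
  m$gene_view <- m$values
  m
}
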