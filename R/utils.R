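# Internal helpers shared across modules.

#' @noRd
well_id <- function(row, col) {
  sprintf("R%02dC%02d", row, col)
}

# Convert a 0-based half-open interval table to GRanges (1-based closed).
# Columns required: chrom, start, end.
#' @noRd
as_granges0 <- function(df, keep = character()) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
  for (k in keep) S4Vectors::mcols(gr)[[k]] <- df[[k]]
  gr
}

# Draw n random fixed-length DNA sequences. Uses a letter matrix + column
# paste, which is vectorised and fast for the sizes the simulator produces.
#' @noRd
random_sequences <- function(n, length) {
  if (n == 0L) return(character())
  m <- matrix(
    sample(c("A", "C", "G", "T"), n * length, replace = TRUE),
    nrow = n, ncol = length
  )
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# Apply per-base substitutions to sequences at a given rate.
#' @noRd
mutate_sequences <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  vapply(seqs, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- runif(length(ch)) < rate
    if (any(hit)) {
      ch[hit] <- vapply(ch[hit], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1L)
      }, character(1))
    }
    paste0(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Hamming distance between two equal-length strings.
#' @noRd
hamming <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

#' @noRd
`%||%` <- function(x, y) if (is.null(x)) y else x
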