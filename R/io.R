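# Plain-text readers/writers for the pipeline's interchange formats.
# Coordinates are 0-based half-open throughout, matching BED.

#' Write per-well FASTQ files
#'
#' One 4-line-record FASTQ per well, named `<well>.fastq`, with constant
#' quality (the simulator has no quality model).
#'
#' @param reads Read tibble with `read_id`, `well`, `sequence`.
#' @param dir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_well_fastq <- function(reads, dir) {
  if (anyNA(reads$sequence)) {
    abort("reads must carry sequences to be written as FASTQ",
          class = "atacwell_sequence_error")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- purrr::map_chr(split(reads, reads$well), function(w) {
    path <- file.path(dir, paste0(w$well[1], ".fastq"))
    rec <- paste0(
      "@", w$read_id, "\n", w$sequence, "\n+\n",
      strrep("I", nchar(w$sequence))
    )
    writeLines(rec, path)
    path
  })
  invisible(unname(files))
}

#' Read/write the tabular read store
#'
#' TSV with columns `read_id`, `well`, `row`, `col`, `chrom`, `start`,
#' `end`, `sequence`, `origin`.
#'
#' @param reads Read tibble.
#' @param path File path.
#' @return `write_reads_tsv` returns `path` invisibly; `read_reads_tsv`
#'   returns the tibble.
#' @export
write_reads_tsv <- function(reads, path) {
  readr::write_tsv(reads, path)
  invisible(path)
}

#' @rdname write_reads_tsv
#' @export
read_reads_tsv <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      read_id = "c", well = "c", row = "i", col = "i",
      chrom = "c", start = "i", end = "i",
      sequence = "c", origin = "c"
    )
  )
}

#' Read/write BED interval files
#'
#' Three mandatory BED columns plus an optional name; written and read
#' bit-exactly (no coordinate shifting — BED is already 0-based
#' half-open).
#'
#' @param intervals Tibble with `chrom`, `start`, `end` and optionally a
#'   `name` column.
#' @param path File path.
#' @return `write_bed` returns `path` invisibly; `read_bed` a tibble.
#' @export
write_bed <- function(intervals, path) {
  cols <- intersect(c("chrom", "start", "end", "name"), names(intervals))
  readr::write_tsv(intervals[cols], path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE,
                        col_types = readr::cols(.default = "c"))
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df[, 1:min(4, ncol(df))]
}

#' Write an accessibility matrix as TSV plus a sparse triplet file
#'
#' `matrix.tsv` holds the dense binary matrix with cell rownames;
#' `matrix_triplets.tsv` the (cell, peak) pairs of open entries;
#' `peaks.bed` the retained reference peaks; `gene_view.tsv` the
#' gene-level view when present.
#'
#' @param m An `access_matrix`.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_access_matrix <- function(m, dir) {
  stopifnot(inherits(m, "access_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dense <- as_tibble(m$values, rownames = "cell")
  readr::write_tsv(dense, file.path(dir, "matrix.tsv"))
  idx <- which(m$values == 1L, arr.ind = TRUE)
  trip <- tibble(
    cell = rownames(m$values)[idx[, 1]],
    peak_id = colnames(m$values)[idx[, 2]]
  ) %>% arrange(.data$cell, .data$peak_id)
  readr::write_tsv(trip, file.path(dir, "matrix_triplets.tsv"))
  write_bed(
    m$peaks %>% mutate(name = .data$peak_id),
    file.path(dir, "peaks.bed")
  )
  if (!is.null(m$gene_view)) {
    readr::write_tsv(as_tibble(m$gene_view, rownames = "cell"),
                     file.path(dir, "gene_view.tsv"))
  }
  invisible(dir)
}

#' Write simulation ground truth as JSON
#'
#' @param sim A `chip_sim`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(sim, path) {
  stopifnot(inherits(sim, "chip_sim"))
  jsonlite::write_json(
    list(
      wells = sim$truth$wells,
      leaks = sim$truth$leaks,
      deleted_arms = sim$truth$deleted_arms
    ),
    path, auto_unbox = TRUE, digits = 10
  )
  invisible(path)
}
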