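#' Tile a genome into overlapping coverage windows
#'
#' Slides a fixed-size window along each chromosome with step
#' `window_bp - overlap_bp`. A final partial window is retained when it is
#' at least half a window long; a chromosome shorter than one window
#' yields a single whole-chromosome window. Windows carry the chromosome
#' arm of their midpoint.
#'
#' @param genome_model Tibble with `chrom`, `length`, `arm_boundary`.
#' @param window_bp Window size in bp (default 10 Mb).
#' @param overlap_bp Overlap between consecutive windows (default 2 Mb,
#'   i.e. an 8 Mb step).
#' @return A tibble: `window_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `arm`, ordered by (chrom, start).
#' @export
#' @examples
#' gm <- tibble::tibble(chrom = "chrA", length = 26e6, arm_boundary = 13e6)
#' tile_windows(gm)[, c("start", "end")]
tile_windows <- function(genome_model, window_bp = 10000000L,
                         overlap_bp = 2000000L) {
  stopifnot(window_bp > overlap_bp, overlap_bp >= 0)
  step <- window_bp - overlap_bp
  w <- purrr::pmap(genome_model, function(chrom, length, arm_boundary, ...) {
    if (length < window_bp) {
      starts <- 0
    } else {
      starts <- seq(0, length - 1, by = step)
    }
    ends <- pmin(starts + window_bp, length)
    keep <- (ends - starts) >= window_bp / 2 | seq_along(starts) == 1L
    tibble(chrom = chrom, start = starts[keep], end = ends[keep])
  }) %>%
    bind_rows() %>%
    arrange(.data$chrom, .data$start) %>%
    mutate(
      arm = arm_label(genome_model, .data$chrom,
                      floor((.data$start + .data$end) / 2)),
      window_id = sprintf("w%04d", row_number())
    ) %>%
    select("window_id", "chrom", "start", "end", "arm")
  w
}

#' Attach GC content to coverage windows
#'
#' Joins a per-window GC table, or, when none is supplied, assigns a
#' smooth deterministic synthetic GC profile (a sinusoid around 0.5 with
#' per-chromosome phase) so GC-matched background selection is exercised
#' without a reference sequence.
#'
#' @param windows Tibble from [tile_windows()].
#' @param gc_table Optional tibble `chrom`, `start`, `end`, `gc` matching
#'   the windows exactly.
#' @return The window tibble with a `gc` column in `[0, 1]`.
#' @export
window_gc <- function(windows, gc_table = NULL) {
  if (is.null(gc_table)) {
    phase <- as.integer(factor(windows$chrom))
    mid <- (windows$start + windows$end) / 2
    windows$gc <- 0.5 + 0.12 * sin(mid / 7919 + phase)
    return(windows)
  }
  out <- windows %>%
    left_join(gc_table, by = c("chrom", "start", "end"))
  if (anyNA(out$gc)) {
    abort("gc_table does not cover every window", class = "atacwell_input_error")
  }
  out
}

#' Mean per-base coverage of each cell in each window
#'
#' For every (cell, window) pair, coverage is the total read-bases
#' overlapping the window divided by the window length; a read straddling
#' a window boundary contributes only its overlapping bases.
#'
#' @param reads Read tibble with `well`, `chrom`, `start`, `end`.
#' @param windows Window tibble from [tile_windows()] (GC optional).
#' @return A list of class `coverage_windows`: `coverage` (cells x windows
#'   matrix of mean depth), `windows`, `mask` (integer window indices
#'   excluded from normalization, empty by default).
#' @export
window_coverage <- function(reads, windows) {
  cellcol <- cell_column(reads)
  cells <- sort(unique(reads[[cellcol]]))
  cov <- matrix(0, nrow = length(cells), ncol = nrow(windows),
                dimnames = list(cells, windows$window_id))
  if (nrow(reads) > 0) {
    rgr <- as_granges0(reads)
    wgr <- as_granges0(windows)
    hits <- GenomicRanges::findOverlaps(rgr, wgr)
    if (length(hits) > 0) {
      ov <- IRanges::width(IRanges::pintersect(
        rgr[S4Vectors::queryHits(hits)], wgr[S4Vectors::subjectHits(hits)]
      ))
      dt <- tibble(
        cell = reads[[cellcol]][S4Vectors::queryHits(hits)],
        win = S4Vectors::subjectHits(hits),
        bases = ov
      ) %>%
        group_by(.data$cell, .data$win) %>%
        summarise(bases = sum(.data$bases), .groups = "drop")
      cov[cbind(match(dt$cell, cells), dt$win)] <- dt$bases
    }
  }
  cov <- sweep(cov, 2, windows$end - windows$start, "/")
  structure(
    list(coverage = cov, windows = windows, mask = integer()),
    class = "coverage_windows"
  )
}

#' @export
print.coverage_windows <- function(x, ...) {
  cat(sprintf("<coverage_windows> %d cells x %d windows (%d masked)\n",
              nrow(x$coverage), ncol(x$coverage), length(x$mask)))
  invisible(x)
}

#' Select GC-matched background windows for every window
#'
#' For each window w0, picks the `n_background` eligible windows with the
#' smallest absolute GC difference to w0 (ties broken by genomic order).
#' Eligible windows are unmasked, lie outside `excluded_arms`, and are not
#' w0 itself. Excluding putatively altered arms (1p/19q in codeleted
#' gliomas) keeps the background copy-number neutral. When fewer than
#' `n_background` windows are eligible, all of them are used with a
#' warning.
#'
#' @param windows Window tibble with a `gc` column (see [window_gc()]).
#' @param n_background Number of background windows per target
#'   (default 100).
#' @param excluded_arms Character vector of arm labels never used as
#'   background.
#' @param mask Integer indices of masked windows (telomeric/centromeric/
#'   low-mapping), excluded from background.
#' @return A list (one integer vector of window indices per window),
#'   named by `window_id`.
#' @export
match_gc_background <- function(windows, n_background = 100L,
                                excluded_arms = character(),
                                mask = integer()) {
  if (!"gc" %in% names(windows)) {
    abort("windows need a gc column; run window_gc() first",
          class = "atacwell_input_error")
  }
  n_win <- nrow(windows)
  eligible_base <- setdiff(which(!windows$arm %in% excluded_arms), mask)
  if (length(eligible_base) - 1L < n_background) {
    warn(sprintf(
      "only %d eligible background window(s) (< %d requested); using all",
      max(0L, length(eligible_base) - 1L), n_background
    ))
  }
  out <- vector("list", n_win)
  for (i in seq_len(n_win)) {
    elig <- setdiff(eligible_base, i)
    d <- abs(windows$gc[elig] - windows$gc[i])
    # ties broken by genomic order: elig is already in genomic order and
    # order() is stable
    take <- elig[order(d)][seq_len(min(n_background, length(elig)))]
    out[[i]] <- sort(take)
  }
  names(out) <- windows$window_id
  out
}

#' GC-matched normalized coverage (CovNorm)
#'
#' For each cell and window w0, the normalized coverage is the mean over
#' the matched background windows w_i of
#' `log((cov(w0) + 1) / (cov(w_i) + 1))` (natural log). A copy-neutral
#' window sits near 0; a hemizygous deletion halves coverage and, at
#' adequate depth, drives the value toward `-ln 2` (about -0.693). The +1
#' pseudocount stabilizes empty windows but damps the signal when mean
#' depth is much below 1. Masked windows emit no value (`NA`).
#'
#' @param cov_windows A `coverage_windows` object.
#' @param background_map Output of [match_gc_background()].
#' @return A list of class `covnorm_track`: `normalized` (cells x windows
#'   matrix), `windows`, `background_map`.
#' @export
covnorm <- function(cov_windows, background_map) {
  stopifnot(inherits(cov_windows, "coverage_windows"))
  cov <- cov_windows$coverage
  n_win <- ncol(cov)
  if (length(background_map) != n_win) {
    abort("background_map must cover every window", class = "atacwell_input_error")
  }
  lc <- log(cov + 1)
  norm <- matrix(NA_real_, nrow = nrow(cov), ncol = n_win,
                 dimnames = dimnames(cov))
  for (j in seq_len(n_win)) {
    if (j %in% cov_windows$mask) next
    bg <- background_map[[j]]
    norm[, j] <- lc[, j] - rowMeans(lc[, bg, drop = FALSE])
  }
  structure(
    list(normalized = norm, windows = cov_windows$windows,
         background_map = background_map, mask = cov_windows$mask),
    class = "covnorm_track"
  )
}

#' @export
print.covnorm_track <- function(x, ...) {
  cat(sprintf("<covnorm_track> %d cells x %d windows over %d arm(s)\n",
              nrow(x$normalized), ncol(x$normalized),
              dplyr::n_distinct(x$windows$arm)))
  invisible(x)
}

#' Call arm-level copy loss per cell
#'
#' Averages the normalized coverage over an arm's unmasked windows and
#' calls a loss when the mean falls below `threshold`. The default -0.3
#' sits between the copy-neutral expectation 0 and the hemizygous
#' expectation -ln 2. Cells with every arm window masked get `NA`
#' (no-call).
#'
#' @param track A `covnorm_track`.
#' @param arms Arm labels to call; `NULL` means every arm in the track.
#' @param threshold Loss-call threshold on the arm-mean normalized
#'   coverage (default -0.3).
#' @return A tibble: `cell`, `arm`, `mean_covnorm`, `loss` (logical, `NA`
#'   when no-call).
#' @export
call_arm_loss <- function(track, arms = NULL, threshold = -0.3) {
  stopifnot(inherits(track, "covnorm_track"))
  arms <- arms %||% unique(track$windows$arm)
  cells <- rownames(track$normalized)
  purrr::map(arms, function(a) {
    idx <- setdiff(which(track$windows$arm == a), track$mask)
    if (length(idx) == 0) {
      return(tibble(cell = cells, arm = a, mean_covnorm = NA_real_,
                    loss = NA))
    }
    mu <- rowMeans(track$normalized[, idx, drop = FALSE])
    tibble(cell = cells, arm = a, mean_covnorm = unname(mu),
           loss = unname(mu < threshold))
  }) %>%
    bind_rows() %>%
    arrange(.data$cell, .data$arm)
}
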