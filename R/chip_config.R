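#' Default synthetic genome model
#'
#' A small multi-chromosome genome used by the chip simulator. It carries a
#' scaled-down analog of chromosomes 1 and 19 (the arms involved in the
#' 1p/19q co-deletion of oligodendroglioma) plus three neutral chromosomes.
#' Arm labels are derived from the chromosome name and the p/q boundary,
#' so the deletion machinery can address "1p" and "19q" directly.
#'
#' @param scale Multiplier applied to all lengths (default 1 gives a
#'   ~400 kb genome; real chromosomes are not needed because coordinates
#'   are synthetic throughout).
#' @return A tibble with columns `chrom`, `length`, `arm_boundary`.
#' @export
default_genome_model <- function(scale = 1) {
  tibble(
    chrom = c("chr1", "chr2", "chr3", "chr4", "chr19"),
    length = as.integer(scale * c(100000L, 80000L, 80000L, 80000L, 60000L)),
    arm_boundary = as.integer(scale * c(50000L, 40000L, 40000L, 40000L, 26000L))
  )
}

#' Arm label for positions on a genome model
#'
#' @param genome_model Tibble with `chrom`, `length`, `arm_boundary`.
#' @param chrom,pos Vectors of chromosome names and positions.
#' @return Character vector of arm labels such as `"1p"`, `"19q"`.
#' @export
arm_label <- function(genome_model, chrom, pos) {
  bd <- setNames(genome_model$arm_boundary, genome_model$chrom)
  stem <- sub("^chr", "", chrom)
  paste0(stem, ifelse(pos < bd[chrom], "p", "q"))
}

#' Configuration for a simulated microfluidic chip experiment
#'
#' Bundles every tunable of [simulate_chip()]: chip geometry, well occupancy,
#' the per-subtype peak-accessibility model, read generation, PCR
#' duplication, cross-well leakage geometry, and arm-level deletions.
#' Defaults emulate a C1-style high-throughput chip run on a two-subtype
#' tumor (non-codeleted vs 1p/19q-codeleted), with subtype proportions
#' matching a 145:191 cell split.
#'
#' @param n_rows,n_cols Chip grid dimensions.
#' @param empty_well_rate Probability a well captures no nucleus.
#' @param doublet_rate Probability an occupied well holds two nuclei.
#' @param n_peaks Number of reference accessible regions in the synthetic
#'   genome.
#' @param peak_width Width of each synthetic peak in bp.
#' @param n_genes Number of synthetic genes (TSS annotation rows).
#' @param intergenic_peak_fraction Fraction of peaks placed away from any
#'   promoter.
#' @param subtype_fractions Named probability vector over subtypes; must
#'   sum to 1.
#' @param open_prob_by_subtype Optional subtypes x peaks matrix of open
#'   probabilities. When `NULL`, a matrix is built from `open_prob_base`
#'   and the marker block parameters below.
#' @param open_prob_base Open probability of non-marker peaks in every
#'   subtype.
#' @param marker_fraction Fraction of peaks made subtype-specific markers
#'   (split evenly across subtypes).
#' @param open_prob_marker_high,open_prob_marker_low Open probability of a
#'   marker peak in its own vs the other subtypes.
#' @param reads_per_open_peak Poisson mean of reads drawn inside each open
#'   peak of a cell.
#' @param n_background_reads Uniform background reads per cell.
#' @param read_length Fixed read length in bp.
#' @param pcr_dup_rate Probability each read gains one exact PCR copy.
#' @param pcr_substitution_rate Per-base substitution rate applied to PCR
#'   copies (0 disables mutant amplicons).
#' @param leak_donor_fraction Fraction of occupied wells acting as leakage
#'   donors.
#' @param leak_targets_per_donor Recipient wells drawn per donor.
#' @param leak_reads_per_target Reads copied into each recipient.
#' @param leak_row_weight,leak_col_weight,leak_other_weight Sampling
#'   weights for recipients in the donor's row, column, or elsewhere. The
#'   row weight dominates, mirroring the observed geometry of cross-well
#'   contamination; the small off-grid weight models diffuse background
#'   contamination and keeps the non-row/non-column baseline nonzero.
#' @param leak_empty_weight Multiplier on a recipient's weight when its
#'   well is empty — empty chambers are the main target of spilled
#'   material, and feeding each empty well from several donors keeps the
#'   pairwise sharing geometry stable.
#' @param deleted_arms_by_subtype Named list mapping a subtype to the
#'   chromosome arms hemizygously deleted in its cells (coverage halved).
#' @param genome_model Tibble of `chrom`, `length`, `arm_boundary`.
#' @param rng_seed Integer seed; the simulator is reproducible under it.
#' @return A list of class `chip_config`.
#' @export
#' @examples
#' cfg <- chip_config(n_rows = 4, n_cols = 4, n_peaks = 50, rng_seed = 7)
#' cfg$n_peaks
chip_config <- function(n_rows = 8L,
                        n_cols = 8L,
                        empty_well_rate = 0.10,
                        doublet_rate = 0.08,
                        n_peaks = 100L,
                        peak_width = 500L,
                        n_genes = 40L,
                        intergenic_peak_fraction = 0.1,
                        subtype_fractions = c(noncodel = 145 / 336, codel = 191 / 336),
                        open_prob_by_subtype = NULL,
                        open_prob_base = 0.3,
                        marker_fraction = 0.2,
                        open_prob_marker_high = 0.9,
                        open_prob_marker_low = 0.05,
                        reads_per_open_peak = 10,
                        n_background_reads = 400L,
                        read_length = 50L,
                        pcr_dup_rate = 0.15,
                        pcr_substitution_rate = 0,
                        leak_donor_fraction = 0.25,
                        leak_targets_per_donor = 10L,
                        leak_reads_per_target = 30L,
                        leak_row_weight = 3,
                        leak_col_weight = 1,
                        leak_other_weight = 0.25,
                        leak_empty_weight = 3,
                        deleted_arms_by_subtype = list(codel = c("1p", "19q")),
                        genome_model = default_genome_model(),
                        rng_seed = 1L) {
  cfg <- structure(
    list(
      n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
      empty_well_rate = empty_well_rate, doublet_rate = doublet_rate,
      n_peaks = as.integer(n_peaks), peak_width = as.integer(peak_width),
      n_genes = as.integer(n_genes),
      intergenic_peak_fraction = intergenic_peak_fraction,
      subtype_fractions = subtype_fractions,
      open_prob_by_subtype = open_prob_by_subtype,
      open_prob_base = open_prob_base,
      marker_fraction = marker_fraction,
      open_prob_marker_high = open_prob_marker_high,
      open_prob_marker_low = open_prob_marker_low,
      reads_per_open_peak = reads_per_open_peak,
      n_background_reads = as.integer(n_background_reads),
      read_length = as.integer(read_length),
      pcr_dup_rate = pcr_dup_rate,
      pcr_substitution_rate = pcr_substitution_rate,
      leak_donor_fraction = leak_donor_fraction,
      leak_targets_per_donor = as.integer(leak_targets_per_donor),
      leak_reads_per_target = as.integer(leak_reads_per_target),
      leak_row_weight = leak_row_weight,
      leak_col_weight = leak_col_weight,
      leak_other_weight = leak_other_weight,
      leak_empty_weight = leak_empty_weight,
      deleted_arms_by_subtype = deleted_arms_by_subtype,
      genome_model = genome_model,
      rng_seed = as.integer(rng_seed)
    ),
    class = "chip_config"
  )
  validate_chip_config(cfg)
  cfg
}

#' Chip configuration for the arm-deletion recovery study
#'
#' A chip design dimensioned for copy-number inference rather than
#' sequence-level QC: a full 10x10 chip (no empty wells or doublets), a
#' 50 kb five-chromosome genome, and ~12,000 background reads of 100 bp
#' per cell, giving about 24x mean depth per 1 kb window. At that depth
#' the +1 pseudocount in the normalized-coverage formula biases the
#' hemizygous log-ratio to log(13/25) = -0.654, comfortably within 0.1 of
#' -ln 2; at single-cell depths well below 1x the pseudocount would
#' swallow the signal entirely (see the methods vignette). Cells split
#' evenly between a neutral subtype and a codeleted subtype carrying
#' hemizygous 1p and 19q losses.
#'
#' Intended to be simulated with `with_sequences = FALSE`.
#'
#' @param rng_seed Integer seed.
#' @param n_cells_side Chip side length (default 10, i.e. 100 cells).
#' @return A `chip_config`.
#' @export
cnv_study_config <- function(rng_seed = 1L, n_cells_side = 10L) {
  gm <- tibble(
    chrom = c("chr1", "chr2", "chr3", "chr4", "chr19"),
    length = rep(10000L, 5),
    arm_boundary = rep(5000L, 5)
  )
  chip_config(
    n_rows = n_cells_side, n_cols = n_cells_side,
    empty_well_rate = 0, doublet_rate = 0,
    n_peaks = 20L, peak_width = 200L, n_genes = 10L,
    subtype_fractions = c(neutral = 0.5, codel = 0.5),
    reads_per_open_peak = 5, n_background_reads = 12000L,
    read_length = 100L,
    pcr_dup_rate = 0, leak_donor_fraction = 0,
    deleted_arms_by_subtype = list(codel = c("1p", "19q")),
    genome_model = gm,
    rng_seed = rng_seed
  )
}

#' @noRd
validate_chip_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (cfg$n_rows < 1L || cfg$n_cols < 1L) {
    abort("chip layout must contain at least one well", class = "atacwell_config_error")
  }
  probs <- c(
    cfg$empty_well_rate, cfg$doublet_rate, cfg$pcr_dup_rate,
    cfg$pcr_substitution_rate, cfg$leak_donor_fraction,
    cfg$intergenic_peak_fraction, cfg$marker_fraction,
    cfg$open_prob_base, cfg$open_prob_marker_high, cfg$open_prob_marker_low,
    cfg$subtype_fractions
  )
  if (any(probs < 0 | probs > 1)) {
    abort("all probabilities must lie in [0, 1]", class = "atacwell_config_error")
  }
  if (abs(sum(cfg$subtype_fractions) - 1) > 1e-8) {
    abort("subtype_fractions must sum to 1", class = "atacwell_config_error")
  }
  if (is.null(names(cfg$subtype_fractions))) {
    abort("subtype_fractions must be named", class = "atacwell_config_error")
  }
  if (!is.null(cfg$open_prob_by_subtype)) {
    m <- cfg$open_prob_by_subtype
    if (!is.matrix(m) ||
        nrow(m) != length(cfg$subtype_fractions) ||
        ncol(m) != cfg$n_peaks) {
      abort(
        "open_prob_by_subtype must be a subtypes x peaks matrix matching the config",
        class = "atacwell_config_error"
      )
    }
    if (any(m < 0 | m > 1)) {
      abort("open probabilities must lie in [0, 1]", class = "atacwell_config_error")
    }
  }
  gm <- cfg$genome_model
  if (!all(c("chrom", "length", "arm_boundary") %in% names(gm))) {
    abort("genome_model needs chrom, length, arm_boundary", class = "atacwell_config_error")
  }
  arms <- unlist(cfg$deleted_arms_by_subtype, use.names = FALSE)
  known <- c(
    arm_label(gm, gm$chrom, 0),
    arm_label(gm, gm$chrom, gm$length - 1L)
  )
  if (length(arms) && !all(arms %in% known)) {
    abort("deleted arms must be arms of the genome model", class = "atacwell_config_error")
  }
  invisible(cfg)
}

# Build the default subtype x peak open-probability matrix: a shared
# baseline plus an even split of marker peaks with high/low contrast.
#' @noRd
default_open_probs <- function(cfg) {
  n_sub <- length(cfg$subtype_fractions)
  m <- matrix(cfg$open_prob_base, nrow = n_sub, ncol = cfg$n_peaks,
              dimnames = list(names(cfg$subtype_fractions), NULL))
  n_marker <- floor(cfg$marker_fraction * cfg$n_peaks)
  if (n_marker > 0) {
    owner <- rep_len(seq_len(n_sub), n_marker)
    for (i in seq_len(n_marker)) {
      m[, i] <- cfg$open_prob_marker_low
      m[owner[i], i] <- cfg$open_prob_marker_high
    }
  }
  m
}

#' @export
print.chip_config <- function(x, ...) {
  cat(sprintf(
    "<chip_config> %dx%d wells, %d peaks, %d genes, subtypes: %s (seed %d)\n",
    x$n_rows, x$n_cols, x$n_peaks, x$n_genes,
    paste(names(x$subtype_fractions), collapse = "/"), x$rng_seed
  ))
  invisible(x)
}
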