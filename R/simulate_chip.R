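#' Simulate a microfluidic snATAC-seq chip with known ground truth
#'
#' Generates a rows x columns chip experiment: wells are empty, singlet or
#' doublet; each nucleus opens peaks according to its subtype's
#' per-peak probabilities; reads are drawn inside open peaks plus a uniform
#' genomic background; cells of a subtype with hemizygously deleted arms
#' draw reads on those arms at half rate. In sequence mode, reads carry
#' i.i.d. random DNA sequences, PCR duplicates add exact (optionally
#' mutated) within-well copies, and cross-well leakage copies exact
#' sequences from donor wells into recipient wells, preferentially along
#' the donor's chip row and, to a lesser degree, its column.
#'
#' Every random draw flows from `config$rng_seed`, so repeated calls with
#' the same configuration are identical.
#'
#' @param config A [chip_config()].
#' @param with_sequences If `TRUE` (default) reads carry sequences and the
#'   PCR-duplication and leakage stages run. `FALSE` gives a
#'   coordinate-only store (sequence `NA`, no duplicates, no leakage),
#'   suitable for coverage and CNV studies where sequence-level phenomena
#'   are irrelevant.
#' @return A list of class `chip_sim` with elements:
#' \describe{
#'   \item{reads}{tibble: `read_id`, `well`, `row`, `col`, `chrom`,
#'     `start`, `end` (0-based half-open), `sequence`, `origin`
#'     (`"peak"`, `"background"`, `"pcr_dup"`, `"leak"`).}
#'   \item{cell_peaks}{tibble of truly open ("called") peaks per occupied
#'     well: `well`, `chrom`, `start`, `end`, `peak_id`.}
#'   \item{peaks}{master reference peak table with `peak_id` and `gene`
#'     (NA for intergenic peaks).}
#'   \item{genes}{TSS annotation: `gene`, `chrom`, `tss`, `strand`.}
#'   \item{truth}{ground truth: `wells` (status and subtype per well),
#'     `leaks` (injected copy id, source read id, donor and recipient
#'     well), `deleted_arms` (well, arm).}
#'   \item{config}{the configuration used.}
#' }
#' @export
#' @examples
#' sim <- simulate_chip(chip_config(n_rows = 4, n_cols = 4, n_peaks = 40,
#'                                  n_background_reads = 50, rng_seed = 7))
#' dplyr::count(sim$reads, origin)
simulate_chip <- function(config, with_sequences = TRUE) {
  validate_chip_config(config)
  withr::with_seed(config$rng_seed, {
    simulate_chip_impl(config, with_sequences)
  })
}

#' @noRd
simulate_chip_impl <- function(cfg, with_sequences) {
  gm <- cfg$genome_model
  L <- cfg$read_length
  subtypes <- names(cfg$subtype_fractions)

  ## --- wells and nuclei -------------------------------------------------
  wells <- tidyr::expand_grid(row = seq_len(cfg$n_rows), col = seq_len(cfg$n_cols)) %>%
    mutate(well = well_id(.data$row, .data$col), .before = 1)
  n_wells <- nrow(wells)
  is_empty <- runif(n_wells) < cfg$empty_well_rate
  is_doublet <- !is_empty & (runif(n_wells) < cfg$doublet_rate)
  wells$status <- ifelse(is_empty, "empty", ifelse(is_doublet, "doublet", "singlet"))

  components <- wells %>%
    filter(.data$status != "empty") %>%
    mutate(n_nuclei = ifelse(.data$status == "doublet", 2L, 1L)) %>%
    tidyr::uncount(.data$n_nuclei, .id = "component") %>%
    mutate(subtype = sample(subtypes, n(), replace = TRUE,
                            prob = cfg$subtype_fractions))

  wells <- wells %>%
    left_join(
      components %>%
        group_by(.data$well) %>%
        summarise(subtype = .data$subtype[1],
                  subtype2 = ifelse(n() > 1, .data$subtype[2], NA_character_),
                  .groups = "drop"),
      by = "well"
    )

  ## --- genes and peaks --------------------------------------------------
  genes <- tibble(
    gene = sprintf("g%03d", seq_len(cfg$n_genes)),
    chrom = sample(gm$chrom, cfg$n_genes, replace = TRUE, prob = gm$length),
    strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  ) %>%
    mutate(tss = floor(runif(n(), 2000, setNames(gm$length, gm$chrom)[.data$chrom] - 2000)))

  # Reference peak sets are non-overlapping intervals, so genic peaks are
  # placed on disjoint slots around each TSS (promoter plus flanking
  # elements) and intergenic peaks are rejection-sampled against overlap.
  chrom_len <- setNames(gm$length, gm$chrom)
  n_intergenic <- round(cfg$intergenic_peak_fraction * cfg$n_peaks)
  n_genic <- cfg$n_peaks - n_intergenic
  slot_offsets <- round(seq(-1750, 1750, length.out = 5))
  slot_grid <- tidyr::expand_grid(gene_idx = seq_len(cfg$n_genes),
                                  offset = slot_offsets)
  slot_grid <- slot_grid[sample(nrow(slot_grid), min(n_genic, nrow(slot_grid))), ]
  genic <- tibble(
    chrom = genes$chrom[slot_grid$gene_idx],
    center = genes$tss[slot_grid$gene_idx] + slot_grid$offset,
    gene = genes$gene[slot_grid$gene_idx]
  )
  peaks <- genic %>%
    mutate(
      start = pmin(pmax(.data$center - cfg$peak_width %/% 2L, 0L),
                   chrom_len[.data$chrom] - cfg$peak_width),
      end = .data$start + cfg$peak_width
    ) %>%
    arrange(.data$chrom, .data$start) %>%
    # greedy drop of the rare cross-gene collisions
    group_by(.data$chrom) %>%
    filter(is.na(dplyr::lag(.data$end)) |
             .data$start >= cummax(dplyr::lag(.data$end, default = 0L))) %>%
    ungroup()
  # top up with non-overlapping uniform intergenic peaks
  n_needed <- cfg$n_peaks - nrow(peaks)
  tries <- 0L
  while (n_needed > 0L && tries < 1000L) {
    tries <- tries + 1L
    ch <- sample(gm$chrom, 1L, prob = gm$length)
    st <- floor(runif(1, 0, chrom_len[ch] - cfg$peak_width))
    cand_end <- st + cfg$peak_width
    clash <- any(peaks$chrom == ch & peaks$start < cand_end & peaks$end > st)
    if (!clash) {
      peaks <- bind_rows(peaks, tibble(chrom = ch, center = NA_real_,
                                       gene = NA_character_,
                                       start = as.integer(st),
                                       end = as.integer(cand_end)))
      n_needed <- n_needed - 1L
    }
  }
  peaks <- peaks %>%
    arrange(.data$chrom, .data$start) %>%
    mutate(peak_id = sprintf("peak%04d", row_number())) %>%
    select("peak_id", "chrom", "start", "end", "gene")

  open_prob <- cfg$open_prob_by_subtype %||% default_open_probs(cfg)

  ## --- per-nucleus open peaks ------------------------------------------
  comp_open <- components %>%
    mutate(open = purrr::map(.data$subtype, function(s) {
      which(runif(cfg$n_peaks) < open_prob[s, ])
    })) %>%
    select("well", "row", "col", "component", "subtype", "open") %>%
    tidyr::unnest_longer("open", values_to = "peak_idx") %>%
    mutate(peak_id = peaks$peak_id[.data$peak_idx])

  cell_peaks <- comp_open %>%
    distinct(.data$well, .data$peak_id) %>%
    left_join(peaks, by = "peak_id") %>%
    arrange(.data$well, .data$chrom, .data$start) %>%
    select("well", "chrom", "start", "end", "peak_id")

  ## --- reads ------------------------------------------------------------
  peak_reads <- comp_open %>%
    left_join(peaks, by = "peak_id") %>%
    mutate(n_reads = rpois(n(), cfg$reads_per_open_peak)) %>%
    filter(.data$n_reads > 0) %>%
    tidyr::uncount(.data$n_reads) %>%
    mutate(
      offset = floor(runif(n()) * pmax(1L, .data$end - .data$start - L + 1L)),
      start = .data$start + .data$offset,
      origin = "peak"
    ) %>%
    select("well", "row", "col", "component", "subtype", "chrom", "start", "origin")

  n_bg <- nrow(components) * cfg$n_background_reads
  bg_chrom <- sample(gm$chrom, n_bg, replace = TRUE, prob = gm$length)
  bg_reads <- components[rep(seq_len(nrow(components)), each = cfg$n_background_reads),
                         c("well", "row", "col", "component", "subtype")] %>%
    mutate(
      chrom = bg_chrom,
      start = floor(runif(n_bg) * (chrom_len[bg_chrom] - L)),
      origin = "background"
    )

  reads <- bind_rows(peak_reads, bg_reads) %>%
    mutate(
      start = as.integer(pmin(pmax(.data$start, 0L), chrom_len[.data$chrom] - L)),
      end = .data$start + L
    )

  # hemizygous deletions: reads on a deleted arm of the nucleus' subtype
  # survive with probability 1/2
  del_map <- cfg$deleted_arms_by_subtype
  if (length(del_map) && nrow(reads)) {
    arm <- arm_label(gm, reads$chrom, reads$start)
    deleted <- purrr::map2_lgl(reads$subtype, arm, function(s, a) {
      a %in% del_map[[s]]
    })
    keep <- !deleted | (runif(nrow(reads)) < 0.5)
    reads <- reads[keep, , drop = FALSE]
  }

  reads <- reads %>%
    arrange(.data$well, .data$chrom, .data$start, .data$end, .data$origin) %>%
    group_by(.data$well) %>%
    mutate(read_id = sprintf("%s_r%05d", .data$well, row_number())) %>%
    ungroup() %>%
    select("read_id", "well", "row", "col", "chrom", "start", "end", "origin")

  deleted_arms <- components %>%
    mutate(arms = purrr::map(.data$subtype, ~ del_map[[.x]] %||% character())) %>%
    tidyr::unnest_longer("arms", values_to = "arm") %>%
    filter(!is.na(.data$arm)) %>%
    distinct(.data$well, .data$arm)

  leaks <- tibble(read_id = character(), source_read_id = character(),
                  donor_well = character(), well = character())

  if (with_sequences) {
    reads$sequence <- random_sequences(nrow(reads), L)

    ## PCR duplicates: exact within-well copies, optionally mutated
    dup <- which(runif(nrow(reads)) < cfg$pcr_dup_rate)
    if (length(dup)) {
      copies <- reads[dup, , drop = FALSE] %>%
        mutate(
          read_id = paste0(.data$read_id, "_dup"),
          sequence = mutate_sequences(.data$sequence, cfg$pcr_substitution_rate),
          origin = "pcr_dup"
        )
      reads <- bind_rows(reads, copies)
    }

    ## cross-well leakage
    occupied <- wells$well[wells$status != "empty"]
    n_donors <- round(cfg$leak_donor_fraction * length(occupied))
    if (n_donors > 0) {
      donors <- sample(occupied, n_donors)
      leak_list <- vector("list", length(donors))
      for (i in seq_along(donors)) {
        d <- donors[i]
        drow <- wells$row[wells$well == d]
        dcol <- wells$col[wells$well == d]
        cand <- wells %>% filter(.data$well != d)
        w <- ifelse(cand$row == drow, cfg$leak_row_weight,
                    ifelse(cand$col == dcol, cfg$leak_col_weight,
                           cfg$leak_other_weight))
        # empty chambers are the main recipients of spilled material
        w <- w * ifelse(cand$status == "empty", cfg$leak_empty_weight, 1)
        n_t <- min(cfg$leak_targets_per_donor, nrow(cand))
        targets <- sample(cand$well, n_t, prob = w)
        donor_reads <- reads %>%
          filter(.data$well == d, .data$origin %in% c("peak", "background"))
        if (nrow(donor_reads) == 0) next
        per_target <- purrr::map(targets, function(t) {
          src <- donor_reads %>%
            slice(sample(n(), min(cfg$leak_reads_per_target, n())))
          trow <- wells$row[wells$well == t]
          tcol <- wells$col[wells$well == t]
          src %>%
            mutate(
              source_read_id = .data$read_id,
              donor_well = d,
              well = t, row = trow, col = tcol,
              read_id = sprintf("leak_%s_to_%s_%03d", d, t, row_number()),
              origin = "leak"
            )
        })
        leak_list[[i]] <- bind_rows(per_target)
      }
      leaked <- bind_rows(leak_list)
      if (nrow(leaked)) {
        leaks <- leaked %>%
          select("read_id", "source_read_id", "donor_well", "well")
        reads <- bind_rows(
          reads,
          leaked %>% select(-"source_read_id", -"donor_well")
        )
      }
    }
  } else {
    reads$sequence <- NA_character_
  }

  reads <- reads %>%
    arrange(.data$well, .data$read_id) %>%
    select("read_id", "well", "row", "col", "chrom", "start", "end",
           "sequence", "origin")

  structure(
    list(
      reads = reads,
      cell_peaks = cell_peaks,
      peaks = peaks,
      genes = genes,
      truth = list(wells = wells, leaks = leaks, deleted_arms = deleted_arms),
      open_prob = open_prob,
      config = cfg
    ),
    class = "chip_sim"
  )
}

#' @export
print.chip_sim <- function(x, ...) {
  st <- table(x$truth$wells$status)
  cat(sprintf(
    "<chip_sim> %dx%d chip: %s | %d reads, %d peaks, %d genes, %d leaked copies\n",
    x$config$n_rows, x$config$n_cols,
    paste(sprintf("%s=%d", names(st), st), collapse = " "),
    nrow(x$reads), nrow(x$peaks), nrow(x$genes), nrow(x$truth$leaks)
  ))
  invisible(x)
}
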