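test_that("within-well dedup collapses exact duplicates and keeps singletons", {
  r <- toy_reads(c("a", "b", "c"), "R01C01",
                 sequence = c("ACGT", "ACGT", "TTTT"))
  out <- dedup_within_well(r, 0)
  expect_setequal(out$sequence, c("ACGT", "TTTT"))
  expect_true("a" %in% out$read_id)  # smallest id among equal sequences
  # empty input is the identity
  expect_equal(nrow(dedup_within_well(r[0, ], 0)), 0)
})

test_that("dedup with substitutions groups near-identical reads and keeps the
           lexicographically smallest sequence", {
  r <- toy_reads(c("a", "b"), "R01C01", sequence = c("ACGT", "ACGA"))
  out <- dedup_within_well(r, 1)
  expect_equal(nrow(out), 1)
  expect_equal(out$sequence, "ACGA")
  # brute-force pairwise Hamming grouping on a bigger toy set
  seqs <- c("AAAA", "AAAT", "AATT", "GGGG", "GGGC", "CCCC")
  r2 <- toy_reads(letters[1:6], "R01C01", sequence = seqs)
  out2 <- dedup_within_well(r2, 1)
  # components at Hamming<=1: {AAAA,AAAT,AATT}(chained), {GGGG,GGGC}, {CCCC}
  expect_setequal(out2$sequence, c("AAAA", "GGGC", "CCCC"))
  # wells are independent: same sequences in another well are untouched
  r3 <- dplyr::bind_rows(r2, toy_reads("z", "R02C01", sequence = "AAAA",
                                       row = 2L))
  expect_equal(sum(dedup_within_well(r3, 1)$well == "R02C01"), 1)
})

test_that("dedup at radius 0 preserves the distinct-sequence set per well", {
  sim <- simulate_chip(leak_chip_config(4))
  out <- dedup_within_well(sim$reads, 0)
  before <- tapply(sim$reads$sequence, sim$reads$well, function(s) sort(unique(s)))
  after <- tapply(out$sequence, out$well, function(s) sort(unique(s)))
  expect_identical(before, after[names(before)])
})

test_that("cross-well purge removes shared sequences from all wells", {
  r <- dplyr::bind_rows(
    toy_reads(c("a1", "a2"), "R01C01", sequence = c("AAAA", "CCCC")),
    toy_reads(c("b1", "b2"), "R01C02", sequence = c("CCCC", "GGGG"), col = 2L)
  )
  out <- purge_cross_well(r)
  expect_setequal(out$reads$sequence, c("AAAA", "GGGG"))
  expect_equal(out$report$removed_count, 2)
  expect_equal(out$report$removed_fraction, 0.5)
  # no sharing -> no-op
  r2 <- dplyr::bind_rows(
    toy_reads("a", "R01C01", sequence = "AAAA"),
    toy_reads("b", "R01C02", sequence = "TTTT", col = 2L)
  )
  out2 <- purge_cross_well(r2)
  expect_equal(out2$report$removed_count, 0)
  expect_identical(out2$reads, r2)
})

test_that("purge leaves no sequence in more than one well and is idempotent", {
  sim <- simulate_chip(leak_chip_config(5))
  deduped <- dedup_within_well(sim$reads, 0)
  once <- purge_cross_well(deduped)
  multi <- once$reads |>
    dplyr::distinct(sequence, well) |>
    dplyr::count(sequence) |>
    dplyr::filter(n >= 2)
  expect_equal(nrow(multi), 0)
  twice <- purge_cross_well(once$reads)
  expect_identical(twice$reads, once$reads)
  expect_equal(twice$report$removed_count, 0)
})

test_that("purge removes exactly the leak-affected reads on a synthetic chip", {
  sim <- simulate_chip(leak_chip_config(6))
  deduped <- dedup_within_well(sim$reads, 0)
  cleaned <- purge_cross_well(deduped)$reads
  removed <- setdiff(deduped$read_id, cleaned$read_id)
  affected <- union(sim$truth$leaks$read_id, sim$truth$leaks$source_read_id)
  expect_setequal(removed, affected)
})

test_that("pairwise sharing statistics follow their definition", {
  # 2x2 chip: one same-row pair shares half the smaller well's reads
  r <- dplyr::bind_rows(
    toy_reads(c("a1", "a2", "a3", "a4"), "R01C01",
              sequence = c("AAAA", "CCCC", "GGGG", "TTTT")),
    toy_reads(c("b1", "b2"), "R01C02", sequence = c("AAAA", "ACGT"), col = 2L),
    toy_reads("c1", "R02C01", sequence = "CAAA", row = 2L),
    toy_reads("d1", "R02C02", sequence = "CCGG", row = 2L, col = 2L)
  )
  rep <- leakage_diagnostics(r)
  pw <- rep$pairwise_shared
  target <- pw[pw$well_a == "R01C01" & pw$well_b == "R01C02", ]
  expect_equal(target$fraction, 0.5)
  expect_equal(target$relation, "row")
  expect_true(all(pw$fraction[pw$well_a != "R01C01" | pw$well_b != "R01C02"] == 0))
  # no sharing anywhere -> enrichments are 1 by convention
  r0 <- dplyr::bind_rows(
    toy_reads("a", "R01C01", sequence = "AAAA"),
    toy_reads("b", "R01C02", sequence = "CCCC", col = 2L),
    toy_reads("c", "R02C01", sequence = "GGGG", row = 2L)
  )
  rep0 <- leakage_diagnostics(r0)
  expect_equal(rep0$row_enrichment, 1)
  expect_equal(rep0$col_enrichment, 1)
})

test_that("row-weighted leakage yields row enrichment above column above 1", {
  sim <- simulate_chip(leak_chip_config(8))
  rep <- leakage_diagnostics(dedup_within_well(sim$reads, 0))
  expect_gt(rep$row_enrichment, rep$col_enrichment)
  expect_gt(rep$col_enrichment, 1)
})

test_that("TSS profile measures signed midpoint distances and the 2 kb fraction", {
  tss <- tibble::tibble(gene = c("gA", "gB"), chrom = c("chr1", "chr1"),
                        tss = c(10000L, 50000L), strand = c("+", "-"))
  mk <- function(mid) toy_reads(sprintf("r%05d", mid), "R01C01",
                                start = mid - 50L, end = mid + 50L)
  # all reads centered on a TSS
  all_on <- dplyr::bind_rows(lapply(c(10000L, 50000L), mk))
  expect_equal(tss_profile(all_on, tss)$fraction_within, 1)
  # all reads >= 10 kb away
  all_off <- dplyr::bind_rows(lapply(c(25000L, 30000L, 70000L), mk))
  expect_equal(tss_profile(all_off, tss)$fraction_within, 0)
  # hand-placed toy: 3 of 10 within +/- 2 kb
  mids <- c(10000L, 11000L, 8500L,            # within (d = 0, 1000, -1500)
            13000L, 6000L, 20000L, 30000L,    # outside
            55000L, 60000L, 40000L)           # outside (gB side)
  prof <- tss_profile(dplyr::bind_rows(lapply(mids, mk)), tss)
  expect_equal(prof$fraction_within, 0.3)
  # sign follows strand: read downstream of the minus-strand gB TSS at 50500
  d <- tss_profile(mk(50500L), tss)$distances$distance
  expect_equal(d, -500)
  # reads on unknown chromosomes stay in the denominator at infinite distance
  odd <- dplyr::bind_rows(mk(10000L), toy_reads("x", "R01C01", chrom = "chrUn",
                                                start = 0L, end = 100L))
  expect_equal(tss_profile(odd, tss)$fraction_within, 0.5)
  expect_error(tss_profile(mk(1L), tss[0, ]), class = "atacwell_input_error")
})
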