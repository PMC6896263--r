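test_that("the 50 bp overlap rule is enforced at the boundary", {
  ref <- tibble::tibble(chrom = "chr1", start = 150L, end = 300L)
  hit <- overlap_with_reference(
    tibble::tibble(cell = "c1", chrom = "chr1", start = 100L, end = 200L), ref
  )
  expect_equal(unname(hit$values[1, 1]), 1L)  # overlap exactly 50
  miss <- overlap_with_reference(
    tibble::tibble(cell = "c1", chrom = "chr1", start = 100L, end = 199L), ref
  )
  expect_equal(unname(miss$values[1, 1]), 0L)  # overlap 49
})

test_that("overlap matrix agrees with brute-force interval intersection", {
  set.seed(42)
  ref <- tibble::tibble(
    chrom = sample(c("chr1", "chr2"), 10, replace = TRUE),
    start = sample.int(5000, 10)
  ) |>
    dplyr::mutate(end = start + sample(60:400, 10, replace = TRUE)) |>
    dplyr::arrange(chrom, start)
  cells <- tibble::tibble(
    cell = sample(paste0("c", 1:4), 25, replace = TRUE),
    chrom = sample(c("chr1", "chr2"), 25, replace = TRUE),
    start = sample.int(5000, 25)
  ) |>
    dplyr::mutate(end = start + sample(60:400, 25, replace = TRUE))
  m <- suppressWarnings(overlap_with_reference(cells, ref, 50))
  for (ci in rownames(m$values)) {
    cp <- cells[cells$cell == ci, ]
    for (j in seq_len(nrow(m$peaks))) {
      rp <- m$peaks[j, ]
      ov <- pmax(0, pmin(cp$end, rp$end) - pmax(cp$start, rp$start)) *
        (cp$chrom == rp$chrom)
      expect_equal(unname(m$values[ci, rp$peak_id]),
                   as.integer(any(ov >= 50)))
    }
  }
  # identical peak sets: every reference column is hit (self-overlap >= 50)
  self <- ref |> dplyr::mutate(cell = "c1")
  ms <- overlap_with_reference(self, ref, 50)
  expect_true(all(ms$values[1, ] == 1L))
})

test_that("overlap detection is symmetric in the two peak sets", {
  set.seed(7)
  a <- tibble::tibble(chrom = "chr1", start = sort(sample.int(4000, 6) * 3L)) |>
    dplyr::mutate(end = start + 200L, peak_id = sprintf("a%02d", 1:6))
  b <- tibble::tibble(chrom = "chr1", start = sort(sample.int(4000, 5) * 3L)) |>
    dplyr::mutate(end = start + 150L, peak_id = sprintf("b%02d", 1:5))
  m_ab <- overlap_with_reference(
    a |> dplyr::mutate(cell = peak_id), b, 50
  )
  m_ba <- overlap_with_reference(
    b |> dplyr::mutate(cell = peak_id), a, 50
  )
  expect_identical(m_ab$values[a$peak_id, b$peak_id],
                   t(m_ba$values[b$peak_id, a$peak_id]))
})

test_that("the filter cascade matches an exhaustive brute-force filter", {
  # toy designed per the narrative: one peak below min-cells, one cell with
  # a single positive, one overloaded cell
  v <- rbind(
    c(1, 1, 1, 1), c(1, 1, 1, 0), c(1, 1, 0, 0),
    c(1, 1, 1, 0), c(1, 0, 0, 0), c(0, 1, 1, 0)
  )
  m <- as_access_matrix(v)
  out <- filter_cascade(m, min_cells_per_peak = 5, min_peaks_per_cell = 2,
                        max_peaks_per_cell = 3)
  expect_identical(out$values,
                   brute_filter(m$values, 5, 2, 3))
  # grid of thresholds on seeded random toys
  set.seed(11)
  for (i in 1:5) {
    v <- matrix(rbinom(100, 1, 0.4), 10, 10)
    m <- as_access_matrix(v)
    for (mc in c(0, 2, 4)) {
      for (mp in c(0, 2, 5)) {
        for (xp in c(3, 6, Inf)) {
          oracle <- brute_filter(m$values, mc, mp, xp)
          if (nrow(oracle) == 0) {
            expect_error(filter_cascade(m, mc, mp, xp),
                         class = "atacwell_empty_error")
          } else {
            expect_identical(filter_cascade(m, mc, mp, xp)$values, oracle)
          }
        }
      }
    }
  }
  # identity thresholds
  m <- as_access_matrix(matrix(rbinom(36, 1, 0.5), 6, 6))
  expect_identical(filter_cascade(m, 0, 0, Inf)$values, m$values)
})

test_that("cascade reports the realized percentile and the fixpoint mode terminates", {
  set.seed(3)
  v <- matrix(rbinom(400, 1, 0.3), 20, 20)
  m <- as_access_matrix(v)
  out <- filter_cascade(m, 2, 2, 10)
  expect_equal(out$max_peak_percentile, 100 * mean(rowSums(v) <= 10))
  fix <- filter_cascade(m, 2, 2, 10, iterate = TRUE)
  # a fixpoint really is a fixpoint
  again <- filter_cascade(fix, 2, 2, 10)
  expect_identical(again$values, fix$values)
  expect_true(all(colSums(fix$values) >= 2))
  expect_true(all(rowSums(fix$values) >= 2 & rowSums(fix$values) <= 10))
})

test_that("gene collapsing ORs member peaks and skips far/intergenic peaks", {
  peaks <- tibble::tibble(
    peak_id = sprintf("p%d", 1:5),
    chrom = "chr1",
    start = c(900L, 1500L, 9000L, 20000L, 52000L),
    end = c(1400L, 2000L, 9500L, 20500L, 52500L)
  )
  ann <- tibble::tibble(gene = c("gA", "gB", "gC"), chrom = "chr1",
                        tss = c(1000L, 9200L, 30000L), strand = "+")
  v <- rbind(
    c(0, 1, 0, 1, 0),
    c(0, 0, 1, 0, 1),
    c(0, 0, 0, 0, 0)
  )
  rownames(v) <- c("c1", "c2", "c3")
  colnames(v) <- peaks$peak_id
  m <- atacwell:::new_access_matrix(v, peaks = peaks, filtered = TRUE)
  m <- collapse_to_genes(m, ann, promoter_window = 2000)
  # p1,p2 -> gA; p3 -> gB; p4 (10.8 kb from gB) and p5 (22 kb from gC) unassigned
  expect_identical(sort(colnames(m$gene_view)), c("gA", "gB"))
  expect_equal(unname(m$gene_view["c1", ]), c(1L, 0L))  # OR over p1=0, p2=1
  expect_equal(unname(m$gene_view["c2", ]), c(0L, 1L))
  expect_equal(unname(m$gene_view["c3", ]), c(0L, 0L))
  # brute-force OR over the peak-to-gene map
  for (g in colnames(m$gene_view)) {
    member <- m$gene_map$peak_id[!is.na(m$gene_map$gene) & m$gene_map$gene == g]
    expect_equal(unname(m$gene_view[, g]),
                 unname(as.integer(rowSums(v[, member, drop = FALSE]) > 0)))
    # gene column sums never exceed the member peak totals
    expect_lte(sum(m$gene_view[, g]), sum(v[, member]))
  }
  expect_warning(collapse_to_genes(m, ann[ann$chrom == "none", ]),
                 "lacks chromosome")
})

test_that("open promoter fractions reproduce the printed subgroup contrasts", {
  gv <- matrix(0L, nrow = 336, ncol = 1,
               dimnames = list(sprintf("cell%03d", 1:336), "CYTOR"))
  noncodel <- rownames(gv)[1:145]
  codel <- rownames(gv)[146:336]
  gv[noncodel[1:101], "CYTOR"] <- 1L
  gv[codel[1:20], "CYTOR"] <- 1L
  m <- as_gene_view(gv)
  f1 <- open_promoter_fraction(m, "CYTOR", noncodel)
  expect_equal(f1$positives, 101)
  expect_equal(f1$group_size, 145)
  expect_equal(round(f1$percentage), 70)   # paper prints 70% (101/145)
  f2 <- open_promoter_fraction(m, "CYTOR", codel)
  expect_equal(f2$percentage, 10.5)        # paper prints 10.5% (20/191)
  # 0 of n and error cases
  f0 <- open_promoter_fraction(m, "CYTOR", codel[21:40])
  expect_equal(f0$percentage, 0)
  expect_error(open_promoter_fraction(m, "CYTOR", character()),
               class = "atacwell_empty_error")
  expect_error(open_promoter_fraction(m, "NOPE"), class = "atacwell_input_error")
})
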