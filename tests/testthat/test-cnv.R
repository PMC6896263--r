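gm_toy <- tibble::tibble(chrom = "chrA", length = 26000000L,
                         arm_boundary = 13000000L)

test_that("window tiling follows size, overlap, and partial-window rules", {
  w <- tile_windows(gm_toy, 10e6, 2e6)
  expect_equal(w$start, c(0, 8e6, 16e6))
  expect_equal(w$end, c(10e6, 18e6, 26e6))
  expect_equal(w$arm, c("Ap", "Aq", "Aq"))
  # zero overlap -> disjoint tiling; trailing 6 Mb window kept (>= half size)
  w0 <- tile_windows(gm_toy, 10e6, 0)
  expect_equal(w0$start, c(0, 10e6, 20e6))
  expect_equal(w0$end, c(10e6, 20e6, 26e6))
  expect_true(all(utils::head(w0$end, -1) == utils::tail(w0$start, -1)))
  # chromosome shorter than a window -> one whole-chromosome window
  short <- tile_windows(tibble::tibble(chrom = "chrB", length = 4000000L,
                                       arm_boundary = 2000000L), 10e6, 2e6)
  expect_equal(nrow(short), 1)
  expect_equal(c(short$start, short$end), c(0, 4e6))
  # a trailing fragment below half a window is dropped
  w2 <- tile_windows(tibble::tibble(chrom = "chrC", length = 12000000L,
                                    arm_boundary = 6000000L), 10e6, 2e6)
  expect_equal(w2$start, 0)
})

test_that("window coverage is mean depth with boundary-aware attribution", {
  w <- tile_windows(gm_toy, 10e6, 2e6)
  r <- tibble::tibble(well = "c1", chrom = "chrA",
                      start = 1000L, end = 1100L)
  cw <- window_coverage(r, w)
  expect_equal(unname(cw$coverage[1, 1]), 100 / 1e7)
  # no reads at all -> zero coverage everywhere
  cw0 <- window_coverage(r[0, ] |> dplyr::mutate(well = character()), w)
  expect_equal(nrow(cw0$coverage), 0)
  # straddling read on a toy 20 bp genome: per-base brute force
  gm20 <- tibble::tibble(chrom = "chrT", length = 20L, arm_boundary = 10L)
  w20 <- tile_windows(gm20, 10L, 0L)
  r20 <- tibble::tibble(well = "c1", chrom = "chrT", start = 5L, end = 15L)
  cw20 <- window_coverage(r20, w20)
  base_hits <- vapply(seq_len(nrow(w20)), function(j) {
    sum(seq(w20$start[j], w20$end[j] - 1) >= r20$start &
          seq(w20$start[j], w20$end[j] - 1) < r20$end)
  }, numeric(1))
  expect_equal(unname(cw20$coverage[1, ]), base_hits / 10)
})

test_that("GC matching picks nearest-GC eligible windows with genomic tie-break", {
  w <- tibble::tibble(
    window_id = sprintf("w%02d", 1:12),
    chrom = "chrA",
    start = seq(0, 11) * 1000L, end = seq(1, 12) * 1000L,
    arm = rep(c("Ap", "Aq"), each = 6),
    gc = c(0.40, 0.45, 0.50, 0.55, 0.60, 0.42,
           0.48, 0.52, 0.58, 0.44, 0.46, 0.54)
  )
  bg <- match_gc_background(w, n_background = 5)
  for (i in seq_len(nrow(w))) {
    elig <- setdiff(seq_len(nrow(w)), i)
    oracle <- elig[order(abs(w$gc[elig] - w$gc[i]))][1:5]
    expect_setequal(bg[[i]], oracle)
    expect_false(i %in% bg[[i]])
  }
  # excluded arms and masks never appear in a background
  bg2 <- match_gc_background(w, n_background = 3, excluded_arms = "Ap",
                             mask = 7L)
  for (i in seq_len(nrow(w))) {
    expect_true(all(w$arm[bg2[[i]]] != "Ap"))
    expect_false(7L %in% bg2[[i]])
    expect_false(i %in% bg2[[i]])
  }
  # all-identical GC: the first n in genomic order are taken
  w3 <- w |> dplyr::mutate(gc = 0.5)
  bg3 <- match_gc_background(w3, n_background = 5)
  expect_equal(bg3[[12]], 1:5)
  expect_equal(bg3[[1]], 2:6)
  # too few eligible windows -> use all, with a warning
  expect_warning(match_gc_background(w, n_background = 50), "eligible")
})

test_that("normalized coverage matches its closed form", {
  w <- tibble::tibble(window_id = c("w1", "w2", "w3"), chrom = "chrA",
                      start = c(0L, 1000L, 2000L), end = c(1000L, 2000L, 3000L),
                      arm = "Ap", gc = 0.5)
  cw <- structure(
    list(coverage = matrix(c(4, 9, 9), nrow = 1,
                           dimnames = list("c1", w$window_id)),
         windows = w, mask = integer()),
    class = "coverage_windows"
  )
  bg <- list(w1 = 2:3, w2 = c(1L, 3L), w3 = 1:2)
  tr <- covnorm(cw, bg)
  expect_equal(unname(tr$normalized[1, "w1"]), log(5 / 10))
  # equal coverage everywhere -> 0
  cw$coverage[1, ] <- 7
  expect_equal(unname(covnorm(cw, bg)$normalized[1, ]), c(0, 0, 0))
  # masked windows emit no value
  cw$mask <- 2L
  expect_true(is.na(covnorm(cw, bg)$normalized[1, "w2"]))
})

test_that("normalization is scale-invariant in the large-count limit", {
  w <- tibble::tibble(window_id = sprintf("w%d", 1:4), chrom = "chrA",
                      start = 0:3 * 1000L, end = 1:4 * 1000L,
                      arm = "Ap", gc = 0.5)
  mk <- function(cov) structure(
    list(coverage = matrix(cov, nrow = 1, dimnames = list("c1", w$window_id)),
         windows = w, mask = integer()),
    class = "coverage_windows"
  )
  bg <- match_gc_background(w, n_background = 3)
  base <- c(2e6, 1e6, 4e6, 3e6)
  t1 <- covnorm(mk(base), bg)$normalized
  t2 <- covnorm(mk(10 * base), bg)$normalized
  expect_equal(t1, t2, tolerance = 1e-5)
})

test_that("hemizygous arm deletion is recovered from a seeded chip", {
  cfg <- cnv_study_config(rng_seed = 17, n_cells_side = 6)
  sim <- simulate_chip(cfg, with_sequences = FALSE)
  w <- window_gc(tile_windows(cfg$genome_model, 1000L, 0L))
  cw <- window_coverage(sim$reads, w)
  bg <- match_gc_background(w, 30L, excluded_arms = c("1p", "19q"))
  calls <- call_arm_loss(covnorm(cw, bg), threshold = -0.3)
  truth <- sim$truth$deleted_arms
  ev <- dplyr::left_join(calls,
                         dplyr::mutate(truth, deleted = TRUE),
                         by = c(cell = "well", "arm"))
  ev$deleted <- !is.na(ev$deleted)
  del <- ev$mean_covnorm[ev$deleted]
  ret <- ev$mean_covnorm[!ev$deleted]
  expect_lt(abs(mean(del) - log(0.5)), 0.1)
  expect_lt(abs(mean(ret)), 0.1)
  expect_gte(mean(ev$loss[ev$deleted]), 0.9)      # sensitivity
  expect_gte(mean(!ev$loss[!ev$deleted]), 0.9)    # specificity
  # degenerate thresholds follow the < rule
  track <- covnorm(cw, bg)
  expect_true(all(call_arm_loss(track, threshold = Inf)$loss))
  expect_false(any(call_arm_loss(track, threshold = -Inf)$loss))
  # no-call when an arm is fully masked
  track$mask <- which(track$windows$arm == "1p")
  nc <- call_arm_loss(track, arms = "1p")
  expect_true(all(is.na(nc$loss)))
})
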