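mkwin <- function(n, seq_id = "1", gc = 0.4, depth = 30, frac_proper = 1,
                  frac_large = 0, frac_small = 0, n_reads = 200) {
  data.frame(seq_id = seq_id, start = (seq_len(n) - 1L) * 1000L,
             end = seq_len(n) * 1000L, gc = gc, depth = depth,
             frac_proper = frac_proper, frac_large_insert = frac_large,
             frac_small_insert = frac_small, n_reads = n_reads,
             stringsAsFactors = FALSE)
}

test_that("GC normalization divides by the per-bin median", {
  w <- mkwin(3, depth = c(10, 20, 30))
  out <- gc_normalize(w, min_bin_windows = 1)
  expect_equal(out$norm_depth, c(0.5, 1.0, 1.5))

  # two bins, medians 30 and 60; a depth-30 window in the second bin -> 0.5
  w2 <- rbind(mkwin(51, gc = 0.30, depth = 30),
              mkwin(51, gc = 0.50, depth = c(rep(60, 50), 30)))
  out2 <- gc_normalize(w2, min_bin_windows = 50)
  expect_equal(out2$norm_depth[102], 30 / 60)
  expect_equal(out2$norm_depth[1], 1)

  # sparse bin falls back to the global median
  w3 <- rbind(mkwin(60, gc = 0.40, depth = 40),
              mkwin(10, gc = 0.60, depth = 20))
  out3 <- gc_normalize(w3, min_bin_windows = 50)
  expect_equal(out3$norm_depth[61], 20 / 40)  # global median is 40

  expect_error(gc_normalize(mkwin(5, depth = 0)), "zero")
})

test_that("classification flags follow the thresholds and union rules", {
  w <- mkwin(10)
  w$norm_depth <- 1
  w$norm_depth[4] <- 0.1
  w$frac_proper[7] <- 0.5
  cl <- classify_windows(w)
  expect_true(cl$LC[4] && !any(cl$LC[-4]))
  expect_true(cl$LPP[7] && !any(cl$LPP[-7]))
  expect_equal(sum(cl$lqlc), 2L)
  expect_equal(sum((cl$end - cl$start)[cl$lqlc]), 2000L)
  # lq excludes pure LC
  expect_false(cl$lq[4])
  expect_true(cl$lq[7])

  # uniform track at the median with all proper reads: no flags
  w0 <- mkwin(20)
  w0$norm_depth <- 1
  cl0 <- classify_windows(w0)
  expect_equal(sum(cl0$lqlc), 0L)

  # low-read windows are LC but not evaluated for read-composition flags
  wl <- mkwin(2, n_reads = c(2L, 200L), frac_proper = c(0, 1))
  wl$norm_depth <- 1
  cll <- classify_windows(wl)
  expect_true(cll$LC[1])
  expect_false(cll$LPP[1])
})

test_that("flag unions satisfy the category arithmetic", {
  sim <- simulate_genome(small_sim_config(seed = 21))
  tr <- simulate_window_track(sim)
  cl <- classify_windows(gc_normalize(tr$windows))
  wb <- cl$end - cl$start
  bases <- function(f) sum(wb[f])
  expect_lte(bases(cl$lqlc), bases(cl$lq) + bases(cl$LC))
  expect_lte(bases(cl$lq), bases(cl$HC) + bases(cl$LPP) + bases(cl$LLI) + bases(cl$LSI))
})

test_that("relaxing thresholds never increases flagged bases", {
  sim <- simulate_genome(small_sim_config(seed = 22))
  tr <- simulate_window_track(sim)
  w <- gc_normalize(tr$windows)
  strict <- classify_windows(w, qc_thresholds())
  relaxed <- classify_windows(w, qc_thresholds(
    lc_norm_depth_max = 0.1, hc_norm_depth_min = 3, proper_min = 0.6,
    large_insert_max = 0.3, small_insert_max = 0.3, min_reads = 1))
  for (f in c("HC", "LC", "LPP", "LLI", "LSI", "lq", "lqlc")) {
    expect_lte(sum(relaxed[[f]]), sum(strict[[f]]))
  }
})

test_that("mask subtraction keeps only non-intersecting LQLC windows", {
  w <- mkwin(10)
  w$norm_depth <- 1
  w$norm_depth[c(2, 4, 6, 8, 9)] <- 0.05   # 5 LQLC windows
  cl <- classify_windows(w)
  expect_equal(sum(cl$lqlc), 5L)

  none <- subtract_mask(cl, data.frame(seq_id = "zz", start = 0L, end = 10L))
  expect_equal(nrow(none$windows), 5L)

  all_mask <- subtract_mask(cl, data.frame(seq_id = "1", start = 0L, end = 10000L))
  expect_equal(all_mask$bases, 0)

  # mask overlapping windows 2 and 4 (1 bp suffices)
  two <- subtract_mask(cl, data.frame(seq_id = "1",
                                      start = c(1999L, 3999L), end = c(2000L, 4000L)))
  expect_equal(nrow(two$windows), 3L)
  expect_equal(two$bases, 3000)

  # BED path input
  bed <- tempfile(fileext = ".bed")
  write_bed(data.frame(seq_id = "1", start = 1000L, end = 2000L), bed)
  expect_equal(nrow(subtract_mask(cl, bed)$windows), 4L)
})

test_that("qc_summary reports per-category bases, percentages and LQLC GC", {
  w <- mkwin(10)
  w$norm_depth <- 1
  cl0 <- classify_windows(w)
  s0 <- qc_summary(cl0)
  expect_true(all(s0$table$bases == 0))

  w$norm_depth[1] <- 3      # HC
  w$gc[1] <- 0.62
  w$norm_depth[2] <- 0.1    # LC
  w$gc[2] <- 0.60
  cl <- classify_windows(w)
  s <- qc_summary(cl)
  expect_equal(s$table$bases[s$table$category == "high_coverage"], 1000)
  expect_equal(s$table$bases[s$table$category == "lqlc"], 2000)
  expect_equal(s$table$pct_genome[s$table$category == "lqlc"], 20)
  expect_equal(s$mean_gc_lqlc, 0.61)

  sm <- qc_summary(cl, data.frame(seq_id = "1", start = 0L, end = 1000L))
  expect_equal(sm$table$bases[sm$table$category == "lqlc_unmasked"], 1000)
})

test_that("window summaries from alignments count pairing and depth", {
  # 10 reads in the first window, 4 lacking the proper-pair flag
  reads <- data.frame(pos = seq(1, 300, length.out = 10),
                      flag = c(rep(99L, 6), rep(97L, 4)),
                      len = 100L, isize = 300L)
  sam <- write_tmp_sam("t1", 2000L, reads)
  recs <- Biostrings::DNAStringSet(c(t1 = paste(rep("ACGT", 500), collapse = "")))
  w <- windows_from_alignments(sam, recs, window = 1000L,
                               insert_bounds = c(100, 1000))
  expect_equal(nrow(w), 2L)
  expect_equal(w$n_reads, c(10L, 0L))
  expect_equal(w$frac_proper, c(0.6, 0))
  expect_equal(w$gc, c(0.5, 0.5))

  # empty alignment file: every window present with zero reads
  sam0 <- write_tmp_sam("t1", 2000L, NULL)
  w0 <- windows_from_alignments(sam0, recs, window = 1000L,
                                insert_bounds = c(100, 1000))
  expect_equal(w0$n_reads, c(0L, 0L))
  expect_equal(w0$depth, c(0, 0))

  # uniform tiling at depth 30: 3 reads of 100 bp starting every 10 bp
  pos <- rep(seq(1, 1901, by = 10), each = 3)
  reads30 <- data.frame(pos = pos, flag = 99L, len = 100L, isize = 300L)
  sam30 <- write_tmp_sam("t1", 2000L, reads30)
  w30 <- windows_from_alignments(sam30, recs, window = 1000L,
                                 insert_bounds = c(100, 1000))
  expect_true(all(abs(w30$depth - 30) < 2))
  expect_equal(w30$frac_proper, c(1, 1))

  # improper insert fractions from |template length|
  readsI <- data.frame(pos = seq(1, 100, length.out = 10), flag = 99L,
                       len = 100L, isize = c(rep(300L, 7), 5000L, 5000L, 20L))
  samI <- write_tmp_sam("t1", 2000L, readsI)
  wI <- windows_from_alignments(samI, recs, window = 1000L,
                                insert_bounds = c(100, 1000))
  expect_equal(wI$frac_large_insert[1], 0.2)
  expect_equal(wI$frac_small_insert[1], 0.1)
})

test_that("window stats TSV round-trips through read/write", {
  sim <- simulate_genome(small_sim_config(seed = 23))
  tr <- simulate_window_track(sim)
  p <- tempfile(fileext = ".tsv")
  write_window_stats(tr$windows, p)
  back <- read_window_stats(p)
  expect_equal(back, tr$windows, tolerance = 1e-12)
})
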