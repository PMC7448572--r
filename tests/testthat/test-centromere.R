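test_that("RepeatMasker .out parsing handles both strand dialects", {
  p <- rm_out_fixture()
  rec <- read_repeatmasker_out(p)
  expect_equal(nrow(rec), 2L)
  # + strand: repeat cols 1 300 (50) -> aligned 300, consensus 350
  expect_equal(rec$consensus_aligned[1], 300L)
  expect_equal(rec$consensus_length[1], 350L)
  expect_equal(rec$start[1], 1000L)   # 0-based
  expect_equal(rec$end[1], 1300L)
  expect_equal(rec$strand[1], "+")
  expect_false(rec$overlap_flag[1])
  # C strand: swapped columns (50) 300 1 -> same consensus arithmetic
  expect_equal(rec$consensus_aligned[2], 300L)
  expect_equal(rec$consensus_length[2], 350L)
  expect_equal(rec$strand[2], "-")
  expect_true(rec$overlap_flag[2])
  expect_equal(rec$repeat_class[2], "Satellite/centr")

  # headers only -> empty
  empty <- tempfile()
  writeLines(c("   SW   perc ...", "score   div. ...", ""), empty)
  expect_equal(nrow(read_repeatmasker_out(empty)), 0L)

  # truncated row -> parse error naming the line
  bad <- tempfile()
  writeLines(c("", " 1200 12.5 0.1 0.2 chrA 1 100"), bad)
  expect_error(read_repeatmasker_out(bad), "line 2")
})

test_that("divergence/length filtering keeps the stated boundaries", {
  mk <- function(div, aligned, clen = 300L) {
    data.frame(seq_id = "s", start = 0L, end = 100L, strand = "+",
               repeat_name = "r", repeat_class = "LINE", pct_div = div,
               consensus_aligned = aligned, consensus_length = clen,
               score = 1, overlap_flag = FALSE)
  }
  expect_equal(nrow(filter_repeats(mk(41.0, 300))), 0L)
  expect_equal(nrow(filter_repeats(mk(40.0, 300))), 1L)
  expect_equal(nrow(filter_repeats(mk(10, 200))), 0L)   # 66.7 % of consensus
  expect_equal(nrow(filter_repeats(mk(10, 210))), 1L)   # exactly 70 %
  expect_equal(nrow(filter_repeats(mk(10, 300)[0, ])), 0L)
})

test_that("repeat filtering is an order-independent pure subset", {
  set.seed(41)
  rec <- data.frame(seq_id = "s", start = 0L, end = 100L, strand = "+",
                    repeat_name = sprintf("r%d", 1:50), repeat_class = "x",
                    pct_div = runif(50, 0, 60),
                    consensus_aligned = sample(100:300, 50, TRUE),
                    consensus_length = 300L, score = 1, overlap_flag = FALSE)
  kept <- filter_repeats(rec)
  expect_true(all(kept$repeat_name %in% rec$repeat_name))
  perm <- rec[sample(nrow(rec)), ]
  kept_perm <- filter_repeats(perm)
  expect_setequal(kept_perm$repeat_name, kept$repeat_name)
})

test_that("monomer search recovers exact and diverged tandem copies", {
  set.seed(43)
  mono <- paste(sample(c("A", "C", "G", "T"), 340, replace = TRUE), collapse = "")
  bg1 <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE), collapse = "")
  bg2 <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE), collapse = "")
  s <- paste0(bg1, strrep(mono, 20), bg2)
  recs <- Biostrings::DNAStringSet(c(chr = s))
  mons <- Biostrings::DNAStringSet(c(SAT = mono))
  hits <- search_satellite_monomers(recs, mons)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 2000L)
  expect_equal(hits$end, 2000L + 20L * 340L)
  expect_equal(hits$identity, 1.0)

  # no seed match
  none <- search_satellite_monomers(Biostrings::DNAStringSet(c(x = bg1)), mons)
  expect_equal(nrow(none), 0L)

  expect_error(search_satellite_monomers(recs,
    Biostrings::DNAStringSet(c(short = "ACGTACGT"))), "shorter than seed")

  # 10 % per-base mutated copies: identity near 0.9, most copies recovered
  copies <- vapply(1:20, function(i) {
    ch <- strsplit(mono, "")[[1]]
    hit <- which(runif(340) < 0.10)
    for (j in hit) ch[j] <- sample(setdiff(c("A", "C", "G", "T"), ch[j]), 1)
    paste(ch, collapse = "")
  }, character(1))
  s2 <- paste0(bg1, paste(copies, collapse = ""), bg2)
  hits2 <- search_satellite_monomers(Biostrings::DNAStringSet(c(chr = s2)), mons)
  covered <- sum(hits2$end - hits2$start)
  expect_gte(covered / (20 * 340), 0.9)
  expect_true(all(abs(hits2$identity - 0.9) < 0.08))
})

test_that("monomer search finds reverse-complement arrays", {
  set.seed(44)
  mono <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
  arr_rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(strrep(mono, 10))))
  bg <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE), collapse = "")
  s <- paste0(bg, arr_rc, bg)
  hits <- search_satellite_monomers(Biostrings::DNAStringSet(c(chr = s)),
                                    Biostrings::DNAStringSet(c(SAT = mono)))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 1000L)
  expect_equal(hits$end, 1000L + 2000L)
})

test_that("interval merging collapses nearby regions and is idempotent", {
  expect_equal(nrow(merge_and_collapse(data.frame(seq_id = character(),
                                                  start = integer(),
                                                  end = integer()))), 0L)
  df <- data.frame(seq_id = "c", start = c(0L, 3400L, 7000L),
                   end = c(3000L, 6000L, 7200L))
  m <- merge_and_collapse(df, 500L)
  expect_equal(m$start, c(0L, 7000L))
  expect_equal(m$end, c(6000L, 7200L))
  expect_equal(m$n_merged, c(2L, 1L))
  m2 <- merge_and_collapse(m, 500L)
  expect_equal(m2[, c("seq_id", "start", "end")], m[, c("seq_id", "start", "end")])
  expect_equal(m2$n_merged, m$n_merged)
})

test_that("merging matches the transitive-closure oracle on random sets", {
  set.seed(45)
  for (i in 1:200) {
    n <- sample(1:30, 1)
    df <- data.frame(seq_id = sample(c("a", "b"), n, TRUE),
                     start = sample(0:5000, n, TRUE))
    df$end <- df$start + sample(1:800, n, TRUE)
    d <- sample(c(0L, 100L, 500L), 1)
    got <- merge_and_collapse(df, d)
    got <- got[order(got$seq_id, got$start), c("seq_id", "start", "end")]
    want <- oracle_merge(df, d)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
    # output disjoint with gaps strictly > d
    for (sid in unique(got$seq_id)) {
      g <- got[got$seq_id == sid, ]
      if (nrow(g) > 1) expect_true(all(g$start[-1] - g$end[-nrow(g)] > d))
    }
  }
})

test_that("centromere calls keep only regions strictly longer than 5 kb", {
  df <- data.frame(seq_id = "c", start = c(0L, 10000L), end = c(5000L, 16000L),
                   sources = "x", n_merged = 1L)
  calls <- call_centromeres(df)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$length, 6000L)
})

test_that("three-source prediction merges annotations with provenance", {
  sim <- simulate_genome(small_sim_config(seed = 46))
  rm_path <- tempfile(fileext = ".out")
  simulate_repeatmasker_out(sim, rm_path)
  rm <- read_repeatmasker_out(rm_path)
  hits <- search_satellite_monomers(sim$records, sim$monomer)
  pred <- predict_centromeres(list(default_library = rm), hits)
  expect_equal(nrow(pred$calls), nrow(sim$truth$centromeres))
  for (i in seq_len(nrow(sim$truth$centromeres))) {
    tr <- sim$truth$centromeres[i, ]
    j <- which(pred$calls$seq_id == tr$seq_id)
    expect_length(j, 1L)
    expect_lte(pred$calls$start[j], tr$start)
    expect_gte(pred$calls$end[j], tr$end)
    expect_match(pred$calls$sources[j], "default_library")
    expect_match(pred$calls$sources[j], "monomer_search")
  }
  expect_true(pred$summary$mean_length >= pred$summary$median_length ||
                pred$summary$n_merged_regions <= 2)
  # decoy interspersed repeats must not seed calls
  expect_false(any(grepl("DECOY", pred$calls$sources)))
})
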