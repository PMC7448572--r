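test_that("karyotype order sorts numerics, sex chromosomes, then scaffolds", {
  expect_equal(karyotype_order(c("2", "10", "1", "X")), c("1", "2", "10", "X"))
  expect_equal(karyotype_order(c("X", "Y", "MT", "AEMK02000361.1")),
               c("X", "Y", "MT", "AEMK02000361.1"))
  expect_equal(karyotype_order(c("scaffold_10", "scaffold_2", "1")),
               c("1", "scaffold_2", "scaffold_10"))
})

test_that("karyotype order is invariant under input permutation", {
  set.seed(51)
  base_names <- c(as.character(1:18), "X", "Y", "MT",
                  sprintf("scaffold_%d", sample(1:500, 79)))
  ref <- karyotype_order(base_names)
  for (i in 1:20) {
    expect_equal(karyotype_order(sample(base_names)), ref)
  }
})

mk_manifest <- function(n, chrom = "1") {
  data.frame(marker_id = sprintf("m%02d", seq_len(n)), chip = "c1",
             manifest_chrom = chrom, manifest_pos = seq_len(n) * 1000L,
             stringsAsFactors = FALSE)
}

test_that("rank assignment applies the -1 unmapped penalty", {
  man <- mk_manifest(5)
  pl <- data.frame(marker_id = man$marker_id, assembly_chrom = "1",
                   assembly_pos = man$manifest_pos)
  rk <- assign_ranks(man, pl)
  expect_equal(rk$manifest_rank, 1:5)
  expect_equal(rk$assembly_rank, 1:5)

  pl2 <- pl[-3, ]
  rk2 <- assign_ranks(man, pl2)
  expect_equal(rk2$assembly_rank, c(1L, 2L, -1L, 3L, 4L))

  # placement for an unknown marker is ignored with a warning
  pl3 <- rbind(pl, data.frame(marker_id = "ghost", assembly_chrom = "1",
                              assembly_pos = 1L))
  expect_warning(rk3 <- assign_ranks(man, pl3), "absent")
  expect_equal(rk3$assembly_rank, 1:5)
})

test_that("an inverted chromosome reverses its assembly rank block", {
  man <- rbind(mk_manifest(5, "1"), within(mk_manifest(5, "2"), {
    marker_id <- sprintf("n%02d", 1:5)
  }))
  pl <- data.frame(marker_id = man$marker_id, assembly_chrom = man$manifest_chrom,
                   assembly_pos = man$manifest_pos)
  pl$assembly_pos[6:10] <- rev(pl$assembly_pos[6:10])   # invert chromosome 2
  rk <- assign_ranks(man, pl)
  expect_equal(rk$assembly_rank[1:5], 1:5)
  expect_equal(rk$assembly_rank[6:10], 10:6)
})

test_that("spearman_rho reproduces the worked rank examples", {
  man <- mk_manifest(5)
  pl <- data.frame(marker_id = man$marker_id, assembly_chrom = "1",
                   assembly_pos = man$manifest_pos)
  r1 <- spearman_rho(assign_ranks(man, pl))
  expect_equal(r1$rho, 1.0)
  expect_equal(r1$n_unmapped, 0L)

  # x = 1..5 against y = (1,2,-1,3,4): rank(y) = (2,3,1,4,5) -> rho 0.7
  rk <- assign_ranks(man, pl[-3, ])
  r2 <- spearman_rho(rk)
  expect_equal(r2$rho, 0.7, tolerance = 1e-12)
  expect_equal(r2$n_unmapped, 1L)
  expect_lt(r2$p_value, 1)
})

test_that("spearman_rho matches the independent oracle, with -1 blocks", {
  set.seed(52)
  for (i in 1:300) {
    n <- sample(3:50, 1)
    x <- seq_len(n)
    y <- sample(n)
    y[stats::runif(n) < 0.2] <- -1L
    if (stats::sd(y) == 0) next
    got <- spearman_rho(data.frame(marker_id = as.character(x),
                                   manifest_chrom = "1",
                                   manifest_rank = x, assembly_rank = y))$rho
    expect_equal(got, oracle_spearman(x, y), tolerance = 1e-12)
  }
})

test_that("tie-free small cases agree with cor on explicit ranks", {
  set.seed(53)
  for (i in 1:50) {
    n <- sample(4:8, 1)
    x <- sample(n)
    y <- sample(n)
    got <- spearman_rho(data.frame(marker_id = as.character(1:n),
                                   manifest_chrom = "1",
                                   manifest_rank = x, assembly_rank = y))$rho
    expect_equal(got, stats::cor(rank(x), rank(y)), tolerance = 1e-12)
  }
})

test_that("perfect reversal of all chromosomes gives rho = -1", {
  man <- mk_manifest(20)
  pl <- data.frame(marker_id = man$marker_id, assembly_chrom = "1",
                   assembly_pos = rev(man$manifest_pos))
  expect_equal(spearman_rho(assign_ranks(man, pl))$rho, -1)
})

test_that("marker spacing statistics and desert detection", {
  one <- data.frame(marker_id = c("a", "b"), assembly_chrom = "1",
                    assembly_pos = c(0L, 1000L))
  s1 <- marker_spacing(one)
  expect_equal(s1$mean_spacing, 1000)
  expect_equal(s1$sd_spacing, 0)

  three <- data.frame(marker_id = c("a", "b", "c"), assembly_chrom = "1",
                      assembly_pos = c(0L, 1000L, 3000L))
  s3 <- marker_spacing(three)
  expect_equal(s3$mean_spacing, 1500)
  expect_equal(s3$sd_spacing, stats::sd(c(1000, 2000)))
  expect_equal(s3$max_desert$length, 2000L)
  expect_equal(s3$max_desert$start, 1000L)

  # spacings never cross chromosomes
  two_chr <- data.frame(marker_id = c("a", "b", "c", "d"),
                        assembly_chrom = c("1", "1", "2", "2"),
                        assembly_pos = c(0L, 500L, 90000L, 90500L))
  s2 <- marker_spacing(two_chr)
  expect_equal(s2$n_spacings, 2L)
  expect_equal(s2$mean_spacing, 500)

  expect_error(marker_spacing(data.frame(marker_id = "a", assembly_chrom = "1",
                                         assembly_pos = 1L)), "2 mapped")
})

test_that("spacing is translation-invariant and scales linearly", {
  set.seed(54)
  pl <- data.frame(marker_id = sprintf("m%d", 1:30), assembly_chrom = "1",
                   assembly_pos = sort(sample(1:100000, 30)))
  s <- marker_spacing(pl)
  shifted <- pl; shifted$assembly_pos <- shifted$assembly_pos + 77777L
  s_sh <- marker_spacing(shifted)
  expect_equal(s_sh$mean_spacing, s$mean_spacing)
  expect_equal(s_sh$sd_spacing, s$sd_spacing)
  scaled <- pl; scaled$assembly_pos <- scaled$assembly_pos * 3L
  s_sc <- marker_spacing(scaled)
  expect_equal(s_sc$mean_spacing, 3 * s$mean_spacing)
  expect_equal(s_sc$sd_spacing, 3 * s$sd_spacing)
})

test_that("exact probe placement enforces uniqueness on both strands", {
  set.seed(55)
  bg <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE), collapse = "")
  probe <- substr(bg, 1001, 1070)
  dup <- substr(bg, 2001, 2070)
  recs <- Biostrings::DNAStringSet(c(chr1 = paste0(bg, dup)))  # dup occurs twice
  rc_probe <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(bg, 3001, 3070))))
  man <- data.frame(marker_id = c("u", "d", "r", "absent"),
                    probe_seq = c(probe, dup, rc_probe, strrep("ACGTT", 14)))
  pl <- place_probes_exact(recs, man)
  expect_equal(pl$assembly_pos[1], 1001L)
  expect_equal(pl$strand[1], "+")
  expect_true(is.na(pl$assembly_chrom[2]))   # two occurrences
  expect_false(pl$unique[2])
  expect_equal(pl$assembly_pos[3], 3001L)    # leftmost base of the - strand hit
  expect_equal(pl$strand[3], "-")
  expect_true(is.na(pl$assembly_chrom[4]))
})

test_that("dotplot export carries unmapped penalties and facets", {
  man <- mk_manifest(5)
  rk <- assign_ranks(man, data.frame(marker_id = man$marker_id[-2],
                                     assembly_chrom = "1",
                                     assembly_pos = man$manifest_pos[-2]))
  df <- dotplot_export(rk)
  expect_equal(nrow(df), 5L)
  expect_equal(sum(df$assembly_rank == -1L), 1L)
  expect_true(all(c("manifest_chrom", "manifest_rank", "assembly_rank") %in% names(df)))
  p <- tempfile(fileext = ".tsv")
  dotplot_export(rk, p)
  expect_equal(nrow(utils::read.delim(p)), 5L)
})

test_that("manifests read from CSV/TSV with chromosome aliases", {
  man <- mk_manifest(4)
  man$manifest_chrom <- c("SSC1", "SSC1", "SSC2", "SSCX")
  p <- tempfile(fileext = ".csv")
  utils::write.csv(man, p, row.names = FALSE, quote = FALSE)
  got <- read_manifest(p, chrom_aliases = c(SSC1 = "1", SSC2 = "2", SSCX = "X"))
  expect_equal(got$manifest_chrom, c("1", "1", "2", "X"))
})
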