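## Fixture builders shared across test files. Everything is generated in
## code; nothing is read from disk except what a test writes itself.

write_tmp_fasta <- function(named_seqs, gz = FALSE) {
  path <- tempfile(fileext = if (gz) ".fa.gz" else ".fa")
  con <- if (gz) gzfile(path, "w") else file(path, "w")
  for (nm in names(named_seqs)) {
    writeLines(c(paste0(">", nm), named_seqs[[nm]]), con)
  }
  close(con)
  path
}

## small, fast simulation used by many tests
small_sim_config <- function(seed = 1L, ...) {
  sim_config(
    seed = seed,
    chromosomes = data.frame(name = c("1", "2"),
                             length = c(300000L, 200000L),
                             gc = c(0.42, 0.46), stringsAsFactors = FALSE),
    n_unplaced = 2L, unplaced_length = 20000L,
    n_probes = 150L, ...)
}

## tiny simulation for replicate loops: one 60 kb chromosome, no satellite
tiny_telomere_config <- function(seed, mut = 0, units = 334L) {
  sim_config(seed = seed,
             chromosomes = data.frame(name = "1", length = 60000L, gc = 0.42,
                                      stringsAsFactors = FALSE),
             n_unplaced = 0L, centromere_array_length = 0L,
             n_spanned_gaps = 1L, n_unspanned_gaps = 0L,
             telomere_units = units, telomere_mut = mut, n_probes = 10L)
}

## write a coordinate-sorted SAM file for one reference sequence
write_tmp_sam <- function(seq_id, ref_len, reads) {
  path <- tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", seq_id, ref_len))
  body <- character(0)
  if (!is.null(reads) && nrow(reads)) {
    reads$pos <- as.integer(reads$pos)
    reads$isize <- as.integer(reads$isize)
    reads <- reads[order(reads$pos), , drop = FALSE]
    body <- sprintf("r%d\t%d\t%s\t%d\t60\t%dM\t%s\t%d\t%d\t%s\t*",
                    seq_len(nrow(reads)), reads$flag, seq_id, reads$pos,
                    reads$len, ifelse(reads$isize == 0, "*", "="),
                    ifelse(reads$isize == 0, 0L, reads$pos + 1L),
                    reads$isize,
                    vapply(reads$len, function(l)
                      paste(rep("A", l), collapse = ""), character(1)))
  }
  writeLines(c(hdr, body), path)
  path
}

## minimal RepeatMasker .out content with controlled field values
rm_out_fixture <- function(extra_lines = character(0)) {
  path <- tempfile(fileext = ".out")
  writeLines(c(
    "   SW   perc perc perc  query      position in query     matching       repeat            position in  repeat",
    "score   div. del. ins.  sequence    begin     end    (left)    repeat         class/family         begin  end (left)   ID",
    "",
    ##  + strand: repeat cols begin end (left) = 1 300 (50)
    " 1200 12.5  0.1  0.2  chrA   1001  1300  (8700) +  REP1  LINE/L1  1 300 (50)  1",
    ##  C strand: repeat cols (left) end begin = (50) 300 1
    "  950 38.0  0.0  0.0  chrA   5001  5300  (4700) C  REP2  Satellite/centr  (50) 300 1  2 *",
    extra_lines), path)
  path
}
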