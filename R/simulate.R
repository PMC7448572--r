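#' Simulation configuration
#'
#' Defines the study conditions for the synthetic genome: chromosome sizes
#' and GC, telomere and centromeric-satellite specifications, gap
#' structure, the alignment-window depth model, planted anomalies, and the
#' probe set. All randomness flows from `seed`; the same configuration
#' always yields byte-identical outputs.
#'
#' Defaults describe a desk-scale version of a long-read mammalian
#' assembly: three chromosome-scale sequences (0.6-1 Mb) with distinct GC,
#' a handful of unplaced scaffolds, 334-unit telomeric arrays at both
#' chromosome ends, a 50 kb centromeric array of a 340 bp satellite
#' monomer at 5% divergence, a few spanned gaps plus one unspanned
#' (100 bp, linkage-no) gap per chromosome, and a ~65x short-read depth
#' track with mild overdispersion.
#'
#' @param seed Integer seed.
#' @param chromosomes data.frame with `name`, `length`, `gc`.
#' @param n_unplaced,unplaced_length,unplaced_gc Unplaced scaffold spec.
#' @param telomere_units Exact hexamer units planted at each chromosome
#'   end (334 units = 2,004 bp).
#' @param telomere_mut Per-base substitution rate within planted telomeres.
#' @param centromere_monomer_length,centromere_array_length,centromere_divergence
#'   Satellite monomer length (bp), planted array length (bp), and
#'   per-base divergence of each copy from the consensus monomer.
#' @param n_spanned_gaps,spanned_gap_range,n_unspanned_gaps,unspanned_gap_length
#'   Per-chromosome gap counts and sizes; unspanned gaps are emitted as
#'   AGP type-U linkage-no lines and 100 N in sequence.
#' @param window,depth_mean,depth_dispersion,read_len,proper_p,improper_insert_p
#'   Window width (bp), mean depth, negative-binomial `size`, read length,
#'   nominal properly-paired probability, and nominal improper-insert
#'   fraction per side.
#' @param n_lc_intervals,lc_interval_windows,lc_factor Planted low-coverage
#'   intervals (count, width in windows, depth multiplier).
#' @param n_hc_intervals,hc_interval_windows,hc_factor Planted collapsed
#'   repeats (high coverage).
#' @param n_misassembly,misassembly_windows,misassembly_proper,misassembly_large_insert
#'   Planted misassembly junctions and their pairing signature.
#' @param n_probes,probe_length,probe_dropout Probe set size, probe length
#'   (bp) and the probability that a probe's site is destroyed in the
#'   derived assembly (making it unmapped).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(
    seed = 1L,
    chromosomes = data.frame(name = c("1", "2", "3"),
                             length = c(1000000L, 800000L, 600000L),
                             gc = c(0.42, 0.46, 0.40),
                             stringsAsFactors = FALSE),
    n_unplaced = 3L, unplaced_length = 50000L, unplaced_gc = 0.41,
    telomere_units = 334L, telomere_mut = 0,
    centromere_monomer_length = 340L, centromere_array_length = 50000L,
    centromere_divergence = 0.05,
    n_spanned_gaps = 3L, spanned_gap_range = c(200L, 800L),
    n_unspanned_gaps = 1L, unspanned_gap_length = 100L,
    window = 1000L, depth_mean = 65, depth_dispersion = 100,
    read_len = 150L, proper_p = 0.98, improper_insert_p = 0.02,
    n_lc_intervals = 2L, lc_interval_windows = 10L, lc_factor = 0.15,
    n_hc_intervals = 2L, hc_interval_windows = 10L, hc_factor = 2.5,
    n_misassembly = 2L, misassembly_windows = 3L, misassembly_proper = 0.5,
    misassembly_large_insert = 0.3,
    n_probes = 600L, probe_length = 70L, probe_dropout = 0) {
  stopifnot(all(chromosomes$gc >= 0 & chromosomes$gc <= 1),
            telomere_mut >= 0, telomere_mut <= 1,
            centromere_divergence >= 0, centromere_divergence <= 1,
            probe_dropout >= 0, probe_dropout <= 1,
            all(chromosomes$length > 0))
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

random_bases <- function(n, gc) {
  sample(c("A", "T", "G", "C"), n, replace = TRUE,
         prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
}

mutate_bases <- function(chars, rate) {
  if (rate <= 0) return(chars)
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  chars
}

TELO_UNIT_P <- "CCCTAA"   # plus-strand reading at a p end
TELO_UNIT_Q <- "TTAGGG"

## resample the flank next to a planted telomere until no chance occurrence
## of either motif overlaps it (including occurrences crossing the
## array/background boundary), so planted truth boundaries are exact
scrub_motif <- function(chars, flank_from, flank_to, gc) {
  flank_from <- max(1L, flank_from); flank_to <- min(length(chars), flank_to)
  if (flank_to < flank_from) return(chars)
  scan_from <- max(1L, flank_from - 5L)
  scan_to <- min(length(chars), flank_to + 5L)
  repeat {
    s <- paste(chars[scan_from:scan_to], collapse = "")
    hits <- c(unlist(gregexpr(TELO_UNIT_P, s, fixed = TRUE)),
              unlist(gregexpr(TELO_UNIT_Q, s, fixed = TRUE)))
    hits <- hits[hits > 0L]
    if (length(hits)) {
      abs_start <- scan_from + hits - 1L
      hits <- hits[abs_start + 5L >= flank_from & abs_start <= flank_to]
    }
    if (length(hits) == 0L) return(chars)
    chars[flank_from:flank_to] <- random_bases(flank_to - flank_from + 1L, gc)
  }
}

#' Simulate a genome with planted chromosome features
#'
#' Draws per-chromosome background sequence at the configured GC, plants
#' telomeric hexamer arrays at both ends (p end on the reverse-complement
#' strand, q end forward, optionally mutated), a centromeric satellite
#' monomer array near the chromosome midpoint, and spanned/unspanned gaps
#' as N-runs with matching AGP lines. Flanking bases next to each planted
#' telomere are guaranteed motif-free so truth boundaries are exact.
#'
#' @param config A [sim_config()].
#' @return list of class `karyosim` with elements `records`
#'   ([Biostrings::DNAStringSet]), `layout` ([assembly_layout()]), `truth`
#'   (list of 0-based half-open interval data.frames: `telomeres`,
#'   `centromeres`, `gaps`), `monomer` (the satellite consensus) and
#'   `config`.
#' @export
simulate_genome <- function(config = sim_config()) {
  set.seed(config$seed)
  telo_len <- 6L * config$telomere_units
  mono <- random_bases(config$centromere_monomer_length, 0.5)

  seqs <- character(0)
  truth_tel <- truth_cen <- truth_gap <- NULL
  comp <- NULL; gaps_df <- NULL; objects <- NULL

  for (ci in seq_len(nrow(config$chromosomes))) {
    nm <- config$chromosomes$name[ci]
    L <- config$chromosomes$length[ci]
    gc <- config$chromosomes$gc[ci]
    if (L < 2L * telo_len + config$centromere_array_length + 20000L) {
      stop("chromosome ", nm, " too short for the configured features")
    }
    chars <- random_bases(L, gc)

    ## telomeres (0-based truth intervals [0, telo_len) and [L - telo_len, L))
    if (telo_len > 0L) {
      p_arr <- mutate_bases(rep(strsplit(TELO_UNIT_P, "")[[1L]], config$telomere_units),
                            config$telomere_mut)
      q_arr <- mutate_bases(rep(strsplit(TELO_UNIT_Q, "")[[1L]], config$telomere_units),
                            config$telomere_mut)
      chars[seq_len(telo_len)] <- p_arr
      chars[(L - telo_len + 1L):L] <- q_arr
      chars <- scrub_motif(chars, telo_len + 1L, telo_len + 60L, gc)
      chars <- scrub_motif(chars, L - telo_len - 59L, L - telo_len, gc)
      truth_tel <- rbind(truth_tel,
        data.frame(seq_id = nm, start = c(0L, L - telo_len),
                   end = c(telo_len, L), position_class = c("p_end", "q_end")))
    }

    ## centromeric satellite array near the midpoint
    ## whole monomer copies only, so the planted interval is exactly the
    ## tandem array and detectors can be held to containment
    ncopy <- floor(config$centromere_array_length / config$centromere_monomer_length)
    alen <- ncopy * config$centromere_monomer_length
    if (alen > 0L) {
      cstart <- as.integer(L / 2L - alen / 2L)            # 0-based
      arr <- unlist(lapply(seq_len(ncopy), function(i)
        mutate_bases(mono, config$centromere_divergence)))[seq_len(alen)]
      chars[(cstart + 1L):(cstart + alen)] <- arr
      truth_cen <- rbind(truth_cen,
        data.frame(seq_id = nm, start = cstart, end = cstart + alen))
    } else {
      cstart <- NA_integer_
    }

    ## gaps: sampled outside telomeres/centromere, pairwise well separated
    n_sp <- config$n_spanned_gaps
    n_un <- config$n_unspanned_gaps
    glens <- c(
      if (n_sp > 0L) sample(seq(config$spanned_gap_range[1L],
                                config$spanned_gap_range[2L]), n_sp, replace = TRUE),
      rep(config$unspanned_gap_length, n_un))
    gkind <- c(rep("spanned", n_sp), rep("unspanned", n_un))
    placed <- NULL
    guard <- 0L
    lo <- telo_len + 2000L
    hi <- L - telo_len - 2000L
    forbid <- if (is.na(cstart)) IRanges::IRanges() else
      IRanges::IRanges(start = cstart + 1L - 1000L, end = cstart + alen + 1000L)
    while (length(glens) > (if (is.null(placed)) 0L else nrow(placed))) {
      guard <- guard + 1L
      if (guard > 10000L) stop("could not place gaps on chromosome ", nm)
      i <- (if (is.null(placed)) 0L else nrow(placed)) + 1L
      s <- sample(lo:(hi - glens[i]), 1L)                 # 0-based start
      cand <- IRanges::IRanges(s + 1L - 1000L, s + glens[i] + 1000L)
      busy <- c(forbid, if (!is.null(placed))
        IRanges::IRanges(placed$start + 1L, placed$end))
      if (length(IRanges::findOverlaps(cand, busy)) > 0L) next
      placed <- rbind(placed, data.frame(start = s, end = s + glens[i],
                                         kind = gkind[i]))
    }
    if (!is.null(placed)) {
      placed <- placed[order(placed$start), , drop = FALSE]
      for (j in seq_len(nrow(placed))) {
        chars[(placed$start[j] + 1L):placed$end[j]] <- "N"
      }
      truth_gap <- rbind(truth_gap,
        data.frame(seq_id = nm, start = placed$start, end = placed$end,
                   gap_kind = placed$kind))
    }

    ## AGP decomposition of [1, L] at the gap intervals
    part <- 0L; k <- 0L; cursor <- 1L
    bounds <- if (is.null(placed)) integer(0) else placed$start
    for (j in seq_len(length(bounds) + 1L)) {
      seg_end <- if (j <= length(bounds)) placed$start[j] else L   # 1-based end = 0-based start
      if (seg_end >= cursor) {
        part <- part + 1L; k <- k + 1L
        comp <- rbind(comp, data.frame(
          object_id = nm, object_start = cursor, object_end = seg_end,
          part_number = part, component_id = sprintf("%s_ctg%d", nm, k),
          component_start = 1L, component_end = seg_end - cursor + 1L,
          orientation = "+", stringsAsFactors = FALSE))
      }
      if (j <= length(bounds)) {
        part <- part + 1L
        gaps_df <- rbind(gaps_df, data.frame(
          object_id = nm, start = placed$start[j] + 1L, end = placed$end[j],
          part_number = part,
          gap_type = if (placed$kind[j] == "spanned") "N" else "U",
          gap_kind = placed$kind[j],
          declared_length = placed$end[j] - placed$start[j],
          linkage = if (placed$kind[j] == "spanned") "yes" else "no",
          stringsAsFactors = FALSE))
        cursor <- placed$end[j] + 1L
      }
    }
    objects <- rbind(objects, data.frame(object_id = nm, length = L,
                                         chromosome = nm, stringsAsFactors = FALSE))
    seqs[nm] <- paste(chars, collapse = "")
  }

  for (u in seq_len(config$n_unplaced)) {
    nm <- sprintf("scaffold_%d", u)
    chars <- random_bases(config$unplaced_length, config$unplaced_gc)
    seqs[nm] <- paste(chars, collapse = "")
    comp <- rbind(comp, data.frame(
      object_id = nm, object_start = 1L, object_end = config$unplaced_length,
      part_number = 1L, component_id = sprintf("%s_ctg1", nm),
      component_start = 1L, component_end = config$unplaced_length,
      orientation = "+", stringsAsFactors = FALSE))
    objects <- rbind(objects, data.frame(object_id = nm,
                                         length = config$unplaced_length,
                                         chromosome = NA_character_,
                                         stringsAsFactors = FALSE))
  }

  layout <- assembly_layout(objects,
                            if (is.null(comp)) empty_components() else comp,
                            if (is.null(gaps_df)) empty_gaps() else gaps_df)
  structure(list(
    records = Biostrings::DNAStringSet(seqs),
    layout = layout,
    truth = list(telomeres = truth_tel,
                 centromeres = truth_cen,
                 gaps = truth_gap),
    monomer = Biostrings::DNAStringSet(stats::setNames(paste(mono, collapse = ""), "SAT1")),
    config = config), class = "karyosim")
}

#' @export
print.karyosim <- function(x, ...) {
  cat(sprintf("karyosim: %d sequence(s), %s bp total (seed %d)\n",
              length(x$records),
              format(sum(Biostrings::width(x$records)), big.mark = ","),
              x$config$seed))
  invisible(x)
}

#' Simulate a per-window alignment-summary track with planted anomalies
#'
#' Window depths are drawn from a negative binomial whose mean follows a
#' smooth unimodal GC-bias curve (peak near GC 0.45) scaled to the
#' configured mean depth, so GC normalization is genuinely exercised.
#' Planted anomalies: low-coverage intervals at `lc_factor` x the local
#' mean, collapsed repeats at `hc_factor` x, and misassembly junctions
#' with depressed proper pairing and elevated large-insert fractions. Gap
#' (N-run) windows receive depth in proportion to their non-N bases; fully
#' gapped windows have no reads. The returned truth labels every window
#' `nominal`, `lc`, `hc`, `misassembly` or `gap`.
#'
#' @param sim A `karyosim` from [simulate_genome()].
#' @param config Configuration; defaults to the one inside `sim`.
#' @return list with `windows` (window-statistics data.frame) and `truth`
#'   (`seq_id`, `start`, `end`, `label`).
#' @export
simulate_window_track <- function(sim, config = sim$config) {
  set.seed(config$seed + 1L)
  w <- config$window
  gc_bias <- function(gc) exp(-((gc - 0.45)^2) / (2 * 0.12^2))

  windows <- NULL
  for (sid in names(sim$records)) {
    sq <- sim$records[[sid]]
    L <- length(sq)
    ws <- seq(0L, max(L - 1L, 0L), by = w)
    we <- pmin(ws + w, L)
    vw <- Biostrings::Views(sq, start = ws + 1L, end = we)
    fr <- Biostrings::letterFrequency(vw, c("A", "C", "G", "T", "N"))
    acgt <- rowSums(fr[, 1:4, drop = FALSE])
    gc <- ifelse(acgt > 0, (fr[, "C"] + fr[, "G"]) / acgt, NA_real_)
    nonN_frac <- acgt / (we - ws)
    windows <- rbind(windows, data.frame(
      seq_id = sid, start = ws, end = we, gc = gc, nonN = nonN_frac,
      stringsAsFactors = FALSE))
  }
  n <- nrow(windows)
  mu <- config$depth_mean * gc_bias(ifelse(is.na(windows$gc), 0.45, windows$gc)) /
    gc_bias(0.45)
  mu <- mu * windows$nonN

  ## plant anomalies on chromosome (placed) windows that are gap-free
  truth_label <- rep("nominal", n)
  truth_label[windows$nonN < 1] <- "gap"
  placed_chroms <- sim$layout$objects$object_id[!is.na(sim$layout$objects$chromosome)]
  eligible <- which(windows$seq_id %in% placed_chroms & windows$nonN == 1 &
                      (windows$end - windows$start) == w)
  pick_interval <- function(k) {
    guard <- 0L
    repeat {
      guard <- guard + 1L
      if (guard > 10000L) stop("cannot place anomaly interval")
      i <- sample(eligible, 1L)
      idx <- i:(i + k - 1L)
      if (max(idx) > n) next
      if (!all(idx %in% eligible)) next
      if (length(unique(windows$seq_id[idx])) != 1L) next
      if (any(truth_label[idx] != "nominal")) next
      return(idx)
    }
  }
  depth_factor <- rep(1, n)
  for (r in seq_len(config$n_lc_intervals)) {
    idx <- pick_interval(config$lc_interval_windows)
    depth_factor[idx] <- config$lc_factor
    truth_label[idx] <- "lc"
  }
  for (r in seq_len(config$n_hc_intervals)) {
    idx <- pick_interval(config$hc_interval_windows)
    depth_factor[idx] <- config$hc_factor
    truth_label[idx] <- "hc"
  }
  mis <- rep(FALSE, n)
  for (r in seq_len(config$n_misassembly)) {
    idx <- pick_interval(config$misassembly_windows)
    mis[idx] <- TRUE
    truth_label[idx] <- "misassembly"
  }

  depth <- stats::rnbinom(n, size = config$depth_dispersion,
                          mu = pmax(mu * depth_factor, 1e-9))
  depth[mu * depth_factor < 1e-8] <- 0
  n_reads <- as.integer(round(depth * (windows$end - windows$start) / config$read_len))
  p_proper <- ifelse(mis, config$misassembly_proper, config$proper_p)
  frac_proper <- ifelse(n_reads > 0,
                        stats::rbinom(n, n_reads, p_proper) / pmax(n_reads, 1L), 0)
  p_large <- ifelse(mis, config$misassembly_large_insert, config$improper_insert_p)
  frac_large <- ifelse(n_reads > 0,
                       stats::rbinom(n, n_reads, p_large) / pmax(n_reads, 1L), 0)
  frac_small <- ifelse(n_reads > 0,
                       stats::rbinom(n, n_reads, config$improper_insert_p) /
                         pmax(n_reads, 1L), 0)

  out <- data.frame(seq_id = windows$seq_id, start = windows$start,
                    end = windows$end, gc = windows$gc, depth = depth,
                    frac_proper = frac_proper, frac_large_insert = frac_large,
                    frac_small_insert = frac_small, n_reads = n_reads,
                    stringsAsFactors = FALSE)
  truth <- data.frame(seq_id = windows$seq_id, start = windows$start,
                      end = windows$end, label = truth_label,
                      stringsAsFactors = FALSE)
  list(windows = out, truth = truth)
}

#' Simulate a SNP-probe set with known order truth
#'
#' Samples unique probe-length substrings of the truth genome (outside
#' gaps, telomeres and the satellite array, so probes are effectively
#' single-copy), records their manifest coordinates, and derives an
#' "assembly" copy of the genome in which configured intervals are
#' inverted and a `probe_dropout` fraction of probe sites is destroyed
#' (overwritten with random sequence), so those probes become unmapped.
#'
#' @param sim A `karyosim` from [simulate_genome()].
#' @param inversions Optional data.frame (`seq_id`, `start`, `end`,
#'   0-based half-open) of intervals to invert in the derived assembly.
#' @param config Configuration; defaults to the one inside `sim`.
#' @return list with `manifest` (marker_id, chip, manifest_chrom,
#'   manifest_pos 1-based, probe_seq), `assembly`
#'   ([Biostrings::DNAStringSet]), `truth` (per-marker: true coordinates,
#'   `mapped_expected`, `inverted`) and `lift` (coordinate lift table from
#'   [apply_structural_edit()], `NULL` when no inversions).
#' @export
simulate_probe_set <- function(sim, inversions = NULL, config = sim$config) {
  set.seed(config$seed + 2L)
  plen <- config$probe_length
  nwant <- config$n_probes
  placed <- sim$layout$objects$object_id[!is.na(sim$layout$objects$chromosome)]

  allowed <- list()
  for (sid in placed) {
    L <- Biostrings::width(sim$records)[match(sid, names(sim$records))]
    busy <- IRanges::IRanges()
    for (tr in sim$truth[c("telomeres", "centromeres", "gaps")]) {
      if (!is.null(tr)) {
        sel <- tr$seq_id == sid
        if (any(sel)) busy <- c(busy, IRanges::IRanges(tr$start[sel] + 1L, tr$end[sel]))
      }
    }
    allowed[[sid]] <- IRanges::setdiff(IRanges::IRanges(1L, L - plen + 1L),
                                       IRanges::reduce(busy + plen))
  }
  pool_n <- 3L * nwant
  cand <- NULL
  for (sid in placed) {
    ir <- allowed[[sid]]
    tot <- sum(IRanges::width(ir))
    take <- round(pool_n * tot / sum(vapply(allowed, function(z)
      sum(IRanges::width(z)), numeric(1))))
    if (take == 0L) next
    offs <- sort(sample(tot, min(take, tot)))
    pos <- unlist(mapply(function(s, w) s:(s + w - 1L), IRanges::start(ir),
                         IRanges::width(ir), SIMPLIFY = FALSE))[offs]
    cand <- rbind(cand, data.frame(seq_id = sid, pos = pos))
  }
  cand <- cand[sample(nrow(cand)), , drop = FALSE]
  probe_seq <- vapply(seq_len(nrow(cand)), function(i) {
    as.character(Biostrings::subseq(sim$records[[cand$seq_id[i]]],
                                    cand$pos[i], cand$pos[i] + plen - 1L))
  }, character(1))
  ok <- !grepl("N", probe_seq, fixed = TRUE) & !duplicated(probe_seq)
  cand <- cand[ok, , drop = FALSE]; probe_seq <- probe_seq[ok]

  ## genome-wide uniqueness, both strands
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(probe_seq))
  cnt <- rowSums(Biostrings::vcountPDict(pd, sim$records)) +
    rowSums(Biostrings::vcountPDict(pd, Biostrings::reverseComplement(sim$records)))
  uniq <- cnt == 1L
  ## greedily enforce non-overlap between selected probes so that a
  ## dropout replacement never destroys a neighbouring probe's site
  sel <- integer(0)
  taken <- list()
  for (i in which(uniq)) {
    sid <- cand$seq_id[i]; p <- cand$pos[i]
    prev <- taken[[sid]]
    if (!is.null(prev) && any(abs(prev - p) < plen)) next
    sel <- c(sel, i)
    taken[[sid]] <- c(prev, p)
    if (length(sel) == nwant) break
  }
  if (length(sel) < nwant) {
    stop("could not find ", nwant, " unique non-overlapping probes; try longer probes")
  }
  cand <- cand[sel, , drop = FALSE]; probe_seq <- probe_seq[sel]
  ord <- order(match(cand$seq_id, karyotype_order(cand$seq_id)), cand$pos)
  cand <- cand[ord, , drop = FALSE]; probe_seq <- probe_seq[ord]

  manifest <- data.frame(
    marker_id = sprintf("M%05d", seq_len(nwant)),
    chip = rep(c("chipA", "chipB"), length.out = nwant),
    manifest_chrom = cand$seq_id, manifest_pos = cand$pos,
    probe_seq = probe_seq, stringsAsFactors = FALSE)

  drop <- stats::runif(nwant) < config$probe_dropout
  inv <- rep(FALSE, nwant)
  assembly <- sim$records
  if (any(drop)) {
    for (i in which(drop)) {
      repl <- paste(random_bases(plen, 0.5), collapse = "")
      assembly[[manifest$manifest_chrom[i]]] <-
        Biostrings::replaceAt(assembly[[manifest$manifest_chrom[i]]],
                              IRanges::IRanges(manifest$manifest_pos[i],
                                               manifest$manifest_pos[i] + plen - 1L),
                              Biostrings::DNAString(repl))
    }
  }
  lift <- NULL
  if (!is.null(inversions) && nrow(inversions)) {
    inversions$type <- "inversion"
    edited <- apply_structural_edit(assembly, inversions)
    assembly <- edited$records
    lift <- edited$lift
    for (i in seq_len(nwant)) {
      sel <- inversions$seq_id == manifest$manifest_chrom[i] &
        inversions$start <= manifest$manifest_pos[i] - 1L &
        inversions$end >= manifest$manifest_pos[i] - 1L + plen
      inv[i] <- any(sel)
    }
  }
  truth <- data.frame(marker_id = manifest$marker_id,
                      true_chrom = manifest$manifest_chrom,
                      true_pos = manifest$manifest_pos,
                      mapped_expected = !drop, inverted = inv,
                      stringsAsFactors = FALSE)
  list(manifest = manifest, assembly = assembly, truth = truth, lift = lift)
}

#' Apply structural edits (inversions, deletions) to sequences
#'
#' Edits are given in 0-based half-open truth coordinates and must not
#' overlap. Inversions reverse-complement the interval in place; deletions
#' remove it and shift downstream coordinates. A lift table maps every
#' truth segment to its edited coordinates (deleted segments map to
#' nothing).
#'
#' @param records Named [Biostrings::DNAStringSet].
#' @param edits data.frame with `seq_id`, `start`, `end`, `type`
#'   (`"inversion"` or `"deletion"`).
#' @return list with `records` (edited) and `lift` (data.frame `seq_id`,
#'   `src_start`, `src_end`, `dst_start`, `dst_end`, `status` in
#'   `kept`/`inverted`/`deleted`; deleted rows carry `NA` destinations).
#' @export
apply_structural_edit <- function(records, edits) {
  stopifnot(all(edits$type %in% c("inversion", "deletion")))
  out <- as.list(as.character(records))
  lift <- NULL
  for (sid in names(records)) {
    e <- edits[edits$seq_id == sid, , drop = FALSE]
    L <- nchar(out[[sid]])
    if (nrow(e)) {
      if (any(e$start < 0L | e$end > L | e$start >= e$end)) {
        stop("edit out of bounds on ", sid)
      }
      e <- e[order(e$start), , drop = FALSE]
      if (nrow(e) > 1L && any(e$start[-1L] < e$end[-nrow(e)])) {
        stop("overlapping edits on ", sid)
      }
    }
    cursor_src <- 0L; offset <- 0L
    segs <- NULL
    s <- out[[sid]]
    ## process right-to-left so source coordinates stay valid during editing
    for (j in rev(seq_len(nrow(e)))) {
      if (e$type[j] == "inversion") {
        piece <- substr(s, e$start[j] + 1L, e$end[j])
        rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(piece)))
        s <- paste0(substr(s, 1L, e$start[j]), rc,
                    substr(s, e$end[j] + 1L, nchar(s)))
      } else {
        s <- paste0(substr(s, 1L, e$start[j]), substr(s, e$end[j] + 1L, nchar(s)))
      }
    }
    out[[sid]] <- s
    ## lift table, left-to-right
    for (j in seq_len(nrow(e))) {
      if (e$start[j] > cursor_src) {
        segs <- rbind(segs, data.frame(
          seq_id = sid, src_start = cursor_src, src_end = e$start[j],
          dst_start = cursor_src + offset, dst_end = e$start[j] + offset,
          status = "kept"))
      }
      w <- e$end[j] - e$start[j]
      if (e$type[j] == "inversion") {
        segs <- rbind(segs, data.frame(
          seq_id = sid, src_start = e$start[j], src_end = e$end[j],
          dst_start = e$start[j] + offset, dst_end = e$end[j] + offset,
          status = "inverted"))
      } else {
        segs <- rbind(segs, data.frame(
          seq_id = sid, src_start = e$start[j], src_end = e$end[j],
          dst_start = NA_integer_, dst_end = NA_integer_, status = "deleted"))
        offset <- offset - w
      }
      cursor_src <- e$end[j]
    }
    if (cursor_src < L) {
      segs <- rbind(segs, data.frame(
        seq_id = sid, src_start = cursor_src, src_end = L,
        dst_start = cursor_src + offset, dst_end = L + offset, status = "kept"))
    }
    lift <- rbind(lift, segs)
  }
  list(records = Biostrings::DNAStringSet(unlist(out)), lift = lift)
}

#' Write a synthetic RepeatMasker .out annotation for a simulated genome
#'
#' Emits one annotation row per planted satellite monomer copy (class
#' `Satellite/centr`, divergence equal to the configured array
#' divergence, a minority of rows on the `C` strand to exercise the
#' column-swap dialect) plus a configurable number of decoy interspersed
#' repeats with divergence above and consensus coverage below the usual
#' retention cut-offs. The file is synthetic: it reflects the planted
#' truth, not a RepeatMasker run.
#'
#' @param sim A `karyosim` from [simulate_genome()].
#' @param path Output `.out` path.
#' @param n_decoys Number of decoy repeat rows that should be removed by
#'   [filter_repeats()].
#' @return `path`, invisibly.
#' @export
simulate_repeatmasker_out <- function(sim, path, n_decoys = 6L) {
  set.seed(sim$config$seed + 3L)
  mono_len <- sim$config$centromere_monomer_length
  div <- 100 * sim$config$centromere_divergence
  lines <- c(
    "   SW   perc perc perc  query     position in query    matching  repeat         position in repeat",
    "score   div. del. ins.  sequence  begin end   (left)   repeat    class/family   begin end (left)  ID",
    "")
  id <- 0L
  cen <- sim$truth$centromeres
  for (i in seq_len(nrow(cen))) {
    starts <- seq(cen$start[i], cen$end[i] - mono_len, by = mono_len)
    for (s in starts) {
      id <- id + 1L
      strand <- if (id %% 7L == 0L) "C" else "+"
      qb <- s + 1L; qe <- s + mono_len
      if (strand == "+") {
        repcols <- sprintf("%d %d (%d)", 1L, mono_len, 0L)
      } else {
        repcols <- sprintf("(%d) %d %d", 0L, mono_len, 1L)
      }
      lines <- c(lines, sprintf(
        " %5d %5.1f  0.0  0.0  %-8s %7d %7d (%d) %s %-8s %-16s %s %d",
        2500L, div + stats::runif(1, -1, 1), cen$seq_id[i], qb, qe, 0L,
        strand, "SAT1", "Satellite/centr", repcols, id))
    }
  }
  placed <- sim$layout$objects$object_id[!is.na(sim$layout$objects$chromosome)]
  for (d in seq_len(n_decoys)) {
    id <- id + 1L
    sid <- sample(placed, 1L)
    s <- sample(10000:20000, 1L)
    too_diverged <- d %% 2L == 0L
    dv <- if (too_diverged) stats::runif(1, 45, 60) else stats::runif(1, 5, 15)
    clen <- 400L
    alen <- if (too_diverged) 350L else 150L   # short rows fail the 70% rule
    lines <- c(lines, sprintf(
      " %5d %5.1f  0.0  0.0  %-8s %7d %7d (%d) + %-8s %-16s %d %d (%d) %d",
      300L, dv, sid, s, s + alen - 1L, 0L, sprintf("DECOY%d", d),
      "LINE/L1", 1L, alen, clen - alen, id))
  }
  writeLines(lines, path)
  invisible(path)
}
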