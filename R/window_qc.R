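#' Window-classification thresholds
#'
#' Container for the cut-offs used by [classify_windows()]. All values are
#' exposed because the underlying QC workflow publishes no canonical set;
#' the defaults are conventional coverage-anomaly heuristics.
#'
#' @param lc_norm_depth_max Windows with GC-normalized depth below this
#'   ratio are low coverage (LC). Default 0.25.
#' @param hc_norm_depth_min Windows with GC-normalized depth above this
#'   ratio are high coverage (HC). Default 2.0.
#' @param proper_min Minimum fraction of properly paired reads; below it a
#'   window is flagged LPP. Default 0.80.
#' @param large_insert_max,small_insert_max Maximum tolerated fraction of
#'   reads with overlarge / oversmall template lengths (flags LLI / LSI).
#'   Default 0.10 each.
#' @param min_reads Windows with fewer reads are classified LC and not
#'   evaluated for the read-composition flags. Default 4.
#' @param insert_small_bp,insert_large_bp Template-length bounds defining
#'   an improper insert; `NA` means estimate as 0.5x / 2x the modal insert
#'   of the data.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(lc_norm_depth_max = 0.25, hc_norm_depth_min = 2.0,
                          proper_min = 0.80, large_insert_max = 0.10,
                          small_insert_max = 0.10, min_reads = 4L,
                          insert_small_bp = NA_real_, insert_large_bp = NA_real_) {
  stopifnot(lc_norm_depth_max < 1, hc_norm_depth_min > 1)
  structure(list(lc_norm_depth_max = lc_norm_depth_max,
                 hc_norm_depth_min = hc_norm_depth_min,
                 proper_min = proper_min,
                 large_insert_max = large_insert_max,
                 small_insert_max = small_insert_max,
                 min_reads = as.integer(min_reads),
                 insert_small_bp = insert_small_bp,
                 insert_large_bp = insert_large_bp),
            class = "qc_thresholds")
}

#' Read a per-window alignment-summary table
#'
#' @param path Tab-separated file with header columns `seq_id`, `start`,
#'   `end`, `gc`, `depth`, `frac_proper`, `frac_large_insert`,
#'   `frac_small_insert`, `n_reads` (coordinates 0-based half-open).
#' @return data.frame of window statistics.
#' @export
read_window_stats <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("seq_id", "start", "end", "gc", "depth", "frac_proper",
            "frac_large_insert", "frac_small_insert", "n_reads")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("window stats file lacks column(s): ", paste(missing, collapse = ", "))
  }
  df[, need]
}

#' Write a per-window table
#' @param windows data.frame of window statistics (optionally classified).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_window_stats <- function(windows, path) {
  utils::write.table(windows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Summarize coordinate-sorted alignments into tiling windows
#'
#' Computes one row of window statistics per non-overlapping window of
#' `window` bp (the final window of each sequence may be short): mean read
#' depth (overlap bases / window width), GC content of the assembly
#' sequence, fraction of reads with the proper-pair flag, and fractions of
#' reads whose absolute template length falls outside the improper-insert
#' bounds. Reads are assigned to the window containing their leftmost
#' aligned base.
#'
#' @param path BAM file (coordinate-sorted) or SAM file (converted on the
#'   fly via [Rsamtools::asBam()]).
#' @param records Named [Biostrings::DNAStringSet] of the assembly the
#'   reads were aligned to; defines window tiling and GC.
#' @param window Window width in bp (default 1000, non-overlapping).
#' @param insert_bounds Length-2 numeric `c(small, large)`; absolute
#'   template lengths outside `[small, large]` count as improper. `NULL`
#'   estimates `0.5x`/`2x` the modal absolute template length.
#' @return data.frame of window statistics (0-based half-open coordinates).
#' @export
windows_from_alignments <- function(path, records, window = 1000L,
                                    insert_bounds = NULL) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "qwidth", "flag", "isize"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  b <- Rsamtools::scanBam(path, param = p)[[1L]]
  rname <- as.character(b$rname)
  ## sortedness check within each reference
  for (sid in unique(rname)) {
    if (is.unsorted(b$pos[rname == sid])) {
      stop("alignments are not coordinate-sorted (sequence ", sid, ")")
    }
  }
  if (is.null(insert_bounds)) {
    ins <- abs(b$isize[!is.na(b$isize) & b$isize != 0L])
    if (length(ins)) {
      modal <- modal_insert(ins)
      insert_bounds <- c(0.5 * modal, 2 * modal)
    } else {
      insert_bounds <- c(0, Inf)
    }
  }

  out <- NULL
  for (sid in names(records)) {
    L <- Biostrings::width(records)[match(sid, names(records))]
    ws <- seq(0L, max(L - 1L, 0L), by = window)
    we <- pmin(ws + window, L)
    sel <- which(rname == sid)
    pos <- b$pos[sel]
    qw <- b$qwidth[sel]
    qw[is.na(qw)] <- 0L
    flag <- b$flag[sel]
    isz <- b$isize[sel]

    cov <- IRanges::coverage(IRanges::IRanges(start = pos, width = qw), width = L)
    depth <- if (L > 0L) {
      IRanges::viewMeans(IRanges::Views(cov, start = ws + 1L, end = we))
    } else numeric(0)

    widx <- pos %/% window + 1L   # pos is 1-based; window index of leftmost base
    nwin <- length(ws)
    widx[widx > nwin] <- nwin
    n_reads <- tabulate(widx, nbins = nwin)
    proper <- bitwAnd(flag, 2L) > 0L
    has_ins <- !is.na(isz) & isz != 0L
    large <- has_ins & abs(isz) > insert_bounds[2L]
    small <- has_ins & abs(isz) < insert_bounds[1L]
    frac <- function(v) {
      s <- tabulate(widx[v], nbins = nwin)
      ifelse(n_reads > 0L, s / n_reads, 0)
    }

    sq <- records[[sid]]
    vw <- Biostrings::Views(sq, start = ws + 1L, end = we)
    fr <- Biostrings::letterFrequency(vw, c("A", "C", "G", "T"))
    acgt <- rowSums(fr)
    gc <- ifelse(acgt > 0, (fr[, "C"] + fr[, "G"]) / acgt, NA_real_)

    out <- rbind(out, data.frame(
      seq_id = sid, start = ws, end = we, gc = gc, depth = as.numeric(depth),
      frac_proper = frac(proper), frac_large_insert = frac(large),
      frac_small_insert = frac(small), n_reads = n_reads,
      stringsAsFactors = FALSE))
  }
  attr(out, "insert_bounds") <- insert_bounds
  rownames(out) <- NULL
  out
}

## most frequent absolute template length, on a 10 bp grid
modal_insert <- function(ins) {
  bins <- (ins %/% 10L) * 10L + 5L
  tb <- table(bins)
  as.numeric(names(tb)[which.max(tb)])
}

#' GC-normalize window depths
#'
#' Divides each window's depth by the median depth of windows with similar
#' GC content (bins of `gc_bin_width`), removing the sequencing-platform
#' GC bias. Bins holding fewer than `min_bin_windows` windows (and windows
#' with undefined GC) fall back to the global median. The median, not the
#' mean, is used so that collapsed repeats do not drag the reference depth
#' of their GC bin.
#'
#' @param windows data.frame of window statistics.
#' @param gc_bin_width GC bin width as a fraction (default 0.02).
#' @param min_bin_windows Minimum windows per bin (default 50).
#' @return `windows` with an added `norm_depth` column.
#' @export
gc_normalize <- function(windows, gc_bin_width = 0.02, min_bin_windows = 50L) {
  if (all(windows$depth == 0)) stop("cannot GC-normalize: all window depths are zero")
  global_med <- stats::median(windows$depth)
  if (global_med == 0) global_med <- stats::median(windows$depth[windows$depth > 0])
  bin <- ifelse(is.na(windows$gc), NA_integer_,
                as.integer(floor(windows$gc / gc_bin_width)))
  med <- rep(global_med, nrow(windows))
  for (bv in unique(bin[!is.na(bin)])) {
    idx <- which(bin == bv)
    if (length(idx) >= min_bin_windows) {
      m <- stats::median(windows$depth[idx])
      if (m > 0) med[idx] <- m
    }
  }
  windows$norm_depth <- windows$depth / med
  windows
}

#' Classify windows into coverage/pairing quality categories
#'
#' Flags per window: `LC` (low normalized depth, or too few reads), `HC`
#' (high normalized depth), `LPP` (low fraction properly paired), `LLI` /
#' `LSI` (excess large / small template lengths). `lq` is the union of
#' HC/LPP/LLI/LSI; `lqlc` additionally includes LC. Windows below
#' `min_reads` are LC and are not evaluated for the read-composition
#' flags, whose fractions would be meaningless at such depth.
#'
#' @param windows data.frame with `norm_depth` (see [gc_normalize()]).
#' @param thresholds A [qc_thresholds()] object.
#' @return `windows` with logical columns `HC`, `LC`, `LPP`, `LLI`, `LSI`,
#'   `lq`, `lqlc`.
#' @export
classify_windows <- function(windows, thresholds = qc_thresholds()) {
  if (is.null(windows$norm_depth)) {
    stop("windows lack norm_depth; run gc_normalize() first")
  }
  t <- thresholds
  enough <- windows$n_reads >= t$min_reads
  windows$LC <- windows$norm_depth < t$lc_norm_depth_max | !enough
  windows$HC <- windows$norm_depth > t$hc_norm_depth_min
  windows$LPP <- enough & windows$frac_proper < t$proper_min
  windows$LLI <- enough & windows$frac_large_insert > t$large_insert_max
  windows$LSI <- enough & windows$frac_small_insert > t$small_insert_max
  windows$lq <- windows$HC | windows$LPP | windows$LLI | windows$LSI
  windows$lqlc <- windows$lq | windows$LC
  windows
}

#' LQLC windows outside a repeat mask
#'
#' Returns the flagged (`lqlc`) windows whose interval does not intersect
#' any mask interval by even one base, together with their total bases.
#'
#' @param classes Classified windows from [classify_windows()].
#' @param mask Mask intervals: a BED path or a data.frame with `seq_id`,
#'   `start`, `end` (0-based half-open).
#' @return list with `windows` (the unmasked LQLC subset) and `bases`.
#' @export
subtract_mask <- function(classes, mask) {
  if (is.character(mask)) mask <- read_bed(mask)
  lq <- classes[classes$lqlc, , drop = FALSE]
  if (nrow(lq) == 0L) return(list(windows = lq, bases = 0))
  hit <- rep(FALSE, nrow(lq))
  for (sid in unique(lq$seq_id)) {
    mi <- mask[mask$seq_id == sid, , drop = FALSE]
    wi <- which(lq$seq_id == sid)
    if (nrow(mi) == 0L) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(lq$start[wi] + 1L, lq$end[wi]),
      IRanges::IRanges(mi$start + 1L, mi$end))
    hit[wi[unique(S4Vectors::queryHits(ov))]] <- TRUE
  }
  keep <- lq[!hit, , drop = FALSE]
  list(windows = keep, bases = sum(keep$end - keep$start))
}

#' Per-category quality summary
#'
#' Totals the flagged bases per category and expresses them as a
#' percentage of all analysed bases, and reports the mean GC content of
#' the LQLC windows (diagnostic for platform GC bias as the cause of
#' residual low coverage).
#'
#' @param classes Classified windows from [classify_windows()].
#' @param mask Optional mask (see [subtract_mask()]); adds an
#'   `lqlc_unmasked` row.
#' @return list with `table` (category, bases, pct_genome),
#'   `mean_gc_lqlc`, and `total_bases`.
#' @export
qc_summary <- function(classes, mask = NULL) {
  wwidth <- classes$end - classes$start
  total <- sum(wwidth)
  cat_bases <- function(flag) sum(wwidth[flag])
  cats <- c(high_coverage = "HC", low_coverage = "LC",
            low_proper_pair = "LPP", high_large_insert = "LLI",
            high_small_insert = "LSI", lq = "lq", lqlc = "lqlc")
  df <- data.frame(category = names(cats),
                   bases = vapply(cats, function(cl) cat_bases(classes[[cl]]),
                                  numeric(1)),
                   stringsAsFactors = FALSE)
  if (!is.null(mask)) {
    sub <- subtract_mask(classes, mask)
    df[nrow(df) + 1L, ] <- list("lqlc_unmasked", sub$bases)
  }
  df$pct_genome <- 100 * df$bases / total
  lql <- classes$lqlc & !is.na(classes$gc)
  list(table = df,
       mean_gc_lqlc = if (any(lql)) stats::weighted.mean(classes$gc[lql], wwidth[lql])
                      else NA_real_,
       total_bases = total)
}
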