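#' Parse a RepeatMasker .out annotation table
#'
#' Reads the standard whitespace-delimited RepeatMasker output (3 header
#' lines, then one row per hit). Coordinates are converted to 0-based
#' half-open. Consensus coordinates are handled strand-aware: on `+` rows
#' the repeat columns are begin / end / (left); on `C` rows they are
#' (left) / end / begin. In both cases
#' `consensus_length = repeat end + repeat left` and
#' `consensus_aligned = repeat end - repeat begin + 1`.
#'
#' @param path RepeatMasker `.out` file.
#' @return data.frame with columns `seq_id`, `start`, `end` (0-based
#'   half-open), `strand` (`+`/`-`), `repeat_name`, `repeat_class`,
#'   `pct_div`, `consensus_aligned`, `consensus_length`, `score`,
#'   `overlap_flag` (the trailing `*`, `TRUE`/`FALSE`).
#' @export
read_repeatmasker_out <- function(path) {
  if (!file.exists(path)) stop("RepeatMasker .out file not found: ", path)
  lines <- readLines(path)
  out <- data.frame(seq_id = character(), start = integer(), end = integer(),
                    strand = character(), repeat_name = character(),
                    repeat_class = character(), pct_div = numeric(),
                    consensus_aligned = integer(), consensus_length = integer(),
                    score = numeric(), overlap_flag = logical(),
                    stringsAsFactors = FALSE)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    f <- strsplit(ln, "\\s+")[[1L]]
    # header lines start with a non-numeric token ("SW", "score", ...)
    if (is.na(suppressWarnings(as.numeric(f[1L])))) next
    if (length(f) < 14L) {
      stop("RepeatMasker parse error at line ", i, ": expected >= 14 columns, got ",
           length(f))
    }
    strand <- if (f[9L] %in% c("C", "-")) "-" else "+"
    unparen <- function(s) as.integer(gsub("[()]", "", s))
    if (strand == "+") {
      rep_begin <- unparen(f[12L]); rep_end <- unparen(f[13L]); rep_left <- unparen(f[14L])
    } else {
      rep_left <- unparen(f[12L]); rep_end <- unparen(f[13L]); rep_begin <- unparen(f[14L])
    }
    out[nrow(out) + 1L, ] <- list(
      f[5L], as.integer(f[6L]) - 1L, as.integer(f[7L]), strand, f[10L], f[11L],
      as.numeric(f[2L]), rep_end - rep_begin + 1L, rep_end + rep_left,
      as.numeric(f[1L]), identical(f[length(f)], "*"))
  }
  out
}

#' Filter repeat annotations by divergence and consensus-length fraction
#'
#' A record is removed when its divergence exceeds `max_div` percent or
#' when it covers less than `min_frac` of the repeat consensus. Boundary
#' cases (divergence exactly `max_div`, fraction exactly `min_frac`) are
#' kept.
#'
#' @param records data.frame from [read_repeatmasker_out()].
#' @param max_div Maximum tolerated percent divergence (default 40).
#' @param min_frac Minimum aligned fraction of the consensus (default 0.70).
#' @return The retained subset, in input order.
#' @export
filter_repeats <- function(records, max_div = 40, min_frac = 0.70) {
  if (nrow(records) == 0L) return(records)
  frac <- records$consensus_aligned / records$consensus_length
  records[!(records$pct_div > max_div | frac < min_frac), , drop = FALSE]
}

#' Select putatively centromeric repeat records
#'
#' @param records data.frame from [read_repeatmasker_out()].
#' @param class_pattern Regular expression matched against `repeat_class`.
#' @param name_pattern Optional regular expression matched against
#'   `repeat_name`; a record is kept when either pattern matches.
#' @return The matching subset.
#' @export
select_centromeric <- function(records, class_pattern = "Satellite/centr",
                               name_pattern = NULL) {
  keep <- grepl(class_pattern, records$repeat_class)
  if (!is.null(name_pattern)) keep <- keep | grepl(name_pattern, records$repeat_name)
  records[keep, , drop = FALSE]
}

#' Search sequences for satellite monomer copies
#'
#' Seed-and-extend search for (possibly diverged) copies of known
#' centromeric satellite monomers: every non-overlapping k-mer of the
#' monomer is used as an exact seed, each seed hit proposes an ungapped
#' full-length alignment of the monomer at the implied offset, and
#' alignments with identity (matches / monomer length) of at least
#' `min_identity` are kept. Both strands are searched; overlapping or
#' adjacent hits of the same monomer are merged, averaging identity by
#' length.
#'
#' @param records Named [Biostrings::DNAStringSet] to search.
#' @param monomers Named [Biostrings::DNAStringSet] of monomer sequences.
#' @param k Seed length (default 13).
#' @param min_identity Minimum ungapped identity to keep a hit.
#' @return data.frame with columns `seq_id`, `start`, `end` (0-based
#'   half-open), `monomer_id`, `identity`.
#' @export
search_satellite_monomers <- function(records, monomers, k = 13L,
                                      min_identity = 0.70) {
  if (!methods::is(monomers, "DNAStringSet")) {
    monomers <- Biostrings::DNAStringSet(monomers)
  }
  if (any(Biostrings::width(monomers) < k)) {
    stop("monomer(s) shorter than seed length k = ", k, ": ",
         paste(names(monomers)[Biostrings::width(monomers) < k], collapse = ", "))
  }
  out <- data.frame(seq_id = character(), start = integer(), end = integer(),
                    monomer_id = character(), identity = numeric(),
                    stringsAsFactors = FALSE)
  for (si in seq_along(records)) {
    sq <- Biostrings::DNAString(toupper(as.character(records[[si]])))
    W <- length(sq)
    for (mi in seq_along(monomers)) {
      mon_id <- names(monomers)[mi]
      hits <- NULL
      for (strand in c("+", "-")) {
        m <- if (strand == "+") monomers[[mi]] else
          Biostrings::reverseComplement(monomers[[mi]])
        mchr <- as.character(m)
        L <- nchar(mchr)
        if (L > W) next
        offsets <- seq(1L, L - k + 1L, by = k)
        starts <- integer(0)
        for (o in offsets) {
          seed <- substr(mchr, o, o + k - 1L)
          p <- Biostrings::start(Biostrings::matchPattern(seed, sq))
          starts <- c(starts, p - o + 1L)
        }
        starts <- sort(unique(starts))
        starts <- starts[starts >= 1L & starts + L - 1L <= W]
        if (length(starts) == 0L) next
        ned <- Biostrings::neditStartingAt(m, sq, starting.at = starts,
                                           with.indels = FALSE)
        ident <- (L - ned) / L
        keep <- ident >= min_identity
        if (any(keep)) {
          hits <- rbind(hits, data.frame(start = starts[keep] - 1L,
                                         end = starts[keep] + L - 1L,
                                         identity = ident[keep]))
        }
      }
      if (is.null(hits) || nrow(hits) == 0L) next
      ## merge overlapping hits of this monomer
      hits <- hits[order(hits$start, hits$end), , drop = FALSE]
      cur_s <- hits$start[1L]; cur_e <- hits$end[1L]
      wsum <- hits$identity[1L] * (cur_e - cur_s); wlen <- cur_e - cur_s
      flush <- function() {
        out[nrow(out) + 1L, ] <<- list(names(records)[si], cur_s, cur_e,
                                       mon_id, wsum / wlen)
      }
      for (j in seq_len(nrow(hits))[-1L]) {
        if (hits$start[j] <= cur_e) {
          cur_e <- max(cur_e, hits$end[j])
          wsum <- wsum + hits$identity[j] * (hits$end[j] - hits$start[j])
          wlen <- wlen + (hits$end[j] - hits$start[j])
        } else {
          flush()
          cur_s <- hits$start[j]; cur_e <- hits$end[j]
          wsum <- hits$identity[j] * (cur_e - cur_s); wlen <- cur_e - cur_s
        }
      }
      flush()
    }
  }
  out
}

#' Merge interval evidence into super-regions
#'
#' Sorts intervals per sequence and unions any pair that overlaps or whose
#' gap is at most `collapse_dist` bp, so that the output intervals are
#' pairwise separated by strictly more than `collapse_dist`. Source labels
#' are unioned and the number of merged input intervals recorded. The
#' operation is idempotent.
#'
#' @param intervals data.frame with columns `seq_id`, `start`, `end`
#'   (0-based half-open) and optionally `source`.
#' @param collapse_dist Maximum gap (bp) collapsed into one super-region.
#' @return data.frame with columns `seq_id`, `start`, `end`, `sources`
#'   (comma-separated unique labels), `n_merged`.
#' @export
merge_and_collapse <- function(intervals, collapse_dist = 500L) {
  out <- data.frame(seq_id = character(), start = integer(), end = integer(),
                    sources = character(), n_merged = integer(),
                    stringsAsFactors = FALSE)
  if (nrow(intervals) == 0L) return(out)
  if (is.null(intervals$source)) {
    src <- if (is.null(intervals$sources)) rep(NA_character_, nrow(intervals))
           else intervals$sources
  } else {
    src <- intervals$source
  }
  nm <- if (is.null(intervals$n_merged)) rep(1L, nrow(intervals)) else intervals$n_merged
  for (sid in unique(intervals$seq_id)) {
    idx <- which(intervals$seq_id == sid)
    o <- idx[order(intervals$start[idx], intervals$end[idx])]
    cur_s <- intervals$start[o[1L]]; cur_e <- intervals$end[o[1L]]
    cur_src <- src[o[1L]]; cur_n <- nm[o[1L]]
    for (j in o[-1L]) {
      if (intervals$start[j] - cur_e <= collapse_dist) {
        cur_e <- max(cur_e, intervals$end[j])
        cur_src <- c(cur_src, src[j])
        cur_n <- cur_n + nm[j]
      } else {
        out[nrow(out) + 1L, ] <- list(sid, cur_s, cur_e, collapse_sources(cur_src), cur_n)
        cur_s <- intervals$start[j]; cur_e <- intervals$end[j]
        cur_src <- src[j]; cur_n <- nm[j]
      }
    }
    out[nrow(out) + 1L, ] <- list(sid, cur_s, cur_e, collapse_sources(cur_src), cur_n)
  }
  out
}

collapse_sources <- function(x) {
  x <- unique(unlist(strsplit(stats::na.omit(x), ",", fixed = TRUE)))
  if (length(x) == 0L) NA_character_ else paste(sort(x), collapse = ",")
}

#' Retain centromere candidate calls
#'
#' @param super_regions data.frame from [merge_and_collapse()].
#' @param min_len Minimum region length in bp, exclusive (default 5000: a
#'   region of exactly 5000 bp is rejected).
#' @return The retained regions with an added `length` column.
#' @export
call_centromeres <- function(super_regions, min_len = 5000L) {
  len <- super_regions$end - super_regions$start
  out <- super_regions[len > min_len, , drop = FALSE]
  out$length <- out$end - out$start
  out
}

#' Centromere prediction from merged repeat evidence
#'
#' Implements the three-source strategy: centromeric records from a
#' default-library RepeatMasker run, centromeric records from a
#' novel-library run, and direct satellite-monomer search hits are pooled
#' in one coordinate space, divergence/length-filtered (optional), merged
#' with [merge_and_collapse()], and length-thresholded with
#' [call_centromeres()].
#'
#' @param rm_records Named list of data.frames from
#'   [read_repeatmasker_out()] (e.g. `list(default_library = ...,
#'   novel_library = ...)`).
#' @param monomer_hits Optional data.frame from
#'   [search_satellite_monomers()].
#' @param class_pattern,name_pattern Passed to [select_centromeric()].
#' @param apply_filter Apply [filter_repeats()] before merging.
#' @param max_div,min_frac Passed to [filter_repeats()].
#' @param collapse_dist,min_len Passed to [merge_and_collapse()] and
#'   [call_centromeres()].
#' @return A list with `calls` (retained regions), `merged` (all
#'   super-regions) and `summary` (count, median and mean merged-region
#'   length).
#' @export
predict_centromeres <- function(rm_records, monomer_hits = NULL,
                                class_pattern = "Satellite/centr",
                                name_pattern = NULL, apply_filter = TRUE,
                                max_div = 40, min_frac = 0.70,
                                collapse_dist = 500L, min_len = 5000L) {
  pool <- NULL
  for (nm in names(rm_records)) {
    rec <- rm_records[[nm]]
    if (apply_filter) rec <- filter_repeats(rec, max_div, min_frac)
    rec <- select_centromeric(rec, class_pattern, name_pattern)
    if (nrow(rec)) {
      pool <- rbind(pool, data.frame(seq_id = rec$seq_id, start = rec$start,
                                     end = rec$end, source = nm))
    }
  }
  if (!is.null(monomer_hits) && nrow(monomer_hits)) {
    pool <- rbind(pool, data.frame(seq_id = monomer_hits$seq_id,
                                   start = monomer_hits$start,
                                   end = monomer_hits$end,
                                   source = "monomer_search"))
  }
  if (is.null(pool)) pool <- data.frame(seq_id = character(), start = integer(),
                                        end = integer(), source = character())
  merged <- merge_and_collapse(pool, collapse_dist)
  calls <- call_centromeres(merged, min_len)
  mlen <- merged$end - merged$start
  list(calls = calls, merged = merged,
       summary = list(n_merged_regions = nrow(merged),
                      median_length = if (nrow(merged)) stats::median(mlen) else NA_real_,
                      mean_length = if (nrow(merged)) mean(mlen) else NA_real_,
                      n_calls = nrow(calls)))
}
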