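#' Scan sequences for exact-motif tandem arrays
#'
#' Finds every exact occurrence of a hexamer motif (default the vertebrate
#' telomeric repeat `TTAGGG`) and of its reverse complement, and chains
#' occurrences whose start positions are at most `max_gap` bp apart into
#' maximal arrays. An array is reported only when it contains a seed run of
#' at least `min_seed_run` identical, consecutive (6 bp spaced, same
#' strand) units. The hexamer cannot overlap itself, so greedy
#' left-to-right counting of exact matches is exact.
#'
#' @param records A named [Biostrings::DNAStringSet] (or a single character
#'   / `DNAString`, reported under seq_id `"seq"`).
#' @param unit Tandem unit, length 6, over `A`/`C`/`G`/`T`.
#' @param max_gap Maximum distance (bp) between successive match starts
#'   within one array. Default 48 = 8 units.
#' @param min_seed_run Minimum run of identical consecutive units required
#'   to report an array (default 5).
#' @return data.frame with columns `seq_id`, `start`, `end` (0-based
#'   half-open), `unit`, `n_exact_units` (exact matches of either strand
#'   within the span), `max_run`, `density` (= 6 x units / span) and
#'   `strand` (majority strand).
#' @export
find_motif_arrays <- function(records, unit = "TTAGGG", max_gap = 48L,
                              min_seed_run = 5L) {
  unit <- toupper(unit)
  if (nchar(unit) != 6L || grepl("[^ACGT]", unit)) {
    stop("unit must be a hexamer over A/C/G/T, got: ", unit)
  }
  if (!methods::is(records, "DNAStringSet")) {
    records <- Biostrings::DNAStringSet(stats::setNames(
      as.character(records), if (is.null(names(records))) "seq" else names(records)))
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(unit)))

  out <- data.frame(seq_id = character(), start = integer(), end = integer(),
                    unit = character(), n_exact_units = integer(),
                    max_run = integer(), density = numeric(),
                    strand = character(), stringsAsFactors = FALSE)
  for (i in seq_along(records)) {
    sq <- Biostrings::DNAString(toupper(as.character(records[[i]])))
    fwd <- Biostrings::start(Biostrings::matchPattern(unit, sq))
    rev <- Biostrings::start(Biostrings::matchPattern(rc, sq))
    if (length(fwd) + length(rev) == 0L) next
    hits <- data.frame(pos = c(fwd, rev),
                       strand = rep(c("+", "-"), c(length(fwd), length(rev))))
    hits <- hits[order(hits$pos), , drop = FALSE]
    chain <- cumsum(c(1L, diff(hits$pos) > max_gap))
    for (g in split(hits, chain)) {
      run <- max_identical_run(g$pos, g$strand)
      if (run < min_seed_run) next
      span_start <- g$pos[1L] - 1L            # to 0-based
      span_end <- g$pos[nrow(g)] + 6L - 1L
      n_units <- nrow(g)
      n_plus <- sum(g$strand == "+")
      out[nrow(out) + 1L, ] <- list(
        names(records)[i], span_start, span_end, unit, n_units, run,
        6 * n_units / (span_end - span_start),
        if (n_plus * 2L >= n_units) "+" else "-")
    }
  }
  out
}

## longest run of same-strand matches spaced exactly one unit (6 bp) apart
max_identical_run <- function(pos, strand) {
  if (length(pos) == 1L) return(1L)
  consec <- diff(pos) == 6L & strand[-1L] == strand[-length(strand)]
  best <- run <- 1L
  for (ok in consec) {
    run <- if (ok) run + 1L else 1L
    best <- max(best, run)
  }
  best
}

#' Retain telomere-like arrays
#'
#' Applies the telomere retention rule: an array is kept when it contains
#' at least `min_units` exact hexamer units, spans strictly more than
#' `min_len` bp, and has hexamer density strictly greater than
#' `min_density`.
#'
#' @param arrays data.frame from [find_motif_arrays()].
#' @param min_units Minimum exact unit count (inclusive, default 200).
#' @param min_len Minimum span in bp (exclusive, default 2000).
#' @param min_density Minimum density (exclusive, default 0.5).
#' @return The retained subset of `arrays`.
#' @export
filter_telomeric <- function(arrays, min_units = 200L, min_len = 2000L,
                             min_density = 0.5) {
  keep <- arrays$n_exact_units >= min_units &
    (arrays$end - arrays$start) > min_len &
    arrays$density > min_density
  arrays[keep, , drop = FALSE]
}

#' Classify array position on its sequence
#'
#' @param arrays data.frame with `seq_id`, `start`, `end` (0-based
#'   half-open).
#' @param seq_lengths Named vector of sequence lengths (bp).
#' @param end_window Distance from a sequence end (bp) within which an
#'   array counts as terminal.
#' @return `arrays` with an added `position_class` column taking values
#'   `"p_end"`, `"q_end"` or `"interstitial"`; `p_end` takes precedence on
#'   sequences shorter than two windows.
#' @export
classify_position <- function(arrays, seq_lengths, end_window = 10000L) {
  L <- seq_lengths[arrays$seq_id]
  arrays$position_class <- ifelse(
    arrays$start < end_window, "p_end",
    ifelse(arrays$end > L - end_window, "q_end", "interstitial"))
  arrays
}

#' Telomere calling convenience wrapper
#'
#' Runs the motif-array scan, the retention filter and the positional
#' classification in one step.
#'
#' @inheritParams find_motif_arrays
#' @inheritParams filter_telomeric
#' @inheritParams classify_position
#' @return data.frame of retained telomere calls with position classes.
#' @export
find_telomeres <- function(records, unit = "TTAGGG", max_gap = 48L,
                           min_units = 200L, min_len = 2000L,
                           min_density = 0.5, end_window = 10000L) {
  arrays <- find_motif_arrays(records, unit = unit, max_gap = max_gap)
  calls <- filter_telomeric(arrays, min_units, min_len, min_density)
  classify_position(calls,
                    stats::setNames(Biostrings::width(records), names(records)),
                    end_window)
}
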