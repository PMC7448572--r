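## Independent brute-force oracles. These deliberately share no code with
## the implementations they check.

## Nx/Lx by explicit prefix walk over the descending-sorted lengths
oracle_nx <- function(lengths, x) {
  s <- sort(lengths, decreasing = TRUE)
  total <- sum(s)
  acc <- 0
  for (i in seq_along(s)) {
    acc <- acc + s[i]
    if (acc >= x / 100 * total) return(list(nx = s[i], lx = i))
  }
  stop("unreachable")
}

## average-rank transform written from the definition, then the Pearson
## product-moment formula written out
oracle_rank_avg <- function(v) {
  vapply(v, function(a) sum(v < a) + (sum(v == a) + 1) / 2, numeric(1))
}
oracle_spearman <- function(x, y) {
  rx <- oracle_rank_avg(x)
  ry <- oracle_rank_avg(y)
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

## O(n^2) transitive-closure interval merge: union any two intervals (same
## sequence) whose gap is <= collapse_dist, until nothing changes
oracle_merge <- function(df, collapse_dist) {
  rows <- split(df[, c("seq_id", "start", "end")], seq_len(nrow(df)))
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (i in seq_along(rows)) {
      if (is.null(rows[[i]])) next
      for (j in seq_along(rows)) {
        if (i == j || is.null(rows[[j]]) || is.null(rows[[i]])) next
        a <- rows[[i]]; b <- rows[[j]]
        if (a$seq_id != b$seq_id) next
        gap <- max(a$start, b$start) - min(a$end, b$end)
        if (gap <= collapse_dist) {
          rows[[i]]$start <- min(a$start, b$start)
          rows[[i]]$end <- max(a$end, b$end)
          rows[j] <- list(NULL)
          changed <- TRUE
        }
      }
    }
    rows <- rows[!vapply(rows, is.null, logical(1))]
  }
  out <- do.call(rbind, rows)
  out[order(out$seq_id, out$start), , drop = FALSE]
}

## brute-force count of exact 6-mer occurrences within a span (both motifs)
oracle_unit_count <- function(seq_chr, start0, end0, unit) {
  span <- substr(seq_chr, start0 + 1, end0)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(unit)))
  count_one <- function(m) {
    hits <- gregexpr(m, span, fixed = TRUE)[[1]]
    sum(hits > 0)
  }
  count_one(unit) + count_one(rc)
}
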