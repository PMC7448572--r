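#' Karyotype ordering of sequence names
#'
#' Orders chromosome and scaffold names the way a karyotype is reported:
#' numeric chromosomes ascending, then `X`, `Y`, `MT`, then every
#' remaining (scaffold) name in natural sort order (digit runs compared
#' numerically). Unplaced scaffolds therefore always rank after all
#' chromosomes, which places markers mapping to them at the top of a rank
#' dotplot.
#'
#' @param chrom_names Character vector (duplicates allowed).
#' @return Unique names in karyotype order.
#' @export
karyotype_order <- function(chrom_names) {
  nm <- unique(as.character(chrom_names))
  bare <- sub("^chr", "", nm)
  is_num <- grepl("^[0-9]+$", bare)
  sex_mt <- c("X", "Y", "MT")
  is_sex <- bare %in% sex_mt
  nums <- nm[is_num][order(as.integer(bare[is_num]))]
  sexs <- nm[is_sex][order(match(bare[is_sex], sex_mt))]
  rest <- nm[!is_num & !is_sex]
  c(nums, sexs, rest[order(natural_key(rest))])
}

## zero-pad digit runs so lexicographic order equals natural order
natural_key <- function(x) {
  vapply(x, function(s) {
    parts <- regmatches(s, gregexpr("[0-9]+|[^0-9]+", s))[[1L]]
    paste(vapply(parts, function(p) {
      if (grepl("^[0-9]+$", p)) formatC(p, width = 15, flag = "0") else p
    }, character(1)), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Assign manifest and assembly rank orders to markers
#'
#' Markers are numbered 1..N by their manifest coordinates (karyotype
#' chromosome order, then position, ties broken by marker id). Mapped
#' markers are numbered 1..M by their assembly coordinates in the same
#' way; markers without an assembly placement are penalized with the
#' literal rank value -1.
#'
#' @param manifest data.frame with columns `marker_id`, `manifest_chrom`,
#'   `manifest_pos` and optionally `chip`.
#' @param placements data.frame with columns `marker_id`,
#'   `assembly_chrom`, `assembly_pos`; unmapped markers may be absent or
#'   carry `NA` chromosome. Placements for unknown markers are dropped
#'   with a warning.
#' @return data.frame with `marker_id`, `chip` (if given),
#'   `manifest_chrom`, `manifest_rank`, `assembly_rank`.
#' @export
assign_ranks <- function(manifest, placements) {
  stopifnot(all(c("marker_id", "manifest_chrom", "manifest_pos") %in% names(manifest)))
  unknown <- !placements$marker_id %in% manifest$marker_id
  if (any(unknown)) {
    warning("ignoring ", sum(unknown), " placement(s) for markers absent from the manifest")
    placements <- placements[!unknown, , drop = FALSE]
  }
  korder_m <- karyotype_order(manifest$manifest_chrom)
  m_ord <- order(match(manifest$manifest_chrom, korder_m),
                 manifest$manifest_pos, manifest$marker_id)
  out <- manifest[m_ord, , drop = FALSE]
  out$manifest_rank <- seq_len(nrow(out))

  pl <- placements[!is.na(placements$assembly_chrom), , drop = FALSE]
  pl <- pl[!duplicated(pl$marker_id), , drop = FALSE]
  korder_a <- karyotype_order(pl$assembly_chrom)
  a_ord <- order(match(pl$assembly_chrom, korder_a), pl$assembly_pos, pl$marker_id)
  arank <- stats::setNames(seq_len(nrow(pl)), pl$marker_id[a_ord])
  out$assembly_rank <- ifelse(out$marker_id %in% names(arank),
                              unname(arank[out$marker_id]), -1L)
  keep <- c("marker_id", if ("chip" %in% names(out)) "chip",
            "manifest_chrom", "manifest_rank", "assembly_rank")
  rownames(out) <- NULL
  out[, keep]
}

#' Rank-order concordance between manifest and assembly
#'
#' Spearman's rho between the manifest rank and the assembly rank vector,
#' in which every unmapped marker carries the shared penalty value -1.
#' The -1 block forms ties, resolved by the usual average-rank transform;
#' rho is the Pearson correlation of the rank-transformed vectors. A
#' two-sided test against rho = 0 is reported.
#'
#' @param rank_pairs data.frame from [assign_ranks()].
#' @return list of class `concordance_report`: `rho`, `p_value`,
#'   `n_markers`, `n_unmapped`, and `per_chip` (data.frame, present when a
#'   `chip` column exists).
#' @export
spearman_rho <- function(rank_pairs) {
  x <- rank_pairs$manifest_rank
  y <- rank_pairs$assembly_rank
  if (length(x) < 3L) stop("spearman_rho: need at least 3 rank pairs")
  rho_one <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(list(rho = NA_real_, p = NA_real_))
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = FALSE,
                                           alternative = "two.sided"))
    list(rho = unname(ct$estimate), p = ct$p.value)
  }
  main <- rho_one(x, y)
  per_chip <- NULL
  if ("chip" %in% names(rank_pairs)) {
    per_chip <- do.call(rbind, lapply(split(rank_pairs, rank_pairs$chip), function(d) {
      r <- if (nrow(d) >= 3L) rho_one(d$manifest_rank, d$assembly_rank)
           else list(rho = NA_real_, p = NA_real_)
      data.frame(chip = d$chip[1L], n = nrow(d),
                 n_unmapped = sum(d$assembly_rank == -1L), rho = r$rho)
    }))
    rownames(per_chip) <- NULL
  }
  structure(list(rho = main$rho, p_value = main$p, n_markers = length(x),
                 n_unmapped = sum(y == -1L), per_chip = per_chip),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("Spearman rank-order concordance: rho = %.5f (n = %d, unmapped = %d, p = %.3g)\n",
              x$rho, x$n_markers, x$n_unmapped, x$p_value))
  if (!is.null(x$per_chip)) print(x$per_chip, row.names = FALSE)
  invisible(x)
}

#' Marker spacing statistics and largest desert
#'
#' Distances between consecutive mapped markers within each chromosome
#' (never across chromosome boundaries); reports their mean, sample
#' (n - 1) standard deviation, and the largest gap ("marker desert") with
#' its interval. A single spacing has SD 0 by convention.
#'
#' @param placements data.frame with `marker_id`, `assembly_chrom`,
#'   `assembly_pos`; unmapped (`NA`) rows ignored.
#' @return list of class `spacing_report`: `mean_spacing`, `sd_spacing`,
#'   `n_spacings`, `max_desert` (list with `chrom`, `start`, `end`,
#'   `length`).
#' @export
marker_spacing <- function(placements) {
  pl <- placements[!is.na(placements$assembly_chrom), , drop = FALSE]
  spac <- NULL
  for (ch in unique(pl$assembly_chrom)) {
    pos <- sort(pl$assembly_pos[pl$assembly_chrom == ch])
    if (length(pos) < 2L) next
    d <- diff(pos)
    spac <- rbind(spac, data.frame(chrom = ch, start = pos[-length(pos)],
                                   end = pos[-1L], length = d))
  }
  if (is.null(spac)) stop("marker_spacing: need >= 2 mapped markers on some chromosome")
  i <- which.max(spac$length)
  structure(list(
    mean_spacing = mean(spac$length),
    sd_spacing = if (nrow(spac) > 1L) stats::sd(spac$length) else 0,
    n_spacings = nrow(spac),
    max_desert = list(chrom = spac$chrom[i], start = spac$start[i],
                      end = spac$end[i], length = spac$length[i]),
    spacings = spac), class = "spacing_report")
}

#' @export
print.spacing_report <- function(x, ...) {
  cat(sprintf("marker spacing: mean %.1f bp, SD %.1f bp over %d spacings; largest desert %s:%d-%d (%.0f bp)\n",
              x$mean_spacing, x$sd_spacing, x$n_spacings,
              x$max_desert$chrom, x$max_desert$start, x$max_desert$end,
              x$max_desert$length))
  invisible(x)
}

#' Place probes on an assembly by unique exact match
#'
#' A probe is placed if and only if it has exactly one exact occurrence in
#' the assembly, counting both strands; zero or multiple occurrences leave
#' it unmapped. This simple placer supports synthetic tests; mapping real
#' probes against a real genome is an external aligner's job.
#'
#' @param records Named [Biostrings::DNAStringSet] assembly.
#' @param manifest data.frame with `marker_id` and `probe_seq` columns.
#' @param anchor `"left"` reports the leftmost base of the probe alignment
#'   (1-based); `"three_prime"` reports the strand-aware 3' end, the base
#'   adjacent to the assayed variant site.
#' @return data.frame with `marker_id`, `assembly_chrom` (`NA` when
#'   unmapped), `assembly_pos`, `strand`, `unique`.
#' @export
place_probes_exact <- function(records, manifest, anchor = c("left", "three_prime")) {
  anchor <- match.arg(anchor)
  stopifnot(!is.null(manifest$probe_seq))
  probes <- Biostrings::DNAStringSet(toupper(manifest$probe_seq))
  names(probes) <- manifest$marker_id
  up <- Biostrings::DNAStringSet(toupper(records))
  same_w <- length(unique(Biostrings::width(probes))) == 1L

  count_matrix <- function(pb, subj) {
    if (same_w && length(pb) > 1L) {
      pd <- Biostrings::PDict(pb)
      t(Biostrings::vcountPDict(pd, subj))
    } else {
      sapply(seq_along(pb), function(i)
        Biostrings::vcountPattern(as.character(pb[[i]]), subj))
    }
  }
  fwd <- count_matrix(probes, up)                       # seq x probe
  rev <- count_matrix(probes, Biostrings::reverseComplement(up))
  if (is.null(dim(fwd))) { fwd <- matrix(fwd, nrow = length(up)); rev <- matrix(rev, nrow = length(up)) }
  tot <- colSums(fwd) + colSums(rev)

  out <- data.frame(marker_id = manifest$marker_id,
                    assembly_chrom = NA_character_, assembly_pos = NA_integer_,
                    strand = NA_character_, unique = tot == 1L,
                    stringsAsFactors = FALSE)
  seq_w <- Biostrings::width(up)
  for (j in which(tot == 1L)) {
    i <- which(fwd[, j] + rev[, j] == 1L)
    plen <- Biostrings::width(probes)[j]
    if (fwd[i, j] == 1L) {
      s <- Biostrings::start(Biostrings::matchPattern(as.character(probes[[j]]), up[[i]]))
      strand <- "+"
      pos <- if (anchor == "left") s else s + plen - 1L
    } else {
      s_rc <- Biostrings::start(Biostrings::matchPattern(
        as.character(probes[[j]]),
        Biostrings::reverseComplement(up[[i]])))
      s <- seq_w[i] - (s_rc + plen - 1L) + 1L           # leftmost base on + strand
      strand <- "-"
      pos <- if (anchor == "left") s else s             # 3' end of a - strand probe
    }
    out$assembly_chrom[j] <- names(up)[i]
    out$assembly_pos[j] <- pos
    out$strand[j] <- strand
  }
  out
}

#' Export rank pairs for collinearity dotplots
#'
#' One row per marker with its manifest and assembly ranks (unmapped
#' markers keep the -1 penalty value) and the manifest chromosome as a
#' facet column, ready for external plotting of manifest order (x) against
#' assembly order (y).
#'
#' @param rank_pairs data.frame from [assign_ranks()].
#' @param path Optional output TSV path.
#' @return The exported data.frame, invisibly when `path` is given.
#' @export
dotplot_export <- function(rank_pairs, path = NULL) {
  cols <- c("marker_id", if ("chip" %in% names(rank_pairs)) "chip",
            "manifest_chrom", "manifest_rank", "assembly_rank")
  df <- rank_pairs[, cols]
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Read a marker manifest from TSV/CSV
#'
#' @param path Delimited file with columns `marker_id`, `chip`,
#'   `manifest_chrom`, `manifest_pos` and optionally `probe_seq` (comma- or
#'   tab-separated, inferred from the extension).
#' @param chrom_aliases Optional named character vector normalizing
#'   chip-specific chromosome labels, e.g. `c(SSC1 = "1")`.
#' @return data.frame of manifest entries.
#' @export
read_manifest <- function(path, chrom_aliases = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "")
  need <- c("marker_id", "manifest_chrom", "manifest_pos")
  if (!all(need %in% names(df))) {
    stop("manifest lacks column(s): ", paste(setdiff(need, names(df)), collapse = ", "))
  }
  if (!is.null(chrom_aliases)) {
    hit <- df$manifest_chrom %in% names(chrom_aliases)
    df$manifest_chrom[hit] <- unname(chrom_aliases[df$manifest_chrom[hit]])
  }
  if (anyDuplicated(df[, c("marker_id", if ("chip" %in% names(df)) "chip")])) {
    stop("duplicate marker ids within a chip in ", path)
  }
  df
}
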