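#' Nx / Lx contiguity statistic
#'
#' The Nx of a multiset of lengths is the length of the element at which
#' the descending cumulative sum first reaches at least x% of the total;
#' Lx is the number of elements up to and including that element.
#'
#' @param lengths Numeric vector of element lengths (contigs or scaffolds).
#' @param x Percentage in (0, 100]; 50 gives the familiar N50/L50.
#' @return A list with elements `nx` (bp) and `lx` (count).
#' @export
#' @examples
#' nx(c(8, 5, 3, 2), 50)  # N50 = 5, L50 = 2
nx <- function(lengths, x = 50) {
  if (length(lengths) == 0L) stop("nx: empty length set")
  if (!is.numeric(x) || length(x) != 1L || x <= 0 || x > 100) {
    stop("nx: x must be a single value in (0, 100]")
  }
  lengths <- sort(as.numeric(lengths), decreasing = TRUE)
  cum <- cumsum(lengths)
  target <- x / 100 * cum[length(cum)]
  i <- which(cum >= target)[1L]
  list(nx = lengths[i], lx = i)
}

## Contigs break at every AGP gap line (NCBI convention), so contig lengths
## are simply the component spans.
contig_lengths_by_object <- function(layout) {
  data.frame(object_id = layout$components$object_id,
             length = layout$components$object_end -
               layout$components$object_start + 1L,
             stringsAsFactors = FALSE)
}

## Scaffolds are objects split at unspanned gaps; spanned gap bases belong
## to the enclosing scaffold, unspanned gap bases to neither side.
scaffold_lengths_by_object <- function(layout) {
  out <- data.frame(object_id = character(), length = integer(),
                    stringsAsFactors = FALSE)
  for (obj in layout$objects$object_id) {
    comp <- layout$components[layout$components$object_id == obj, , drop = FALSE]
    gp <- layout$gaps[layout$gaps$object_id == obj, , drop = FALSE]
    parts <- rbind(
      if (nrow(comp)) data.frame(part = comp$part_number,
                                 span = comp$object_end - comp$object_start + 1L,
                                 brk = FALSE),
      if (nrow(gp)) data.frame(part = gp$part_number,
                               span = gp$end - gp$start + 1L,
                               brk = gp$gap_kind == "unspanned"))
    if (is.null(parts) || nrow(parts) == 0L) next
    parts <- parts[order(parts$part), ]
    acc <- 0L
    for (i in seq_len(nrow(parts))) {
      if (parts$brk[i]) {
        if (acc > 0L) out[nrow(out) + 1L, ] <- list(obj, acc)
        acc <- 0L
      } else {
        acc <- acc + parts$span[i]
      }
    }
    if (acc > 0L) out[nrow(out) + 1L, ] <- list(obj, acc)
  }
  out
}

#' Assembly contiguity statistics
#'
#' Computes the standard NCBI-convention summary of an assembly from its
#' layout: total and ungapped length, scaffold and contig counts and
#' N50/L50, spanned/unspanned gap counts, and the placed/unplaced
#' decomposition. Contigs are components delimited by every AGP gap line
#' regardless of declared gap length; scaffolds are objects split at
#' unspanned (linkage "no") gaps.
#'
#' @param layout An [assembly_layout()].
#' @param records Optional [Biostrings::DNAStringSet]; when supplied the
#'   layout is validated against it first and any violation is an error.
#' @param include_mt Include mitochondrial sequence in N50/L50 (it is
#'   always counted in `n_chromosomes`, never excluded from totals).
#' @param mt_names Object names treated as mitochondrial.
#' @return An object of class `assembly_stats`: a named list of the 12
#'   summary statistics plus `scaffold_lengths`/`contig_lengths`
#'   attributes for downstream use.
#' @export
assembly_stats <- function(layout, records = NULL, include_mt = FALSE,
                           mt_names = c("MT", "chrM", "M")) {
  if (!is.null(records)) {
    viol <- validate_layout(layout, records)
    if (nrow(viol) > 0L) {
      stop("layout/sequence mismatch (see validate_layout): ",
           nrow(viol), " violation(s), first: ", viol$object_id[1L], " ",
           viol$kind[1L])
    }
  }
  scl <- scaffold_lengths_by_object(layout)
  ctl <- contig_lengths_by_object(layout)
  placed <- !is.na(layout$objects$chromosome)
  names(placed) <- layout$objects$object_id
  is_mt <- layout$objects$object_id %in% mt_names
  names(is_mt) <- layout$objects$object_id

  total <- sum(as.numeric(layout$objects$length))
  gap_bases <- sum(as.numeric(layout$gaps$declared_length))
  scl_n50 <- scl$length[!is_mt[scl$object_id] | include_mt]
  ctl_n50 <- ctl$length[!is_mt[ctl$object_id] | include_mt]
  s50 <- nx(scl_n50, 50)
  c50 <- nx(ctl_n50, 50)

  out <- list(
    total_length = total,
    ungapped_length = total - gap_bases,
    n_scaffolds = nrow(scl),
    n_unplaced_scaffolds = sum(!placed[scl$object_id]),
    scaffold_n50 = s50$nx,
    scaffold_l50 = s50$lx,
    n_unspanned_gaps = sum(layout$gaps$gap_kind == "unspanned"),
    n_spanned_gaps = sum(layout$gaps$gap_kind == "spanned"),
    n_contigs = nrow(ctl),
    contig_n50 = c50$nx,
    contig_l50 = c50$lx,
    n_chromosomes = length(unique(stats::na.omit(layout$objects$chromosome)))
  )
  attr(out, "scaffold_lengths") <- scl
  attr(out, "contig_lengths") <- ctl
  class(out) <- "assembly_stats"
  out
}

#' @export
print.assembly_stats <- function(x, ...) {
  df <- stats_table(list(assembly = x))
  print(df, row.names = FALSE)
  invisible(x)
}

STATS_ROWS <- c(
  total_length = "Total sequence length",
  ungapped_length = "Total ungapped length",
  n_scaffolds = "No. of scaffolds",
  n_unplaced_scaffolds = "No. of unplaced scaffolds",
  scaffold_n50 = "Scaffold N50",
  scaffold_l50 = "Scaffold L50",
  n_unspanned_gaps = "No. of unspanned gaps",
  n_spanned_gaps = "No. of spanned gaps",
  n_contigs = "No. of contigs",
  contig_n50 = "Contig N50",
  contig_l50 = "Contig L50",
  n_chromosomes = "No. of chromosomes"
)

#' Side-by-side assembly comparison table
#'
#' @param assemblies Named list of `assembly_stats` objects.
#' @return data.frame with a `statistic` column and one column per
#'   assembly; 12 rows in the conventional reporting order.
#' @export
stats_table <- function(assemblies) {
  if (length(assemblies) == 0L) stop("stats_table: need at least one assembly")
  stopifnot(!is.null(names(assemblies)))
  df <- data.frame(statistic = unname(STATS_ROWS), stringsAsFactors = FALSE)
  for (nm in names(assemblies)) {
    st <- assemblies[[nm]]
    df[[nm]] <- vapply(names(STATS_ROWS), function(k) as.numeric(st[[k]]),
                       numeric(1))
  }
  df
}

#' Serialize a comparison table
#'
#' @param table Output of [stats_table()].
#' @param prefix Output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @return Character vector of the two paths, invisibly.
#' @export
write_stats_table <- function(table, prefix) {
  tsv <- paste0(prefix, ".tsv")
  json <- paste0(prefix, ".json")
  utils::write.table(table, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(table, json, digits = NA)
  invisible(c(tsv, json))
}
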