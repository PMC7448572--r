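#' Read assembly sequences from FASTA
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that additionally
#' validates the records: every sequence must be non-empty and record names
#' (the first whitespace-delimited token of each header) must be unique.
#'
#' @param path Path to a FASTA file, optionally gzip-compressed.
#' @param uppercase Uppercase all bases on read. Soft-masked (lowercase)
#'   bases carry no information for any analysis in this package, so the
#'   default is `TRUE`; use `FALSE` to preserve case for re-serialization.
#' @return A named [Biostrings::DNAStringSet] in file order.
#' @export
read_fasta <- function(path, uppercase = TRUE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (any(Biostrings::width(x) == 0L)) {
    stop("empty sequence record(s): ",
         paste(names(x)[Biostrings::width(x) == 0L], collapse = ", "))
  }
  if (anyDuplicated(names(x))) {
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  }
  if (uppercase) x <- Biostrings::DNAStringSet(toupper(x))
  x
}

#' Write assembly sequences to FASTA
#'
#' @param records A named [Biostrings::DNAStringSet].
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 80L) {
  Biostrings::writeXStringSet(records, path, width = width,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

## ---------------------------------------------------------------------------
## AGP: the scaffold -> contig -> gap decomposition.  Coordinates are kept
## 1-based inclusive (AGP native); all exported interval files are 0-based
## half-open BED.
## ---------------------------------------------------------------------------

AGP_COMPONENT_TYPES <- c("W", "A", "D", "F", "O")
AGP_GAP_TYPES <- c("N", "U")

#' Construct an assembly layout object
#'
#' An `assembly_layout` bundles three data frames: `objects` (one row per
#' assembled object with its length and chromosome assignment), `components`
#' (AGP W/A/D/F/O lines) and `gaps` (AGP N/U lines). A gap is *spanned* when
#' its AGP linkage field is `"yes"` (within-scaffold) and *unspanned*
#' otherwise (a join between scaffolds placed on the same chromosome).
#'
#' @param objects data.frame with columns `object_id`, `length`,
#'   `chromosome` (`NA` for unplaced objects).
#' @param components data.frame with columns `object_id`, `object_start`,
#'   `object_end`, `part_number`, `component_id`, `component_start`,
#'   `component_end`, `orientation`.
#' @param gaps data.frame with columns `object_id`, `start`, `end`,
#'   `part_number`, `gap_type` (`"N"`/`"U"`), `gap_kind`
#'   (`"spanned"`/`"unspanned"`), `declared_length`, `linkage`.
#' @return An object of class `assembly_layout`.
#' @export
assembly_layout <- function(objects, components, gaps) {
  stopifnot(is.data.frame(objects), is.data.frame(components), is.data.frame(gaps))
  structure(list(objects = objects, components = components, gaps = gaps),
            class = "assembly_layout")
}

#' @export
print.assembly_layout <- function(x, ...) {
  n_placed <- sum(!is.na(x$objects$chromosome))
  cat(sprintf(
    "assembly_layout: %d object(s) (%d chromosome-assigned), %d component(s), %d gap(s) [%d spanned, %d unspanned]\n",
    nrow(x$objects), n_placed, nrow(x$components), nrow(x$gaps),
    sum(x$gaps$gap_kind == "spanned"), sum(x$gaps$gap_kind == "unspanned")))
  invisible(x)
}

empty_components <- function() {
  data.frame(object_id = character(), object_start = integer(),
             object_end = integer(), part_number = integer(),
             component_id = character(), component_start = integer(),
             component_end = integer(), orientation = character(),
             stringsAsFactors = FALSE)
}

empty_gaps <- function() {
  data.frame(object_id = character(), start = integer(), end = integer(),
             part_number = integer(), gap_type = character(),
             gap_kind = character(), declared_length = integer(),
             linkage = character(), stringsAsFactors = FALSE)
}

#' Read an AGP v2.x file into an assembly layout
#'
#' Parses the tab-separated AGP dialect: component lines of type
#' W/A/D/F/O and gap lines of type N (known size) or U (unknown size,
#' conventionally 100 bp). Gaps with linkage `"yes"` are classified
#' spanned, all others unspanned. Each object is validated to tile exactly:
#' consecutive part numbers, each part starting one base after the previous
#' part's end.
#'
#' @param path AGP file (plain or gzip; `#` comment lines ignored).
#' @param chrom_pattern Regular expression; object ids matching it are
#'   treated as chromosome-assigned, with the object id as chromosome name.
#'   Ignored for objects whose AGP lines already carry no such convention.
#' @return An [assembly_layout()].
#' @export
read_agp <- function(path, chrom_pattern = default_chrom_pattern()) {
  if (!file.exists(path)) stop("AGP file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) {
    return(assembly_layout(
      data.frame(object_id = character(), length = integer(),
                 chromosome = character(), stringsAsFactors = FALSE),
      empty_components(), empty_gaps()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 8L)) {
    stop("AGP parse error: line ", lineno[which(nf < 8L)[1L]],
         " has fewer than 8 tab-separated fields")
  }

  comp <- empty_components()
  gaps <- empty_gaps()
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    obj <- f[1L]
    ostart <- suppressWarnings(as.integer(f[2L]))
    oend <- suppressWarnings(as.integer(f[3L]))
    part <- suppressWarnings(as.integer(f[4L]))
    type <- f[5L]
    if (is.na(ostart) || is.na(oend) || ostart < 1L || oend < ostart) {
      stop("AGP validation error in object ", obj, ": bad coordinates at line ",
           lineno[i])
    }
    if (type %in% AGP_COMPONENT_TYPES) {
      comp[nrow(comp) + 1L, ] <- list(obj, ostart, oend, part, f[6L],
                                      as.integer(f[7L]), as.integer(f[8L]),
                                      if (length(f) >= 9L) f[9L] else "?")
    } else if (type %in% AGP_GAP_TYPES) {
      gl <- as.integer(f[6L])
      linkage <- if (length(f) >= 8L) f[8L] else "no"
      gaps[nrow(gaps) + 1L, ] <- list(obj, ostart, oend, part, type,
                                      if (identical(linkage, "yes")) "spanned" else "unspanned",
                                      gl, linkage)
    } else {
      stop("AGP validation error in object ", obj, ": unknown component type '",
           type, "' at line ", lineno[i])
    }
  }

  obj_ids <- unique(c(comp$object_id, gaps$object_id))
  lens <- integer(length(obj_ids))
  names(lens) <- obj_ids
  for (obj in obj_ids) {
    parts <- rbind(
      data.frame(start = comp$object_start[comp$object_id == obj],
                 end = comp$object_end[comp$object_id == obj],
                 part = comp$part_number[comp$object_id == obj]),
      data.frame(start = gaps$start[gaps$object_id == obj],
                 end = gaps$end[gaps$object_id == obj],
                 part = gaps$part_number[gaps$object_id == obj]))
    parts <- parts[order(parts$part), ]
    if (!identical(parts$part, seq_len(nrow(parts)))) {
      stop("AGP validation error in object ", obj,
           ": part numbers not consecutive from 1")
    }
    if (parts$start[1L] != 1L ||
        (nrow(parts) > 1L && any(parts$start[-1L] != parts$end[-nrow(parts)] + 1L))) {
      stop("AGP validation error in object ", obj, ": parts do not tile the object")
    }
    lens[obj] <- parts$end[nrow(parts)]
  }
  ## component span must equal object span
  bad <- (comp$object_end - comp$object_start) !=
    (comp$component_end - comp$component_start)
  if (any(bad)) {
    stop("AGP validation error in object ", comp$object_id[which(bad)[1L]],
         ": component span differs from object span")
  }
  objects <- data.frame(
    object_id = obj_ids, length = unname(lens),
    chromosome = ifelse(grepl(chrom_pattern, obj_ids), obj_ids, NA_character_),
    stringsAsFactors = FALSE)
  assembly_layout(objects, comp, gaps)
}

#' Write an assembly layout as AGP v2.1
#'
#' @param layout An [assembly_layout()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_agp <- function(layout, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.1", con)
  for (obj in layout$objects$object_id) {
    comp <- layout$components[layout$components$object_id == obj, , drop = FALSE]
    gaps <- layout$gaps[layout$gaps$object_id == obj, , drop = FALSE]
    rows <- character(nrow(comp) + nrow(gaps))
    if (nrow(comp)) {
      rows[comp$part_number] <- sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%s",
        obj, comp$object_start, comp$object_end, comp$part_number, "W",
        comp$component_id, comp$component_start, comp$component_end,
        comp$orientation)
    }
    if (nrow(gaps)) {
      gap_cat <- ifelse(gaps$gap_kind == "spanned", "scaffold", "contig")
      evidence <- ifelse(gaps$gap_kind == "spanned", "paired-ends", "na")
      rows[gaps$part_number] <- sprintf("%s\t%d\t%d\t%d\t%s\t%d\t%s\t%s\t%s",
        obj, gaps$start, gaps$end, gaps$part_number, gaps$gap_type,
        gaps$declared_length, gap_cat, gaps$linkage, evidence)
    }
    writeLines(rows, con)
  }
  invisible(path)
}

#' Default chromosome-name pattern
#'
#' Object names consisting of a bare number, `X`, `Y` or `MT` (optionally
#' prefixed with `chr`) are treated as chromosome-assigned.
#' @return A regular expression string.
#' @export
default_chrom_pattern <- function() "^(chr)?([0-9]+|X|Y|MT)$"

#' Infer an assembly layout from sequence alone
#'
#' When no AGP is available, contigs are delimited by maximal runs of `N`
#' of length at least `min_gap_n` (the NCBI assembly-stats convention);
#' shorter N-runs stay inside contigs. All inferred gaps are classified
#' spanned, since sequence alone carries no linkage evidence.
#'
#' @param records A named [Biostrings::DNAStringSet].
#' @param min_gap_n Minimum N-run length that breaks a contig (default 10).
#' @param chrom_pattern Regular expression classifying sequence names as
#'   chromosomes; see [default_chrom_pattern()].
#' @return An [assembly_layout()].
#' @export
infer_layout_from_fasta <- function(records, min_gap_n = 10L,
                                    chrom_pattern = default_chrom_pattern()) {
  comp <- empty_components()
  gaps <- empty_gaps()
  ids <- names(records)
  for (i in seq_along(records)) {
    obj <- ids[i]
    L <- Biostrings::width(records)[i]
    nruns <- Biostrings::matchPattern("N", Biostrings::DNAString(
      toupper(as.character(records[[i]]))), fixed = TRUE)
    ir <- IRanges::reduce(methods::as(nruns, "IRanges"))
    ir <- ir[IRanges::width(ir) >= min_gap_n]
    bounds <- c(0L, as.integer(rbind(IRanges::start(ir) - 1L, IRanges::end(ir))), L)
    part <- 0L
    k <- 0L
    for (j in seq_len(length(bounds) / 2L)) {
      s <- bounds[2L * j - 1L] + 1L
      e <- bounds[2L * j]
      if (e >= s) {
        part <- part + 1L
        k <- k + 1L
        comp[nrow(comp) + 1L, ] <- list(obj, s, e, part,
                                        sprintf("%s_ctg%d", obj, k),
                                        1L, e - s + 1L, "+")
      }
      if (j <= length(ir)) {
        part <- part + 1L
        gs <- IRanges::start(ir)[j]
        ge <- IRanges::end(ir)[j]
        gaps[nrow(gaps) + 1L, ] <- list(obj, gs, ge, part, "N", "spanned",
                                        ge - gs + 1L, "yes")
      }
    }
  }
  objects <- data.frame(
    object_id = ids, length = Biostrings::width(records),
    chromosome = ifelse(grepl(chrom_pattern, ids), ids, NA_character_),
    stringsAsFactors = FALSE)
  assembly_layout(objects, comp, gaps)
}

#' Validate a layout against its sequences
#'
#' Cross-checks an AGP-derived layout against the FASTA records: object
#' lengths must match sequence lengths, gap coordinates must be `N` in the
#' sequence, and component parts must appear in coordinate order.
#'
#' @param layout An [assembly_layout()].
#' @param records A named [Biostrings::DNAStringSet].
#' @return data.frame of violations (`object_id`, `kind`, `detail`); zero
#'   rows when consistent.
#' @export
validate_layout <- function(layout, records) {
  v <- data.frame(object_id = character(), kind = character(),
                  detail = character(), stringsAsFactors = FALSE)
  add <- function(obj, kind, detail) {
    v[nrow(v) + 1L, ] <<- list(obj, kind, detail)
  }
  seqlen <- stats::setNames(Biostrings::width(records), names(records))
  for (i in seq_len(nrow(layout$objects))) {
    obj <- layout$objects$object_id[i]
    L <- layout$objects$length[i]
    if (!obj %in% names(seqlen)) {
      add(obj, "missing_sequence", "object has no FASTA record")
      next
    }
    if (seqlen[[obj]] != L) {
      add(obj, "length_mismatch",
          sprintf("AGP length %d != sequence length %d", L, seqlen[[obj]]))
    }
    comp <- layout$components[layout$components$object_id == obj, , drop = FALSE]
    if (nrow(comp) > 1L) {
      o <- order(comp$part_number)
      if (is.unsorted(comp$object_start[o])) {
        add(obj, "component_order", "components out of coordinate order")
      }
    }
    gp <- layout$gaps[layout$gaps$object_id == obj, , drop = FALSE]
    if (nrow(gp)) {
      sq <- toupper(as.character(records[[obj]]))
      for (j in seq_len(nrow(gp))) {
        if (gp$end[j] > nchar(sq)) next  # already reported as length mismatch
        run <- substr(sq, gp$start[j], gp$end[j])
        if (gsub("N", "", run) != "") {
          add(obj, "gap_not_N",
              sprintf("gap %d..%d contains non-N bases", gp$start[j], gp$end[j]))
        }
      }
    }
  }
  v
}

#' Write intervals as BED (0-based half-open)
#'
#' @param df data.frame with columns `seq_id`, `start`, `end` (already
#'   0-based half-open) and optionally `name`, `score`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  cols <- list(df$seq_id, df$start, df$end)
  if (!is.null(df$name)) {
    cols <- c(cols, list(df$name))
    if (!is.null(df$score)) {
      cols <- c(cols, list(df$score))
      if (!is.null(df$strand)) cols <- c(cols, list(df$strand))
    }
  }
  out <- do.call(paste, c(cols, sep = "\t"))
  writeLines(out, path)
  invisible(path)
}

#' Read a BED file as a 0-based half-open interval data frame
#'
#' Uses [rtracklayer::import()] for the parsing and converts back to BED
#' coordinate semantics.
#'
#' @param path BED file.
#' @return data.frame with columns `seq_id`, `start`, `end` (0-based
#'   half-open) plus `name`/`score`/`strand` when present.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(seq_id = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  if (!is.null(gr$name)) out$name <- gr$name
  if (!is.null(gr$score)) out$score <- gr$score
  out
}
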