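#' Run a configured analysis pipeline
#'
#' Ties the analysis stages together: optional genome simulation, assembly
#' contiguity statistics, window quality classification, telomere and
#' centromere calling, and marker-order concordance. Each requested stage
#' writes its machine-readable outputs under `out_dir` and contributes a
#' block to a combined JSON report that also records the package version,
#' the effective parameter set and the md5 digests of the written files.
#'
#' The configuration is a flat list (or the path of a YAML file with the
#' same structure). Recognized keys:
#' \describe{
#'   \item{out_dir}{Output directory (required).}
#'   \item{seed}{Integer seed for any simulated input (default 1).}
#'   \item{fasta, agp}{Input assembly; omitted when `simulate` is set.}
#'   \item{simulate}{`TRUE` or a named list overriding [sim_config()]
#'     defaults; generates the assembly (and truth files) first.}
#'   \item{stats}{`TRUE` to compute [assembly_stats()].}
#'   \item{windowqc}{`TRUE` (simulated track; requires `simulate`) or a
#'     list with `windows` (TSV path) and optionally `mask` (BED) and any
#'     [qc_thresholds()] field.}
#'   \item{telomeres}{`TRUE` or a list overriding [find_telomeres()]
#'     defaults.}
#'   \item{centromeres}{A list with `rm_out` (one or more .out paths) and
#'     optionally `monomers` (FASTA); with `simulate`, `TRUE` uses the
#'     simulated annotation and monomer.}
#'   \item{markers}{`TRUE` (simulated probe set; requires `simulate`) or a
#'     list with `manifest` (TSV/CSV) and either `placements` (TSV) or
#'     placement by exact probe match against the assembly.}
#' }
#'
#' @param config A named list or the path of a YAML config file.
#' @return The report, invisibly; also written to
#'   `file.path(out_dir, "report.json")`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) stop("config lacks out_dir")
  stages <- intersect(c("stats", "windowqc", "telomeres", "centromeres", "markers"),
                      names(config))
  if (length(stages) == 0L && is.null(config$simulate)) {
    stop("no analysis requested: enable at least one stage")
  }
  ## fail on missing inputs before any stage runs
  for (p in c(config$fasta, config$agp,
              if (is.list(config$windowqc)) config$windowqc$windows,
              if (is.list(config$windowqc)) config$windowqc$mask,
              if (is.list(config$centromeres)) config$centromeres$rm_out,
              if (is.list(config$centromeres)) config$centromeres$monomers,
              if (is.list(config$markers)) config$markers$manifest,
              if (is.list(config$markers)) config$markers$placements)) {
    if (!file.exists(p)) stop("missing input file: ", p)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  report <- list(package = "karyoscan",
                 version = as.character(utils::packageVersion("karyoscan")),
                 seed = seed, parameters = config)
  outfile <- function(...) file.path(config$out_dir, paste0(...))
  written <- character(0)
  log_stage <- function(name) message("[karyoscan] stage: ", name)

  sim <- NULL
  if (!is.null(config$simulate)) {
    log_stage("simulate")
    over <- if (is.list(config$simulate)) config$simulate else list()
    cfg <- do.call(sim_config, c(list(seed = seed), over))
    sim <- simulate_genome(cfg)
    write_fasta(sim$records, outfile("genome.fa"))
    write_agp(sim$layout, outfile("genome.agp"))
    for (nm in names(sim$truth)) {
      if (!is.null(sim$truth[[nm]])) {
        write_bed(sim$truth[[nm]], outfile("truth_", nm, ".bed"))
        written <- c(written, outfile("truth_", nm, ".bed"))
      }
    }
    records <- sim$records
    layout <- sim$layout
    written <- c(written, outfile("genome.fa"), outfile("genome.agp"))
  } else {
    if (is.null(config$fasta)) stop("config needs either fasta or simulate")
    records <- read_fasta(config$fasta)
    layout <- if (!is.null(config$agp)) read_agp(config$agp)
              else infer_layout_from_fasta(records)
  }

  if ("stats" %in% stages) {
    log_stage("stats")
    st <- assembly_stats(layout, records)
    tbl <- stats_table(stats::setNames(list(st), "assembly"))
    write_stats_table(tbl, outfile("stats"))
    report$stats <- st[seq_along(st)]
    written <- c(written, outfile("stats.tsv"), outfile("stats.json"))
  }

  if ("windowqc" %in% stages) {
    log_stage("windowqc")
    wq <- config$windowqc
    if (isTRUE(wq)) {
      if (is.null(sim)) stop("windowqc: TRUE requires simulate")
      track <- simulate_window_track(sim)
      windows <- track$windows
    } else {
      windows <- read_window_stats(wq$windows)
    }
    thr_args <- if (is.list(wq)) wq[intersect(names(wq), names(formals(qc_thresholds)))]
                else list()
    thr <- do.call(qc_thresholds, thr_args)
    classes <- classify_windows(gc_normalize(windows), thr)
    mask <- if (is.list(wq) && !is.null(wq$mask)) wq$mask else NULL
    summ <- qc_summary(classes, mask)
    write_window_stats(classes, outfile("windows_classified.tsv"))
    utils::write.table(summ$table, outfile("qc_summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    report$windowqc <- list(summary = summ$table,
                            mean_gc_lqlc = summ$mean_gc_lqlc,
                            total_bases = summ$total_bases,
                            thresholds = unclass(thr))
    written <- c(written, outfile("windows_classified.tsv"), outfile("qc_summary.tsv"))
  }

  if ("telomeres" %in% stages) {
    log_stage("telomeres")
    args <- if (is.list(config$telomeres)) config$telomeres else list()
    calls <- do.call(find_telomeres, c(list(records = records), args))
    utils::write.table(calls, outfile("telomeres.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (nrow(calls)) write_bed(calls, outfile("telomeres.bed"))
    report$telomeres <- list(n_calls = nrow(calls), calls = calls)
    written <- c(written, outfile("telomeres.tsv"))
  }

  if ("centromeres" %in% stages) {
    log_stage("centromeres")
    cc <- config$centromeres
    if (isTRUE(cc)) {
      if (is.null(sim)) stop("centromeres: TRUE requires simulate")
      rm_path <- outfile("repeats.out")
      simulate_repeatmasker_out(sim, rm_path)
      rm_records <- list(default_library = read_repeatmasker_out(rm_path))
      hits <- search_satellite_monomers(records, sim$monomer)
    } else {
      rm_records <- lapply(cc$rm_out, read_repeatmasker_out)
      names(rm_records) <- if (length(rm_records) > 1L)
        c("default_library", paste0("novel_library", seq_len(length(rm_records) - 1L)))
      else "default_library"
      hits <- if (!is.null(cc$monomers)) {
        search_satellite_monomers(records, read_fasta(cc$monomers))
      } else NULL
    }
    pred <- predict_centromeres(rm_records, hits)
    if (nrow(pred$calls)) write_bed(pred$calls, outfile("centromeres.bed"))
    utils::write.table(pred$calls, outfile("centromeres.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    report$centromeres <- pred$summary
    written <- c(written, outfile("centromeres.tsv"))
  }

  if ("markers" %in% stages) {
    log_stage("markers")
    mk <- config$markers
    if (isTRUE(mk)) {
      if (is.null(sim)) stop("markers: TRUE requires simulate")
      ps <- simulate_probe_set(sim)
      manifest <- ps$manifest
      pl <- place_probes_exact(ps$assembly, manifest)
    } else {
      manifest <- read_manifest(mk$manifest)
      if (!is.null(mk$placements)) {
        pl <- utils::read.delim(mk$placements, stringsAsFactors = FALSE)
      } else {
        pl <- place_probes_exact(records, manifest)
      }
    }
    ranks <- assign_ranks(manifest, pl)
    conc <- spearman_rho(ranks)
    spacing <- tryCatch(marker_spacing(pl), error = function(e) NULL)
    dotplot_export(ranks, outfile("rank_pairs.tsv"))
    report$markers <- list(
      rho = conc$rho, p_value = conc$p_value, n_markers = conc$n_markers,
      n_unmapped = conc$n_unmapped,
      mean_spacing = if (is.null(spacing)) NA else spacing$mean_spacing,
      sd_spacing = if (is.null(spacing)) NA else spacing$sd_spacing,
      max_desert = if (is.null(spacing)) NULL else spacing$max_desert)
    written <- c(written, outfile("rank_pairs.tsv"))
  }

  report$files <- lapply(stats::setNames(written, basename(written)),
                         function(f) unname(tools::md5sum(f)))
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}
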