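# End-to-end drivers: the in-memory analysis (detect -> annotate ->
# associate -> filter -> family -> rank) and the file-based pipeline with
# its run manifest.

#' Run the full hotspot analysis on in-memory inputs
#'
#' Executes detection, annotation, expression association, retention
#' filtering, peak-family grouping, and ranking in one call. This is the
#' computational core of [run_pipeline()], usable directly on objects such
#' as those produced by [simulate_cohort()].
#'
#' @param svs SV tibble ([read_bedpe()]).
#' @param genes Gene intervals ([read_bed()]).
#' @param expr Expression matrix ([read_expression()]).
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param cn_segments Optional copy-number segments.
#' @param elements Optional regulatory elements.
#' @param detection,annotation,association,filters Stage configurations.
#' @param alpha_dep Peak-family dependency threshold.
#' @return A list of class `svpeaks_analysis`: `detection` (the
#'   [detect_hotspots()] result), `peaks` (annotated peaks),
#'   `associations` (all tested pairs), `retained` (pairs surviving the
#'   filters), `families`, and `report` (ranked retained pairs).
#' @export
analyze_cohort <- function(svs, genes, expr, chrom_lengths,
                           cn_segments = NULL, elements = NULL,
                           detection = detection_config(),
                           annotation = annotation_config(),
                           association = association_config(),
                           filters = filter_config(),
                           alpha_dep = 0.05) {
  check_chrom_vocabulary(svs = svs, genes = genes, cn = cn_segments)
  det <- detect_hotspots(svs, chrom_lengths, detection)
  ann <- annotate_peaks(det$peaks, genes, elements, annotation)
  assoc <- associate_peaks(ann, expr, cn_segments, association)
  retained <- apply_filters(ann, assoc, filters)
  fams <- build_families(retained, ann, cohort = colnames(expr),
                         alpha_dep = alpha_dep)
  report <- rank_peaks(retained)
  structure(
    list(detection = det, peaks = ann, associations = assoc,
         retained = retained, families = fams, report = report),
    class = "svpeaks_analysis"
  )
}

#' @export
print.svpeaks_analysis <- function(x, ...) {
  cat(sprintf(paste0(
    "SV hotspot analysis: %d peak(s), %d (peak, gene) pair(s) tested, ",
    "%d retained, %d famil(ies)\n"),
    nrow(x$peaks), nrow(x$associations), nrow(x$retained),
    nrow(x$families)))
  invisible(x)
}

.read_chrom_lengths <- function(path) {
  dat <- .read_data_lines(path)
  fields <- strsplit(dat$lines, "\t", fixed = TRUE)
  setNames(vapply(fields, function(f) as.numeric(f[[2]]), 0),
           vapply(fields, `[[`, "", 1L))
}

# chromosome lengths inferred from the data when no file is given: the
# largest coordinate seen per chromosome, rounded up to a step boundary
.infer_chrom_lengths <- function(svs, genes, step) {
  pos <- bind_rows(
    tibble(chrom = svs$chrom1, end = pmax(svs$end1, svs$end2)),
    tibble(chrom = svs$chrom2, end = svs$end2),
    tibble(chrom = genes$chrom, end = genes$end)
  )
  out <- vapply(split(pos$end, pos$chrom), max, 0)
  ceiling(out / step) * step
}

#' Run the file-based hotspot pipeline
#'
#' Reads all inputs, runs [analyze_cohort()], and writes the complete
#' output set: final report, peaks BED, annotated-peaks TSV, per-pair
#' association TSV, families TSV, per-chromosome UCSC custom tracks,
#' BedGraph count tracks, optional figures, and a machine-readable JSON
#' manifest recording inputs, parameters, and per-stage record counts. The
#' run is deterministic for fixed inputs.
#'
#' @param config A named list (or path to a YAML file) with entries:
#'   `sv_bedpe`, `genes_bed`, `expression_tsv` (required); `cn_tsv`,
#'   `elements_bed`, `census_file`, `chrom_lengths_tsv` (optional paths);
#'   `out_dir` (required); `make_plots` (logical, default `FALSE`);
#'   `top_n_plots` (default 3); plus any parameter accepted by
#'   [detection_config()], [annotation_config()], [association_config()],
#'   [filter_config()], and `alpha_dep`.
#' @return Invisibly, the `svpeaks_analysis` with elements `out_dir` and
#'   `manifest` attached.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading a YAML config requires the yaml package", call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  required <- c("sv_bedpe", "genes_bed", "expression_tsv", "out_dir")
  miss <- setdiff(required, names(config))
  if (length(miss)) {
    stop("missing config entries: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  paths <- c("sv_bedpe", "genes_bed", "expression_tsv", "cn_tsv",
             "elements_bed", "census_file", "chrom_lengths_tsv")
  for (p in intersect(paths, names(config))) {
    if (!is.null(config[[p]]) && !file.exists(config[[p]])) {
      stop("missing input: ", p, " (", config[[p]], ")", call. = FALSE)
    }
  }
  take <- function(fun, extra = list()) {
    args <- config[intersect(names(config), names(formals(fun)))]
    do.call(fun, c(args, extra))
  }
  detection <- take(detection_config)
  annotation <- take(annotation_config)
  filters_extra <- list()
  if (!is.null(config$census_file)) {
    filters_extra$census_genes <- readLines(config$census_file, warn = FALSE)
    filters_extra$census_genes <-
      trimws(filters_extra$census_genes[nzchar(filters_extra$census_genes)])
  }
  filters <- take(filter_config, filters_extra)
  association <- take(association_config)

  svs <- read_bedpe(config$sv_bedpe)
  genes <- read_bed(config$genes_bed)
  expr <- read_expression(config$expression_tsv)
  cn <- if (!is.null(config$cn_tsv)) read_cn_segments(config$cn_tsv)
  elements <- if (!is.null(config$elements_bed))
    read_bed(config$elements_bed)
  chrom_lengths <- if (!is.null(config$chrom_lengths_tsv)) {
    .read_chrom_lengths(config$chrom_lengths_tsv)
  } else {
    .infer_chrom_lengths(svs, genes, detection$step_size)
  }

  res <- analyze_cohort(
    svs, genes, expr, chrom_lengths, cn_segments = cn, elements = elements,
    detection = detection, annotation = annotation,
    association = association, filters = filters,
    alpha_dep = config$alpha_dep %||% 0.05
  )

  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_final_report(res$report, file.path(out_dir, "final_report.tsv"))
  write_peaks_bed(res$peaks, file.path(out_dir, "peaks.bed"))
  write_annotated_peaks(res$peaks,
                        tsv_path = file.path(out_dir,
                                             "annotated_peaks.tsv"))
  write_association_report(res$associations,
                           file.path(out_dir, "associations.tsv"))
  write_families(res$families, file.path(out_dir, "families.tsv"))
  write_ucsc_tracks(res$peaks, res$detection$tracks,
                    file.path(out_dir, "ucsc_tracks"))
  for (track in res$detection$tracks) {
    write_count_bedgraph(track, file.path(out_dir, "bedgraph"))
  }
  if (isTRUE(config$make_plots)) {
    fig_dir <- file.path(out_dir, "figures")
    dir.create(fig_dir, showWarnings = FALSE)
    plot_genome_summary(res$peaks, chrom_lengths, res$retained,
                        out = file.path(fig_dir, "genome_summary.png"))
    top <- head(unique(res$report$peak_id), config$top_n_plots %||% 3)
    for (pid in top) {
      peak <- res$peaks[res$peaks$peak_id == pid, ]
      plot_region(peak, svs, cn_segments = cn, genes = genes,
                  elements = elements,
                  out = file.path(fig_dir, sprintf("region_%s.png", pid)),
                  chrom_length = chrom_lengths[[peak$chrom]],
                  gain_threshold = association$gain_threshold,
                  loss_threshold = association$loss_threshold)
      pair <- res$report[res$report$peak_id == pid, ][1, ]
      plot_expression_panels(
        peak, pair, expr, cn_segments = cn, cfg = association,
        out = file.path(fig_dir,
                        sprintf("expression_%s_%s.png", pid, pair$gene))
      )
    }
  }

  manifest <- list(
    package = "svpeaks",
    version = as.character(utils::packageVersion("svpeaks")),
    inputs = config[intersect(paths, names(config))],
    parameters = list(
      detection = unclass(detection), annotation = unclass(annotation),
      association = unclass(association),
      filters = unclass(filters)[setdiff(names(filters), "census_genes")],
      n_census_genes = length(filters$census_genes),
      alpha_dep = config$alpha_dep %||% 0.05
    ),
    counts = list(
      n_sv_records = nrow(svs),
      n_sv_samples = res$detection$n_sv_samples,
      n_expression_samples = ncol(expr),
      n_genes_annotation = nrow(genes),
      n_windows = sum(vapply(res$detection$tracks,
                             function(t) length(t$count), 0L)),
      n_peaks = nrow(res$peaks),
      n_pairs_tested = nrow(res$associations),
      n_pairs_retained = nrow(res$retained),
      n_families = nrow(res$families)
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$out_dir <- out_dir
  res$manifest <- manifest
  invisible(res)
}
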