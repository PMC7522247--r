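# Final retention rules, ranking, and browser-track output.

#' Retention-filter parameters
#'
#' The default thresholds reproduce the standard run: peaks smaller than
#' 500 kb (oversized peaks are exempt when associated with a gene on the
#' supplied cancer-census list), present in at least 15% of SV-harboring
#' samples, with a combined-p FDR below 0.05, at least one of the twelve
#' comparisons significant at p < 0.05, and a mean expression above 10 TPM
#' in a group from a significant comparison.
#'
#' @param max_peak_size Maximum peak length in bases.
#' @param census_genes Character vector of cancer-census gene symbols
#'   exempting oversized peaks (none bundled; supply your own list).
#' @param min_pct_samples Minimum recurrence fraction of the merged peak.
#' @param max_fdr FDR threshold on the Fisher-combined p-value.
#' @param min_comparison_p Per-comparison significance threshold.
#' @param min_tpm Mean-expression floor (TPM) for a group in a significant
#'   comparison.
#' @return A validated list of class `filter_config`.
#' @export
filter_config <- function(max_peak_size = 500000, census_genes = character(),
                          min_pct_samples = 0.15, max_fdr = 0.05,
                          min_comparison_p = 0.05, min_tpm = 10) {
  stopifnot(max_peak_size > 0, min_pct_samples > 0, max_fdr > 0,
            min_comparison_p > 0, min_tpm > 0)
  structure(
    list(max_peak_size = max_peak_size, census_genes = census_genes,
         min_pct_samples = min_pct_samples, max_fdr = max_fdr,
         min_comparison_p = min_comparison_p, min_tpm = min_tpm),
    class = "filter_config"
  )
}

#' Apply the final retention rules to (peak, gene) pairs
#'
#' A pair is retained iff (a) the peak is shorter than `max_peak_size` or
#' the gene is on the census list, (b) the peak recurs in at least
#' `min_pct_samples` of SV-harboring samples, (c) its FDR is below
#' `max_fdr`, (d) at least one of the twelve comparisons has a defined
#' p-value below `min_comparison_p`, and (e) some group mean in a
#' significant comparison exceeds `min_tpm`. Filtering is a pure function
#' of the pair set: input order never affects the retained set.
#'
#' @param peaks Peak tibble with `peak_id`, `chrom`, `start`, `end`,
#'   `count`, `pct_samples`.
#' @param associations Association tibble from [associate_peaks()].
#' @param cfg A [filter_config()].
#' @return The retained association rows joined with the peak coordinates
#'   (`chrom,start,end,count,pct_samples` columns added). The attribute
#'   `"rules"` carries the full per-pair logical matrix with columns
#'   `size,recurrence,fdr,comparison_p,expression_level`.
#' @export
apply_filters <- function(peaks, associations, cfg = filter_config()) {
  idx <- match(associations$peak_id, peaks$peak_id)
  if (anyNA(idx)) stop("association references unknown peak id",
                       call. = FALSE)
  len <- peaks$end[idx] - peaks$start[idx]
  rules <- cbind(
    size = len < cfg$max_peak_size |
      associations$gene %in% cfg$census_genes,
    recurrence = peaks$pct_samples[idx] >= cfg$min_pct_samples,
    fdr = !is.na(associations$fdr) & associations$fdr < cfg$max_fdr,
    comparison_p = vapply(associations$comparisons, function(cc) {
      any(cc$p < cfg$min_comparison_p, na.rm = TRUE)
    }, TRUE),
    # vacuously true when nothing is significant (such pairs already fail
    # the comparison-p rule), so each rule reports its own failures
    expression_level = vapply(associations$comparisons, function(cc) {
      sig <- !is.na(cc$p) & cc$p < cfg$min_comparison_p
      !any(sig) ||
        any(sig & (cc$mean_sv > cfg$min_tpm | cc$mean_ctrl > cfg$min_tpm),
            na.rm = TRUE)
    }, TRUE)
  )
  rownames(rules) <- paste(associations$peak_id, associations$gene)
  keep <- rowSums(rules) == ncol(rules)
  out <- associations[keep, , drop = FALSE]
  out$chrom <- peaks$chrom[idx][keep]
  out$start <- peaks$start[idx][keep]
  out$end <- peaks$end[idx][keep]
  out$count <- peaks$count[idx][keep]
  out$pct_samples <- peaks$pct_samples[idx][keep]
  attr(out, "rules") <- rules
  out
}

#' Rank retained peaks and order the report
#'
#' Peaks are ranked by sample count (descending), then by their best FDR
#' (ascending), then by coordinate; pairs are ordered by peak rank and the
#' rank is recorded on every row.
#'
#' @param retained Output of [apply_filters()].
#' @return `retained` ordered by rank with a `rank` column added.
#' @export
rank_peaks <- function(retained) {
  if (!nrow(retained)) {
    retained$rank <- integer()
    return(retained)
  }
  best_fdr <- vapply(split(retained$fdr, retained$peak_id), function(f) {
    if (all(is.na(f))) Inf else min(f, na.rm = TRUE)
  }, 0)
  info <- retained[!duplicated(retained$peak_id),
                   c("peak_id", "count", "chrom", "start")]
  info$best_fdr <- best_fdr[info$peak_id]
  ord <- order(-info$count, info$best_fdr, info$chrom, info$start)
  rank <- setNames(seq_along(ord), info$peak_id[ord])
  retained$rank <- as.integer(rank[retained$peak_id])
  retained[order(retained$rank, retained$fdr, retained$gene), , drop = FALSE]
}

#' Write the final ranked hotspot report
#'
#' One row per retained (peak, gene) pair: rank, peak coordinates and
#' recurrence, all twelve comparison statistics, combined p, FDR, and
#' direction.
#'
#' @param ranked Output of [rank_peaks()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_final_report <- function(ranked, path) {
  wide <- .association_wide(ranked)
  head_cols <- data.frame(
    rank = ranked$rank, chrom = ranked$chrom,
    start = as.integer(ranked$start), end = as.integer(ranked$end),
    count = ranked$count, pct_samples = round(ranked$pct_samples, 6)
  )
  write.table(cbind(head_cols, wide), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write final peaks as BED
#'
#' @param peaks Peak tibble with `peak_id`.
#' @param path Output path.
#' @param track_line Optional UCSC track header.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path, track_line = NULL) {
  write_bed(tibble(chrom = peaks$chrom, start = peaks$start,
                   end = peaks$end, name = peaks$peak_id),
            path, track_line = track_line)
}

# BedGraph body for one track: one non-overlapping step-sized bin per
# window start; the value is the count of the window beginning there.
.bedgraph_lines <- function(track, values) {
  keep <- which(values != 0)
  step_end <- pmin(track$windows$start + track$config$step_size,
                   track$windows$end[length(track$count)])
  sprintf("%s\t%d\t%d\t%s", track$chrom,
          as.integer(track$windows$start[keep]),
          as.integer(step_end[keep]),
          format(values[keep], trim = TRUE, scientific = FALSE))
}

#' Write per-window sample-count tracks as BedGraph
#'
#' One file for the overall count plus one per SV type with any non-zero
#' window. Counts are emitted in non-overlapping step-sized bins; each
#' value is the raw sample count of the sliding window starting at the bin.
#'
#' @param track A `window_track` from [count_samples()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Character vector of written paths, invisibly.
#' @export
write_count_bedgraph <- function(track, dir, prefix = "sv_count") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  series <- c(list(total = track$count),
              setNames(lapply(.SV_TYPES, function(t) track$count_by_type[t, ]),
                       .SV_TYPES))
  for (nm in names(series)) {
    if (nm != "total" && all(series[[nm]] == 0)) next
    path <- file.path(dir, sprintf("%s_%s_%s.bedgraph", prefix, track$chrom,
                                   nm))
    writeLines(c(
      sprintf('track type=bedGraph name="%s samples with SV (%s) %s"',
              prefix, nm, track$chrom),
      .bedgraph_lines(track, series[[nm]])
    ), path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Write UCSC genome-browser custom track files, one per chromosome
#'
#' Each file holds a BED block of the final peaks on that chromosome
#' (omitted when the chromosome has none) followed by BedGraph blocks of
#' the overall and per-type sample counts.
#'
#' @param peaks Final peak tibble with `peak_id`.
#' @param tracks Named list of `window_track`s (e.g.
#'   [detect_hotspots()]`$tracks`).
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of written file paths, invisibly.
#' @export
write_ucsc_tracks <- function(peaks, tracks, out_dir) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create directory: ", out_dir,
                                 call. = FALSE)
  paths <- character()
  for (chrom in names(tracks)) {
    track <- tracks[[chrom]]
    lines <- character()
    sel <- which(peaks$chrom == chrom)
    if (length(sel)) {
      lines <- c(
        sprintf('track name="SV hotspots %s" description="merged SV hotspot peaks" visibility=2',
                chrom),
        sprintf("%s\t%d\t%d\t%s", peaks$chrom[sel],
                as.integer(peaks$start[sel]), as.integer(peaks$end[sel]),
                peaks$peak_id[sel])
      )
    }
    series <- c(list(total = track$count),
                setNames(lapply(.SV_TYPES,
                                function(t) track$count_by_type[t, ]),
                         .SV_TYPES))
    for (nm in names(series)) {
      if (nm != "total" && all(series[[nm]] == 0)) next
      lines <- c(lines,
                 sprintf('track type=bedGraph name="SV sample count (%s) %s"',
                         nm, chrom),
                 .bedgraph_lines(track, series[[nm]]))
    }
    path <- file.path(out_dir, sprintf("ucsc_track_%s.txt", chrom))
    writeLines(lines, path)
    paths[chrom] <- path
  }
  invisible(paths)
}
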