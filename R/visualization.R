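# Region multi-track figures, expression panels, and the per-chromosome
# hotspot summary. All numbers rendered in figures are read from the same
# result objects as the tabular reports.

.region_bins <- function(region_start, region_end, n_bins = 200) {
  edges <- seq(region_start, region_end, length.out = n_bins + 1)
  tibble(start = edges[-length(edges)], end = edges[-1],
         mid = (edges[-length(edges)] + edges[-1]) / 2)
}

# fraction (or count) of distinct samples whose intervals overlap each bin
.bin_sample_counts <- function(bins, starts, ends, samples) {
  vapply(seq_len(nrow(bins)), function(i) {
    hit <- starts < bins$end[i] & ends > bins$start[i]
    length(unique(samples[hit]))
  }, 0L)
}

.track_theme <- function() {
  theme_minimal(base_size = 9) +
    theme(panel.grid.minor = element_blank(),
          plot.title = element_text(size = 9, face = "bold"))
}

.peak_bounds <- function(peak) {
  geom_vline(xintercept = c(peak$start, peak$end), linetype = "dashed",
             colour = "grey30")
}

#' Multi-track figure of the genomic context of one hotspot
#'
#' Renders, top to bottom: (1) the per-position fraction of samples with
#' copy-number gain or loss, (2) a per-sample pileup of duplication and
#' deletion segments, (3) the per-position aggregation of samples with
#' DUP/DEL regions, (4) the per-position per-SV-type sample aggregation,
#' (5) an optional coverage track (two-column position/value table, e.g.
#' H3K27ac ChIP-seq signal), and (6) gene and regulatory-element
#' annotation. Peak boundaries are drawn as vertical dashed lines on every
#' track.
#'
#' @param peak One-row peak tibble (annotated or not) with
#'   `chrom,start,end` and optionally `peak_id`.
#' @param svs SV tibble.
#' @param cn_segments Optional copy-number segments.
#' @param genes,elements Optional interval tibbles for the annotation
#'   track.
#' @param coverage Optional data frame with columns `pos`, `value`.
#' @param out Output image path (e.g. `.png` or `.pdf`).
#' @param flank Flank width in bases on each side of the peak; default
#'   twice the peak length (so the region spans five peak lengths).
#' @param chrom_length Optional chromosome length used to clip the region.
#' @param gain_threshold,loss_threshold Copy-number status thresholds for
#'   track 1.
#' @param n_bins Number of aggregation bins across the region.
#' @return Invisibly, a list with `file`, `tracks` (named list of ggplot
#'   objects in rendering order), and `n_tracks`.
#' @export
plot_region <- function(peak, svs, cn_segments = NULL, genes = NULL,
                        elements = NULL, coverage = NULL, out,
                        flank = NULL, chrom_length = NULL,
                        gain_threshold = 2.5, loss_threshold = 1.5,
                        n_bins = 200) {
  chrom <- peak$chrom
  if (is.null(flank)) flank <- 2 * (peak$end - peak$start)
  r0 <- max(0, peak$start - flank)
  r1 <- peak$end + flank
  if (!is.null(chrom_length)) r1 <- min(r1, chrom_length)
  bins <- .region_bins(r0, r1, n_bins)
  tracks <- list()

  # 1. copy-number aggregation
  cn_df <- NULL
  if (!is.null(cn_segments) && nrow(cn_segments)) {
    seg <- cn_segments[cn_segments$chrom == chrom &
                         cn_segments$start < r1 & cn_segments$end > r0, ]
    n_cn <- max(1L, length(unique(cn_segments$sample)))
    if (nrow(seg)) {
      gain <- seg$cn >= gain_threshold
      loss <- seg$cn <= loss_threshold
      cn_df <- bind_rows(
        tibble(pos = bins$mid, status = "gain",
               frac = .bin_sample_counts(bins, seg$start[gain], seg$end[gain],
                                         seg$sample[gain]) / n_cn),
        tibble(pos = bins$mid, status = "loss",
               frac = .bin_sample_counts(bins, seg$start[loss], seg$end[loss],
                                         seg$sample[loss]) / n_cn)
      )
    }
  }
  p_cn <- ggplot(cn_df %||% tibble(pos = double(), frac = double(),
                                   status = character()),
                 aes(x = .data$pos, y = .data$frac, fill = .data$status)) +
    geom_area(position = "identity", alpha = 0.5) +
    scale_fill_manual(values = c(gain = "#c0392b", loss = "#2980b9"),
                      limits = c("gain", "loss"), drop = FALSE) +
    coord_cartesian(xlim = c(r0, r1)) + .peak_bounds(peak) +
    labs(title = "Copy-number alteration (fraction of samples)",
         x = NULL, y = "fraction") + .track_theme()
  tracks$cn_aggregate <- p_cn

  # DUP/DEL region footprints in the window
  reg <- .sv_chrom_intervals(svs, chrom)
  dupdel <- reg[reg$svtype %in% c("DUP", "DEL") &
                  reg$start < r1 & reg$end > r0, ]

  # 2. per-sample pileup
  pile <- dupdel
  pile$y <- as.integer(factor(pile$sample))
  p_pile <- ggplot(pile, aes(x = .data$start, xend = .data$end, y = .data$y,
                             yend = .data$y, colour = .data$svtype)) +
    geom_segment(linewidth = 1.2) +
    scale_colour_manual(values = c(DUP = "#c0392b", DEL = "#2980b9"),
                        limits = c("DUP", "DEL"), drop = FALSE) +
    coord_cartesian(xlim = c(r0, r1)) + .peak_bounds(peak) +
    labs(title = "Duplication/deletion pileup (one row per sample)",
         x = NULL, y = "sample") + .track_theme()
  tracks$dup_del_pileup <- p_pile

  # 3. DUP/DEL aggregation
  agg_dupdel <- bind_rows(lapply(c("DUP", "DEL"), function(t) {
    sel <- dupdel$svtype == t
    tibble(pos = bins$mid, svtype = t,
           n = .bin_sample_counts(bins, dupdel$start[sel], dupdel$end[sel],
                                  dupdel$sample[sel]))
  }))
  p_dd <- ggplot(agg_dupdel, aes(x = .data$pos, y = .data$n,
                                 colour = .data$svtype)) +
    geom_line() +
    scale_colour_manual(values = c(DUP = "#c0392b", DEL = "#2980b9"),
                        limits = c("DUP", "DEL"), drop = FALSE) +
    coord_cartesian(xlim = c(r0, r1)) + .peak_bounds(peak) +
    labs(title = "Duplication/deletion sample aggregation", x = NULL,
         y = "samples") + .track_theme()
  tracks$dup_del_aggregate <- p_dd

  # 4. all SV types
  agg_all <- bind_rows(lapply(.SV_TYPES, function(t) {
    sel <- reg$svtype == t
    tibble(pos = bins$mid, svtype = t,
           n = .bin_sample_counts(bins, reg$start[sel], reg$end[sel],
                                  reg$sample[sel]))
  }))
  p_all <- ggplot(agg_all, aes(x = .data$pos, y = .data$n,
                               colour = .data$svtype)) +
    geom_line() + coord_cartesian(xlim = c(r0, r1)) + .peak_bounds(peak) +
    labs(title = "SV sample aggregation by type", x = NULL, y = "samples") +
    .track_theme()
  tracks$sv_type_aggregate <- p_all

  # 5. optional coverage
  if (!is.null(coverage)) {
    cov <- coverage[coverage[[1]] >= r0 & coverage[[1]] <= r1, ]
    p_cov <- ggplot(tibble(pos = cov[[1]], value = cov[[2]]),
                    aes(x = .data$pos, y = .data$value)) +
      geom_area(fill = "grey40") + coord_cartesian(xlim = c(r0, r1)) +
      .peak_bounds(peak) +
      labs(title = "Coverage", x = NULL, y = "signal") + .track_theme()
    tracks$coverage <- p_cov
  }

  # 6. gene + element annotation
  ann <- list()
  if (!is.null(genes) && nrow(genes)) {
    g <- genes[genes$chrom == chrom & genes$start < r1 & genes$end > r0, ]
    if (nrow(g)) ann$gene <- tibble(start = g$start, end = g$end,
                                    name = g$name, kind = "gene", y = 1)
  }
  if (!is.null(elements) && nrow(elements)) {
    e <- elements[elements$chrom == chrom & elements$start < r1 &
                    elements$end > r0, ]
    if (nrow(e)) ann$element <- tibble(start = e$start, end = e$end,
                                       name = e$name, kind = "element",
                                       y = 2)
  }
  ann_df <- if (length(ann)) bind_rows(ann) else
    tibble(start = double(), end = double(), name = character(),
           kind = character(), y = double())
  p_ann <- ggplot(ann_df, aes(x = .data$start, xend = .data$end,
                              y = .data$y, yend = .data$y,
                              colour = .data$kind)) +
    geom_segment(linewidth = 3) +
    geom_text(aes(x = (.data$start + .data$end) / 2, label = .data$name),
              vjust = -1.2, size = 2.6, show.legend = FALSE) +
    scale_colour_manual(values = c(gene = "#27ae60", element = "#f39c12"),
                        limits = c("gene", "element"), drop = FALSE) +
    coord_cartesian(xlim = c(r0, r1), ylim = c(0.5, 2.8)) +
    .peak_bounds(peak) +
    labs(title = "Genes and regulatory elements", x = chrom, y = NULL) +
    .track_theme() + theme(axis.text.y = element_blank())
  tracks$annotation <- p_ann

  fig <- patchwork::wrap_plots(tracks, ncol = 1)
  ggsave(out, fig, width = 9, height = 1.7 * length(tracks), dpi = 110)
  invisible(list(file = out, tracks = tracks, n_tracks = length(tracks)))
}

.format_p <- function(p) {
  if (is.na(p)) "p = n/a" else sprintf("p = %.3g", p)
}

#' Expression boxplot panels for one (peak, gene) association
#'
#' Three panels: (b) expression in samples with vs without SVs targeting
#' the peak, (c) expression by SV type targeting the peak, and (d)
#' expression grouped by the joint copy-number status of the peak and the
#' gene. Group sizes are annotated, and every printed p-value is read from
#' the supplied association row, so figures and report tables can never
#' disagree.
#'
#' @param peak One-row peak tibble with `samples` and `samples_by_type`.
#' @param association Matching one-row tibble from [associate_peaks()].
#' @param expr Expression matrix.
#' @param cn_segments Optional copy-number segments (used for panel d).
#' @param cfg An [association_config()] for status thresholds.
#' @param out Output image path.
#' @return Invisibly, a list with `file`, `panels` (named ggplots), and
#'   `printed_p` (named character vector of every p annotation).
#' @export
plot_expression_panels <- function(peak, association, expr,
                                   cn_segments = NULL,
                                   cfg = association_config(), out) {
  gene <- association$gene
  samples <- colnames(expr)
  vals <- setNames(expr[gene, ], samples)
  comps <- association$comparisons[[1]]
  slot_p <- function(type, stratum) {
    comps$p[comps$svtype == type & comps$stratum == stratum]
  }
  in_peak <- samples %in% peak$samples[[1]]
  printed <- character()

  df_b <- tibble(tpm = vals,
                 group = ifelse(in_peak, "SV", "no SV"))
  lab_b <- sprintf("%s (n=%d vs n=%d)", .format_p(slot_p("all_sv", "all")),
                   sum(in_peak), sum(!in_peak))
  printed["all_sv"] <- .format_p(slot_p("all_sv", "all"))
  p_b <- ggplot(df_b, aes(x = .data$group, y = .data$tpm,
                          fill = .data$group)) +
    geom_boxplot(show.legend = FALSE) +
    labs(title = sprintf("%s expression by SV status", gene),
         subtitle = lab_b, x = NULL, y = "TPM") + .track_theme()

  by_type <- peak$samples_by_type[[1]]
  type_rows <- lapply(names(by_type), function(t) {
    s <- intersect(by_type[[t]], samples)
    if (!length(s)) return(NULL)
    tibble(tpm = vals[s], group = t)
  })
  df_c <- bind_rows(c(type_rows,
                      list(tibble(tpm = vals[!in_peak], group = "no SV"))))
  type_labs <- vapply(names(by_type), function(t) {
    sprintf("%s: %s", t, .format_p(slot_p(t, "all")))
  }, "")
  printed[paste0("type_", names(by_type))] <-
    vapply(names(by_type), function(t) .format_p(slot_p(t, "all")), "")
  p_c <- ggplot(df_c, aes(x = .data$group, y = .data$tpm,
                          fill = .data$group)) +
    geom_boxplot(show.legend = FALSE) +
    labs(title = sprintf("%s expression by SV type", gene),
         subtitle = paste(type_labs, collapse = "   "),
         x = NULL, y = "TPM") + .track_theme()

  gene_cn <- classify_cn_status(
    cn_segments,
    list(chrom = peak$chrom, start = association$gene_start,
         end = association$gene_end),
    samples, cfg$gain_threshold, cfg$loss_threshold
  )
  peak_cn <- classify_cn_status(
    cn_segments, list(chrom = peak$chrom, start = peak$start,
                      end = peak$end),
    samples, cfg$gain_threshold, cfg$loss_threshold
  )
  df_d <- tibble(
    tpm = vals,
    group = paste0("peak:", peak_cn$status, "\ngene:", gene_cn$status)
  )
  counts <- table(df_d$group)
  p_d <- ggplot(df_d, aes(x = .data$group, y = .data$tpm,
                          fill = .data$group)) +
    geom_boxplot(show.legend = FALSE) +
    labs(title = sprintf("%s expression by copy-number status", gene),
         subtitle = paste(sprintf("%s n=%d", gsub("\n", " ", names(counts)),
                                  as.integer(counts)), collapse = "   "),
         x = NULL, y = "TPM") + .track_theme() +
    theme(axis.text.x = element_text(size = 6))

  panels <- list(sv_status = p_b, sv_type = p_c, cn_status = p_d)
  fig <- patchwork::wrap_plots(panels, nrow = 1)
  ggsave(out, fig, width = 11, height = 3.6, dpi = 110)
  invisible(list(file = out, panels = panels, printed_p = printed))
}

#' Per-chromosome summary of hotspot and associated-gene counts
#'
#' Bar chart of the number of hotspots and the number of distinct
#' associated genes per chromosome, with genome-wide totals in the title.
#'
#' @param peaks Final peak tibble.
#' @param chrom_lengths Named vector of chromosome lengths (defines the
#'   chromosome order, including chromosomes with zero peaks).
#' @param associations Optional retained association tibble used for the
#'   gene counts.
#' @param out Output image path.
#' @return Invisibly, a list with `file` and the per-chromosome `data`.
#' @export
plot_genome_summary <- function(peaks, chrom_lengths, associations = NULL,
                                out) {
  chroms <- names(chrom_lengths)
  n_peaks <- vapply(chroms, function(ch) sum(peaks$chrom == ch), 0L)
  n_genes <- vapply(chroms, function(ch) {
    if (is.null(associations) || !nrow(associations)) return(0L)
    length(unique(associations$gene[associations$chrom == ch]))
  }, 0L)
  df <- bind_rows(
    tibble(chrom = chroms, what = "hotspots", n = n_peaks),
    tibble(chrom = chroms, what = "associated genes", n = n_genes)
  )
  df$chrom <- factor(df$chrom, levels = chroms)
  p <- ggplot(df, aes(x = .data$chrom, y = .data$n, fill = .data$what)) +
    geom_col(position = "dodge") +
    labs(title = sprintf("%d hotspot(s), %d associated gene(s)",
                         sum(n_peaks), sum(n_genes)),
         x = NULL, y = "count", fill = NULL) + .track_theme()
  ggsave(out, p, width = 7, height = 3.5, dpi = 110)
  invisible(list(file = out, data = df))
}
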