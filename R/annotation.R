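# Peak annotation: nearby genes and overlapping regulatory elements.

#' Annotation parameters
#'
#' @param gene_flank Distance in bases within which a gene counts as
#'   "nearby" a peak (measured between closest interval edges; overlapping
#'   genes have distance 0). The 1-Mb default is wide enough to capture
#'   regulatory hotspots acting on genes several hundred kb away, such as
#'   enhancer loci ~625 kb from their target gene.
#' @return A validated list of class `annotation_config`.
#' @export
annotation_config <- function(gene_flank = 1e6) {
  stopifnot(gene_flank >= 0)
  structure(list(gene_flank = gene_flank), class = "annotation_config")
}

# IRanges on 0-based half-open coordinates: shift start by +1 to the 1-based
# closed convention IRanges uses. Adjacent half-open intervals then have
# IRanges distance 0, matching edge-to-edge distance with overlap = 0.
.as_iranges <- function(start, end) IRanges::IRanges(start + 1, end)

#' Annotate peaks with nearby genes and overlapping regulatory elements
#'
#' Genes within `gene_flank` of either peak edge (or overlapping the peak)
#' are attached as nearby genes, ordered by distance then coordinate;
#' overlapping genes are the subset at distance 0 that intersect the peak.
#' Regulatory elements are attached only when they intersect the peak.
#' Interval arithmetic uses half-open semantics throughout; strand is
#' ignored.
#'
#' @param peaks Peak tibble (from [detect_hotspots()]`$peaks` or
#'   [merge_peaks()]).
#' @param genes Gene intervals as returned by [read_bed()].
#' @param elements Optional regulatory element intervals ([read_bed()]).
#' @param cfg An [annotation_config()].
#' @return `peaks` with list-columns `nearby_genes` (tibble
#'   `name,start,end,distance` per peak), `overlapping_genes` (character),
#'   and `regulatory_hits` (tibble `name,start,end`).
#' @export
annotate_peaks <- function(peaks, genes, elements = NULL,
                           cfg = annotation_config()) {
  n <- nrow(peaks)
  peaks$nearby_genes <- rep(list(tibble(
    name = character(), start = double(), end = double(), distance = double()
  )), n)
  peaks$overlapping_genes <- rep(list(character()), n)
  peaks$regulatory_hits <- rep(list(tibble(
    name = character(), start = double(), end = double()
  )), n)
  if (!n) return(peaks)
  for (chrom in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == chrom)
    pr <- .as_iranges(peaks$start[pi], peaks$end[pi])
    gi <- which(genes$chrom == chrom)
    if (length(gi)) {
      gr <- .as_iranges(genes$start[gi], genes$end[gi])
      hits <- IRanges::findOverlaps(pr, gr, maxgap = cfg$gene_flank)
      qh <- S4Vectors::queryHits(hits)
      sh <- S4Vectors::subjectHits(hits)
      dist <- IRanges::distance(pr[qh], gr[sh])
      overlap <- genes$start[gi][sh] < peaks$end[pi][qh] &
        peaks$start[pi][qh] < genes$end[gi][sh]
      for (q in unique(qh)) {
        sel <- which(qh == q)
        g <- gi[sh[sel]]
        ord <- order(dist[sel], genes$start[g])
        peaks$nearby_genes[[pi[q]]] <- tibble(
          name = genes$name[g][ord],
          start = genes$start[g][ord],
          end = genes$end[g][ord],
          distance = as.double(dist[sel][ord])
        )
        peaks$overlapping_genes[[pi[q]]] <- genes$name[g][ord][overlap[sel][ord]]
      }
    }
    if (!is.null(elements) && nrow(elements)) {
      ei <- which(elements$chrom == chrom)
      if (length(ei)) {
        er <- .as_iranges(elements$start[ei], elements$end[ei])
        hits <- IRanges::findOverlaps(pr, er) # maxgap 0 => true intersection
        qh <- S4Vectors::queryHits(hits)
        sh <- S4Vectors::subjectHits(hits)
        # drop edge-adjacent pairs (half-open intervals that merely touch)
        touch <- !(elements$start[ei][sh] < peaks$end[pi][qh] &
                     peaks$start[pi][qh] < elements$end[ei][sh])
        qh <- qh[!touch]; sh <- sh[!touch]
        for (q in unique(qh)) {
          e <- ei[sh[qh == q]]
          e <- e[order(elements$start[e])]
          peaks$regulatory_hits[[pi[q]]] <- tibble(
            name = elements$name[e],
            start = elements$start[e],
            end = elements$end[e]
          )
        }
      }
    }
  }
  peaks
}

#' Write annotated peaks to BED and TSV
#'
#' The BED file carries `chrom,start,end,peak_id`; the TSV additionally
#' lists pipe-joined nearby genes, overlapping genes, and regulatory
#' elements per peak.
#'
#' @param annotated Output of [annotate_peaks()] (with a `peak_id` column).
#' @param bed_path,tsv_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the written paths.
#' @export
write_annotated_peaks <- function(annotated, bed_path = NULL,
                                  tsv_path = NULL) {
  if (!is.null(bed_path)) {
    write_bed(tibble(chrom = annotated$chrom, start = annotated$start,
                     end = annotated$end, name = annotated$peak_id),
              bed_path)
  }
  if (!is.null(tsv_path)) {
    join <- function(x) if (length(x)) paste(x, collapse = "|") else "."
    df <- data.frame(
      peak_id = annotated$peak_id,
      chrom = annotated$chrom,
      start = as.integer(annotated$start),
      end = as.integer(annotated$end),
      count = annotated$count,
      pct_samples = round(annotated$pct_samples, 6),
      nearby_genes = vapply(annotated$nearby_genes,
                            function(g) join(g$name), ""),
      overlapping_genes = vapply(annotated$overlapping_genes, join, ""),
      regulatory_elements = vapply(annotated$regulatory_hits,
                                   function(e) join(e$name), "")
    )
    write.table(df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(c(bed = bed_path, tsv = tsv_path))
}
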