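# Peak families: grouping peaks associated with the same gene whose
# SV-harboring sample sets overlap more than chance.

#' One-sided dependency test between two peaks' sample sets
#'
#' Tests whether the overlap between the samples supporting two peaks is
#' larger than expected by chance, via the one-sided (enrichment) Fisher's
#' exact test on the 2x2 table \[in both, A only; B only, neither\] — the
#' hypergeometric upper tail of the observed overlap.
#'
#' @param samples_a,samples_b Character vectors of sample identifiers
#'   (subsets of `cohort`).
#' @param cohort Character vector of all cohort samples.
#' @return The one-sided p-value.
#' @export
test_dependency <- function(samples_a, samples_b, cohort) {
  cohort <- unique(cohort)
  n <- length(cohort)
  if (n == 0L) stop("empty cohort", call. = FALSE)
  a <- unique(intersect(samples_a, cohort))
  b <- unique(intersect(samples_b, cohort))
  x <- length(intersect(a, b))
  phyper(x - 1, length(a), n - length(a), length(b), lower.tail = FALSE)
}

# connected components of an undirected graph on nodes 1..n (union-find)
.components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (e in edges) parent[find(e[1])] <- find(e[2])
  vapply(seq_len(n), find, 0L)
}

#' Group dependent peaks associated with the same gene into families
#'
#' For each gene, peaks among the supplied (already filtered) associations
#' are pairwise tested for sample-set dependency; edges with
#' `p < alpha_dep` are drawn and connected components of two or more peaks
#' become families (transitive closure yields a well-defined partition).
#' The representative is the member with the highest sample count, ties
#' breaking to the leftmost coordinate. Singleton peaks remain standalone
#' and are not reported as families.
#'
#' @param associations Association tibble (typically the retained pairs
#'   from [apply_filters()]) with columns `peak_id`, `gene`.
#' @param peaks Peak tibble carrying `peak_id`, `chrom`, `start`, `count`,
#'   `samples`.
#' @param cohort Character vector of all cohort samples.
#' @param alpha_dep Dependency significance threshold (unadjusted).
#' @return A tibble `gene, members (list), representative, n_members`.
#' @export
build_families <- function(associations, peaks, cohort, alpha_dep = 0.05) {
  empty <- tibble(gene = character(), members = list(),
                  representative = character(), n_members = integer())
  if (!nrow(associations)) return(empty)
  out <- list()
  for (gene in unique(associations$gene)) {
    ids <- unique(associations$peak_id[associations$gene == gene])
    if (length(ids) < 2L) next
    rows <- match(ids, peaks$peak_id)
    ord <- order(peaks$chrom[rows], peaks$start[rows])
    ids <- ids[ord]; rows <- rows[ord]
    m <- length(ids)
    edges <- list()
    for (i in seq_len(m - 1L)) {
      for (j in seq(i + 1L, m)) {
        p <- test_dependency(peaks$samples[[rows[i]]],
                             peaks$samples[[rows[j]]], cohort)
        if (p < alpha_dep) edges[[length(edges) + 1L]] <- c(i, j)
      }
    }
    comp <- .components(m, edges)
    for (cid in unique(comp)) {
      member <- which(comp == cid)
      if (length(member) < 2L) next
      rep_i <- member[order(-peaks$count[rows[member]],
                            peaks$start[rows[member]])][1]
      out[[length(out) + 1L]] <- tibble(
        gene = gene, members = list(ids[member]),
        representative = ids[rep_i], n_members = length(member)
      )
    }
  }
  if (!length(out)) return(empty)
  bind_rows(out)
}

#' Write peak families to TSV
#'
#' @param families Output of [build_families()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_families <- function(families, path) {
  df <- data.frame(
    gene = families$gene,
    members = vapply(families$members, paste, "", collapse = "|"),
    representative = families$representative,
    n_members = families$n_members
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
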