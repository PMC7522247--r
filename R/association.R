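# Expression association: the twelve-comparison battery per (peak, gene)
# pair, Fisher's combined probability, and Benjamini-Hochberg FDR control
# across pairs.

#' Association-testing parameters
#'
#' @param test Two-group test for expression comparisons: Wilcoxon rank-sum
#'   (default) or Welch t-test.
#' @param min_group Minimum samples per group for a comparison's p-value to
#'   be defined; smaller groups still report sizes and means.
#' @param gain_threshold,loss_threshold Copy-number thresholds on the scale
#'   of the input segments: a sample is a gain at gene-level copy number
#'   `>= gain_threshold` and a loss at `<= loss_threshold`. Defaults 2.5 /
#'   1.5 suit linear copy number (diploid = 2); pass `0.3` / `-0.3` for
#'   log2-ratio segments.
#' @return A validated list of class `association_config`.
#' @export
association_config <- function(test = c("wilcoxon", "ttest"), min_group = 3,
                               gain_threshold = 2.5, loss_threshold = 1.5) {
  test <- match.arg(test)
  stopifnot(min_group >= 1, gain_threshold > loss_threshold)
  structure(list(test = test, min_group = as.integer(min_group),
                 gain_threshold = gain_threshold,
                 loss_threshold = loss_threshold),
            class = "association_config")
}

#' Classify per-sample copy-number status of a gene
#'
#' A sample's gene-level copy number is the length-weighted mean of its
#' segments overlapping the gene body; status is `gain` at
#' `>= gain_threshold`, `loss` at `<= loss_threshold`, otherwise `neutral`.
#' Samples with no overlapping segment are treated as neutral (no evidence
#' of alteration).
#'
#' @param segments Copy-number segment tibble ([read_cn_segments()]), or
#'   `NULL` for an all-neutral cohort.
#' @param gene A one-row list/tibble with `chrom`, `start`, `end`.
#' @param samples Character vector of sample identifiers to classify.
#' @param gain_threshold,loss_threshold See [association_config()].
#' @return A tibble `sample, cn, status` with exactly one row per sample
#'   (`cn` is `NA` for samples without overlapping segments).
#' @export
classify_cn_status <- function(segments, gene, samples,
                               gain_threshold = 2.5, loss_threshold = 1.5) {
  stopifnot(gain_threshold > loss_threshold)
  out <- tibble(sample = samples, cn = NA_real_,
                status = rep("neutral", length(samples)))
  if (is.null(segments) || !nrow(segments)) return(out)
  hit <- segments$chrom == gene$chrom & segments$start < gene$end &
    segments$end > gene$start
  if (!any(hit)) return(out)
  seg <- segments[hit, , drop = FALSE]
  w <- pmin(seg$end, gene$end) - pmax(seg$start, gene$start)
  cn <- vapply(split(seq_len(nrow(seg)), seg$sample), function(i) {
    sum(seg$cn[i] * w[i]) / sum(w[i])
  }, 0)
  idx <- match(names(cn), out$sample)
  ok <- !is.na(idx)
  out$cn[idx[ok]] <- cn[ok]
  out$status[idx[ok]] <- ifelse(cn[ok] >= gain_threshold, "gain",
                                ifelse(cn[ok] <= loss_threshold, "loss",
                                       "neutral"))
  out
}

#' Compare expression between two sample groups
#'
#' Two-sided Wilcoxon rank-sum (exact null when the pooled size is <= 20
#' and tie-free, normal approximation with tie/continuity correction
#' otherwise) or Welch t-test. When either group is smaller than
#' `min_group` the p-value is undefined but sizes and means are still
#' reported.
#'
#' @param a,b Numeric TPM vectors for the SV and control groups.
#' @param test `"wilcoxon"` or `"ttest"`.
#' @param min_group Minimum per-group size for a defined p-value.
#' @return A list `n_a, n_b, mean_a, mean_b, p` (`p` is `NA` when
#'   undefined).
#' @export
compare_groups <- function(a, b, test = c("wilcoxon", "ttest"),
                           min_group = 3) {
  test <- match.arg(test)
  res <- list(
    n_a = length(a), n_b = length(b),
    mean_a = if (length(a)) mean(a) else NA_real_,
    mean_b = if (length(b)) mean(b) else NA_real_,
    p = NA_real_
  )
  if (length(a) < min_group || length(b) < min_group) return(res)
  p <- tryCatch({
    if (test == "wilcoxon") {
      exact <- (length(a) + length(b)) <= 20 && !anyDuplicated(c(a, b))
      suppressWarnings(wilcox.test(a, b, exact = exact,
                                   correct = TRUE)$p.value)
    } else {
      suppressWarnings(t.test(a, b)$p.value)
    }
  }, error = function(e) NA_real_)
  # degenerate tests (all values tied) carry no evidence against the null
  if (is.nan(p)) p <- 1
  res$p <- p
  res
}

.comparison_grid <- function() {
  expand.grid(svtype = c("all_sv", .SV_TYPES),
              stratum = c("all", "cn_neutral"),
              stringsAsFactors = FALSE)
}

#' Run the twelve-comparison battery for one peak-gene pair
#'
#' Six SV groupings (any SV plus each of the five types targeting the
#' peak) are each compared against the samples without any SV targeting the
#' peak, once over all samples and once restricted to samples copy-neutral
#' for the gene. Exactly twelve slots are always emitted; slots with groups
#' below `min_group` carry undefined p-values.
#'
#' @param peak_samples Character vector of samples with any SV targeting
#'   the peak.
#' @param samples_by_type Named list (by SV type) of samples targeting the
#'   peak with that type.
#' @param gene_expr Named numeric vector of the gene's expression (TPM) per
#'   sample; its names define the cohort tested.
#' @param cn_status Tibble from [classify_cn_status()] for this gene, or
#'   `NULL` for an all-neutral cohort.
#' @param cfg An [association_config()].
#' @return A 12-row tibble `svtype, stratum, n_sv, n_ctrl, mean_sv,
#'   mean_ctrl, p`.
#' @export
run_comparison_battery <- function(peak_samples, samples_by_type, gene_expr,
                                   cn_status = NULL,
                                   cfg = association_config()) {
  samples <- names(gene_expr)
  sv_all <- intersect(samples, peak_samples)
  ctrl <- setdiff(samples, peak_samples)
  neutral <- if (is.null(cn_status)) samples else
    cn_status$sample[cn_status$status == "neutral"]
  grid <- .comparison_grid()
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    grp <- if (grid$svtype[i] == "all_sv") sv_all else
      intersect(samples, samples_by_type[[grid$svtype[i]]] %||% character())
    ctl <- ctrl
    if (grid$stratum[i] == "cn_neutral") {
      grp <- intersect(grp, neutral)
      ctl <- intersect(ctl, neutral)
    }
    cmp <- compare_groups(gene_expr[grp], gene_expr[ctl],
                          test = cfg$test, min_group = cfg$min_group)
    tibble(svtype = grid$svtype[i], stratum = grid$stratum[i],
           n_sv = cmp$n_a, n_ctrl = cmp$n_b,
           mean_sv = cmp$mean_a, mean_ctrl = cmp$mean_b, p = cmp$p)
  })
  bind_rows(rows)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Combine p-values with Fisher's method
#'
#' Computes `X^2 = -2 * sum(log(p))` and refers it to a chi-square
#' distribution with `2 * length(p)` degrees of freedom. Undefined
#' (`NA`) entries are dropped, so the degrees of freedom adapt to the
#' number of defined comparisons; zero p-values are clamped to the smallest
#' positive double with a warning.
#'
#' @param p Numeric vector of p-values in `(0, 1]` (NAs allowed, dropped).
#' @return The combined p-value (scalar), with attributes `statistic` and
#'   `df`; `NA` when no p-value is defined.
#' @export
fisher_combine <- function(p) {
  p <- p[!is.na(p)]
  if (!length(p)) return(NA_real_)
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]", call. = FALSE)
  if (any(p == 0)) {
    warning("p-value of 0 clamped to smallest positive double")
    p[p == 0] <- .Machine$double.xmin
  }
  stat <- -2 * sum(log(p))
  out <- pchisq(stat, df = 2 * length(p), lower.tail = FALSE)
  attr(out, "statistic") <- stat
  attr(out, "df") <- 2 * length(p)
  out
}

#' Benjamini-Hochberg false discovery rate
#'
#' Standard step-up adjustment across all tested (peak, gene) pairs;
#' undefined p-values are excluded from the number of tests and stay
#' undefined.
#'
#' @param p Numeric vector of combined p-values (NAs allowed).
#' @return Vector of BH-adjusted values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Test all (peak, nearby gene) pairs for expression association
#'
#' For every annotated peak and each of its nearby genes present in the
#' expression matrix, runs the twelve-comparison battery, combines defined
#' p-values with Fisher's method, and controls the FDR globally across all
#' pairs with Benjamini-Hochberg. The association direction (up/down) is
#' taken from the group means of the unstratified any-SV comparison.
#'
#' @param annotated Annotated peak tibble from [annotate_peaks()].
#' @param expr Expression matrix from [read_expression()].
#' @param cn_segments Copy-number segments ([read_cn_segments()]) or `NULL`.
#' @param cfg An [association_config()].
#' @return A tibble with one row per (peak, gene) pair: `peak_id, gene,
#'   gene_start, gene_end, distance, combined_p, fdr, direction,
#'   n_defined`, plus the list-column `comparisons` holding each pair's
#'   12-row battery.
#' @export
associate_peaks <- function(annotated, expr, cn_segments = NULL,
                            cfg = association_config()) {
  empty <- tibble(peak_id = character(), gene = character(),
                  gene_start = double(), gene_end = double(),
                  distance = double(), combined_p = double(),
                  fdr = double(), direction = character(),
                  n_defined = integer(), comparisons = list())
  if (!nrow(annotated)) return(empty)
  samples <- colnames(expr)
  cn_cache <- new.env(parent = emptyenv())
  rows <- list()
  for (i in seq_len(nrow(annotated))) {
    nearby <- annotated$nearby_genes[[i]]
    for (j in seq_len(nrow(nearby))) {
      gene <- nearby$name[j]
      if (!gene %in% rownames(expr)) {
        warning("gene absent from expression matrix, association skipped: ",
                gene, call. = FALSE)
        next
      }
      key <- gene
      if (is.null(cn_cache[[key]])) {
        cn_cache[[key]] <- classify_cn_status(
          cn_segments,
          list(chrom = annotated$chrom[i], start = nearby$start[j],
               end = nearby$end[j]),
          samples, cfg$gain_threshold, cfg$loss_threshold
        )
      }
      comps <- run_comparison_battery(
        annotated$samples[[i]], annotated$samples_by_type[[i]],
        setNames(expr[gene, ], samples), cn_cache[[key]], cfg
      )
      all_sv <- comps[comps$svtype == "all_sv" & comps$stratum == "all", ]
      direction <- if (is.na(all_sv$mean_sv) || is.na(all_sv$mean_ctrl) ||
                       all_sv$mean_sv == all_sv$mean_ctrl) NA_character_
      else if (all_sv$mean_sv > all_sv$mean_ctrl) "up" else "down"
      rows[[length(rows) + 1L]] <- tibble(
        peak_id = annotated$peak_id[i], gene = gene,
        gene_start = nearby$start[j], gene_end = nearby$end[j],
        distance = nearby$distance[j],
        combined_p = as.numeric(fisher_combine(comps$p)),
        fdr = NA_real_, direction = direction,
        n_defined = sum(!is.na(comps$p)),
        comparisons = list(comps)
      )
    }
  }
  if (!length(rows)) return(empty)
  out <- bind_rows(rows)
  out$fdr <- bh_fdr(out$combined_p)
  out
}

# Wide per-pair table: one column per comparison slot for p-values, group
# sizes, and means, used by the report writers.
.association_wide <- function(associations) {
  grid <- .comparison_grid()
  slot <- ifelse(grid$stratum == "all", tolower(grid$svtype),
                 paste0(tolower(grid$svtype), "_cnn"))
  base <- data.frame(
    peak_id = associations$peak_id,
    gene = associations$gene,
    combined_p = associations$combined_p,
    fdr = associations$fdr,
    direction = ifelse(is.na(associations$direction), ".",
                       associations$direction),
    n_defined = associations$n_defined
  )
  for (k in seq_along(slot)) {
    base[[paste0("p_", slot[k])]] <-
      vapply(associations$comparisons, function(cc) cc$p[k], 0)
    base[[paste0("n_sv_", slot[k])]] <-
      vapply(associations$comparisons, function(cc) cc$n_sv[k], 0L)
    base[[paste0("n_ctrl_", slot[k])]] <-
      vapply(associations$comparisons, function(cc) cc$n_ctrl[k], 0L)
    base[[paste0("mean_sv_", slot[k])]] <-
      vapply(associations$comparisons, function(cc) cc$mean_sv[k], 0)
    base[[paste0("mean_ctrl_", slot[k])]] <-
      vapply(associations$comparisons, function(cc) cc$mean_ctrl[k], 0)
  }
  base
}

#' Write the per-pair association table
#'
#' One row per (peak, gene) pair with the twelve comparison p-values, group
#' sizes, group means, the Fisher-combined p, FDR, and direction.
#'
#' @param associations Output of [associate_peaks()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_association_report <- function(associations, path) {
  write.table(.association_wide(associations), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
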