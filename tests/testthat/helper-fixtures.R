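# Small in-code fixtures shared across test files.

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# A window track built directly from a count vector (uniform non-clamped
# windows), with one synthetic sample per counted unit so thresholds and
# sample-set plumbing behave as in real tracks.
make_track <- function(counts, chrom = "chr1", window_size = 100000,
                       step_size = 30000) {
  cfg <- detection_config(window_size = window_size, step_size = step_size)
  n <- length(counts)
  chrom_len <- (n - 1) * step_size + window_size
  windows <- make_windows(chrom_len, cfg)[seq_len(n), ]
  sets <- lapply(seq_len(n), function(i) {
    if (counts[i] > 0) sprintf("w%d_s%03d", i, seq_len(counts[i]))
    else character()
  })
  structure(
    list(chrom = chrom, windows = windows, count = as.integer(counts),
         count_smooth = as.numeric(counts),
         count_by_type = matrix(0L, 5, n, dimnames = list(sv_types(), NULL)),
         sample_sets = sets,
         sample_sets_by_type = lapply(sets, function(s) list(DUP = s)),
         config = cfg),
    class = "window_track"
  )
}

# Candidate-peak tibble from explicit positions/counts, with disjoint
# per-peak sample sets unless sets are supplied.
make_candidates <- function(starts, counts, width = 100000, chrom = "chr1",
                            sets = NULL) {
  n <- length(starts)
  if (is.null(sets)) {
    sets <- lapply(seq_len(n), function(i) sprintf("p%d_s%03d", i,
                                                   seq_len(counts[i])))
  }
  tibble::tibble(
    chrom = chrom, start = starts, end = starts + width,
    count = as.integer(counts), samples = sets,
    samples_by_type = lapply(sets, function(s) list(DUP = s)),
    window = seq_len(n)
  )
}

# Minimal association row (with a hand-built 12-slot battery) for testing
# the retention filters without running the whole pipeline.
make_pair <- function(peak_id, gene, fdr, p_all = 0.01, mean_sv = 50,
                      mean_ctrl = 20) {
  grid <- expand.grid(svtype = c("all_sv", sv_types()),
                      stratum = c("all", "cn_neutral"),
                      stringsAsFactors = FALSE)
  comps <- tibble::tibble(
    svtype = grid$svtype, stratum = grid$stratum,
    n_sv = 10L, n_ctrl = 50L,
    mean_sv = mean_sv, mean_ctrl = mean_ctrl,
    p = ifelse(grid$svtype == "all_sv" & grid$stratum == "all", p_all,
               NA_real_)
  )
  tibble::tibble(
    peak_id = peak_id, gene = gene, gene_start = 0, gene_end = 1000,
    distance = 0, combined_p = p_all, fdr = fdr, direction = "up",
    n_defined = sum(!is.na(comps$p)), comparisons = list(comps)
  )
}

make_peak_row <- function(peak_id, start, end, count = 40, n_cohort = 100,
                          chrom = "chr1", samples = NULL) {
  if (is.null(samples)) samples <- sprintf("S%03d", seq_len(count))
  n_samples <- length(samples)
  sample_col <- list(samples)
  by_type_col <- list(list(DUP = samples))
  tibble::tibble(
    peak_id = peak_id, chrom = chrom, start = start, end = end,
    count = as.integer(n_samples), samples = sample_col,
    samples_by_type = by_type_col,
    n_windows = 1L, pct_samples = n_samples / n_cohort
  )
}

# The reference synthetic cohort used by recovery/power tests.
default_cohort <- function(seed, effect = 2) {
  spec <- simulation_spec(seed = seed)
  spec$hotspots[[1]]$expression_effect <- effect
  simulate_cohort(spec)
}

# Truth helpers for the implanted hotspot.
implant_recovered <- function(res, truth) {
  nrow(res$peaks) == 1 &&
    res$peaks$chrom == truth$chrom &&
    res$peaks$start <= truth$start &&
    res$peaks$end >= truth$end
}

linked_gene_retained <- function(res, truth, max_fdr = 0.05) {
  any(res$retained$gene == truth$linked_gene &
        res$retained$fdr < max_fdr)
}
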