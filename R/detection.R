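# Hotspot detection: sliding-window sample counting, robust local peak
# calling, and the top-peak/k-delta merging walk.

#' Detection parameters
#'
#' Defaults mirror the standard run configuration: 100-kb windows sliding by
#' 30 kb, a 50-kb merge distance, `k = 1` stop-triggering windows and a 5%
#' relative count change for merging, and a 15% candidate recurrence
#' threshold. `stdlim` and `flank_windows` govern the robust local
#' background test used for peak calling (see [call_candidate_peaks()]);
#' `smoothing_span` is the width of the centred moving average applied to
#' window counts before shape detection.
#'
#' @param window_size Sliding window width in bases.
#' @param step_size Step between window starts in bases; must be
#'   `0 < step_size <= window_size`.
#' @param min_pct_samples Candidate threshold: minimum fraction of
#'   SV-harboring samples a window must reach, in `[0, 1]`.
#' @param merge_distance Maximum gap between candidate peaks joined into one
#'   cluster, in bases.
#' @param k Number of consecutive count-change violations (per direction)
#'   that stops the merge walk; `k >= 1`.
#' @param delta Relative sample-count change versus the top peak below which
#'   a neighbouring peak is merged; `delta > 0`.
#' @param stdlim Multiple of the robust spread a window must rise above the
#'   local background to be a peak.
#' @param flank_windows Number of windows per flank used to estimate the
#'   local background; `>= 2`.
#' @param smoothing_span Odd number of windows for count smoothing; 1
#'   disables smoothing.
#' @return A validated list of class `detection_config`.
#' @export
detection_config <- function(window_size = 100000, step_size = 30000,
                             min_pct_samples = 0.15, merge_distance = 50000,
                             k = 1, delta = 0.05, stdlim = 3,
                             flank_windows = 10, smoothing_span = 3) {
  stopifnot(
    step_size > 0, step_size <= window_size,
    min_pct_samples >= 0, min_pct_samples <= 1,
    k >= 1, delta > 0, stdlim > 0, flank_windows >= 2,
    smoothing_span >= 1, smoothing_span %% 2 == 1
  )
  structure(
    list(window_size = window_size, step_size = step_size,
         min_pct_samples = min_pct_samples, merge_distance = merge_distance,
         k = as.integer(k), delta = delta, stdlim = stdlim,
         flank_windows = as.integer(flank_windows),
         smoothing_span = as.integer(smoothing_span)),
    class = "detection_config"
  )
}

#' Sliding windows over a chromosome
#'
#' Window starts are `0, s, 2s, ...` for all starts strictly below the
#' chromosome length; each window ends at `min(start + window_size, length)`.
#'
#' @param chrom_length Chromosome length in bases; `> 0`.
#' @param cfg A [detection_config()].
#' @return A tibble with columns `start`, `end`, one row per window.
#' @export
make_windows <- function(chrom_length, cfg = detection_config()) {
  stopifnot(chrom_length > 0)
  if (chrom_length <= cfg$window_size) {
    # the chromosome fits in one window: nothing to slide over
    return(tibble(start = 0, end = chrom_length))
  }
  n <- ceiling(chrom_length / cfg$step_size)
  start <- (seq_len(n) - 1) * cfg$step_size
  tibble(start = start, end = pmin(start + cfg$window_size, chrom_length))
}

# Per-chromosome footprint intervals of SV records: the full region for
# DUP/DEL (these change the copy number of everything they contain), the
# breakend intervals for INS/INV/BND (these act near their break ends; a
# translocation contributes each breakend on its own chromosome).
.sv_chrom_intervals <- function(svs, chrom) {
  out <- list()
  reg <- svs$svtype %in% c("DUP", "DEL") & svs$chrom1 == chrom
  if (any(reg)) {
    out[[1]] <- tibble(
      sample = svs$sample[reg], svtype = svs$svtype[reg],
      start = pmin(svs$start1[reg], svs$start2[reg]),
      end = pmax(svs$end1[reg], svs$end2[reg])
    )
  }
  bnd <- svs$svtype %in% c("INS", "INV", "BND")
  b1 <- bnd & svs$chrom1 == chrom
  if (any(b1)) {
    out[[length(out) + 1L]] <- tibble(
      sample = svs$sample[b1], svtype = svs$svtype[b1],
      start = svs$start1[b1], end = svs$end1[b1]
    )
  }
  b2 <- bnd & svs$chrom2 == chrom
  if (any(b2)) {
    out[[length(out) + 1L]] <- tibble(
      sample = svs$sample[b2], svtype = svs$svtype[b2],
      start = svs$start2[b2], end = svs$end2[b2]
    )
  }
  if (!length(out)) {
    return(tibble(sample = character(), svtype = character(),
                  start = double(), end = double()))
  }
  iv <- bind_rows(out)
  iv$end <- pmax(iv$end, iv$start + 1) # zero-width breakends cover one base
  iv
}

# Indices (1-based) of the uniform windows overlapping [a, b).
.window_range <- function(a, b, n_win, cfg) {
  s <- cfg$step_size; w <- cfg$window_size
  lo <- floor((a - w) / s) + 1 # smallest i (0-based) with i*s + w > a
  hi <- ceiling(b / s) - 1     # largest i with i*s < b
  lo <- pmax(lo, 0); hi <- pmin(hi, n_win - 1)
  list(lo = lo + 1, hi = hi + 1)
}

#' Count samples harboring SVs per sliding window
#'
#' A sample contributes to every window overlapping the full SV region for
#' duplications and deletions, and to every window overlapping a breakend
#' interval for insertions, inversions, and translocations (each breakend
#' counted on its own chromosome). Each sample is counted at most once per
#' window overall, and at most once per window and SV type.
#'
#' @param svs SV tibble as returned by [read_bedpe()].
#' @param windows Window tibble from [make_windows()] for `chrom`.
#' @param chrom Chromosome name the windows belong to.
#' @param cfg The [detection_config()] used to build `windows`.
#' @return A `window_track` list: `chrom`, `windows`, `count` (raw
#'   samples-with-any-SV per window), `count_by_type` (5 x n matrix),
#'   `sample_sets` and `sample_sets_by_type` (per-window sample identity),
#'   and `count_smooth` (filled by [smooth_counts()], initially the raw
#'   counts).
#' @export
count_samples <- function(svs, windows, chrom, cfg = detection_config()) {
  n_win <- nrow(windows)
  chrom_len <- windows$end[n_win]
  iv <- .sv_chrom_intervals(svs, chrom)
  iv <- iv[iv$start < chrom_len & iv$end > 0, , drop = FALSE]
  if (nrow(iv)) {
    iv$start <- pmax(iv$start, 0)
    iv$end <- pmin(iv$end, chrom_len)
    rng <- .window_range(iv$start, iv$end, n_win, cfg)
    len <- pmax(rng$hi - rng$lo + 1L, 0L)
    keep <- len > 0L
    win <- unlist(lapply(which(keep), function(i) seq(rng$lo[i], rng$hi[i])))
    hits <- unique(data.frame(
      win = win,
      sample = rep(iv$sample[keep], len[keep]),
      svtype = rep(iv$svtype[keep], len[keep]),
      stringsAsFactors = FALSE
    ))
  } else {
    hits <- data.frame(win = integer(), sample = character(),
                       svtype = character())
  }
  tot <- unique(hits[c("win", "sample")])
  count <- tabulate(tot$win, nbins = n_win)
  count_by_type <- matrix(0L, nrow = length(.SV_TYPES), ncol = n_win,
                          dimnames = list(.SV_TYPES, NULL))
  if (nrow(hits)) {
    tab <- table(factor(hits$svtype, levels = .SV_TYPES),
                 factor(hits$win, levels = seq_len(n_win)))
    count_by_type[] <- as.integer(tab)
  }
  sets <- rep(list(character()), n_win)
  sets_by_type <- rep(list(list()), n_win)
  if (nrow(tot)) {
    filled <- split(tot$sample, tot$win)
    sets[as.integer(names(filled))] <- lapply(filled, sort)
    by_type <- split(hits[c("sample", "svtype")], hits$win)
    sets_by_type[as.integer(names(by_type))] <- lapply(by_type, function(d) {
      lapply(split(d$sample, d$svtype), sort)
    })
  }
  structure(
    list(chrom = chrom, windows = windows, count = count,
         count_smooth = as.numeric(count), count_by_type = count_by_type,
         sample_sets = sets, sample_sets_by_type = sets_by_type,
         config = cfg),
    class = "window_track"
  )
}

#' Smooth window counts with a centred moving average
#'
#' Raw counts are retained in `count` for thresholds and reporting; the
#' smoothed series in `count_smooth` is used only for peak-shape detection.
#' The average is truncated at chromosome edges.
#'
#' @param track A `window_track` from [count_samples()].
#' @param cfg A [detection_config()]; `smoothing_span` must be odd.
#' @return The track with `count_smooth` replaced.
#' @export
smooth_counts <- function(track, cfg = detection_config()) {
  x <- as.numeric(track$count)
  h <- (cfg$smoothing_span - 1L) %/% 2L
  n <- length(x)
  if (h == 0L || n == 0L) {
    track$count_smooth <- x
    return(track)
  }
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L); hi <- pmin(i + h, n)
  track$count_smooth <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  track
}

#' Call single-window candidate peaks
#'
#' A window is a candidate when (a) its smoothed count is a strict local
#' maximum relative to the nearest non-tied neighbours (plateaus of tied
#' windows are all eligible), (b) its smoothed count rises at least
#' `stdlim` robust standard deviations above the local background, taken as
#' the median of the `flank_windows` windows on each side with spread
#' `max(MAD, 1)` (the floor avoids zero-variance blow-ups on flat
#' background), and (c) its raw count reaches `min_pct_samples` of the
#' SV-harboring samples in the cohort. Flanks are truncated at chromosome
#' edges.
#'
#' @param track A smoothed `window_track` (see [smooth_counts()]).
#' @param n_sv_samples Number of distinct samples with at least one SV
#'   anywhere in the input (the denominator of the recurrence fraction).
#' @param cfg A [detection_config()].
#' @return A peak tibble (one row per candidate window) with columns
#'   `chrom,start,end,count,samples,samples_by_type,window`.
#' @export
call_candidate_peaks <- function(track, n_sv_samples,
                                 cfg = detection_config()) {
  stopifnot(n_sv_samples >= 1)
  x <- track$count_smooth
  raw <- track$count
  n <- length(x)
  m <- cfg$flank_windows
  keep <- logical(n)
  for (i in seq_len(n)) {
    if (raw[i] < 1L) next
    if (raw[i] / n_sv_samples < cfg$min_pct_samples) next
    # strict local maximum, skipping ties
    j <- i - 1L
    while (j >= 1L && x[j] == x[i]) j <- j - 1L
    if (j >= 1L && x[j] >= x[i]) next
    j <- i + 1L
    while (j <= n && x[j] == x[i]) j <- j + 1L
    if (j <= n && x[j] >= x[i]) next
    flank <- setdiff(seq(max(1L, i - m), min(n, i + m)), i)
    if (length(flank)) {
      bg <- median(x[flank])
      spread <- max(mad(x[flank]), 1)
      if (x[i] < bg + cfg$stdlim * spread) next
    }
    keep[i] <- TRUE
  }
  idx <- which(keep)
  tibble(
    chrom = rep(track$chrom, length(idx)),
    start = track$windows$start[idx],
    end = track$windows$end[idx],
    count = track$count[idx],
    samples = track$sample_sets[idx],
    samples_by_type = track$sample_sets_by_type[idx],
    window = idx
  )
}

.union_by_type <- function(sets) {
  types <- unique(unlist(lapply(sets, names)))
  setNames(lapply(types, function(t) {
    sort(unique(unlist(lapply(sets, function(s) s[[t]]))))
  }), types)
}

#' Merge adjacent candidate peaks into hotspots
#'
#' Candidates are first partitioned into clusters by single-linkage: two
#' contiguous peaks belong to the same cluster when the gap between their
#' intervals is at most `merge_distance`. Within a cluster the unconsumed
#' peak with the highest sample count is taken as the top peak (ties break
#' to the leftmost), and the walk moves outward upstream then downstream
#' over the cluster's unconsumed peaks in coordinate order, merging every
#' peak whose count differs from the top peak's by less than `delta`
#' (relative change) and stopping a direction after `k` consecutive
#' violations. Merged peaks span their constituent windows and pool their
#' sample sets; the process repeats until the cluster is exhausted.
#'
#' When the window `track` is supplied, each merged peak's boundaries are
#' additionally extended outward over adjacent track windows by the same
#' walk — neighbouring windows whose raw counts stay within `delta` of the
#' top peak's count are absorbed until `k` consecutive windows violate the
#' rule — so a hotspot spans its full elevated plateau rather than only the
#' summit windows that qualified as candidates.
#'
#' @param candidates Candidate peak tibble from [call_candidate_peaks()],
#'   sorted by coordinate.
#' @param cfg A [detection_config()].
#' @param track Optional `window_track` the candidates were called from,
#'   enabling the boundary extension described above.
#' @return A peak tibble with columns
#'   `chrom,start,end,count,samples,samples_by_type,n_windows`, sorted by
#'   coordinate. `count` is the size of the pooled sample set.
#' @export
merge_peaks <- function(candidates, cfg = detection_config(), track = NULL) {
  empty <- tibble(chrom = character(), start = double(), end = double(),
                  count = integer(), samples = list(),
                  samples_by_type = list(), n_windows = integer())
  if (!nrow(candidates)) return(empty)
  candidates <- candidates[order(candidates$start), , drop = FALSE]
  gap <- candidates$start[-1] - candidates$end[-nrow(candidates)]
  cluster <- cumsum(c(1, as.integer(gap > cfg$merge_distance)))
  out <- list()
  for (cl in split(seq_len(nrow(candidates)), cluster)) {
    alive <- rep(TRUE, length(cl))
    cnt <- candidates$count[cl]
    while (any(alive)) {
      ai <- which(alive)
      top <- ai[order(-cnt[ai], cl[ai])][1]
      consumed <- top
      alive[top] <- FALSE
      for (side in list(rev(ai[ai < top]), ai[ai > top])) {
        viol <- 0L
        for (p in side) {
          if (abs(cnt[top] - cnt[p]) / cnt[top] < cfg$delta) {
            consumed <- c(consumed, p)
            alive[p] <- FALSE
            viol <- 0L
          } else {
            viol <- viol + 1L
            if (viol >= cfg$k) break
          }
        }
      }
      rows <- cl[consumed]
      peak_start <- min(candidates$start[rows])
      peak_end <- max(candidates$end[rows])
      sample_sets <- candidates$samples[rows]
      type_sets <- candidates$samples_by_type[rows]
      n_windows <- length(rows)
      if (!is.null(track)) {
        win_lo <- min(candidates$window[rows])
        win_hi <- max(candidates$window[rows])
        c_top <- cnt[top]
        for (dir in c(-1L, 1L)) {
          j <- if (dir < 0L) win_lo else win_hi
          viol <- 0L
          repeat {
            j <- j + dir
            if (j < 1L || j > length(track$count)) break
            if (abs(c_top - track$count[j]) / c_top < cfg$delta) {
              if (dir < 0L) win_lo <- j else win_hi <- j
              viol <- 0L
            } else {
              viol <- viol + 1L
              if (viol >= cfg$k) break
            }
          }
        }
        peak_start <- min(peak_start, track$windows$start[win_lo])
        peak_end <- max(peak_end, track$windows$end[win_hi])
        span <- seq(win_lo, win_hi)
        sample_sets <- c(sample_sets, track$sample_sets[span])
        type_sets <- c(type_sets, track$sample_sets_by_type[span])
        n_windows <- length(span)
      }
      samples <- sort(unique(unlist(sample_sets)))
      out[[length(out) + 1L]] <- tibble(
        chrom = candidates$chrom[rows[1]],
        start = peak_start,
        end = peak_end,
        count = length(samples),
        samples = list(samples),
        samples_by_type = list(.union_by_type(type_sets)),
        n_windows = n_windows
      )
    }
  }
  merged <- bind_rows(out)
  merged[order(merged$start), , drop = FALSE]
}

#' Recompute the sample support of merged peaks from the SV calls
#'
#' After merging, a peak's interval can cover positions between its
#' constituent candidate windows; this recomputes, for each peak, the set of
#' samples with an SV footprint (region or breakend, per type semantics)
#' overlapping the merged interval, together with per-type sets and the
#' recurrence fraction.
#'
#' @param peaks Merged peak tibble (columns `chrom,start,end`).
#' @param svs SV tibble.
#' @param n_sv_samples Denominator for `pct_samples`.
#' @return `peaks` with refreshed `samples`, `samples_by_type`, `count`, and
#'   a `pct_samples` column.
#' @export
assign_peak_samples <- function(peaks, svs, n_sv_samples) {
  if (!nrow(peaks)) {
    peaks$pct_samples <- double()
    return(peaks)
  }
  iv_by_chrom <- lapply(
    setNames(nm = unique(peaks$chrom)),
    function(ch) .sv_chrom_intervals(svs, ch)
  )
  for (i in seq_len(nrow(peaks))) {
    iv <- iv_by_chrom[[peaks$chrom[i]]]
    hit <- iv$start < peaks$end[i] & iv$end > peaks$start[i]
    samples <- sort(unique(iv$sample[hit]))
    peaks$samples[[i]] <- samples
    peaks$samples_by_type[[i]] <-
      lapply(split(iv$sample[hit], iv$svtype[hit]), function(s) sort(unique(s)))
    peaks$count[i] <- length(samples)
  }
  peaks$pct_samples <- peaks$count / n_sv_samples
  peaks
}

#' Detect SV hotspots across the genome
#'
#' Runs the full detection stage: builds sliding windows per chromosome,
#' counts SV-harboring samples, smooths, calls candidate peaks, and merges
#' them into final hotspots whose sample sets are then recomputed against
#' the merged intervals.
#'
#' @param svs SV tibble as returned by [read_bedpe()].
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @param cfg A [detection_config()].
#' @return A list of class `svpeaks_detection`: `peaks` (tibble with
#'   `peak_id,chrom,start,end,count,pct_samples,samples,samples_by_type`),
#'   `tracks` (per-chromosome `window_track`s), `n_sv_samples`, and
#'   `config`.
#' @export
detect_hotspots <- function(svs, chrom_lengths, cfg = detection_config()) {
  stopifnot(length(chrom_lengths) > 0, !is.null(names(chrom_lengths)))
  n_sv_samples <- length(unique(svs$sample))
  seen <- unique(c(svs$chrom1, svs$chrom2))
  missing <- setdiff(seen, names(chrom_lengths))
  if (length(missing)) {
    warning(sprintf(
      "%d SV record(s) on chromosome(s) absent from chrom_lengths skipped: %s",
      sum(svs$chrom1 %in% missing | svs$chrom2 %in% missing),
      paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  tracks <- list()
  peak_list <- list()
  for (chrom in names(chrom_lengths)) {
    windows <- make_windows(chrom_lengths[[chrom]], cfg)
    track <- smooth_counts(count_samples(svs, windows, chrom, cfg), cfg)
    tracks[[chrom]] <- track
    if (n_sv_samples > 0) {
      cands <- call_candidate_peaks(track, n_sv_samples, cfg)
      peak_list[[chrom]] <- merge_peaks(cands, cfg, track = track)
    }
  }
  peaks <- bind_rows(peak_list)
  if (nrow(peaks)) {
    peaks <- assign_peak_samples(peaks, svs, n_sv_samples)
    peaks$peak_id <- sprintf("pk%03d", seq_len(nrow(peaks)))
    peaks <- peaks[, c("peak_id", setdiff(names(peaks), "peak_id"))]
  } else {
    peaks <- tibble(peak_id = character(), chrom = character(),
                    start = double(), end = double(), count = integer(),
                    samples = list(), samples_by_type = list(),
                    n_windows = integer(), pct_samples = double())
  }
  structure(
    list(peaks = peaks, tracks = tracks, n_sv_samples = n_sv_samples,
         config = cfg),
    class = "svpeaks_detection"
  )
}

#' @export
print.svpeaks_detection <- function(x, ...) {
  cat(sprintf(
    "SV hotspot detection: %d peak(s) on %d chromosome(s), %d SV sample(s)\n",
    nrow(x$peaks), length(x$tracks), x$n_sv_samples
  ))
  if (nrow(x$peaks)) {
    print(x$peaks[, c("peak_id", "chrom", "start", "end", "count",
                      "pct_samples")], ...)
  }
  invisible(x)
}
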