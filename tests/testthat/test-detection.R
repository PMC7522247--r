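test_that("make_windows tiles chromosomes as forced by the arithmetic", {
  cfg <- detection_config()
  w <- make_windows(250000, cfg)
  expect_equal(nrow(w), 9L)
  expect_equal(w$start, seq(0, 240000, by = 30000))
  expect_equal(w$end[9], 250000)
  expect_equal(w$end[1], 100000)

  cfg_tile <- detection_config(window_size = 100000, step_size = 100000)
  w2 <- make_windows(250000, cfg_tile)
  expect_equal(nrow(w2), ceiling(250000 / 100000))
  expect_true(all(w2$start[-1] == w2$end[-nrow(w2)]))

  w3 <- make_windows(50000, cfg)
  expect_equal(nrow(w3), 1L)
  expect_equal(unlist(w3), c(start = 0, end = 50000))
})

test_that("count_samples uses region semantics for DUP/DEL and breakends otherwise", {
  cfg <- detection_config(window_size = 100000, step_size = 100000)
  windows <- make_windows(300000, cfg)
  del <- tibble::tibble(chrom1 = "chr1", start1 = 50000, end1 = 50001,
                        chrom2 = "chr1", start2 = 249999, end2 = 250000,
                        sample = "S1", svtype = "DEL")
  track <- count_samples(del, windows, "chr1", cfg)
  expect_equal(track$count, c(1L, 1L, 1L))

  bnd <- tibble::tibble(chrom1 = "chr1", start1 = 150000, end1 = 150001,
                        chrom2 = "chr9", start2 = 5, end2 = 6,
                        sample = "S1", svtype = "BND")
  track <- count_samples(bnd, windows, "chr1", cfg)
  expect_equal(track$count, c(0L, 1L, 0L))

  # a sample with two DUPs in the same window still counts once
  dup2 <- tibble::tibble(chrom1 = "chr1", start1 = c(10, 500), end1 = c(11, 501),
                         chrom2 = "chr1", start2 = c(900, 1500),
                         end2 = c(901, 1501),
                         sample = "S1", svtype = "DUP")
  track <- count_samples(dup2, windows, "chr1", cfg)
  expect_equal(track$count, c(1L, 0L, 0L))
  expect_equal(unname(track$count_by_type["DUP", ]), c(1L, 0L, 0L))
  expect_equal(track$sample_sets[[1]], "S1")
})

test_that("count_samples matches brute-force enumeration on random instances", {
  set.seed(101)
  for (trial in 1:25) {
    cfg <- detection_config(
      window_size = sample(c(50000, 100000), 1),
      step_size = sample(c(20000, 30000, 50000), 1)
    )
    windows <- make_windows(1e6, cfg)
    svs <- random_sv_set(20, sprintf("S%d", 1:5), c("chr1", "chr2"), 1e6)
    track <- count_samples(svs, windows, "chr1", cfg)
    oracle <- oracle_count_samples(svs, windows, "chr1")
    expect_equal(track$count, oracle$count)
    expect_equal(track$count_by_type, oracle$count_by_type)
  }
})

test_that("smoothing is a truncated centred moving average", {
  cfg1 <- detection_config(smoothing_span = 1)
  t1 <- smooth_counts(make_track(c(3, 1, 4, 1, 5)), cfg1)
  expect_equal(t1$count_smooth, c(3, 1, 4, 1, 5))

  cfg3 <- detection_config(smoothing_span = 3)
  t2 <- smooth_counts(make_track(rep(7, 6)), cfg3)
  expect_equal(t2$count_smooth, rep(7, 6))

  t3 <- smooth_counts(make_track(c(0, 0, 9, 0, 0)), cfg3)
  expect_equal(t3$count_smooth, c(0, 3, 3, 3, 0))
  expect_equal(t3$count, c(0L, 0L, 9L, 0L, 0L)) # raw counts retained
})

test_that("candidate calling requires local maximum, background rise, and recurrence", {
  cfg <- detection_config(flank_windows = 3, stdlim = 3, smoothing_span = 1)

  # constant counts: no local maxima, no candidates
  flat <- smooth_counts(make_track(rep(5, 9)), cfg)
  expect_equal(nrow(call_candidate_peaks(flat, 100, cfg)), 0L)

  # an isolated spike clears the floor-1 background test: 20 >= 2 + 3*1
  spike <- smooth_counts(make_track(c(2, 2, 2, 20, 2, 2, 2)), cfg)
  cands <- call_candidate_peaks(spike, 100, cfg)
  expect_equal(cands$window, 4L)
  expect_equal(cands$count, 20L)

  # recurrence threshold: 10 of 100 SV samples < 15%
  low <- smooth_counts(make_track(c(2, 2, 2, 10, 2, 2, 2)), cfg)
  expect_equal(nrow(call_candidate_peaks(low, 100, cfg)), 0L)
  # the same spike passes when the cohort is small enough
  expect_equal(nrow(call_candidate_peaks(low, 50, cfg)), 1L)

  # tied plateau windows are all eligible local maxima
  plateau <- smooth_counts(make_track(c(2, 2, 30, 30, 30, 2, 2)), cfg)
  expect_equal(call_candidate_peaks(plateau, 100, cfg)$window, c(3L, 4L, 5L))
})

test_that("increasing the recurrence threshold never adds candidates", {
  set.seed(77)
  counts <- rpois(40, 3) + c(rep(0, 18), 25, 30, 25, rep(0, 19))
  track <- smooth_counts(make_track(counts), detection_config())
  n_prev <- Inf
  for (t in c(0.05, 0.15, 0.25, 0.4)) {
    cfg <- detection_config(min_pct_samples = t)
    n <- nrow(call_candidate_peaks(track, 100, cfg))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("merge walk follows the top-peak / k-delta procedure", {
  # 30-kb gap <= 50 kb and 3.3% count change < 5%: one merged peak
  cands <- make_candidates(c(100000, 230000), c(30, 29))
  merged <- merge_peaks(cands, detection_config())
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$start, 100000)
  expect_equal(merged$end, 330000)
  expect_equal(merged$count, 59L) # disjoint supporting sample sets pool

  # 60-kb gap > 50 kb: two clusters, two peaks
  apart <- make_candidates(c(100000, 260000), c(30, 29))
  expect_equal(nrow(merge_peaks(apart, detection_config())), 2L)

  # 33% change >= 5% with k = 1 stops immediately: two peaks
  jump <- make_candidates(c(100000, 230000), c(30, 20))
  out <- merge_peaks(jump, detection_config())
  expect_equal(nrow(out), 2L)
  expect_equal(out$count, c(30L, 20L))
})

test_that("merging conserves the union of supporting samples per cluster", {
  set.seed(5)
  for (trial in 1:20) {
    n <- sample(2:6, 1)
    starts <- cumsum(c(1e5, sample(c(110000, 130000, 200000), n - 1,
                                   replace = TRUE)))
    cands <- make_candidates(starts, sample(15:40, n, replace = TRUE))
    merged <- merge_peaks(cands, detection_config())
    expect_setequal(unlist(merged$samples), unlist(cands$samples))
  }
})

test_that("increasing the merge distance never increases the cluster count", {
  set.seed(6)
  starts <- cumsum(c(1e5, sample(c(105000, 120000, 160000, 200000), 7,
                                 replace = TRUE)))
  cands <- make_candidates(starts, rep(20, 8))
  n_prev <- Inf
  for (d in c(0, 25000, 50000, 100000)) {
    cfg <- detection_config(merge_distance = d, delta = 1e9)
    # huge delta merges every cluster fully, so peaks == clusters
    n <- nrow(merge_peaks(cands, cfg))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("detection recovers an implanted hotspot end to end", {
  sim <- default_cohort(seed = 424242)
  det <- detect_hotspots(sim$svs, sim$spec$chrom_lengths)
  expect_equal(nrow(det$peaks), 1L)
  expect_lte(det$peaks$start, sim$truth$start)
  expect_gte(det$peaks$end, sim$truth$end)
  # merged sample set recomputed over the interval covers all hit samples
  hits <- strsplit(sim$truth$hit_samples, "|", fixed = TRUE)[[1]]
  expect_true(all(hits %in% det$peaks$samples[[1]]))
  expect_equal(det$n_sv_samples, length(unique(sim$svs$sample)))
})

test_that("SVs on unknown chromosomes are skipped with a warning", {
  svs <- tibble::tibble(
    chrom1 = c("chr1", "chrUn"), start1 = c(100, 5), end1 = c(101, 6),
    chrom2 = c("chr1", "chrUn"), start2 = c(900, 50), end2 = c(901, 51),
    sample = c("S1", "S2"), svtype = "DEL"
  )
  expect_warning(det <- detect_hotspots(svs, c(chr1 = 1e6)), "chrUn")
  expect_equal(sum(det$tracks$chr1$count), 1L)
})
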