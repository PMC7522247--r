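test_that("each retention rule removes exactly the pair engineered to trip it", {
  peaks <- dplyr::bind_rows(
    make_peak_row("pk_ok", 1.0e6, 1.2e6),       # 200 kb, 40%
    make_peak_row("pk_big", 2.0e6, 2.6e6),      # 600 kb: size rule
    make_peak_row("pk_rare", 3.0e6, 3.2e6, samples = sprintf("S%03d", 1:10)),
    make_peak_row("pk_fdr", 4.0e6, 4.2e6),
    make_peak_row("pk_nop", 5.0e6, 5.2e6),
    make_peak_row("pk_dim", 6.0e6, 6.2e6)       # both means 5 TPM
  )
  pairs <- dplyr::bind_rows(
    make_pair("pk_ok", "G_OK", fdr = 0.001),
    make_pair("pk_big", "G_BIG", fdr = 0.001),
    make_pair("pk_rare", "G_RARE", fdr = 0.001),
    make_pair("pk_fdr", "G_FDR", fdr = 0.2),
    make_pair("pk_nop", "G_NOP", fdr = 0.001, p_all = 0.3),
    make_pair("pk_dim", "G_DIM", fdr = 0.001, mean_sv = 5, mean_ctrl = 5)
  )
  cfg <- filter_config()
  kept <- apply_filters(peaks, pairs, cfg)
  expect_equal(kept$gene, "G_OK")
  rules <- attr(kept, "rules")
  # every rule fails exactly one pair
  expect_equal(unname(colSums(!rules)),
               rep(1L, 5L))

  # census membership exempts the oversized peak from the size rule only
  cfg_census <- filter_config(census_genes = "G_BIG")
  kept2 <- apply_filters(peaks, pairs, cfg_census)
  expect_setequal(kept2$gene, c("G_OK", "G_BIG"))
})

test_that("filtering is order-invariant and census removal only shrinks the set", {
  peaks <- dplyr::bind_rows(
    make_peak_row("pk1", 1e6, 1.7e6),
    make_peak_row("pk2", 3e6, 3.2e6)
  )
  pairs <- dplyr::bind_rows(
    make_pair("pk1", "BIGGENE", fdr = 0.01),
    make_pair("pk2", "SMALLGENE", fdr = 0.01)
  )
  cfg <- filter_config(census_genes = "BIGGENE")
  kept <- apply_filters(peaks, pairs, cfg)
  shuffled <- apply_filters(peaks, pairs[2:1, ], cfg)
  expect_setequal(kept$gene, shuffled$gene)
  without <- apply_filters(peaks, pairs, filter_config())
  expect_true(all(without$gene %in% kept$gene))
  expect_lt(nrow(without), nrow(kept))
})

test_that("peaks rank by count, then FDR, then coordinate", {
  peaks <- dplyr::bind_rows(
    make_peak_row("pkA", 1e6, 1.2e6, samples = sprintf("S%03d", 1:40)),
    make_peak_row("pkB", 2e6, 2.2e6, samples = sprintf("S%03d", 1:30)),
    make_peak_row("pkC", 3e6, 3.2e6, samples = sprintf("S%03d", 11:40))
  )
  pairs <- dplyr::bind_rows(
    make_pair("pkA", "G1", fdr = 0.04),
    make_pair("pkB", "G2", fdr = 1e-3),
    make_pair("pkC", "G3", fdr = 1e-6)
  )
  ranked <- rank_peaks(apply_filters(peaks, pairs, filter_config()))
  expect_equal(ranked$peak_id, c("pkA", "pkC", "pkB"))
  expect_equal(ranked$rank, 1:3)

  single <- rank_peaks(apply_filters(peaks[1, ], pairs[1, ],
                                     filter_config()))
  expect_equal(single$rank, 1L)
})

test_that("UCSC custom tracks carry the peak BED block and count tracks", {
  sim <- default_cohort(seed = 515)
  det <- detect_hotspots(sim$svs, sim$spec$chrom_lengths)
  out_dir <- file.path(tempdir(), "ucsc_test")
  paths <- write_ucsc_tracks(det$peaks, det$tracks, out_dir)
  expect_true(file.exists(paths[["chr1"]]))
  blocks <- read_ucsc_track(paths[["chr1"]])
  expect_equal(blocks[[1]]$type, "bed")
  expect_equal(nrow(blocks[[1]]$data), nrow(det$peaks))
  # peak coordinates round-trip exactly
  expect_equal(blocks[[1]]$data$start, det$peaks$start)
  expect_equal(blocks[[1]]$data$end, det$peaks$end)
  types <- vapply(blocks, `[[`, "", "type")
  expect_true(sum(types == "bedGraph") >= 2) # total plus >= 1 SV type

  # a chromosome without peaks gets a counts-only file
  no_peaks <- det$peaks[0, ]
  paths2 <- write_ucsc_tracks(no_peaks, det$tracks,
                              file.path(tempdir(), "ucsc_test2"))
  blocks2 <- read_ucsc_track(paths2[["chr1"]])
  expect_true(all(vapply(blocks2, `[[`, "", "type") == "bedGraph"))
})

test_that("bedgraph count tracks re-parse to the window counts", {
  sim <- default_cohort(seed = 516)
  det <- detect_hotspots(sim$svs, sim$spec$chrom_lengths)
  track <- det$tracks$chr1
  dir <- file.path(tempdir(), "bedgraph_test")
  paths <- write_count_bedgraph(track, dir)
  total <- paths[grepl("_total", paths)]
  parsed <- read_bedgraph(total)
  nonzero <- which(track$count != 0)
  expect_equal(parsed$start, track$windows$start[nonzero])
  expect_equal(parsed$value, as.numeric(track$count[nonzero]))
})
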