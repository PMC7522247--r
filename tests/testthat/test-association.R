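test_that("gene-level copy-number status is a length-weighted mean call", {
  gene <- list(chrom = "chr1", start = 1000, end = 2000)
  seg <- function(s, e, cn, sample = "S1") {
    tibble::tibble(chrom = "chr1", start = s, end = e, sample = sample,
                   cn = cn)
  }
  st <- function(segs) {
    classify_cn_status(segs, gene, "S1", 2.5, 1.5)$status
  }
  expect_equal(st(seg(0, 5000, 2.0)), "neutral")
  expect_equal(st(seg(0, 5000, 4.0)), "gain")
  expect_equal(st(seg(0, 5000, 1.0)), "loss")
  # two half-covering segments, cn 2 and 4 -> weighted mean 3 -> gain
  two <- dplyr::bind_rows(seg(0, 1500, 2.0), seg(1500, 5000, 4.0))
  res <- classify_cn_status(two, gene, "S1", 2.5, 1.5)
  expect_equal(res$cn, 3.0)
  expect_equal(res$status, "gain")
  # absent samples are neutral with unknown cn
  res2 <- classify_cn_status(seg(0, 5000, 4.0), gene, c("S1", "S2"), 2.5, 1.5)
  expect_equal(res2$status, c("gain", "neutral"))
  expect_true(is.na(res2$cn[2]))
})

test_that("two-group comparison handles exact, degenerate, and undefined cases", {
  # fully separated tie-free groups: exact two-sided Wilcoxon p = 0.1
  r <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p, 0.1)
  expect_equal(r$p, oracle_wilcoxon_exact(c(1, 2, 3), c(4, 5, 6)))

  # identical singleton groups carry no evidence
  r1 <- compare_groups(5, 5, min_group = 1)
  expect_equal(r1$p, 1)

  # an empty group leaves p undefined but records sizes and means
  r2 <- compare_groups(numeric(0), c(1, 2, 3))
  expect_equal(r2$n_a, 0L)
  expect_equal(r2$n_b, 3L)
  expect_true(is.na(r2$p))
  expect_true(is.na(r2$mean_a))
  expect_equal(r2$mean_b, 2)

  # groups below min_group are undefined even when non-empty
  expect_true(is.na(compare_groups(c(1, 2), c(3, 4, 5))$p))
})

test_that("exact Wilcoxon matches full enumeration on random tie-free draws", {
  set.seed(11)
  for (trial in 1:20) {
    n_a <- sample(3:5, 1)
    n_b <- sample(3:5, 1)
    pool <- sample.int(1000, n_a + n_b) / 7
    a <- pool[seq_len(n_a)]
    b <- pool[-seq_len(n_a)]
    expect_equal(compare_groups(a, b)$p, oracle_wilcoxon_exact(a, b))
  }
})

test_that("Fisher combination matches the chi-square upper tail", {
  expect_equal(as.numeric(fisher_combine(c(1, 1, 1))), 1)
  # a single p-value passes through unchanged
  expect_equal(as.numeric(fisher_combine(0.037)), 0.037, tolerance = 1e-12)
  # {0.05, 0.05}: X^2 = -4 log(0.05) = 11.9829..., df 4
  res <- fisher_combine(c(0.05, 0.05))
  expect_equal(attr(res, "statistic"), 11.98293, tolerance = 1e-5)
  expect_equal(as.numeric(res), 0.01747866, tolerance = 1e-6)
  set.seed(21)
  for (trial in 1:10) {
    p <- runif(sample(1:6, 1))
    got <- fisher_combine(p)
    expect_equal(as.numeric(got),
                 oracle_chisq_upper(attr(got, "statistic"), 2 * length(p)),
                 tolerance = 1e-8)
  }
  # NAs are dropped and the degrees of freedom adapt
  expect_equal(attr(fisher_combine(c(0.05, NA, 0.05)), "df"), 4)
  expect_true(is.na(fisher_combine(c(NA_real_, NA_real_))))
  expect_warning(out <- fisher_combine(c(0, 0.5)), "clamped")
  expect_gt(as.numeric(out), 0)
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  set.seed(9)
  for (trial in 1:20) {
    p <- runif(sample(1:15, 1))
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p))
    expect_true(all(diff(q[order(p)]) >= -1e-12)) # monotone in sorted order
  }
  # undefined pairs are excluded from m and stay undefined
  q <- bh_fdr(c(0.01, NA, 0.02, 0.03))
  expect_true(is.na(q[2]))
  expect_equal(q[-2], c(0.03, 0.03, 0.03))
})

test_that("the battery always emits 12 slots with sensible group structure", {
  samples <- sprintf("S%02d", 1:30)
  expr <- setNames(rlnorm(30, log(30), 0.5), samples)
  peak_samples <- samples[1:10]
  by_type <- list(DUP = samples[1:10])
  comps <- run_comparison_battery(peak_samples, by_type, expr, NULL)
  expect_equal(nrow(comps), 12L)
  expect_setequal(unique(comps$svtype), c("all_sv", sv_types()))
  # a DUP-only peak defines all_sv and DUP slots; other types are undefined
  defined <- comps[!is.na(comps$p), ]
  expect_setequal(unique(defined$svtype), c("all_sv", "DUP"))
  # with no CN data every sample is neutral: strata coincide
  for (tp in c("all_sv", "DUP")) {
    pair <- comps$p[comps$svtype == tp]
    expect_equal(pair[1], pair[2])
  }
  # groups are disjoint: SV + control sizes sum to the cohort
  expect_equal(comps$n_sv[1] + comps$n_ctrl[1], 30L)

  # all samples CN-altered for the gene: the 6 cn_neutral slots undefined
  cn_all_gain <- tibble::tibble(sample = samples, cn = 4,
                                status = "gain")
  comps2 <- run_comparison_battery(peak_samples, by_type, expr, cn_all_gain)
  expect_true(all(is.na(comps2$p[comps2$stratum == "cn_neutral"])))
  expect_false(all(is.na(comps2$p[comps2$stratum == "all"])))
})

test_that("a DUP-driven effect concentrates in DUP slots, not BND slots", {
  set.seed(2024)
  wins <- 0L
  n_seeds <- 50L
  for (s in seq_len(n_seeds)) {
    spec <- simulation_spec(seed = 9000 + s)
    spec$hotspots <- list(
      hotspot_spec("chr1", 3.44e6, 3.56e6, "DUP", penetrance = 0.25,
                   linked_gene = "GENE10", expression_effect = 2,
                   direction = "up"),
      hotspot_spec("chr1", 3.44e6, 3.56e6, "BND", penetrance = 0.20)
    )
    sim <- simulate_cohort(spec)
    det <- detect_hotspots(sim$svs, spec$chrom_lengths)
    ann <- annotate_peaks(det$peaks, sim$genes)
    assoc <- associate_peaks(ann, sim$expr, sim$cn)
    row <- assoc[assoc$gene == "GENE10", ]
    if (nrow(row) != 1L) next
    comps <- row$comparisons[[1]]
    p_dup <- comps$p[comps$svtype == "DUP" & comps$stratum == "all"]
    p_bnd <- comps$p[comps$svtype == "BND" & comps$stratum == "all"]
    if (!is.na(p_dup) && !is.na(p_bnd) && p_dup < p_bnd) wins <- wins + 1L
  }
  expect_gte(wins / n_seeds, 0.9)
})

test_that("an implanted +2 SD effect at 40% penetrance is recovered at FDR < 0.05", {
  hits <- 0L
  n_seeds <- 50L
  for (s in seq_len(n_seeds)) {
    sim <- default_cohort(seed = 20000 + s)
    res <- analyze_cohort(sim$svs, sim$genes, sim$expr,
                          sim$spec$chrom_lengths, cn_segments = sim$cn)
    if (linked_gene_retained(res, sim$truth)) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.9)
})

test_that("Fisher combination over the battery is only mildly anticonservative under the null", {
  # Mixed-SV-type hotspot (as real hotspots are) with no expression effect:
  # the combined p is a smoke check, not a calibrated test, because the 12
  # comparisons are correlated.
  n_pairs <- 0L
  n_sig <- 0L
  s <- 0L
  while (n_pairs < 200L) {
    s <- s + 1L
    spec <- simulation_spec(seed = 31000 + s)
    spec$hotspots <- list(
      hotspot_spec("chr1", 3.44e6, 3.56e6, "DUP", penetrance = 0.15),
      hotspot_spec("chr1", 3.44e6, 3.56e6, "DEL", penetrance = 0.10),
      hotspot_spec("chr1", 3.44e6, 3.56e6, "INV", penetrance = 0.08),
      hotspot_spec("chr1", 3.44e6, 3.56e6, "BND", penetrance = 0.07)
    )
    sim <- simulate_cohort(spec)
    det <- detect_hotspots(sim$svs, spec$chrom_lengths)
    ann <- annotate_peaks(det$peaks, sim$genes)
    assoc <- associate_peaks(ann, sim$expr, sim$cn)
    ok <- !is.na(assoc$combined_p)
    n_pairs <- n_pairs + sum(ok)
    n_sig <- n_sig + sum(assoc$combined_p[ok] < 0.05)
  }
  expect_lte(n_sig / n_pairs, 0.10)
})

test_that("associations skip genes missing from the expression matrix", {
  peaks <- make_peak_row("pk001", 100000, 200000)
  genes <- tibble::tibble(chrom = "chr1", start = c(150000, 220000),
                          end = c(160000, 230000),
                          name = c("PRESENT", "ABSENT"), strand = "+")
  ann <- annotate_peaks(peaks, genes)
  samples <- sprintf("S%03d", 1:100)
  set.seed(1)
  expr <- matrix(rlnorm(100, log(30), 0.5), nrow = 1,
                 dimnames = list("PRESENT", samples))
  expect_warning(assoc <- associate_peaks(ann, expr), "ABSENT")
  expect_equal(assoc$gene, "PRESENT")
  expect_equal(assoc$fdr, assoc$combined_p) # single pair: BH is identity
})
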