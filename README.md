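# svpeaks

Detection of genomic hotspots recurrently targeted by structural variants
(SVs) in a cancer cohort, and evaluation of their association with the
expression of nearby genes.

## Who this is for

Cancer-genomics groups with cohort-level WGS SV calls (BEDPE), matched
expression (TPM), and optionally copy-number segments, who want an
automated answer to: *which loci are hit by SVs in an unusually large
fraction of patients, and does being hit move the expression of a nearby
gene?* The canonical use case is rediscovering regulatory hotspots such as
tandem-duplicated enhancers acting on a driver gene hundreds of kb away,
alongside classical coding hits (fusions, tumour-suppressor disruption).

## The method

1. **Counting.** Each chromosome is tiled with sliding windows (width
   *w* = 100 kb, step *s* = 30 kb). Per window, count the number of
   distinct samples with an SV targeting it — the full region for DUP/DEL
   (they change the copy number of what they contain), breakend positions
   for INS/INV/BND.
2. **Peak calling.** Window *i* (after a 3-window moving-average smooth)
   is a candidate peak if it is a strict local maximum, rises above the
   local background, *c_i* ≥ median(*F_i*) + λ·max(MAD(*F_i*), 1) over the
   *m* = 10 flanking windows per side (λ = 3), and its raw count reaches
   *t* = 15% of SV-harboring samples.
3. **Merging.** Candidates within *d* = 50 kb cluster together; within a
   cluster, the top peak (highest count) absorbs neighbours whose counts
   differ by less than *delta* = 5%, stopping a direction after *k* = 1
   consecutive violations, and the merged peak's boundaries extend over
   adjacent track windows by the same rule. Repeat until the cluster is
   empty.
4. **Annotation.** Peaks gain genes within 1 Mb and intersecting
   regulatory elements.
5. **Association.** For each (peak, nearby gene) pair, 12 comparisons
   (any-SV + 5 per-type groups, each vs samples without hotspot SVs;
   unstratified and restricted to gene-copy-neutral samples) with Wilcoxon
   rank-sum (or *t*) tests; Fisher's combination
   X² = −2 Σ log *p* ~ χ²(2k) over defined comparisons;
   Benjamini–Hochberg FDR across all pairs.
6. **Families, filters, ranking.** Peaks on the same gene with
   significantly overlapping sample sets (one-sided Fisher's exact test)
   group into families; retained pairs must satisfy peak < 500 kb (census
   genes exempt), ≥ 15% recurrence, FDR < 0.05, ≥ 1 comparison *p* < 0.05,
   and a group mean > 10 TPM in a significant comparison; ranking is by
   sample count, then FDR.

A deterministic synthetic-cohort generator (`simulate_cohort()`) produces
complete inputs with known ground truth, which is how the package tests
itself end to end. See the methods vignette
(`vignettes/hotspot-detection-methods.Rmd`) for assumptions, parameter
rationale, and limitations.

## Worked example

```r
library(svpeaks)

spec <- simulation_spec(seed = 7)   # 100 samples, 10-Mb chromosome,
                                    # one 120-kb DUP hotspot at 40% penetrance
sim <- simulate_cohort(spec)
res <- analyze_cohort(sim$svs, sim$genes, sim$expr, spec$chrom_lengths,
                      cn_segments = sim$cn, elements = sim$elements)
res
#> SV hotspot analysis: 1 peak(s), 5 (peak, gene) pair(s) tested, 1 retained, 0 famil(ies)

res$peaks[, c("peak_id", "chrom", "start", "end", "count", "pct_samples")]
#>   peak_id chrom   start     end count pct_samples
#> 1 pk001   chr1  3390000 3610000    40       0.656

res$report[, c("rank", "peak_id", "gene", "combined_p", "fdr", "direction")]
#>   rank peak_id   gene   combined_p          fdr direction
#> 1    1   pk001 GENE10 2.938395e-39 1.469197e-38        up
```

Reading the output: the pipeline found exactly one hotspot, `pk001`,
spanning 3.39–3.61 Mb — covering the implanted 3.44–3.56 Mb duplication
hotspot — supported by 40 samples (65.6% of the 61 SV-harboring samples).
Of the five genes within 1 Mb, only `GENE10` (the gene whose expression
the generator actually shifted, 300 kb downstream) survives the filters,
with expression up in SV samples: the unstratified any-SV comparison gives
mean 86.3 vs 34.7 TPM (*p* = 2.7e-13), the copy-neutral stratum confirms
it (*p* = 4.7e-10), and the per-pair battery combines to FDR ≈ 1.5e-38.

The same analysis runs from the shell over on-disk inputs:

```sh
Rscript inst/cli/svpeaks.R simulate --out fixture --seed 7
Rscript inst/cli/svpeaks.R run \
  --sv fixture/svs.bedpe --genes fixture/genes.bed \
  --expression fixture/expression.tsv --cn fixture/cn_segments.tsv \
  --elements fixture/elements.bed --chrom-lengths fixture/chrom_lengths.tsv \
  --out results_dir --plots
```

writing the ranked report, annotated peaks, per-pair association table,
families, per-chromosome UCSC custom tracks, BedGraph count tracks,
figures, and a JSON run manifest into `results_dir/`.

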