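---
title: "Detecting recurrent SV hotspots and their expression consequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting recurrent SV hotspots and their expression consequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svpeaks)
```

## The problem

Whole-genome sequencing of tumour cohorts yields thousands of structural
variant (SV) calls per study — deletions (DEL), tandem duplications (DUP),
insertions (INS), inversions (INV), and translocations (BND). Most are
passengers. Loci that are *recurrently* targeted across patients, however,
are candidate drivers, and many of the most interesting ones lie in
non-coding regulatory DNA (a classic example being the tandem-duplicated
enhancer several hundred kb upstream of *AR* in metastatic prostate
cancer). svpeaks automates the chain from raw cohort SV calls to a ranked
table of hotspot regions whose SVs are statistically associated with the
expression of nearby genes.

## The procedure

### 1. Sliding-window sample counts

Each chromosome is tiled with windows of width $w$ (default 100 kb) sliding
by $s$ (default 30 kb). For every window we count the number of *distinct
samples* with an SV targeting it:

* DUP and DEL contribute their **entire region** — these events change the
  copy number of everything they contain;
* INS, INV and BND contribute only their **breakend positions** — they act
  near their break ends. A translocation contributes each breakend on its
  own chromosome.

A sample is counted at most once per window, and at most once per
(window, SV type). The per-window counts are optionally smoothed with a
centred moving average (`smoothing_span`, default 3 windows) before shape
detection; all thresholds and all reported counts use the raw counts. The
smoothed series exists purely to stop single-window noise from fragmenting
peak shapes, which is why the two series are kept side by side.

### 2. Peak calling

A window $i$ is a candidate peak when

1. its smoothed count is a strict local maximum relative to the nearest
   non-tied neighbours (tied plateau windows are all eligible);
2. its smoothed count satisfies
   $c_i \ge \mathrm{median}(F_i) + \lambda \cdot \max(\mathrm{MAD}(F_i), 1)$,
   where $F_i$ is the set of `flank_windows` = $m$ windows on each side
   (default 10, truncated at chromosome edges) and $\lambda$ = `stdlim`
   (default 3);
3. its **raw** count reaches `min_pct_samples` (default 15%) of the number
   of samples with at least one SV anywhere in the input.

The local background in rule 2 is estimated with the median and the MAD
rather than the mean and standard deviation. This is a deliberate design
choice: a hotspot of realistic width (a 120-kb region plus breakpoint
jitter spans roughly nine overlapping 100-kb/30-kb windows) places its own
shoulders inside the flanks of every window it contains. Mean/SD
background estimates are dragged upward by exactly the signal being tested
— to the point where no window of a broad peak can ever clear the
threshold — whereas the median and MAD are unaffected as long as the peak
occupies less than half the flank. The MAD floor of 1 sample prevents
zero-variance blow-ups over flat background. The denominator of rule 3 is
the number of SV-harboring samples, not the full cohort, because that is
the natural recurrence scale for an SV-based statistic; both the threshold
and the statistic it applies to are reported per peak.

### 3. Peak merging

Candidates are clustered by single linkage: two contiguous candidates
belong to one cluster when the gap between their intervals is at most
`merge_distance` $d$ (default 50 kb). Within a cluster, the unconsumed
candidate with the highest sample count is the *top peak* (ties break to
the leftmost for determinism). The walk then moves upstream and downstream
over the cluster's unconsumed candidates in coordinate order, merging every
peak whose count differs from the top peak's by less than `delta` (default
5%, relative), and stopping a direction after `k` (default 1) consecutive
violations. The process repeats until the cluster is exhausted, so minor
side-peaks seed their own merged peaks rather than vanishing.

When merging is run with access to the window track (as the pipeline does),
each merged peak's boundaries are then extended outward over adjacent
track windows by the same top-peak/$k$–$\delta$ rule: neighbouring windows
whose raw counts stay within `delta` of the top count are absorbed until
`k` consecutive windows violate the rule. Without this step a merged peak
consists only of summit windows — the strict-local-maximum rule admits very
few candidates per bump once sampling noise breaks count ties — and its
interval can stop one step short of the true extent of the recurrently hit
region. The extension makes a hotspot span its full elevated plateau while
the shoulders (where counts drop by more than `delta`) are excluded.
Finally the sample support of every merged peak is recomputed against the
merged interval, since merging can cover positions between candidate
windows.

### 4. Annotation

Peaks are annotated with *nearby* genes — within `gene_flank` of either
edge, default 1 Mb — and with regulatory elements that intersect the peak.
All interval arithmetic is 0-based half-open; distance is measured between
closest edges, overlap meaning distance zero; strand is ignored. The 1-Mb
default is a documented choice, not a canonical value: regulatory hotspots
are known to act on genes several hundred kb away (the *AR*-enhancer case
is ~625 kb), so "nearby" has to reach at least that far, while reaching
much beyond 1 Mb would mostly add noise pairs.

### 5. Expression association

For every (peak, nearby gene) pair, twelve two-group comparisons are run:
samples harbouring any hotspot SV, and samples harbouring each of the five
SV types, are each compared against the samples *without any SV targeting
the peak* (the same control group throughout); each of those six
comparisons is run once over all samples and once restricted to samples
copy-neutral for the gene. Gene-level copy-number status is the
length-weighted mean of a sample's segments over the gene body, called
gain at ≥ 2.5 and loss at ≤ 1.5 on linear copy number (pass ±0.3 with
log2-ratio input); samples without overlapping segments are treated as
neutral — absence of evidence of alteration.

The two-group test is the Wilcoxon rank-sum by default (exact null when
the pooled size is ≤ 20 and tie-free, normal approximation with tie and
continuity correction otherwise), with Welch's *t* as an option. A
comparison with fewer than `min_group` = 3 samples in either group is
undefined; its sizes and means are still reported.

Defined p-values are combined with Fisher's method,
$X^2 = -2\sum \log p_i \sim \chi^2_{2k}$; undefined comparisons are
*dropped* (the degrees of freedom adapt) rather than imputed at $p = 1$,
which would systematically deflate $X^2$. The combined p-values are then
adjusted across **all** (peak, gene) pairs with Benjamini–Hochberg. Both
choices — dropping undefined slots, and applying BH globally rather than
per gene or per peak — are design decisions documented here.

The twelve comparisons on one pair are positively correlated (they share
the control group, and per-type groups are subsets of the any-SV group),
so Fisher's combination is anticonservative. This is inherent to the
specified procedure and is not "fixed"; the package's null simulations
measure it instead (see below), and the final FDR threshold should be read
with that caveat.

### 6. Peak families, filters, ranking

Peaks associated with the same gene whose supporting sample sets overlap
more than expected by chance — one-sided Fisher's exact test
(hypergeometric enrichment tail), unadjusted $p <$ `alpha_dep` = 0.05 —
are grouped into families; connected components make the grouping a
well-defined partition when more than two peaks chain together, and the
member with the highest sample count (ties to the leftmost) represents the
family.

A (peak, gene) pair is retained when: the peak is shorter than 500 kb
(unless the gene is on a user-supplied cancer-census list — no census data
is bundled, for licensing reasons); the merged peak recurs in ≥ 15% of
SV-harboring samples (applied post-merge, the stricter reading, since
merging can only grow sample sets); FDR < 0.05; at least one of the twelve
comparisons has $p < 0.05$; and some group mean in a significant
comparison exceeds 10 TPM. Retained peaks are ranked by sample count, then
best FDR, then coordinate; the ranking key is a package choice.

## The synthetic cohort generator

`simulation_spec()` / `simulate_cohort()` generate complete cohorts —
BEDPE SVs, copy-number segments, a TPM matrix, gene and element BEDs, and
a ground-truth table — so that every stage is testable without external
data. The defaults define the package's reference study condition, chosen
once for realism at desk scale:

* 100 samples, one 10-Mb chromosome;
* a gene grid of one 30-kb gene every 400 kb (human-like density);
* uniform background SVs of mixed types at 0.03 events/sample/Mb, i.e.
  roughly 0.3–0.5 expected SV-harboring samples per 100-kb window across
  the cohort — low enough that background never reaches the 15% recurrence
  threshold, high enough to break count ties and exercise the per-type
  bookkeeping;
* one implanted 120-kb DUP hotspot at 3.44–3.56 Mb hitting exactly 40% of
  samples, with per-event start/end jitter of ±20% of the interval length
  so that merging has to aggregate genuinely heterogeneous events;
* a +2 SD expression effect (applied on the log scale:
  $\mathrm{meanlog} + 2\,\mathrm{sdlog}$) on the gene 300 kb downstream;
  expression is log-normal TPM (meanlog $\log 30$, sdlog 0.5), giving
  positive support and realistic skew;
* an enhancer element inside the hotspot;
* a cancer-like copy-number landscape: an arm-level gain (copy number 3,
  20% of samples), a focal gain over the linked gene (copy number 4, 25%),
  and an arm-level loss (copy number 1, 20%), mutually disjoint so
  per-sample segments never overlap.

What the generator deliberately does **not** model: breakpoint
microhomology or read-level artefacts, clustered/chained rearrangements
(chromothripsis), correlation between SV presence and copy-number events,
dosage effects of copy number on expression, or batch structure in the
expression matrix. Passing tests on these cohorts therefore demonstrates
the correctness of the counting, merging, testing, and filtering
machinery under clean recurrence — not robustness to every artefact of
real tumour data.

## Numerical choices and degenerate inputs

* Coordinates are uniformly 0-based half-open; chromosome names are taken
  verbatim, with a warning when inputs share no chromosome vocabulary.
* Zero-width breakend records are widened to one base before overlap
  counting.
* Degenerate two-group tests in which every pooled value is tied return
  $p = 1$: no evidence, not an error.
* A p-value of exactly 0 entering Fisher's combination is clamped to the
  smallest positive double, with a warning.
* Ties in top-peak selection and in family representatives break to the
  leftmost coordinate, making every stage deterministic for fixed inputs.
* Chromosomes no longer than one window get a single window `[0, L)`.

## Problem sizes used by the test-suite simulations

The recovery and null properties are measured on 100-seed batches of the
reference cohort (and 50-seed batches for the per-type power property);
one cohort analysis takes a fraction of a second at these sizes, so the
whole suite, including the brute-force counting and merging oracles (200
and 500 randomized instances), completes in a few minutes. These sizes are
the package's validation conditions; the generator scales to larger
genomes and cohorts if heavier simulation studies are wanted.

Measured behaviour under the reference condition (recomputed from scratch
by `scripts/acceptance.R` and asserted by the test suite): the implanted
hotspot is recovered as exactly one merged peak covering the implanted
interval, and its linked gene is retained at FDR < 0.05, in well over 90%
of seeds; with the expression effect set to zero the linked pair is
retained in under 10% of seeds — the measured footprint of the Fisher
anticonservativeness discussed above.

## Known limitations

* The twelve-comparison battery is not a calibrated joint test; treat the
  FDR column as a ranking device more than a strict error rate.
* Recurrence is count-based; there is no background mutation-rate model
  (in the style of GISTIC G-scores), so regions with elevated neutral SV
  rates (fragile sites) can surface as hotspots.
* "Nearby" is positional only; no contact-map or eQTL evidence links a
  peak to a gene.
* Expression input is taken as given (TPM); no normalisation or covariate
  adjustment (purity, site) is performed.
* With `k > 1`, peaks skipped during a merge walk can later seed peaks
  whose intervals overlap an earlier merged peak; with the default
  `k = 1` merged peaks are disjoint.

## A minimal run

```{r example, eval = FALSE}
spec <- simulation_spec(seed = 7)
sim <- simulate_cohort(spec)
res <- analyze_cohort(sim$svs, sim$genes, sim$expr, spec$chrom_lengths,
                      cn_segments = sim$cn, elements = sim$elements)
res$report[, c("rank", "peak_id", "gene", "combined_p", "fdr", "direction")]
```

The file-based equivalent (`run_pipeline()`, or the `inst/cli/svpeaks.R`
script) reads BEDPE/BED/TSV inputs, writes the ranked report, annotated
peaks, association table, families, per-chromosome UCSC custom tracks and
BedGraph count tracks, and a JSON manifest with per-stage record counts.
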