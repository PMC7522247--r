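# Synthetic cohorts with known ground truth: background SVs scattered
# uniformly, implanted hotspots of chosen type/penetrance driving the
# expression of a linked gene, a copy-number landscape, and a log-normal
# TPM expression matrix.

#' Describe one implanted hotspot
#'
#' @param chrom,start,end Target interval (0-based half-open).
#' @param svtype SV type of the implanted events.
#' @param penetrance Fraction of cohort samples hit; exactly
#'   `round(penetrance * n_samples)` samples receive an event.
#' @param linked_gene Gene whose expression the hotspot drives (`NA` for
#'   none; required when `expression_effect != 0`).
#' @param expression_effect Shift of the hit samples' mean, in units of the
#'   gene's log-scale standard deviation.
#' @param direction `"up"` or `"down"`.
#' @return A list describing the hotspot.
#' @export
hotspot_spec <- function(chrom, start, end, svtype = "DUP", penetrance = 0.4,
                         linked_gene = NA_character_, expression_effect = 0,
                         direction = c("up", "down")) {
  direction <- match.arg(direction)
  stopifnot(start < end, svtype %in% .SV_TYPES,
            penetrance >= 0, penetrance <= 1,
            expression_effect == 0 || !is.na(linked_gene))
  list(chrom = chrom, start = start, end = end, svtype = svtype,
       penetrance = penetrance, linked_gene = linked_gene,
       expression_effect = expression_effect, direction = direction)
}

#' Describe one copy-number event
#'
#' @param chrom,start,end Event interval.
#' @param type `"gain"` or `"loss"`.
#' @param cn Linear copy number of carrier segments.
#' @param penetrance Fraction of samples carrying the event.
#' @return A list describing the event.
#' @export
cn_event_spec <- function(chrom, start, end, type = c("gain", "loss"),
                          cn = if (match.arg(type) == "gain") 4 else 1,
                          penetrance = 0.2) {
  type <- match.arg(type)
  stopifnot(start < end, cn >= 0, penetrance >= 0, penetrance <= 1)
  list(chrom = chrom, start = start, end = end, type = type, cn = cn,
       penetrance = penetrance)
}

.default_genes <- function(chrom_lengths) {
  rows <- list()
  idx <- 0L
  for (chrom in names(chrom_lengths)) {
    starts <- seq(260e3, by = 400e3,
                  length.out = max(0, floor((chrom_lengths[[chrom]] - 360e3) /
                                              400e3)))
    starts <- starts[starts + 30e3 <= chrom_lengths[[chrom]]]
    rows[[chrom]] <- tibble(
      chrom = chrom, start = starts, end = starts + 30e3,
      name = sprintf("GENE%02d", idx + seq_along(starts)), strand = "+"
    )
    idx <- idx + length(starts)
  }
  bind_rows(rows)
}

#' Specify a synthetic cohort
#'
#' The defaults define the reference study condition used throughout the
#' package's tests: a 100-sample cohort on one 10-Mb chromosome with a
#' human-like gene grid (one 30-kb gene every 400 kb), uniform background
#' SVs at 0.03 events/sample/Mb (about 0.3-0.5 expected SV-harboring
#' samples per 100-kb window), one 120-kb tandem-duplication hotspot at
#' 3.44-3.56 Mb hitting 40% of samples and shifting the expression of the
#' gene 300 kb downstream (GENE10) up by two log-scale standard
#' deviations, an enhancer element inside the hotspot, and a cancer-like
#' copy-number landscape (arm-level gain and loss plus a focal gain over
#' the linked gene; events are mutually disjoint so per-sample segments
#' never overlap).
#'
#' @param n_samples Cohort size.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param background_rate Expected background SVs per sample per Mb.
#' @param genes Gene interval tibble (`chrom,start,end,name`); default grid
#'   as above.
#' @param hotspots List of [hotspot_spec()]s.
#' @param baseline_expression Tibble `gene, meanlog, sdlog` of log-normal
#'   TPM parameters; defaults to meanlog log(30), sdlog 0.5 for every gene.
#' @param cn_events List of [cn_event_spec()]s; must be mutually disjoint.
#' @param elements Regulatory-element tibble (`chrom,start,end,name`).
#' @param seed Integer RNG seed; the cohort is fully reproducible from it.
#' @return A validated list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_samples = 100,
                            chrom_lengths = c(chr1 = 10e6),
                            background_rate = 0.03,
                            genes = NULL,
                            hotspots = NULL,
                            baseline_expression = NULL,
                            cn_events = NULL,
                            elements = NULL,
                            seed = 42) {
  stopifnot(n_samples >= 1, length(chrom_lengths) >= 1,
            !is.null(names(chrom_lengths)), all(chrom_lengths > 0),
            background_rate >= 0)
  if (is.null(genes)) genes <- .default_genes(chrom_lengths)
  if (is.null(hotspots)) {
    hotspots <- list(hotspot_spec(
      chrom = names(chrom_lengths)[1], start = 3.44e6, end = 3.56e6,
      svtype = "DUP", penetrance = 0.4, linked_gene = "GENE10",
      expression_effect = 2, direction = "up"
    ))
  }
  if (is.null(baseline_expression)) {
    baseline_expression <- tibble(gene = genes$name, meanlog = log(30),
                                  sdlog = 0.5)
  }
  if (is.null(cn_events)) {
    ch <- names(chrom_lengths)[1]
    cn_events <- list(
      cn_event_spec(ch, 0.2e6, 3.6e6, "gain", cn = 3, penetrance = 0.20),
      cn_event_spec(ch, 3.8e6, 4.0e6, "gain", cn = 4, penetrance = 0.25),
      cn_event_spec(ch, 5.2e6, 9.8e6, "loss", cn = 1, penetrance = 0.20)
    )
  }
  if (is.null(elements)) {
    elements <- tibble(chrom = names(chrom_lengths)[1], start = 3.48e6,
                       end = 3.50e6, name = "ENH01", strand = ".")
  }
  for (h in hotspots) {
    if (!h$chrom %in% names(chrom_lengths) ||
        h$end > chrom_lengths[[h$chrom]] || h$start < 0) {
      stop("hotspot interval outside the genome: ",
           sprintf("%s:%d-%d", h$chrom, h$start, h$end), call. = FALSE)
    }
    if (!is.na(h$linked_gene) && !h$linked_gene %in% genes$name) {
      stop("linked gene not in gene annotation: ", h$linked_gene,
           call. = FALSE)
    }
  }
  if (length(cn_events) > 1L) {
    for (i in seq_len(length(cn_events) - 1L)) {
      for (j in seq(i + 1L, length(cn_events))) {
        a <- cn_events[[i]]; b <- cn_events[[j]]
        if (a$chrom == b$chrom && a$start < b$end && b$start < a$end) {
          stop("copy-number events must be mutually disjoint", call. = FALSE)
        }
      }
    }
  }
  if (anyDuplicated(genes$name)) stop("gene names must be unique",
                                      call. = FALSE)
  structure(
    list(n_samples = as.integer(n_samples), chrom_lengths = chrom_lengths,
         background_rate = background_rate, genes = genes,
         hotspots = hotspots, baseline_expression = baseline_expression,
         cn_events = cn_events, elements = elements,
         seed = as.integer(seed)),
    class = "simulation_spec"
  )
}

.random_background_sv <- function(sample_id, spec) {
  chrom <- sample(names(spec$chrom_lengths), 1)
  len_chrom <- spec$chrom_lengths[[chrom]]
  svtype <- sample(.SV_TYPES, 1)
  if (svtype %in% c("DUP", "DEL")) {
    len <- round(10^runif(1, log10(5e3), log10(2e5)))
    a <- round(runif(1, 0, max(1, len_chrom - len)))
    tibble(chrom1 = chrom, start1 = a, end1 = a + 1, chrom2 = chrom,
           start2 = a + len - 1, end2 = a + len, sample = sample_id,
           svtype = svtype)
  } else if (svtype == "BND") {
    chrom2 <- sample(names(spec$chrom_lengths), 1)
    p1 <- round(runif(1, 0, len_chrom - 1))
    p2 <- round(runif(1, 0, spec$chrom_lengths[[chrom2]] - 1))
    tibble(chrom1 = chrom, start1 = p1, end1 = p1 + 1, chrom2 = chrom2,
           start2 = p2, end2 = p2 + 1, sample = sample_id, svtype = svtype)
  } else {
    p1 <- round(runif(1, 0, len_chrom - 1))
    p2 <- if (svtype == "INV") {
      min(p1 + round(runif(1, 5e4, 5e5)), len_chrom - 1)
    } else p1
    tibble(chrom1 = chrom, start1 = p1, end1 = p1 + 1, chrom2 = chrom,
           start2 = p2, end2 = p2 + 1, sample = sample_id, svtype = svtype)
  }
}

.hotspot_sv <- function(sample_id, h, spec) {
  len_chrom <- spec$chrom_lengths[[h$chrom]]
  if (h$svtype %in% c("DUP", "DEL")) {
    # start/end jitter within +/-20% of the interval length, so merged
    # peaks must genuinely aggregate heterogeneous events
    L <- h$end - h$start
    a <- round(h$start + runif(1, -0.2, 0.2) * L)
    b <- round(h$end + runif(1, -0.2, 0.2) * L)
    a <- max(0, a); b <- min(len_chrom, b)
    if (b <= a + 1) b <- a + 2
    tibble(chrom1 = h$chrom, start1 = a, end1 = a + 1, chrom2 = h$chrom,
           start2 = b - 1, end2 = b, sample = sample_id, svtype = h$svtype)
  } else {
    p1 <- round(runif(1, h$start, h$end - 1))
    if (h$svtype == "BND") {
      chrom2 <- sample(names(spec$chrom_lengths), 1)
      p2 <- round(runif(1, 0, spec$chrom_lengths[[chrom2]] - 1))
      tibble(chrom1 = h$chrom, start1 = p1, end1 = p1 + 1, chrom2 = chrom2,
             start2 = p2, end2 = p2 + 1, sample = sample_id, svtype = h$svtype)
    } else {
      p2 <- if (h$svtype == "INV") {
        min(p1 + round(runif(1, 5e4, 5e5)), len_chrom - 1)
      } else p1
      tibble(chrom1 = h$chrom, start1 = p1, end1 = p1 + 1, chrom2 = h$chrom,
             start2 = p2, end2 = p2 + 1, sample = sample_id, svtype = h$svtype)
    }
  }
}

#' Generate a synthetic cohort
#'
#' Background SV counts per sample are Poisson with mean
#' `background_rate * genome_Mb`, placed uniformly; each hotspot hits
#' exactly `round(penetrance * n_samples)` samples drawn without
#' replacement, with DUP/DEL events jittered within 20% of the interval
#' length and breakend events placed inside the interval. Expression is
#' log-normal TPM per gene; hit samples of a hotspot have their linked
#' gene's log-scale mean shifted by `expression_effect * sdlog` in the
#' stated direction. The output is fully reproducible from `spec$seed`.
#'
#' @param spec A [simulation_spec()].
#' @return A list of class `simulated_cohort`: `svs` (SV tibble), `cn`
#'   (copy-number segments), `expr` (genes x samples TPM matrix), `genes`,
#'   `elements`, `truth` (one row per implanted hotspot with its hit
#'   samples), `samples`, and the `spec`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  samples <- sprintf("S%03d", seq_len(spec$n_samples))
  genome_mb <- sum(spec$chrom_lengths) / 1e6
  sv_rows <- list()
  for (s in samples) {
    n_bg <- rpois(1, spec$background_rate * genome_mb)
    for (i in seq_len(n_bg)) {
      sv_rows[[length(sv_rows) + 1L]] <- .random_background_sv(s, spec)
    }
  }
  truth_rows <- list()
  for (hi in seq_along(spec$hotspots)) {
    h <- spec$hotspots[[hi]]
    n_hit <- round(h$penetrance * spec$n_samples)
    hits <- sort(sample(samples, n_hit))
    for (s in hits) {
      sv_rows[[length(sv_rows) + 1L]] <- .hotspot_sv(s, h, spec)
    }
    truth_rows[[hi]] <- tibble(
      hotspot_id = sprintf("hs%02d", hi), chrom = h$chrom,
      start = h$start, end = h$end, svtype = h$svtype,
      penetrance = h$penetrance, n_hit = n_hit,
      linked_gene = h$linked_gene, expression_effect = h$expression_effect,
      direction = h$direction,
      hit_samples = paste(hits, collapse = "|")
    )
  }
  svs <- if (length(sv_rows)) bind_rows(sv_rows) else
    tibble(chrom1 = character(), start1 = double(), end1 = double(),
           chrom2 = character(), start2 = double(), end2 = double(),
           sample = character(), svtype = character())
  if (nrow(svs)) {
    svs <- svs[order(svs$chrom1, svs$start1, svs$sample), , drop = FALSE]
  }
  cn_rows <- list()
  for (ev in spec$cn_events) {
    carriers <- sort(sample(samples, round(ev$penetrance * spec$n_samples)))
    if (length(carriers)) {
      cn_rows[[length(cn_rows) + 1L]] <- tibble(
        chrom = ev$chrom, start = ev$start, end = ev$end,
        sample = carriers, cn = ev$cn
      )
    }
  }
  cn <- if (length(cn_rows)) bind_rows(cn_rows) else
    tibble(chrom = character(), start = double(), end = double(),
           sample = character(), cn = double())
  if (nrow(cn)) cn <- cn[order(cn$sample, cn$chrom, cn$start), , drop = FALSE]
  base <- spec$baseline_expression
  shift <- matrix(0, nrow = nrow(base), ncol = spec$n_samples,
                  dimnames = list(base$gene, samples))
  for (hi in seq_along(spec$hotspots)) {
    h <- spec$hotspots[[hi]]
    if (is.na(h$linked_gene) || h$expression_effect == 0) next
    hits <- strsplit(truth_rows[[hi]]$hit_samples, "|", fixed = TRUE)[[1]]
    sdlog <- base$sdlog[base$gene == h$linked_gene]
    sign <- if (h$direction == "up") 1 else -1
    shift[h$linked_gene, hits] <- shift[h$linked_gene, hits] +
      sign * h$expression_effect * sdlog
  }
  expr <- matrix(0, nrow = nrow(base), ncol = spec$n_samples,
                 dimnames = list(base$gene, samples))
  for (g in seq_len(nrow(base))) {
    expr[g, ] <- rlnorm(spec$n_samples,
                        meanlog = base$meanlog[g] + shift[g, ],
                        sdlog = base$sdlog[g])
  }
  structure(
    list(svs = svs, cn = cn, expr = expr, genes = spec$genes,
         elements = spec$elements, truth = bind_rows(truth_rows),
         samples = samples, spec = spec),
    class = "simulated_cohort"
  )
}

#' Write a simulated cohort to the pipeline's on-disk formats
#'
#' Emits exactly the formats the pipeline consumes — BEDPE SVs, BED gene
#' and element annotations, copy-number TSV, expression TSV — plus the
#' ground-truth table.
#'
#' @param sim A `simulated_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of paths (`svs, genes, elements, cn,
#'   expr, truth, chrom_lengths`), invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    svs = file.path(dir, "svs.bedpe"),
    genes = file.path(dir, "genes.bed"),
    elements = file.path(dir, "elements.bed"),
    cn = file.path(dir, "cn_segments.tsv"),
    expr = file.path(dir, "expression.tsv"),
    truth = file.path(dir, "truth.tsv"),
    chrom_lengths = file.path(dir, "chrom_lengths.tsv")
  )
  write_bedpe(sim$svs, paths[["svs"]])
  write_bed(sim$genes, paths[["genes"]])
  write_bed(sim$elements, paths[["elements"]])
  write_cn_segments(sim$cn, paths[["cn"]])
  write_expression(sim$expr, paths[["expr"]])
  write.table(as.data.frame(sim$truth), paths[["truth"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(sprintf("%s\t%d", names(sim$spec$chrom_lengths),
                     as.integer(sim$spec$chrom_lengths)),
             paths[["chrom_lengths"]])
  invisible(paths)
}
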