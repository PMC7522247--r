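# Readers and writers for the plain-text genomic formats the pipeline
# touches. All coordinates are 0-based half-open internally (BED native);
# 1-based inputs must be converted by the caller. Chromosome names are taken
# verbatim (no "chr" normalisation).

.stop_line <- function(path, lineno, msg) {
  stop(sprintf("%s: line %d: %s", path, lineno, msg), call. = FALSE)
}

.read_data_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines)) &
    !grepl("^(track|browser)\\b", lines)
  list(lines = lines[keep], lineno = which(keep))
}

.as_coord <- function(x) {
  v <- suppressWarnings(as.numeric(x))
  v[!is.na(v) & v != floor(v)] <- NA # coordinates must be whole numbers
  v
}

#' Read structural variant calls from a BEDPE file
#'
#' Expected columns: 1-6 the two breakend coordinate triples
#' (chrom1/start1/end1, chrom2/start2/end2), 7 the sample identifier,
#' 8 a score (ignored), 9-10 strands (ignored), 11 the SV type (one of
#' [sv_types()]). Files with exactly 8 columns are also accepted, with the
#' SV type read from column 8. Lines beginning with `#` are skipped.
#'
#' @param path Path to a tab-separated BEDPE file.
#' @return A tibble with columns `chrom1,start1,end1,chrom2,start2,end2,
#'   sample,svtype`, one row per SV call, validated against the SV
#'   invariants (ordered breakend coordinates; intra-chromosomal for
#'   DUP/DEL/INS/INV).
#' @export
read_bedpe <- function(path) {
  dat <- .read_data_lines(path)
  if (length(dat$lines) == 0L) {
    warning("no SV records in ", path)
    return(tibble(
      chrom1 = character(), start1 = double(), end1 = double(),
      chrom2 = character(), start2 = double(), end2 = double(),
      sample = character(), svtype = character()
    ))
  }
  fields <- strsplit(dat$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 8L | (nf > 8L & nf < 11L))
  if (length(bad)) {
    .stop_line(path, dat$lineno[bad[1]], sprintf(
      "expected 8 or >= 11 tab-separated columns, found %d", nf[bad[1]]
    ))
  }
  col <- function(i) vapply(fields, `[[`, "", i)
  svtype <- toupper(ifelse(nf >= 11L, vapply(fields, `[[`, "", 11L), col(8L)))
  coords <- lapply(c(2L, 3L, 5L, 6L), function(i) .as_coord(col(i)))
  bad <- which(Reduce(`|`, lapply(coords, is.na)))
  if (length(bad)) {
    .stop_line(path, dat$lineno[bad[1]], "malformed coordinate")
  }
  bad <- which(!svtype %in% .SV_TYPES)
  if (length(bad)) {
    .stop_line(path, dat$lineno[bad[1]], sprintf(
      "unknown SV type '%s' (expected one of %s)",
      svtype[bad[1]], paste(.SV_TYPES, collapse = ", ")
    ))
  }
  svs <- tibble(
    chrom1 = col(1L), start1 = coords[[1]], end1 = coords[[2]],
    chrom2 = col(4L), start2 = coords[[3]], end2 = coords[[4]],
    sample = col(7L), svtype = svtype
  )
  bad <- which(svs$start1 > svs$end1 | svs$start2 > svs$end2)
  if (length(bad)) {
    .stop_line(path, dat$lineno[bad[1]], "breakend start exceeds end")
  }
  bad <- which(svs$svtype != "BND" & svs$chrom1 != svs$chrom2)
  if (length(bad)) {
    .stop_line(path, dat$lineno[bad[1]],
               "intra-chromosomal SV type with differing chromosomes")
  }
  svs
}

#' Write structural variant calls to BEDPE
#'
#' Inverse of [read_bedpe()]: writes the 11-column dialect with the sample
#' identifier in column 7 and the SV type in column 11.
#'
#' @param svs Tibble of SV records as returned by [read_bedpe()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(svs, path) {
  lines <- sprintf(
    "%s\t%d\t%d\t%s\t%d\t%d\t%s\t.\t+\t-\t%s",
    svs$chrom1, as.integer(svs$start1), as.integer(svs$end1),
    svs$chrom2, as.integer(svs$start2), as.integer(svs$end2),
    svs$sample, svs$svtype
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read genomic intervals from a BED file
#'
#' Accepts BED3/BED4/BED6. When the name column is absent, names default to
#' `chrom:start-end`. Coordinates are 0-based half-open, as in BED itself.
#'
#' @param path Path to a BED file.
#' @return A tibble with columns `chrom,start,end,name,strand` in file order.
#' @export
read_bed <- function(path) {
  dat <- .read_data_lines(path)
  if (length(dat$lines) == 0L) {
    return(tibble(chrom = character(), start = double(), end = double(),
                  name = character(), strand = character()))
  }
  fields <- strsplit(dat$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 3L)
  if (length(bad)) {
    .stop_line(path, dat$lineno[bad[1]], "expected >= 3 tab-separated columns")
  }
  col <- function(i, default) {
    vapply(seq_along(fields), function(j) {
      if (nf[j] >= i) fields[[j]][[i]] else default
    }, "")
  }
  start <- .as_coord(col(2L, NA))
  end <- .as_coord(col(3L, NA))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) .stop_line(path, dat$lineno[bad[1]], "malformed coordinate")
  bad <- which(start >= end)
  if (length(bad)) {
    .stop_line(path, dat$lineno[bad[1]], "interval start must be < end")
  }
  chrom <- col(1L, NA)
  name <- col(4L, "")
  auto <- !nzchar(name)
  name[auto] <- sprintf("%s:%d-%d", chrom[auto],
                        as.integer(start[auto]), as.integer(end[auto]))
  strand <- col(6L, ".")
  strand[!strand %in% c("+", "-", ".")] <- "."
  tibble(chrom = chrom, start = start, end = end, name = name, strand = strand)
}

#' Write genomic intervals to a BED file
#'
#' Writes BED4 (or BED6 when any strand is set), with coordinates
#' byte-identical to the stored values.
#'
#' @param intervals Tibble with columns `chrom,start,end` and optionally
#'   `name`, `strand`.
#' @param path Output path.
#' @param track_line Optional UCSC `track` header line written verbatim.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path, track_line = NULL) {
  name <- if ("name" %in% names(intervals)) intervals$name else
    sprintf("%s:%d-%d", intervals$chrom,
            as.integer(intervals$start), as.integer(intervals$end))
  strand <- if ("strand" %in% names(intervals)) intervals$strand else
    rep(".", nrow(intervals))
  body <- if (all(strand == ".")) {
    sprintf("%s\t%d\t%d\t%s", intervals$chrom, as.integer(intervals$start),
            as.integer(intervals$end), name)
  } else {
    sprintf("%s\t%d\t%d\t%s\t0\t%s", intervals$chrom,
            as.integer(intervals$start), as.integer(intervals$end),
            name, strand)
  }
  writeLines(c(track_line, body), path)
  invisible(path)
}

#' Read per-sample copy-number segments
#'
#' Tab-separated columns `chrom, start, end, sample, cn`, with an optional
#' header line. Copy number is on the linear scale (diploid = 2) unless the
#' caller later classifies it with log2-ratio thresholds. Segments belonging
#' to one sample must not overlap.
#'
#' @param path Path to the segment table.
#' @return A tibble with columns `chrom,start,end,sample,cn`.
#' @export
read_cn_segments <- function(path) {
  dat <- .read_data_lines(path)
  empty <- tibble(chrom = character(), start = double(), end = double(),
                  sample = character(), cn = double())
  if (length(dat$lines) == 0L) return(empty)
  fields <- strsplit(dat$lines, "\t", fixed = TRUE)
  # optional header: second column not numeric
  if (is.na(suppressWarnings(as.numeric(fields[[1]][[2]])))) {
    fields <- fields[-1]
    dat$lineno <- dat$lineno[-1]
  }
  if (length(fields) == 0L) return(empty)
  nf <- lengths(fields)
  bad <- which(nf < 5L)
  if (length(bad)) {
    .stop_line(path, dat$lineno[bad[1]],
               "expected 5 columns: chrom, start, end, sample, cn")
  }
  col <- function(i) vapply(fields, `[[`, "", i)
  start <- .as_coord(col(2L))
  end <- .as_coord(col(3L))
  cn <- suppressWarnings(as.numeric(col(5L)))
  bad <- which(is.na(start) | is.na(end) | start >= end)
  if (length(bad)) .stop_line(path, dat$lineno[bad[1]], "malformed interval")
  bad <- which(is.na(cn) | cn < 0)
  if (length(bad)) {
    .stop_line(path, dat$lineno[bad[1]],
               "copy number must be a number >= 0")
  }
  segs <- tibble(chrom = col(1L), start = start, end = end,
                 sample = col(4L), cn = cn)
  validate_cn_segments(segs)
  segs
}

#' Validate per-sample non-overlap of copy-number segments
#'
#' @param segs Tibble as returned by [read_cn_segments()].
#' @return `segs`, invisibly; errors on the first overlapping pair found.
#' @export
validate_cn_segments <- function(segs) {
  for (key in split(seq_len(nrow(segs)),
                    paste(segs$sample, segs$chrom, sep = "\r"))) {
    if (length(key) < 2L) next
    idx <- key[order(segs$start[key])]
    s <- segs$start[idx]; e <- segs$end[idx]
    ov <- which(s[-1] < e[-length(e)])
    if (length(ov)) {
      i <- idx[ov[1]]; j <- idx[ov[1] + 1L]
      stop(sprintf(
        "overlapping copy-number segments for sample %s: %s:%d-%d and %s:%d-%d",
        segs$sample[i], segs$chrom[i], as.integer(segs$start[i]),
        as.integer(segs$end[i]), segs$chrom[j], as.integer(segs$start[j]),
        as.integer(segs$end[j])
      ), call. = FALSE)
    }
  }
  invisible(segs)
}

#' Write copy-number segments
#'
#' @param segs Tibble with columns `chrom,start,end,sample,cn`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cn_segments <- function(segs, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%s", segs$chrom, as.integer(segs$start),
                   as.integer(segs$end), segs$sample,
                   format(segs$cn, trim = TRUE, scientific = FALSE))
  writeLines(c("chrom\tstart\tend\tsample\tcn", lines), path)
  invisible(path)
}

#' Read a gene-by-sample expression matrix
#'
#' Tab-separated with a header line; first column gene symbol, remaining
#' columns one per sample, values in TPM.
#'
#' @param path Path to the expression TSV.
#' @return A numeric matrix (genes x samples) with gene symbols as row
#'   names and sample identifiers as column names, in file order.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  if (ncol(df) < 2L) stop(path, ": expected gene column plus >= 1 sample",
                          call. = FALSE)
  genes <- df[[1]]
  dup <- genes[duplicated(genes)]
  if (length(dup)) {
    stop(path, ": duplicated gene symbol: ", dup[1], call. = FALSE)
  }
  samples <- colnames(df)[-1]
  if (anyDuplicated(samples)) {
    stop(path, ": duplicated sample identifier", call. = FALSE)
  }
  vals <- suppressWarnings(
    vapply(df[-1], as.numeric, numeric(nrow(df)))
  )
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(genes, samples))
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("%s: missing or non-numeric value for gene %s, sample %s",
                 path, genes[idx[1]], samples[idx[2]]), call. = FALSE)
  }
  if (any(vals < 0)) {
    idx <- which(vals < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("%s: negative expression for gene %s, sample %s",
                 path, genes[idx[1]], samples[idx[2]]), call. = FALSE)
  }
  vals
}

#' Write a gene-by-sample expression matrix
#'
#' @param expr Numeric matrix with gene row names and sample column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  header <- paste(c("gene", colnames(expr)), collapse = "\t")
  body <- vapply(seq_len(nrow(expr)), function(i) {
    paste(c(rownames(expr)[i],
            format(expr[i, ], trim = TRUE, scientific = FALSE)),
          collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a BedGraph file
#'
#' @param path Path to a BedGraph file; `track`/`browser`/comment lines are
#'   skipped.
#' @return A tibble with columns `chrom,start,end,value`.
#' @export
read_bedgraph <- function(path) {
  dat <- .read_data_lines(path)
  if (length(dat$lines) == 0L) {
    return(tibble(chrom = character(), start = double(), end = double(),
                  value = double()))
  }
  fields <- strsplit(dat$lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 4L)
  if (length(bad)) .stop_line(path, dat$lineno[bad[1]], "expected 4 columns")
  col <- function(i) vapply(fields, `[[`, "", i)
  tibble(chrom = col(1L), start = .as_coord(col(2L)), end = .as_coord(col(3L)),
         value = as.numeric(col(4L)))
}

#' Read a UCSC custom track file into its constituent blocks
#'
#' Parses a multi-block custom track file (as written by
#' [write_ucsc_tracks()]) into one element per `track` header line.
#'
#' @param path Path to the custom track file.
#' @return A list of blocks, each a list with elements `name` (from the
#'   track line), `type` (`"bed"` or `"bedGraph"`), and `data` (a tibble
#'   parsed with the corresponding reader).
#' @export
read_ucsc_track <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  heads <- grep("^track\\b", lines)
  if (length(heads) == 0L) return(list())
  bounds <- c(heads, length(lines) + 1L)
  lapply(seq_along(heads), function(i) {
    hdr <- lines[heads[i]]
    type <- if (grepl("type=bedGraph", hdr)) "bedGraph" else "bed"
    name <- sub('.*name="([^"]*)".*', "\\1", hdr)
    body <- lines[seq(bounds[i] + 1L, bounds[i + 1L] - 1L)]
    body <- body[nzchar(trimws(body))]
    tmp <- tempfile(fileext = ".txt")
    on.exit(unlink(tmp), add = TRUE)
    writeLines(body, tmp)
    data <- if (type == "bedGraph") read_bedgraph(tmp) else read_bed(tmp)
    list(name = name, type = type, data = data)
  })
}

#' Warn when inputs use disjoint chromosome vocabularies
#'
#' Chromosome names are taken verbatim throughout the pipeline; this check
#' flags the common failure mode of mixing "chr1" and "1" naming between
#' input files.
#'
#' @param ... Named inputs; each may be an SV tibble (columns
#'   `chrom1`/`chrom2`) or an interval/segment tibble (column `chrom`).
#' @return Invisibly, the list of per-input chromosome name sets.
#' @export
check_chrom_vocabulary <- function(...) {
  inputs <- list(...)
  vocab <- lapply(inputs, function(x) {
    if (is.null(x) || !nrow(x)) return(character())
    if ("chrom" %in% names(x)) unique(x$chrom)
    else unique(c(x$chrom1, x$chrom2))
  })
  nonempty <- which(lengths(vocab) > 0)
  if (length(nonempty) > 1L) {
    for (i in nonempty[-1]) {
      a <- nonempty[1]
      if (!length(intersect(vocab[[a]], vocab[[i]]))) {
        warning(sprintf(
          "inputs '%s' and '%s' share no chromosome names (e.g. %s vs %s)",
          names(inputs)[a], names(inputs)[i], vocab[[a]][1], vocab[[i]][1]
        ), call. = FALSE)
      }
    }
  }
  invisible(vocab)
}
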