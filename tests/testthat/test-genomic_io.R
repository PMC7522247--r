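test_that("read_bedpe maps columns, skips headers, and validates records", {
  path <- write_lines_tmp(c(
    "#chrom1\tstart1\tend1\tchrom2\tstart2\tend2\tname\tscore\ts1\ts2\ttype",
    "chr1\t100\t101\tchr1\t5000\t5001\tS1\t.\t+\t-\tDEL",
    "chr1\t200\t201\tchr2\t300\t301\tS2\t.\t+\t-\tBND"
  ), ".bedpe")
  svs <- read_bedpe(path)
  expect_equal(nrow(svs), 2L)
  expect_equal(svs$chrom1[1], "chr1")
  expect_equal(svs$start1[1], 100)
  expect_equal(svs$end2[1], 5001)
  expect_equal(svs$sample, c("S1", "S2"))
  expect_equal(svs$svtype, c("DEL", "BND"))

  # 8-column dialect carries the type in column 8
  path8 <- write_lines_tmp("chr1\t10\t11\tchr1\t900\t901\tS1\tDUP")
  expect_equal(read_bedpe(path8)$svtype, "DUP")

  expect_warning(empty <- read_bedpe(write_lines_tmp("#header only")),
                 "no SV records")
  expect_equal(nrow(empty), 0L)
})

test_that("read_bedpe rejects malformed lines with their line number", {
  bad_type <- write_lines_tmp(c(
    "chr1\t1\t2\tchr1\t3\t4\tS1\t.\t+\t-\tDUP",
    "chr1\t1\t2\tchr1\t3\t4\tS1\t.\t+\t-\tCNV"
  ))
  expect_error(read_bedpe(bad_type), "line 2.*unknown SV type 'CNV'")
  bad_coord <- write_lines_tmp("chr1\tfoo\t2\tchr1\t3\t4\tS1\tDEL")
  expect_error(read_bedpe(bad_coord), "line 1.*coordinate")
  inverted <- write_lines_tmp("chr1\t5\t2\tchr1\t3\t4\tS1\tDEL")
  expect_error(read_bedpe(inverted), "start exceeds end")
  cross <- write_lines_tmp("chr1\t1\t2\tchr2\t3\t4\tS1\tDEL")
  expect_error(read_bedpe(cross), "differing chromosomes")
})

test_that("BEDPE records round-trip through write and re-read", {
  path <- write_lines_tmp(c(
    "chrX\t66000000\t66000001\tchrX\t66900000\t66900001\tS7\t.\t+\t-\tDUP",
    "chr2\t10\t11\tchr9\t99\t100\tS1\t.\t+\t-\tBND"
  ))
  svs <- read_bedpe(path)
  out <- tempfile(fileext = ".bedpe")
  write_bedpe(svs, out)
  expect_equal(read_bedpe(out), svs)
})

test_that("read_bed handles BED3/BED4, auto-names, and rejects bad intervals", {
  bed <- read_bed(write_lines_tmp(c(
    "chrX\t66000000\t66100000\tAR_enh",
    "chr1\t500\t900"
  ), ".bed"))
  expect_equal(bed$name, c("AR_enh", "chr1:500-900"))
  expect_equal(bed$strand, c(".", "."))
  expect_error(read_bed(write_lines_tmp("chr1\t500\t400")), "start must be <")

  out <- tempfile(fileext = ".bed")
  write_bed(bed, out)
  expect_equal(read_bed(out), bed)
  # coordinates byte-identical for untouched records
  expect_equal(readLines(out)[1], "chrX\t66000000\t66100000\tAR_enh")
})

test_that("copy-number segment reader validates values and per-sample overlap", {
  ok <- read_cn_segments(write_lines_tmp(c(
    "chrom\tstart\tend\tsample\tcn",
    "chr1\t0\t100\tS1\t2.5",
    "chr1\t100\t200\tS1\t2",
    "chr1\t50\t150\tS2\t1"
  ), ".tsv"))
  expect_equal(nrow(ok), 3L)
  expect_equal(ok$cn, c(2.5, 2, 1))

  overlapping <- write_lines_tmp(c(
    "chr1\t0\t100\tS1\t2",
    "chr1\t50\t150\tS1\t3"
  ))
  expect_error(read_cn_segments(overlapping),
               "overlapping.*S1.*chr1:0-100.*chr1:50-150")
  negative <- write_lines_tmp("chr1\t0\t100\tS1\t-1")
  expect_error(read_cn_segments(negative), "copy number")
})

test_that("expression reader enforces uniqueness and numeric completeness", {
  expr <- read_expression(write_lines_tmp(c(
    "gene\tS1\tS2\tS3",
    "TP53\t1.5\t2\t3",
    "PTEN\t0\t10\t20"
  ), ".tsv"))
  expect_equal(dim(expr), c(2L, 3L))
  expect_equal(rownames(expr), c("TP53", "PTEN"))
  expect_equal(expr["TP53", "S2"], 2)

  dup <- write_lines_tmp(c("gene\tS1", "TP53\t1", "TP53\t2"))
  expect_error(read_expression(dup), "duplicated gene symbol: TP53")
  hole <- write_lines_tmp(c("gene\tS1\tS2", "TP53\t1\tx"))
  expect_error(read_expression(hole), "gene TP53, sample S2")
})

test_that("bedgraph and UCSC custom-track files parse back into blocks", {
  bg <- write_lines_tmp(c(
    'track type=bedGraph name="counts"',
    "chr1\t0\t30000\t5",
    "chr1\t30000\t60000\t7"
  ), ".bedgraph")
  parsed <- read_bedgraph(bg)
  expect_equal(parsed$value, c(5, 7))

  track_file <- write_lines_tmp(c(
    'track name="peaks" visibility=2',
    "chr1\t100\t900\tpk001",
    'track type=bedGraph name="counts"',
    "chr1\t0\t30000\t3"
  ))
  blocks <- read_ucsc_track(track_file)
  expect_length(blocks, 2L)
  expect_equal(blocks[[1]]$type, "bed")
  expect_equal(blocks[[1]]$data$name, "pk001")
  expect_equal(blocks[[2]]$type, "bedGraph")
  expect_equal(blocks[[2]]$data$value, 3)
})

test_that("disjoint chromosome vocabularies trigger a warning", {
  svs <- tibble::tibble(chrom1 = "chr1", start1 = 1, end1 = 2,
                        chrom2 = "chr1", start2 = 5, end2 = 6,
                        sample = "S1", svtype = "DEL")
  genes <- tibble::tibble(chrom = "1", start = 0, end = 10, name = "G")
  expect_warning(check_chrom_vocabulary(svs = svs, genes = genes),
                 "share no chromosome names")
  genes$chrom <- "chr1"
  expect_silent(check_chrom_vocabulary(svs = svs, genes = genes))
})
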