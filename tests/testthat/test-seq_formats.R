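test_that("FASTA round-trips preserve ids, order and soft-mask case", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT"), path)
  expect_identical(read_fasta(path), c(a = "ACGT"))

  set.seed(1)
  recs <- setNames(
    vapply(1:100, function(i)
      random_dna(sample(50:400, 1), c("A", "C", "G", "T", "a", "c", "g", "t", "N")), ""),
    paste0("rec", 1:100))
  write_fasta(recs, path, wrap = 60)
  expect_identical(read_fasta(path), recs)
  write_fasta(recs, path, wrap = 0)      # unwrapped variant
  expect_identical(read_fasta(path), recs)
})

test_that("FASTA errors name the offence", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c("ACGT", ">a"), path)
  expect_error(read_fasta(path), "line 1")
  writeLines(c(">a", "ACGT", ">empty", ">b", "AC"), path)
  expect_error(read_fasta(path), "empty sequence")
  expect_error(read_fasta(file.path(tempdir(), "no-such.fa")), "no such file")
})

test_that("probe header grammar parses and is lenient", {
  h <- ">uce-7_p2 |design:x,probes-locus:uce-7,probes-probe:2,probes-source:tax1"
  p <- parse_probe_header(sub("^>", "", h))
  expect_equal(p$locus, "uce-7")
  expect_equal(p$probe_index, 2L)
  expect_equal(p$source, "tax1")
  expect_equal(p$design, "x")
  # lenient: any uce-<N> token; unparsed tail kept verbatim
  p2 <- parse_probe_header("uce-123_weird junk |here")
  expect_equal(p2$locus, "uce-123")
  expect_equal(p2$tail, "junk |here")
  expect_error(parse_probe_header("no-locus-token"), "uce-<N>")
})

test_that("probe FASTA round-trips through the header grammar", {
  ps <- probe_set(c("uce-1", "uce-1", "uce-2"), c(1, 2, 1),
                  c("tax1", "tax1", "tax2"), "testdesign",
                  replicate(3, random_dna(120)))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_probe_fasta(ps, path)
  back <- read_probe_fasta(path)
  expect_equal(back$locus, ps$locus)
  expect_equal(back$probe_index, ps$probe_index)
  expect_equal(back$source, ps$source)
  expect_equal(back$sequence, ps$sequence)
})

test_that("monolithic locus FASTA round-trips", {
  df <- data.frame(locus = c("uce-1", "uce-1", "uce-2"),
                   taxon = c("taxA", "taxB", "taxA"),
                   sequence = replicate(3, random_dna(200)),
                   stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_monolithic(df, path)
  expect_equal(read_monolithic(path), df)
  expect_error(write_monolithic(df[c(1, 1, 2), ], path), "one record per")
})

test_that("BED round-trips 0-based half-open coordinates exactly", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t0\t10", path)
  iv <- read_bed(path)
  expect_equal(iv$contig, "chr1")
  expect_equal(iv$start, 0)
  expect_equal(iv$end, 10)

  set.seed(2)
  start <- sample(0:1e6, 1000)
  x <- intervals(contig = sample(paste0("c", 1:5), 1000, TRUE),
                 start = start, end = start + sample(1:500, 1000, TRUE),
                 strand = sample(c("+", "-"), 1000, TRUE),
                 name = paste0("iv", 1:1000), score = sample(0:99, 1000, TRUE))
  write_bed(x, path)
  back <- read_bed(path)
  expect_equal(back$contig, x$contig)
  expect_equal(back$start, x$start)
  expect_equal(back$end, x$end)
  expect_equal(back$strand, x$strand)
  expect_equal(back$name, x$name)
})

test_that("invalid intervals are rejected", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t10\t10", path)
  expect_error(read_bed(path), "start must be <")
  writeLines("chr1\t-5\t10", path)
  expect_error(read_bed(path), "negative")
  expect_error(intervals("c", 5, 5), "start must be <")
})

sam_file <- function(records) {
  path <- withr::local_tempfile(fileext = ".sam", .local_envir = parent.frame())
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:ref\tLN:100000", records), path)
  path
}

test_that("SAM records reduce to reference intervals with 0-based starts", {
  p <- sam_file(c(
    "r1\t0\tref\t1\t60\t100M\t*\t0\t0\t*\t*",
    "r2\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*",             # unmapped
    "r3\t0\tref\t11\t60\t50M10D50M\t*\t0\t0\t*\t*",
    "r4\t1024\tref\t1\t60\t100M\t*\t0\t0\t*\t*",    # duplicate
    "r5\t256\tref\t1\t60\t100M\t*\t0\t0\t*\t*",     # secondary
    "r6\t16\tref\t21\t60\t10S30M5I30M10S\t*\t0\t0\t*\t*"))
  iv <- read_sam_intervals(p)
  expect_equal(nrow(iv), 3L)
  expect_equal(iv$start, c(0, 10, 20))
  expect_equal(iv$end, c(100, 120, 80))   # S and I consume no reference
  expect_equal(iv$strand, c("+", "+", "-"))
})

test_that("SAM without header errors; CIGAR walk matches a re-walk", {
  path <- withr::local_tempfile(fileext = ".sam")
  writeLines("r1\t0\tref\t1\t60\t100M\t*\t0\t0\t*\t*", path)
  expect_error(read_sam_intervals(path), "header")

  # property: interval length == sum of reference-consuming ops
  set.seed(3)
  ops_ref <- c("M", "D", "N", "=", "X")
  ops_all <- c(ops_ref, "I", "S")
  cigars <- vapply(1:50, function(i) {
    k <- sample(1:6, 1)
    ops <- c("M", sample(ops_all, k, TRUE))   # guarantee one ref-consuming op
    paste0(sample(5:80, k + 1, TRUE), ops, collapse = "")
  }, "")
  recs <- sprintf("r%d\t0\tref\t%d\t60\t%s\t*\t0\t0\t*\t*", 1:50,
                  sample(1:1000, 50), cigars)
  p <- sam_file(recs)
  iv <- read_sam_intervals(p)
  rewalk <- vapply(cigars, function(cg) {
    m <- regmatches(cg, gregexpr("\\d+[A-Z=]", cg))[[1]]
    sum(as.numeric(sub("[A-Z=]", "", m))[sub("\\d+", "", m) %in% ops_ref])
  }, numeric(1), USE.NAMES = FALSE)
  expect_equal(iv$end - iv$start, rewalk)
})
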