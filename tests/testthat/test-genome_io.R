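test_that("read_bed maps fields, strands and skips non-data lines", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("track name=x", "# comment",
               "chr1\t100\t200\tx\t0\t+",
               "chr2\t0\t50",
               "chr1\t300\t400\ty\t0\t."), f)
  got <- read_bed(f)
  expect_length(got, 3)
  expect_equal(as.character(GenomicRanges::seqnames(got)),
               c("chr1", "chr2", "chr1"))
  expect_equal(bed_start(got), c(100, 0, 300))
  expect_equal(bed_end(got), c(200, 50, 400))
  expect_equal(as.character(GenomicRanges::strand(got)), c("+", "*", "*"))
})

test_that("read_bed handles empty files and rejects malformed lines by number", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(character(0), f)
  expect_length(read_bed(f), 0)

  writeLines(c("chr1\t10\t20", "chr1\t200\t100"), f)
  expect_error(read_bed(f), "line 2")
  writeLines(c("chr1\t10"), f)
  expect_error(read_bed(f, min_fields = 3), "line 1")
})

test_that("BED and refGene writers round-trip through their readers", {
  f <- withr::local_tempfile(fileext = ".bed")
  x <- gr_bed("chr1", c(0, 500), c(100, 900), strand = c("+", "-"))
  write_bed(x, f)
  y <- read_bed(f)
  expect_equal(bed_start(y), bed_start(x))
  expect_equal(bed_end(y), bed_end(x))
  expect_equal(as.character(GenomicRanges::strand(y)),
               as.character(GenomicRanges::strand(x)))

  g <- genes_bed("chr1", c(1000, 5000), c(3000, 9000), c("+", "-"))
  fa <- withr::local_tempfile(fileext = ".tsv")
  write_refgene(g, fa)
  g2 <- read_refgene(fa)
  expect_equal(S4Vectors::mcols(g2)$name, S4Vectors::mcols(g)$name)
  expect_equal(bed_start(g2), bed_start(g))
  expect_equal(bed_end(g2), bed_end(g))
})

test_that("merge_intervals unions overlapping and bookended intervals", {
  x <- gr_bed("chr1", c(100, 150, 250), c(200, 250, 300))
  m <- merge_intervals(x, bookended = TRUE)
  expect_equal(bed_start(m), 100)
  expect_equal(bed_end(m), 300)
  m2 <- merge_intervals(x, bookended = FALSE)
  expect_length(m2, 2)  # (100,250) and (250,300) stay apart

  expect_length(merge_intervals(GenomicRanges::GRanges()), 0)
  d <- gr_bed(c("chr1", "chr2"), c(100, 100), c(200, 200))
  expect_length(merge_intervals(d), 2)
})

test_that("merge_intervals is idempotent and never expands covered bp", {
  set.seed(11)
  for (rep in 1:5) {
    x <- random_intervals(200)
    m <- merge_intervals(x)
    expect_equal(merge_intervals(m), m)
    expect_lte(sum(GenomicRanges::width(m)), sum(GenomicRanges::width(x)))
  }
})

test_that("closest_distance measures edge gaps with sentinel off-chromosome", {
  q <- gr_bed("chr1", 1000, 1100)
  s <- gr_bed("chr1", 2000, 5000)
  expect_equal(closest_distance(q, s)$distance, 900)
  inside <- gr_bed("chr1", 0, 10000)
  expect_equal(closest_distance(q, inside)$distance, 0)
  off <- gr_bed("chr2", 0, 100)
  res <- closest_distance(q, off)
  expect_equal(res$distance, Inf)
  expect_true(is.na(res$subject))
  expect_error(closest_distance(q, GenomicRanges::GRanges()), "non-empty")
})

test_that("closest_distance agrees with an exhaustive pairwise scan", {
  set.seed(21)
  subjects <- random_intervals(500)
  queries <- random_intervals(50)
  for (i in seq_along(queries)) {
    got <- closest_distance(queries[i], subjects)$distance
    d <- suppressWarnings(
      GenomicRanges::distance(rep(queries[i], length(subjects)), subjects,
                              ignore.strand = TRUE))
    want <- if (all(is.na(d))) Inf else min(d, na.rm = TRUE)
    expect_equal(got, as.numeric(want))
  }
})

test_that("count_overlapping_reads honors >=1bp overlap and strand rules", {
  reads <- gr_bed("chr1", c(95, 199, 300, 100), c(105, 230, 330, 130),
                  strand = c("+", "+", "+", "+"))
  w_plus <- gr_bed("chr1", 100, 200, "+")
  expect_equal(count_overlapping_reads(w_plus, reads), 3L)
  w_minus <- gr_bed("chr1", 100, 200, "-")
  expect_equal(count_overlapping_reads(w_minus, reads), 0L)
  w_any <- gr_bed("chr1", 100, 200, "*")
  expect_equal(count_overlapping_reads(w_any, reads), 3L)
  # single read fully inside
  expect_equal(count_overlapping_reads(gr_bed("chr1", 50, 200, "+"),
                                       gr_bed("chr1", 100, 130, "*")), 0L)
  expect_equal(count_overlapping_reads(
    gr_bed("chr1", 50, 200, "+"), gr_bed("chr1", 100, 130, "+")), 1L)
})

test_that("counts over a partition sum to the whole-window count", {
  set.seed(31)
  # reads of width 1 cannot span partition boundaries
  pos <- sample.int(1000, 300, replace = TRUE)
  reads <- GenomicRanges::GRanges("chr1", IRanges::IRanges(pos, pos),
                                  strand = "+")
  whole <- gr_bed("chr1", 0, 1000, "+")
  parts <- gr_bed("chr1", c(0, 250, 700), c(250, 700, 1000), "+")
  expect_equal(sum(count_overlapping_reads(parts, reads)),
               count_overlapping_reads(whole, reads))
})

test_that("write_bedgraph scales by depth and signs the minus strand", {
  rs <- read_set(gr_bed("chr1", c(10, 10, 20), c(11, 11, 21),
                        strand = c("+", "+", "-")),
                 total_mapped = 2e6, genome_length = 1e6)
  f <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(rs, f)
  bg <- read.table(f, sep = "\t")
  plus <- bg[bg$V4 > 0, ]
  minus <- bg[bg$V4 < 0, ]
  expect_equal(plus$V4, 1.0)       # coverage 2 / 2 million-mapped
  expect_equal(minus$V4, -0.5)
  expect_equal(plus$V2, 10); expect_equal(plus$V3, 11)

  empty <- read_set(GenomicRanges::GRanges(), total_mapped = 1e6,
                    genome_length = 1e6)
  write_bedgraph(empty, f)
  expect_equal(file.size(f), 0)
  bad <- read_set(GenomicRanges::GRanges(), total_mapped = 0,
                  genome_length = 1e6)
  expect_error(write_bedgraph(bad, f), "total_mapped")
})
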