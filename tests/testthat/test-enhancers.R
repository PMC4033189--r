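test_that("consensus_sites keeps footprints by experiment support", {
  base <- gr_bed("chr1", 1000, 1400)
  shifted <- gr_bed("chr1", 1100, 1500)
  noise <- gr_bed("chr2", 5000, 5400)
  # present (overlapping) in 5 of 7 -> retained
  sets5 <- c(rep(list(base), 3), rep(list(shifted), 2), rep(list(noise), 2))
  got5 <- consensus_sites(sets5, min_support = 5)
  expect_equal(as.character(GenomicRanges::seqnames(got5)), "chr1")
  expect_equal(S4Vectors::mcols(got5)$support, 5L)
  # in 4 of 7 -> dropped
  sets4 <- c(rep(list(base), 4), rep(list(noise), 3))
  got4 <- consensus_sites(sets4, min_support = 5)
  expect_length(got4[as.character(GenomicRanges::seqnames(got4)) == "chr1"], 0)

  ident <- rep(list(base), 7)
  got7 <- consensus_sites(ident, min_support = 5)
  expect_length(got7, 1)
  expect_equal(S4Vectors::mcols(got7)$support, 7L)

  two <- consensus_sites(list(gr_bed("chr1", 100, 200),
                              gr_bed("chr1", 150, 250)), min_support = 2)
  expect_equal(bed_start(two), 100)
  expect_equal(bed_end(two), 250)
  expect_equal(S4Vectors::mcols(two)$support, 2L)
})

test_that("consensus support is monotone and min_support 1 is the union", {
  set.seed(101)
  sets <- lapply(1:7, function(i) random_intervals(80))
  union_merge <- merge_intervals(do.call(c, sets))
  s1 <- consensus_sites(sets, min_support = 1)
  expect_equal(GenomicRanges::granges(s1), union_merge, ignore_attr = TRUE)
  sizes <- vapply(1:7, function(k)
    length(consensus_sites(sets, min_support = k)), integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("stranded_sites doubles sites and filters same-strand genic overlap", {
  sites <- gr_bed("chr1", c(1000, 50000), c(1600, 50600))
  genes <- genes_bed("chr1", 800, 2000, "+")
  rec <- stranded_sites(sites, genes)
  expect_length(rec, 4)  # always two records per site before filtering
  s1 <- rec[S4Vectors::mcols(rec)$site_id == 1]
  expect_equal(S4Vectors::mcols(s1)$kept[
    as.character(GenomicRanges::strand(s1)) == "+"], FALSE)
  expect_equal(S4Vectors::mcols(s1)$kept[
    as.character(GenomicRanges::strand(s1)) == "-"], TRUE)
  s2 <- rec[S4Vectors::mcols(rec)$site_id == 2]
  expect_true(all(S4Vectors::mcols(s2)$kept))

  empty <- stranded_sites(GenomicRanges::GRanges())
  expect_length(empty, 0)
})

test_that("categorize_sites applies the 25-kb rule with target precedence", {
  genes <- genes_bed("chr1", c(100000, 200000, 400000),
                     c(110000, 210000, 410000), c("+", "+", "+"),
                     name = c("target1", "non1", "non2"))
  sites <- gr_bed("chr1",
                  c(140000,   # 30 kb from both flanks -> distal
                    90000,    # 10 kb from target1 and inside nothing
                    195000,   # 5 kb from non1, 85 kb past target1 -> non-target
                    105000),  # inside target1
                  c(140500, 90500, 195500, 105500))
  got <- categorize_sites(sites, genes, targets = "target1")
  expect_equal(S4Vectors::mcols(got)$category,
               c("distal", "proximal_target", "proximal_non_target",
                 "proximal_target"))
  expect_equal(S4Vectors::mcols(got)$dist_gene[4], 0)
  # target within radius wins even when a non-target is closer
  tie <- gr_bed("chr1", 120000, 120500)  # 10 kb from target1, 79.5 kb from non1
  g2 <- genes_bed("chr1", c(100000, 125000), c(110000, 135000), c("+", "+"),
                  name = c("target1", "non1"))
  got2 <- categorize_sites(tie, g2, targets = "target1")
  expect_equal(S4Vectors::mcols(got2)$category, "proximal_target")
  expect_warning(out <- categorize_sites(sites, GenomicRanges::GRanges(),
                                         targets = "x"), "distal")
  expect_true(all(S4Vectors::mcols(out)$category == "distal"))
})

test_that("categorize_sites agrees with a brute-force all-pairs scan", {
  set.seed(111)
  genes <- random_intervals(300, chroms = c("chrA", "chrB"))
  GenomicRanges::strand(genes) <- sample(c("+", "-"), 300, replace = TRUE)
  S4Vectors::mcols(genes)$name <- sprintf("g%03d", 1:300)
  targets <- sample(S4Vectors::mcols(genes)$name, 40)
  sites <- random_intervals(300)
  got <- categorize_sites(sites, genes, targets)
  for (i in sample(seq_along(sites), 60)) {
    d_all <- suppressWarnings(GenomicRanges::distance(
      rep(sites[i], length(genes)), genes, ignore.strand = TRUE))
    dg <- if (all(is.na(d_all))) Inf else min(d_all, na.rm = TRUE)
    is_t <- S4Vectors::mcols(genes)$name %in% targets
    dt <- if (all(is.na(d_all[is_t]))) Inf else min(d_all[is_t], na.rm = TRUE)
    want <- if (dg > 25000) "distal" else if (dt <= 25000)
      "proximal_target" else "proximal_non_target"
    expect_equal(S4Vectors::mcols(got)$category[i], want)
    expect_equal(S4Vectors::mcols(got)$dist_gene[i], as.numeric(dg))
  }
})

test_that("erna_quantify computes per-strand activity and filtered folds", {
  site <- gr_bed("chr1", 10000, 10600)
  rec <- stranded_sites(site)
  mk_reads <- function(n_plus, n_minus) {
    reads <- GenomicRanges::GRanges()
    if (n_plus > 0)
      reads <- c(reads, gr_bed("chr1", rep(10100, n_plus),
                               rep(10150, n_plus), "+"))
    if (n_minus > 0)
      reads <- c(reads, gr_bed("chr1", rep(10200, n_minus),
                               rep(10250, n_minus), "-"))
    read_set(reads, total_mapped = 1e6, genome_length = 1e8)
  }
  rs <- list(ctl = mk_reads(5, 0), trt = mk_reads(20, 0))
  out <- erna_quantify(rec, rs, comparisons = list(c("ctl", "trt")))
  # plus strand: 20 vs 5 at equal depth and length -> fold 4
  f <- out$folds
  expect_equal(nrow(f), 1)  # minus strand had 0 reads: excluded
  expect_equal(f$strand, "+")
  expect_equal(f$fold_change, 4)
  # lambda = 0.03 * 1e6 * 601 / 1e8 = 0.18; 20 reads is clearly active
  trt_plus <- out$records[out$records$sample == "trt" &
                          out$records$strand == "+", ]
  expect_true(trt_plus$active)
  # site-level OR: minus strand inactive alone does not veto
  site_trt <- out$sites[out$sites$sample == "trt", ]
  expect_true(site_trt$active)
  # both strands inactive -> site inactive
  rs0 <- list(none = mk_reads(0, 0))
  out0 <- erna_quantify(rec, rs0)
  expect_false(any(out0$sites$active))
})

test_that("tss_distance_histogram bins signed strand-aware distances", {
  genes <- genes_bed("chr1", c(10000, 30000), c(20000, 40000), c("+", "-"),
                     name = c("plus", "minus"))
  # nearest to plus TSS (10000): midpoint 9500 -> signed -500
  # nearest to minus TSS (40000): midpoint 39500 -> signed +500
  sites <- gr_bed("chr1", c(9400, 39400), c(9600, 39600))
  h <- tss_distance_histogram(genes, sites)
  expect_equal(sum(h$count), 2)
  neg_bin <- h[h$bin_start == -1000 & h$bin_end == 0, ]
  pos_bin <- h[h$bin_start == 0 & h$bin_end == 1000, ]
  expect_equal(neg_bin$count, 1)
  expect_equal(pos_bin$count, 1)
  # bin structure: 10 x 5kb flanks both sides, 1kb inner bins
  expect_equal(nrow(h), 70)
  expect_equal(sum(h$bin_end - h$bin_start == 5000), 20)
  expect_equal(sum(h$bin_end - h$bin_start == 1000), 50)
})

test_that("histogram mass equals genes with a site within 75 kb", {
  set.seed(121)
  n <- 80
  gs <- sort(sample.int(5e6, n))
  genes <- genes_bed("chr1", gs, gs + 2000,
                     sample(c("+", "-"), n, replace = TRUE))
  sites <- random_intervals(40, chroms = "chr1", max_pos = 5e6,
                            max_len = 600)
  h <- tss_distance_histogram(genes, sites)
  st <- as.character(GenomicRanges::strand(genes))
  tss <- ifelse(st == "+", GenomicRanges::start(genes),
                GenomicRanges::end(genes))
  mid <- (GenomicRanges::start(sites) + GenomicRanges::end(sites)) / 2
  nearest <- vapply(seq_len(n), function(i) {
    d <- mid - tss[i]
    d <- d[which.min(abs(d))]
    if (st[i] == "-") -d else d
  }, numeric(1))
  expect_equal(sum(h$count), sum(nearest >= -75000 & nearest < 75000))
})
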