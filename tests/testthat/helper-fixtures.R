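# Small builders shared across the suite.

# GRanges from BED-convention coordinates (0-based half-open).
gr_bed <- function(chrom, start, end, strand = "*") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end),
                         strand = strand)
}

bed_start <- function(x) GenomicRanges::start(x) - 1L
bed_end <- function(x) GenomicRanges::end(x)

# Gene annotation from BED coordinates with names.
genes_bed <- function(chrom, start, end, strand, name = NULL) {
  g <- gr_bed(chrom, start, end, strand)
  S4Vectors::mcols(g)$name <-
    if (is.null(name)) sprintf("g%02d", seq_along(g)) else name
  g
}

# Random unstranded intervals for brute-force comparisons.
random_intervals <- function(n, chroms = c("chrA", "chrB"), max_pos = 1e6,
                             max_len = 5000) {
  start <- sample.int(max_pos, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  GenomicRanges::GRanges(sample(chroms, n, replace = TRUE),
                         IRanges::IRanges(start, start + len - 1L))
}

# Independent brute-force oracle for the conditional NB exact test:
# direct enumeration in probability space, no shared code with the
# implementation.
brute_exact_test <- function(kA, kB, sA, sB, alpha) {
  S <- kA + kB
  if (S == 0) return(1)
  q <- S / (sA + sB)
  dfun <- function(k, mu) {
    if (alpha == 0) dpois(k, mu) else dnbinom(k, size = 1 / alpha, mu = mu)
  }
  pa <- sapply(0:S, dfun, mu = sA * q)
  pb <- sapply(S:0, dfun, mu = sB * q)
  joint <- pa * pb
  obs <- joint[kA + 1]
  min(1, sum(joint[joint <= obs * (1 + 1e-7)]) / sum(joint))
}
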