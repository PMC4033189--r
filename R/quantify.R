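#' Promoter and gene-body counting windows
#'
#' Derives, strand-aware, the two windows every downstream statistic uses:
#' the promoter window spanning -100 to +400 bp around the annotated TSS and
#' the gene body from 1 kb downstream of the TSS to the end of the
#' annotation (the first kilobase is excluded so promoter-proximal polymerase
#' does not inflate body estimates). Genes of 1 kb or less have no body
#' window and are excluded.
#'
#' For a `+` gene the TSS is `txStart`; for a `-` gene it is the last base
#' of the annotation and the windows are reflected. Promoter windows running
#' off the left end of the chromosome are clipped at 0 and flagged.
#'
#' @param genes GRanges with a `name` metadata column (strand `+`/`-`).
#' @return A list with `promoter` and `body` (parallel GRanges for included
#'   genes, each carrying `name` and `clipped` mcols) and `excluded`
#'   (character vector of names of genes too short to quantify).
#' @export
make_windows <- function(genes) {
  stopifnot(all(as.character(GenomicRanges::strand(genes)) %in% c("+", "-")))
  len <- GenomicRanges::width(genes)
  keep <- len > 1000L
  excluded <- as.character(mcols(genes)$name[!keep])
  g <- genes[keep]
  if (!length(g)) {
    return(list(promoter = GenomicRanges::GRanges(),
                body = GenomicRanges::GRanges(), excluded = excluded))
  }
  chr <- as.character(GenomicRanges::seqnames(g))
  st <- as.character(GenomicRanges::strand(g))
  s <- GenomicRanges::start(g)  # 1-based
  e <- GenomicRanges::end(g)
  plus <- st == "+"
  # BED coords: + promoter [TSS-100, TSS+400), body [txStart+1000, txEnd)
  #             - promoter [TSS-399, TSS+101), body [txStart, txEnd-1000)
  prom_start <- ifelse(plus, s - 100L, e - 399L)
  prom_end <- ifelse(plus, s + 399L, e + 100L)
  clipped <- prom_start < 1L
  prom_start <- pmax(prom_start, 1L)
  body_start <- ifelse(plus, s + 1000L, s)
  body_end <- ifelse(plus, e, e - 1000L)
  promoter <- GenomicRanges::GRanges(chr,
    IRanges::IRanges(prom_start, prom_end), strand = st)
  body <- GenomicRanges::GRanges(chr,
    IRanges::IRanges(body_start, body_end), strand = st)
  mcols(promoter)$name <- mcols(body)$name <- mcols(g)$name
  mcols(promoter)$clipped <- clipped
  list(promoter = promoter, body = body, excluded = excluded)
}

#' Fragments per kilobase per million mapped reads
#'
#' @param count Read count (vectorized).
#' @param window_length Window length in bp.
#' @param total_mapped Mapped-read total of the library.
#' @return `count / (window_length/1000) / (total_mapped/1e6)`.
#' @export
fpkm <- function(count, window_length, total_mapped) {
  if (any(window_length <= 0)) stop("window_length must be > 0")
  if (any(total_mapped <= 0)) stop("total_mapped must be > 0")
  count / (window_length / 1000) / (total_mapped / 1e6)
}

#' Poisson background test for transcriptional activity
#'
#' Tests whether an interval holds more reads than expected from a uniform
#' background in which a fixed fraction of the library is scattered over
#' the genome. The background rate for an interval of length L is
#' `lambda = background_fraction * total_mapped * L / genome_length` and the
#' p-value is the Poisson upper tail `P(X >= N)`. An interval is called
#' active when the observed count is improbable under background
#' (`p <= alpha`); `direction = "above"` inverts the rule for callers that
#' want the complementary convention.
#'
#' @param intervals GRanges of intervals to test (vectorized).
#' @param N Observed read counts, one per interval.
#' @param reads A `ReadSet` supplying `total_mapped` and `genome_length`.
#' @param background_fraction Fraction of the library attributed to
#'   background (default 0.03).
#' @param alpha Significance threshold for the activity call (default 0.01).
#' @param direction `"below"` (default): active iff `p <= alpha`.
#' @return data.frame with columns `N`, `lambda`, `p_value`, `active`.
#' @export
poisson_activity <- function(intervals, N, reads, background_fraction = 0.03,
                             alpha = 0.01, direction = c("below", "above")) {
  direction <- match.arg(direction)
  stopifnot(is(reads, "ReadSet"), length(N) == length(intervals))
  if (reads$genome_length <= 0) stop("genome_length must be > 0")
  if (reads$total_mapped <= 0) stop("total_mapped must be > 0")
  L <- GenomicRanges::width(intervals)
  lambda <- background_fraction * reads$total_mapped * L / reads$genome_length
  p <- stats::ppois(N - 1, lambda, lower.tail = FALSE)  # P(X >= N); N=0 -> 1
  active <- if (direction == "below") p <= alpha else p > alpha
  data.frame(N = as.integer(N), lambda = lambda, p_value = p, active = active)
}

#' Quantify genes over promoter and body windows across samples
#'
#' Strand-specific counts (GRO-seq reads carry the transcription strand)
#' over the windows of [make_windows()], with body fpkm per sample.
#'
#' @param genes GRanges annotation with `name` mcol.
#' @param readsets Named list of `ReadSet`, one per sample.
#' @return data.frame in long format: gene, sample, promoter_count,
#'   body_count, body_fpkm, promoter_length, body_length.
#' @export
quantify_genes <- function(genes, readsets) {
  stopifnot(length(readsets) >= 1, !is.null(names(readsets)))
  w <- make_windows(genes)
  out <- lapply(names(readsets), function(sm) {
    rs <- readsets[[sm]]
    pc <- count_overlapping_reads(w$promoter, rs, strand_specific = TRUE)
    bc <- count_overlapping_reads(w$body, rs, strand_specific = TRUE)
    data.frame(
      gene = mcols(w$body)$name,
      sample = sm,
      promoter_count = pc,
      body_count = bc,
      body_fpkm = fpkm(bc, GenomicRanges::width(w$body), rs$total_mapped),
      promoter_length = GenomicRanges::width(w$promoter),
      body_length = GenomicRanges::width(w$body)
    )
  })
  res <- do.call(rbind, out)
  attr(res, "excluded") <- w$excluded
  res
}

#' Wide gene x sample count matrix from quantify_genes output
#'
#' @param quant Output of [quantify_genes()].
#' @param value Which count to spread (default `body_count`).
#' @return Integer matrix, genes x samples.
#' @export
count_matrix <- function(quant, value = "body_count") {
  genes <- unique(quant$gene)
  samples <- unique(quant$sample)
  m <- matrix(0L, length(genes), length(samples),
              dimnames = list(genes, samples))
  m[cbind(match(quant$gene, genes), match(quant$sample, samples))] <-
    as.integer(quant[[value]])
  m
}
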