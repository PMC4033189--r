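#' RNAPII pausing index
#'
#' The pausing index is the ratio of promoter read density to gene-body
#' read density: `PI = (promoter_count/promoter_length) /
#' (body_count/body_length)`. High values indicate promoter-proximal
#' polymerase pausing. Significance of promoter enrichment comes from a
#' one-sided Fisher's exact test on the 2x2 table
#' `[[promoter_count, promoter_length - promoter_count],
#'   [body_count, body_length - body_count]]`
#' (reads vs remaining bp per window; alternative: promoter density
#' greater). When a window holds more reads than base pairs the remaining-bp
#' cell is floored at 0 and the row flagged `saturated`.
#'
#' @param promoter_count,body_count Read counts (vectorized).
#' @param promoter_length,body_length Window lengths in bp (> 0).
#' @param gene Optional gene ids.
#' @return data.frame: gene, promoter_density, body_density, pausing_index
#'   (NA and `undefined = TRUE` when body_count is 0), enrichment_p,
#'   saturated.
#' @export
pausing_index <- function(promoter_count, promoter_length,
                          body_count, body_length, gene = NULL) {
  if (any(promoter_count < 0) || any(body_count < 0))
    stop("counts must be non-negative")
  if (any(promoter_length <= 0) || any(body_length <= 0))
    stop("window lengths must be > 0")
  n <- length(promoter_count)
  pl <- rep_len(promoter_length, n)
  bl <- rep_len(body_length, n)
  pd <- promoter_count / pl
  bd <- body_count / bl
  pi_ <- ifelse(body_count > 0, pd / bd, NA_real_)
  saturated <- promoter_count > pl | body_count > bl
  p <- vapply(seq_len(n), function(i) {
    tab <- matrix(c(promoter_count[i], max(pl[i] - promoter_count[i], 0),
                    body_count[i], max(bl[i] - body_count[i], 0)),
                  nrow = 2, byrow = TRUE)
    stats::fisher.test(round(tab), alternative = "greater")$p.value
  }, numeric(1))
  data.frame(
    gene = if (is.null(gene)) as.character(seq_len(n)) else gene,
    promoter_density = pd, body_density = bd,
    pausing_index = pi_, undefined = body_count == 0,
    enrichment_p = p, saturated = saturated
  )
}

#' Promoter divergence index
#'
#' Quantifies divergent (antisense, upstream-of-TSS) transcription relative
#' to productive sense transcription. For each gene, the sense count is the
#' number of same-strand reads in the first `window` bp downstream of the
#' TSS and the antisense count the opposite-strand reads in the `window` bp
#' upstream; both windows are strand-reflected for minus-strand genes.
#' `DI = antisense/sense`, so high values sort as highly divergent. Genes
#' with fewer than `min_reads` total reads in the two windows are flagged
#' for exclusion from rankings; sense = 0 leaves DI undefined.
#'
#' @param genes GRanges annotation with `name` mcol.
#' @param reads A `ReadSet`.
#' @param window Window size in bp (default 1000).
#' @param min_reads Minimum sense + antisense reads to rank (default 10).
#' @return data.frame: gene, sense_count, antisense_count, divergence_index,
#'   undefined, low_coverage.
#' @export
divergence_index <- function(genes, reads, window = 1000L, min_reads = 10L) {
  stopifnot(window > 0)
  chr <- as.character(GenomicRanges::seqnames(genes))
  st <- as.character(GenomicRanges::strand(genes))
  plus <- st == "+"
  s <- GenomicRanges::start(genes)
  e <- GenomicRanges::end(genes)
  # + gene, TSS = start: sense [TSS, TSS+w) same strand,
  #   antisense [TSS-w, TSS) opposite strand; reflected for - genes.
  sense_start <- ifelse(plus, s, e - window + 1L)
  sense_end <- ifelse(plus, s + window - 1L, e)
  anti_start <- ifelse(plus, pmax(s - window, 1L), e + 1L)
  anti_end <- ifelse(plus, s - 1L, e + window)
  opp <- ifelse(plus, "-", "+")
  sense_w <- GenomicRanges::GRanges(chr,
    IRanges::IRanges(sense_start, sense_end), strand = st)
  anti_w <- GenomicRanges::GRanges(chr,
    IRanges::IRanges(pmax(anti_start, 1L), pmax(anti_end, 1L)), strand = opp)
  sc <- count_overlapping_reads(sense_w, reads, strand_specific = TRUE)
  ac <- count_overlapping_reads(anti_w, reads, strand_specific = TRUE)
  ac[anti_end < anti_start] <- 0L  # gene flush against the chromosome start
  di <- ifelse(sc > 0, ac / sc, NA_real_)
  data.frame(
    gene = mcols(genes)$name,
    sense_count = sc, antisense_count = ac,
    divergence_index = di,
    undefined = sc == 0,
    low_coverage = (sc + ac) < min_reads
  )
}
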