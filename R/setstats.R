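#' Upper-tail hypergeometric overlap test
#'
#' Probability of drawing at least `k` members of a `K`-sized set when `n`
#' items are drawn without replacement from a universe of `N`. Computed in
#' log space so overlaps far beyond expectation report a finite log p even
#' when the probability underflows double precision.
#'
#' @param N Universe size.
#' @param K Size of the reference set.
#' @param n Number of draws.
#' @param k Observed overlap.
#' @return List: `N`, `K`, `n`, `k`, `expected` (null mean `K*n/N`),
#'   `p_value` (`P(X >= k)`, 0 when below double precision), `log10_p`.
#' @export
hypergeometric_overlap <- function(N, K, n, k) {
  if (!(k >= 0 && k <= min(K, n) && min(K, n) <= N && K <= N && n <= N))
    stop("require 0 <= k <= min(K, n) <= N")
  logp <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE)
  list(N = N, K = K, n = n, k = k,
       expected = K * n / N,
       p_value = exp(logp),
       log10_p = logp / log(10))
}

#' Classify basal transcription between two genotypes
#'
#' Per gene, the ratio of basal (untreated) fpkm in genotype A over
#' genotype B, with a small pseudocount to stabilize ratios at very low
#' expression. Genes above `up_threshold` are basally activated in A,
#' below `down_threshold` basally repressed, the rest neutral.
#'
#' @param fpkm_A,fpkm_B Per-gene basal fpkm in the two genotypes.
#' @param up_threshold Fold threshold for activation (default 2).
#' @param down_threshold Fold threshold for repression (default 0.5).
#' @param pseudocount fpkm added to both values (default 0.1).
#' @param gene Optional gene ids.
#' @return data.frame: gene, ratio, class.
#' @export
basal_classification <- function(fpkm_A, fpkm_B, up_threshold = 2,
                                 down_threshold = 0.5, pseudocount = 0.1,
                                 gene = NULL) {
  stopifnot(up_threshold > 1, down_threshold < 1, down_threshold > 0)
  r <- (fpkm_A + pseudocount) / (fpkm_B + pseudocount)
  cls <- ifelse(r > up_threshold, "basally_activated",
                ifelse(r < down_threshold, "basally_repressed", "neutral"))
  data.frame(
    gene = if (is.null(gene)) as.character(seq_along(r)) else gene,
    ratio = r, class = cls
  )
}

#' Binding-proximity enrichment of a gene set
#'
#' A gene "harbors" a binding site when any site footprint lies within
#' `radius` bp of the gene span (edge to edge; 0 when overlapping). Reports
#' the harboring fraction of the gene set and an upper-tail hypergeometric
#' p-value against the harboring rate in the universe.
#'
#' @param gene_set Character vector of gene names (subset of `universe`).
#' @param genes GRanges annotation with `name` mcol covering the universe.
#' @param sites GRanges of site footprints.
#' @param radius Proximity radius in bp (default 25000).
#' @param universe Character vector of names defining the tested universe;
#'   defaults to all annotated genes.
#' @return List: `fraction`, `n_harboring`, `n_set`, and the
#'   [hypergeometric_overlap()] result under `test`.
#' @export
binding_enrichment <- function(gene_set, genes, sites, radius = 25000,
                               universe = mcols(genes)$name) {
  if (!length(universe)) stop("universe must be non-empty")
  if (!all(gene_set %in% universe)) stop("gene_set must be a subset of universe")
  g <- genes[mcols(genes)$name %in% universe]
  harbors <- rep(FALSE, length(g))
  if (length(sites)) {
    hit <- GenomicRanges::distanceToNearest(g, sites, ignore.strand = TRUE)
    harbors[S4Vectors::queryHits(hit)] <- mcols(hit)$distance <= radius
  }
  names(harbors) <- mcols(g)$name
  in_set <- mcols(g)$name %in% gene_set
  k <- sum(harbors[in_set])
  test <- hypergeometric_overlap(N = length(g), K = sum(harbors),
                                 n = sum(in_set), k = k)
  list(fraction = k / sum(in_set), n_harboring = k, n_set = sum(in_set),
       test = test)
}

#' Read a plain-text gene list (one id per line)
#'
#' @param path File path.
#' @return Character vector of ids; blank lines dropped.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}
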