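#' Consensus binding sites across peak experiments
#'
#' Pools peaks from all experiments, union-merges them (bookended merge, as
#' `bedtools merge`), counts for each merged footprint how many experiments
#' contribute at least one overlapping (>= 1 bp) peak, and keeps footprints
#' with support at or above `min_support` (default 5, the five-of-seven
#' consensus rule).
#'
#' @param peak_sets List of GRanges, one per experiment.
#' @param min_support Minimum number of supporting experiments.
#' @return GRanges of retained merged sites with a `support` mcol. The
#'   total number of merged sites before the support filter is attached as
#'   attribute `n_merged`.
#' @export
consensus_sites <- function(peak_sets, min_support = 5L) {
  stopifnot(length(peak_sets) >= 1, min_support <= length(peak_sets))
  lvls <- unique(unlist(lapply(peak_sets, GenomeInfoDb::seqlevels)))
  pooled <- do.call(c, lapply(peak_sets, function(p) {
    p <- granges(p)
    GenomeInfoDb::seqlevels(p) <- lvls
    p
  }))
  merged <- merge_intervals(pooled, bookended = TRUE)
  support <- Reduce(`+`, lapply(peak_sets, function(p) {
    as.integer(IRanges::overlapsAny(merged, p, minoverlap = 1L,
                                    ignore.strand = TRUE))
  }))
  mcols(merged)$support <- support
  out <- merged[support >= min_support]
  attr(out, "n_merged") <- length(merged)
  out
}

#' Stranded copies of binding-site footprints
#'
#' Each unstranded site footprint yields two stranded records (one per
#' strand) for enhancer-RNA quantification. A stranded record is then
#' dropped when it overlaps (>= 1 bp) an annotated gene on the same strand,
#' since reads there cannot be distinguished from genic transcription; the
#' opposite-strand record and the unstranded footprint survive.
#'
#' @param sites GRanges of site footprints.
#' @param genes GRanges annotation (strands `+`/`-`); may be empty.
#' @return GRanges of all `2 * length(sites)` stranded records with mcols
#'   `site_id` (index into `sites`) and `kept` (FALSE where a same-strand
#'   gene overlap removed the record).
#' @export
stranded_sites <- function(sites, genes = GenomicRanges::GRanges()) {
  if (!length(sites)) {
    out <- GenomicRanges::GRanges()
    mcols(out)$site_id <- integer(0)
    mcols(out)$kept <- logical(0)
    return(out)
  }
  plus <- minus <- granges(sites)
  GenomicRanges::strand(plus) <- "+"
  GenomicRanges::strand(minus) <- "-"
  rec <- c(plus, minus)
  mcols(rec)$site_id <- rep(seq_along(sites), 2L)
  kept <- rep(TRUE, length(rec))
  if (length(genes)) {
    rs <- as.character(GenomicRanges::strand(rec))
    gs <- as.character(GenomicRanges::strand(genes))
    for (s in c("+", "-")) {
      sel <- rs == s
      kept[sel] <- !IRanges::overlapsAny(rec[sel], genes[gs == s],
                                         minoverlap = 1L,
                                         ignore.strand = TRUE)
    }
  }
  mcols(rec)$kept <- kept
  rec
}

#' Categorize sites by distance to genes and to target genes
#'
#' Edge-to-edge distance (0 when overlapping) between each site footprint
#' and the nearest annotated gene, and the nearest target gene. A site
#' farther than `radius` from every gene is `distal`; otherwise it is
#' `proximal_target` when any target gene lies within `radius` (targets
#' take precedence) and `proximal_non_target` otherwise.
#'
#' @param sites GRanges of site footprints.
#' @param genes GRanges annotation with `name` mcol.
#' @param targets Character vector of target gene names.
#' @param radius Distance cutoff in bp (default 25000).
#' @return `sites` with mcols `dist_gene`, `dist_target` (Inf when no such
#'   gene shares the chromosome) and `category`.
#' @export
categorize_sites <- function(sites, genes, targets, radius = 25000) {
  stopifnot(radius > 0)
  if (!length(genes)) {
    warning("empty annotation: all sites categorized as distal")
    mcols(sites)$dist_gene <- rep(Inf, length(sites))
    mcols(sites)$dist_target <- rep(Inf, length(sites))
    mcols(sites)$category <- rep("distal", length(sites))
    return(sites)
  }
  dist_to <- function(subjects) {
    d <- rep(Inf, length(sites))
    if (!length(subjects)) return(d)
    hit <- GenomicRanges::distanceToNearest(sites, subjects,
                                            ignore.strand = TRUE)
    d[S4Vectors::queryHits(hit)] <- mcols(hit)$distance
    d
  }
  dg <- dist_to(genes)
  dt <- dist_to(genes[mcols(genes)$name %in% targets])
  cat_ <- ifelse(dg > radius, "distal",
                 ifelse(dt <= radius, "proximal_target", "proximal_non_target"))
  mcols(sites)$dist_gene <- dg
  mcols(sites)$dist_target <- dt
  mcols(sites)$category <- cat_
  sites
}

#' Quantify enhancer RNA on stranded site records
#'
#' For each surviving stranded record and each sample: the strand-matched
#' read count, fpkm, and the Poisson background activity call. Per site and
#' sample, the site is active when either surviving strand is active
#' (logical OR). For each requested comparison `c(A, B)`, fpkm fold changes
#' (B over A) are computed only over records with a positive count in both
#' samples, since a zero denominator or numerator carries no ratio
#' information.
#'
#' @param records Output of [stranded_sites()] (records with `kept = FALSE`
#'   are ignored).
#' @param readsets Named list of `ReadSet`, one per sample.
#' @param background_fraction Background fraction for the activity call.
#' @param alpha Activity significance threshold.
#' @param comparisons List of length-2 character vectors `c(A, B)` naming
#'   samples to contrast; may be empty.
#' @return List: `records` (long data.frame record x sample with count,
#'   fpkm, lambda, p_value, active), `sites` (site_id x sample OR-combined
#'   activity), `folds` (comparison, site_id, strand, fold_change).
#' @export
erna_quantify <- function(records, readsets, background_fraction = 0.03,
                          alpha = 0.01, comparisons = list()) {
  stopifnot(!is.null(names(readsets)))
  rec <- records[mcols(records)$kept]
  per_sample <- lapply(names(readsets), function(sm) {
    rs <- readsets[[sm]]
    n <- count_overlapping_reads(rec, rs, strand_specific = TRUE)
    act <- poisson_activity(rec, n, rs, background_fraction, alpha)
    data.frame(
      site_id = mcols(rec)$site_id,
      strand = as.character(GenomicRanges::strand(rec)),
      sample = sm,
      count = n,
      fpkm = fpkm(n, GenomicRanges::width(rec), rs$total_mapped),
      lambda = act$lambda, p_value = act$p_value, active = act$active
    )
  })
  long <- do.call(rbind, per_sample)
  sites <- stats::aggregate(active ~ site_id + sample, data = long, FUN = any)
  folds <- list()
  for (cmp in comparisons) {
    a <- long[long$sample == cmp[1], c("site_id", "strand", "count", "fpkm")]
    b <- long[long$sample == cmp[2], c("site_id", "strand", "count", "fpkm")]
    m <- merge(a, b, by = c("site_id", "strand"), suffixes = c("_A", "_B"))
    m <- m[m$count_A > 0 & m$count_B > 0, ]
    if (nrow(m)) {
      folds[[length(folds) + 1L]] <- data.frame(
        comparison = paste(cmp[2], "vs", cmp[1]),
        site_id = m$site_id, strand = m$strand,
        fold_change = m$fpkm_B / m$fpkm_A)
    }
  }
  list(records = long, sites = sites,
       folds = if (length(folds)) do.call(rbind, folds) else
         data.frame(comparison = character(0), site_id = integer(0),
                    strand = character(0), fold_change = numeric(0)))
}

#' Histogram of signed distances from TSS to nearest binding site
#'
#' For each gene, the signed distance from its TSS to the midpoint of the
#' nearest site, oriented so positive means downstream in the gene's
#' reading direction (the sign flips for minus-strand genes). Distances are
#' binned as in the source analysis: 1-kb bins across the inner
#' +/- 25 kb, flanked on each side by ten 5-kb bins out to +/- 75 kb;
#' genes whose nearest site is beyond +/- 75 kb are dropped.
#'
#' @param genes GRanges annotation.
#' @param sites GRanges of site footprints (non-empty).
#' @return data.frame with `bin_start`, `bin_end` (bp, left-closed
#'   right-open) and `count`.
#' @export
tss_distance_histogram <- function(genes, sites) {
  if (!length(sites)) stop("sites must be non-empty")
  st <- as.character(GenomicRanges::strand(genes))
  tss <- ifelse(st == "+", GenomicRanges::start(genes),
                GenomicRanges::end(genes))
  mid <- (GenomicRanges::start(sites) + GenomicRanges::end(sites)) / 2
  site_chr <- as.character(GenomicRanges::seqnames(sites))
  gene_chr <- as.character(GenomicRanges::seqnames(genes))
  signed <- vapply(seq_along(genes), function(i) {
    on <- which(site_chr == gene_chr[i])
    if (!length(on)) return(NA_real_)
    d <- mid[on] - tss[i]
    d <- d[which.min(abs(d))]
    if (st[i] == "-") -d else d
  }, numeric(1))
  breaks <- unique(c(seq(-75000, -25000, by = 5000),
                     seq(-25000, 25000, by = 1000),
                     seq(25000, 75000, by = 5000)))
  signed <- signed[!is.na(signed) & signed >= -75000 & signed < 75000]
  cnt <- hist(signed, breaks = breaks, right = FALSE, plot = FALSE)$counts
  data.frame(bin_start = breaks[-length(breaks)], bin_end = breaks[-1],
             count = cnt)
}
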