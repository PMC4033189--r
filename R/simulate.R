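#' Configuration for the synthetic GRO-seq generator
#'
#' Encodes the emulated study conditions: a four-condition design (two
#' genotypes x treated/control), genes with planted negative-binomial
#' expression, induction restricted to the treated wild-type condition,
#' promoter-proximal pausing and upstream divergent transcription, a
#' uniform read background, bidirectionally transcribed enhancer sites, and
#' seven noisy replicate peak experiments over a shared set of true binding
#' sites.
#'
#' @param seed RNG seed.
#' @param n_genes Number of genes.
#' @param genome_length Reference length in bp.
#' @param gene_length_range Min/max gene length in bp.
#' @param n_samples_per_condition Replicates per condition.
#' @param reads_per_sample Reads emitted per sample (exact).
#' @param background_fraction Expected fraction of reads placed uniformly.
#' @param induced_fraction Fraction of genes planted as induced.
#' @param induced_fold Fold change of induced genes in treated wild type.
#' @param dispersion Negative-binomial dispersion alpha (variance
#'   `mu + alpha*mu^2`) of per-gene library-level noise.
#' @param pausing_ratio_range Range of planted promoter/body density ratios.
#' @param divergence_ratio_range Range of planted antisense/sense ratios.
#' @param n_sites Number of enhancer binding sites.
#' @param site_width Site footprint width in bp.
#' @param site_active_fraction Fraction of sites planted as transcribed.
#' @param erna_reads_per_active_site Mean reads per active stranded site.
#' @param site_near_target_fraction Fraction of sites placed within 25 kb of
#'   an induced gene.
#' @param target_site_active_fraction Active probability for near-target
#'   sites (pre-activated enhancer contrast).
#' @param n_peak_experiments Number of peak experiments.
#' @param peak_dropout Probability a true site is missing from one
#'   experiment.
#' @param false_peak_rate Mean spurious peaks per experiment.
#' @param read_length Read length in bp.
#' @param n_chroms Number of synthetic chromosomes.
#' @return A validated list of class `SimConfig`.
#' @export
sim_config <- function(seed = 1L, n_genes = 500L, genome_length = 5e7,
                       gene_length_range = c(2000L, 10000L),
                       n_samples_per_condition = 2L,
                       reads_per_sample = 1e6,
                       background_fraction = 0.03,
                       induced_fraction = 0.1, induced_fold = 6,
                       dispersion = 0.05,
                       pausing_ratio_range = c(2, 20),
                       divergence_ratio_range = c(0.1, 2),
                       n_sites = 200L, site_width = 600L,
                       site_active_fraction = 0.3,
                       erna_reads_per_active_site = 50,
                       site_near_target_fraction = 0.15,
                       target_site_active_fraction = 0.9,
                       n_peak_experiments = 7L, peak_dropout = 0.1,
                       false_peak_rate = 20,
                       read_length = 50L, n_chroms = 1L) {
  cfg <- as.list(environment())
  props <- c("background_fraction", "induced_fraction",
             "site_active_fraction", "site_near_target_fraction",
             "target_site_active_fraction", "peak_dropout")
  for (p in props) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must lie in [0, 1]")
  }
  stopifnot(n_genes >= 0, n_sites >= 0, induced_fold > 0, dispersion >= 0,
            reads_per_sample >= 0, genome_length > 0, read_length >= 1,
            gene_length_range[1] > 1000, n_peak_experiments >= 1,
            false_peak_rate >= 0)
  class(cfg) <- "SimConfig"
  cfg
}

#' Simulate a full GRO-seq dataset with planted ground truth
#'
#' Generates, deterministically for a given config (identical seed, byte
#' identical output): a gene annotation with no overlapping genes, one
#' `ReadSet` per sample across the four conditions (`wt_ctl`, `wt_trt`,
#' `ko_ctl`, `ko_trt`), peak sets for each peak experiment, and a `SimTruth`
#' ledger of every planted parameter. Per sample, exactly
#' `reads_per_sample` reads are emitted: a Binomial(R, background_fraction)
#' number of uniform background reads, with the remainder distributed
#' multinomially over gene and active-enhancer components. Per-sample gene
#' weights are Gamma-randomized around `baseline x fold`, so per-gene
#' counts are (approximately) negative binomial with the configured
#' dispersion — the same mean/variance law the differential module fits.
#' Within a gene, reads split between the promoter window, the gene body
#' and an upstream antisense component according to the planted pausing and
#' divergence ratios.
#'
#' @param config A [sim_config()].
#' @return List: `annotation` (GRanges with `name`), `readsets` (named list
#'   of `ReadSet`), `conditions` (named character: sample -> condition),
#'   `peaks` (list of GRanges), `truth` (list with `gene_truth`,
#'   `site_truth`, `peak_truth` data.frames), `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  G <- config$genome_length
  rl <- config$read_length
  chrom_len <- rep(floor(G / config$n_chroms), config$n_chroms)
  chrom_len[config$n_chroms] <- G - sum(chrom_len[-config$n_chroms])
  chroms <- paste0("chrS", seq_len(config$n_chroms))

  ## -- gene placement: sequential with random gaps, no overlap at all
  len <- round(stats::runif(config$n_genes, config$gene_length_range[1],
                            config$gene_length_range[2]))
  per_chrom <- split(seq_len(config$n_genes),
                     rep_len(seq_len(config$n_chroms), config$n_genes))
  gene_chrom <- character(config$n_genes)
  gene_start <- numeric(config$n_genes)  # 1-based
  margin <- 2000  # room for promoter/antisense windows at either end
  for (ci in seq_along(per_chrom)) {
    idx <- per_chrom[[ci]]
    if (!length(idx)) next
    need <- sum(len[idx]) + 2 * margin
    free <- chrom_len[ci] - need
    if (free < length(idx))
      stop("genome too small to place ", config$n_genes,
           " genes without overlap")
    cuts <- sort(stats::runif(length(idx)))
    gaps <- diff(c(0, cuts)) * free
    gene_start[idx] <- margin + cumsum(gaps) + cumsum(c(0, len[idx[-length(idx)]])) + 1
    gene_chrom[idx] <- chroms[ci]
  }
  gene_start <- round(gene_start)
  gene_end <- gene_start + len - 1
  gene_strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
  gene_name <- sprintf("gene_%04d", seq_len(config$n_genes))
  annotation <- GenomicRanges::GRanges(gene_chrom,
    IRanges::IRanges(gene_start, gene_end), strand = gene_strand)
  mcols(annotation)$name <- gene_name

  ## -- planted per-gene parameters
  n_ind <- round(config$induced_fraction * config$n_genes)
  induced <- rep(FALSE, config$n_genes)
  if (n_ind > 0) induced[sample.int(config$n_genes, n_ind)] <- TRUE
  baseline <- stats::rlnorm(config$n_genes, meanlog = log(100), sdlog = 0.8)
  pausing <- stats::runif(config$n_genes, config$pausing_ratio_range[1],
                          config$pausing_ratio_range[2])
  divergence <- stats::runif(config$n_genes,
                             config$divergence_ratio_range[1],
                             config$divergence_ratio_range[2])

  ## -- enhancer sites: a fraction near induced ("target") genes, rest uniform
  n_near <- if (any(induced))
    round(config$site_near_target_fraction * config$n_sites) else 0L
  site_start <- numeric(config$n_sites)
  site_chrom <- character(config$n_sites)
  near_target <- rep(FALSE, config$n_sites)
  if (n_near > 0) {
    anchor <- sample(which(induced), n_near, replace = TRUE)
    off <- round(stats::runif(n_near, -25000 + config$site_width, 25000)) # edge within 25 kb
    site_start[seq_len(n_near)] <- ifelse(off < 0,
      gene_start[anchor] + off - config$site_width,
      gene_end[anchor] + off)
    site_chrom[seq_len(n_near)] <- gene_chrom[anchor]
    near_target[seq_len(n_near)] <- TRUE
  }
  if (config$n_sites > n_near) {
    rest <- (n_near + 1):config$n_sites
    ci <- sample.int(config$n_chroms, length(rest), replace = TRUE,
                     prob = chrom_len)
    site_chrom[rest] <- chroms[ci]
    site_start[rest] <- round(stats::runif(length(rest), 1,
                                           chrom_len[ci] - config$site_width))
  }
  site_start <- pmax(round(site_start), 1)
  sites <- GenomicRanges::GRanges(site_chrom,
    IRanges::IRanges(site_start, site_start + config$site_width - 1))
  p_active <- ifelse(near_target, config$target_site_active_fraction,
                     config$site_active_fraction)
  site_active <- stats::runif(config$n_sites) < p_active

  ## -- samples
  cond_levels <- c("wt_ctl", "wt_trt", "ko_ctl", "ko_trt")
  samples <- unlist(lapply(cond_levels, function(cn)
    paste0(cn, "_rep", seq_len(config$n_samples_per_condition))))
  conditions <- rep(cond_levels, each = config$n_samples_per_condition)
  names(conditions) <- samples
  fold <- matrix(1, config$n_genes, length(cond_levels),
                 dimnames = list(gene_name, cond_levels))
  fold[induced, "wt_trt"] <- config$induced_fold

  active_ids <- which(site_active)
  n_active_rec <- 2L * length(active_ids)
  site_weight <- rep(config$erna_reads_per_active_site, n_active_rec)
  R <- config$reads_per_sample

  readsets <- lapply(samples, function(sm) {
    cn <- conditions[[sm]]
    n_bg <- stats::rbinom(1, R, config$background_fraction)
    n_sig <- R - n_bg
    mu <- baseline * fold[, cn]
    gene_budget <- max(R * (1 - config$background_fraction) -
                         sum(site_weight), 1)
    mu <- mu / sum(mu) * gene_budget
    gw <- if (config$dispersion > 0)
      stats::rgamma(config$n_genes, shape = 1 / config$dispersion,
                    rate = 1 / (config$dispersion * mu))
    else mu
    w <- c(gw, site_weight)
    if (!length(w)) {
      if (n_sig > 0)
        stop("no genes or active sites to absorb signal reads; ",
             "set background_fraction = 1 for a pure-background dataset")
      alloc <- numeric(0)
    } else {
      alloc <- as.vector(stats::rmultinom(1, n_sig, prob = w))
    }
    gene_n <- alloc[seq_len(config$n_genes)]
    site_n <- alloc[setdiff(seq_along(alloc), seq_len(config$n_genes))]
    .emit_reads(config, chroms, chrom_len, gene_chrom, gene_start, gene_end,
                gene_strand, len, pausing, divergence, gene_n,
                sites, active_ids, site_n, n_bg)
  })
  names(readsets) <- samples

  ## -- peak experiments over the true sites
  peak_truth <- list()
  peaks <- lapply(seq_len(config$n_peak_experiments), function(ex) {
    emit <- which(stats::runif(config$n_sites) >= config$peak_dropout)
    js <- pmax(site_start[emit] + round(stats::rnorm(length(emit), 0, 25)), 1)
    je <- pmax(site_start[emit] + config$site_width - 1 +
                 round(stats::rnorm(length(emit), 0, 25)), js + 50)
    nf <- stats::rpois(1, config$false_peak_rate)
    fci <- sample.int(config$n_chroms, nf, replace = TRUE, prob = chrom_len)
    fw <- round(stats::runif(nf, 200, 1000))
    fs <- round(stats::runif(nf, 1, chrom_len[fci] - fw))
    peak_truth[[ex]] <<- data.frame(experiment = rep(ex, length(emit)),
                                    site_id = emit)
    GenomicRanges::GRanges(c(site_chrom[emit], chroms[fci]),
                           IRanges::IRanges(c(js, fs), c(je, fs + fw - 1)))
  })

  truth <- list(
    gene_truth = data.frame(
      gene = gene_name, chrom = gene_chrom, strand = gene_strand,
      txStart = gene_start - 1L, txEnd = gene_end,
      baseline = baseline, induced = induced,
      fold_wt_trt = fold[, "wt_trt"],
      pausing_ratio = pausing, divergence_ratio = divergence),
    site_truth = data.frame(
      site_id = seq_len(config$n_sites), chrom = site_chrom,
      start = site_start - 1L, end = site_start + config$site_width - 1L,
      active = site_active, near_target = near_target,
      erna_rate = ifelse(site_active, config$erna_reads_per_active_site, 0)),
    peak_truth = do.call(rbind, peak_truth))

  list(annotation = annotation, readsets = readsets, conditions = conditions,
       peaks = peaks, truth = truth, config = config)
}

# Place reads for one sample. Gene reads split promoter/body/antisense by
# the planted ratios; the antisense weight anticipates that ~80% of
# promoter-window reads fall downstream of the TSS (the sense side of the
# divergence windows).
.emit_reads <- function(config, chroms, chrom_len, gene_chrom, gene_start,
                        gene_end, gene_strand, len, pausing, divergence,
                        gene_n, sites, active_ids, site_n, n_bg) {
  rl <- config$read_length
  chr_out <- list(); start_out <- list(); strand_out <- list()
  push <- function(chr, st, sd) {
    if (!length(st)) return()
    i <- length(chr_out) + 1L
    chr_out[[i]] <<- rep_len(chr, length(st))
    start_out[[i]] <<- st
    strand_out[[i]] <<- rep_len(sd, length(st))
  }
  uniform_in <- function(n, lo, hi) {
    lo <- pmax(lo, 1)
    lo + floor(stats::runif(n) * pmax(hi - lo + 1, 1))
  }
  for (i in seq_along(gene_n)) {
    n <- gene_n[i]
    if (n == 0) next
    Lb <- len[i] - 1000
    uB <- 1
    uP <- pausing[i] * 500 / Lb
    uA <- divergence[i] * 0.8 * uP
    split3 <- as.vector(stats::rmultinom(1, n, prob = c(uP, uB, uA)))
    s <- gene_start[i]; e <- gene_end[i]
    if (gene_strand[i] == "+") {
      push(gene_chrom[i], uniform_in(split3[1], s - 100, s + 399), "+")
      push(gene_chrom[i], uniform_in(split3[2], s + 1000, e), "+")
      push(gene_chrom[i], uniform_in(split3[3], s - 1000, s - 1), "-")
    } else {
      push(gene_chrom[i], uniform_in(split3[1], e - 399, e + 100), "-")
      push(gene_chrom[i], uniform_in(split3[2], s, e - 1000), "-")
      push(gene_chrom[i], uniform_in(split3[3], e + 1, e + 1000), "+")
    }
  }
  if (length(active_ids)) {
    rec_site <- rep(active_ids, 2L)
    rec_strand <- rep(c("+", "-"), each = length(active_ids))
    for (j in seq_along(rec_site)) {
      n <- site_n[j]
      if (n == 0) next
      sid <- rec_site[j]
      push(as.character(GenomicRanges::seqnames(sites)[sid]),
           uniform_in(n, GenomicRanges::start(sites)[sid],
                      GenomicRanges::end(sites)[sid]),
           rec_strand[j])
    }
  }
  if (n_bg > 0) {
    ci <- sample.int(length(chroms), n_bg, replace = TRUE, prob = chrom_len)
    push(chroms[ci], uniform_in(n_bg, 1, chrom_len[ci] - rl),
         sample(c("+", "-"), n_bg, replace = TRUE))
  }
  chr <- unlist(chr_out, use.names = FALSE)
  st <- unlist(start_out, use.names = FALSE)
  sd <- unlist(strand_out, use.names = FALSE)
  maxlen <- stats::setNames(chrom_len, chroms)[chr]
  st <- pmin(pmax(st, 1), maxlen - rl)
  reads <- GenomicRanges::GRanges(chr, IRanges::IRanges(st, st + rl - 1),
                                  strand = sd)
  read_set(reads, total_mapped = config$reads_per_sample,
           genome_length = config$genome_length)
}

#' Write a simulated dataset as plain-text fixture files
#'
#' Emits `annotation.tsv` (refGene-style), one BED6 read file per sample
#' (`reads_<sample>.bed`), one BED3 peak file per experiment
#' (`peaks_<k>.bed`), the three truth tables (`gene_truth.tsv`,
#' `site_truth.tsv`, `peak_truth.tsv`) and a `config.json` echo.
#' [read_fixture()] reconstructs the in-memory objects.
#'
#' @param dataset Output of [simulate_dataset()].
#' @param directory Writable output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_fixture <- function(dataset, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) stop("cannot create directory ", directory)
  write_refgene(dataset$annotation, file.path(directory, "annotation.tsv"))
  for (sm in names(dataset$readsets)) {
    write_bed(dataset$readsets[[sm]]$reads,
              file.path(directory, paste0("reads_", sm, ".bed")))
  }
  for (k in seq_along(dataset$peaks)) {
    write_bed(dataset$peaks[[k]],
              file.path(directory, sprintf("peaks_%d.bed", k)))
  }
  for (tb in names(dataset$truth)) {
    data.table::fwrite(dataset$truth[[tb]],
                       file.path(directory, paste0(tb, ".tsv")), sep = "\t")
  }
  cfg <- dataset$config
  class(cfg) <- NULL
  jsonlite::write_json(c(cfg, list(conditions = as.list(dataset$conditions))),
                       file.path(directory, "config.json"), auto_unbox = TRUE)
  invisible(directory)
}

#' Read a fixture directory written by [write_fixture()]
#'
#' @param directory Fixture directory.
#' @return The same structure [simulate_dataset()] returns.
#' @export
read_fixture <- function(directory) {
  cfg <- jsonlite::read_json(file.path(directory, "config.json"),
                             simplifyVector = TRUE)
  conditions <- unlist(cfg$conditions)
  cfg$conditions <- NULL
  cfg$gene_length_range <- as.numeric(cfg$gene_length_range)
  cfg$pausing_ratio_range <- as.numeric(cfg$pausing_ratio_range)
  cfg$divergence_ratio_range <- as.numeric(cfg$divergence_ratio_range)
  class(cfg) <- "SimConfig"
  annotation <- read_refgene(file.path(directory, "annotation.tsv"))
  readsets <- lapply(names(conditions), function(sm) {
    read_set(read_bed(file.path(directory, paste0("reads_", sm, ".bed"))),
             total_mapped = cfg$reads_per_sample,
             genome_length = cfg$genome_length)
  })
  names(readsets) <- names(conditions)
  peak_files <- sort(list.files(directory, "^peaks_\\d+\\.bed$",
                                full.names = TRUE))
  peaks <- lapply(peak_files, read_bed)
  truth <- lapply(c(gene_truth = "gene_truth", site_truth = "site_truth",
                    peak_truth = "peak_truth"), function(tb) {
    data.table::fread(file.path(directory, paste0(tb, ".tsv")),
                      sep = "\t", data.table = FALSE)
  })
  list(annotation = annotation, readsets = readsets, conditions = conditions,
       peaks = peaks, truth = truth, config = cfg)
}
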