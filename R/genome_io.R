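#' @importFrom GenomicRanges GRanges granges reduce countOverlaps coverage
#'   distanceToNearest distance findOverlaps strand start end width seqnames
#' @importFrom IRanges IRanges subsetByOverlaps overlapsAny
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
#' @importFrom methods is
NULL

#' Read a BED file into a GRanges
#'
#' Parses BED3/BED6 (tab-separated, 0-based half-open). The strand is taken
#' from field 6 when present and valid; otherwise intervals are unstranded
#' (`*`). Comment (`#`), `track` and `browser` lines and blank lines are
#' skipped. Coordinates are validated; a malformed line raises an error that
#' names its line number.
#'
#' Internally coordinates are stored 1-based closed (the GRanges convention),
#' so a BED record `start end` becomes `[start+1, end]`. All functions in
#' this package that write BED or report BED-convention coordinates undo the
#' shift.
#'
#' @param path Path to a BED file.
#' @param min_fields Minimum number of tab-separated fields required on each
#'   data line (default 3).
#' @return A [GenomicRanges::GRanges] with one range per data line.
#' @export
read_bed <- function(path, min_fields = 3L) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  if (!any(keep)) return(GenomicRanges::GRanges())
  idx <- which(keep)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < min_fields)) {
    bad <- idx[which(nf < min_fields)[1]]
    stop(sprintf("line %d: expected >= %d tab-separated fields", bad, min_fields))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  s <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  e <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(s) | is.na(e) | s < 0L | s >= e | !nzchar(chrom))
  if (length(bad)) {
    stop(sprintf("line %d: malformed BED coordinates '%s'",
                 idx[bad[1]], lines[idx[bad[1]]]))
  }
  strand <- rep("*", length(fields))
  has6 <- nf >= 6L
  if (any(has6)) {
    s6 <- vapply(fields[has6], `[[`, "", 6L)
    s6[!s6 %in% c("+", "-")] <- "*"
    strand[has6] <- s6
  }
  GenomicRanges::GRanges(chrom, IRanges::IRanges(s + 1L, e), strand = strand)
}

#' Write intervals as BED6
#'
#' @param x A GRanges.
#' @param path Output path.
#' @param name Optional names column (recycled); defaults to `.`.
#' @export
write_bed <- function(x, path, name = ".") {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(x)),
    start = GenomicRanges::start(x) - 1L,
    end = GenomicRanges::end(x),
    name = rep_len(name, length(x)),
    score = 0L,
    strand = sub("\\*", ".", as.character(GenomicRanges::strand(x)))
  )
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a refGene-style annotation table
#'
#' Expects a tab-separated table with a header containing at least the
#' columns `name`, `chrom`, `strand`, `txStart`, `txEnd` (UCSC refGene
#' convention: txStart 0-based, txEnd exclusive).
#'
#' @param path Path to the annotation table.
#' @return A GRanges with a `name` metadata column; strand is always `+` or
#'   `-`.
#' @export
read_refgene <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  need <- c("name", "chrom", "strand", "txStart", "txEnd")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("annotation table missing columns: ",
                         paste(miss, collapse = ", "))
  if (!all(dt$strand %in% c("+", "-"))) stop("gene strand must be + or -")
  if (any(dt$txEnd <= dt$txStart)) stop("gene with txEnd <= txStart")
  gr <- GenomicRanges::GRanges(dt$chrom,
                               IRanges::IRanges(dt$txStart + 1L, dt$txEnd),
                               strand = dt$strand)
  mcols(gr)$name <- dt$name
  gr
}

#' Write a refGene-style annotation table
#'
#' @param genes GRanges with a `name` metadata column.
#' @param path Output path.
#' @export
write_refgene <- function(genes, path) {
  df <- data.frame(
    name = mcols(genes)$name,
    chrom = as.character(GenomicRanges::seqnames(genes)),
    strand = as.character(GenomicRanges::strand(genes)),
    txStart = GenomicRanges::start(genes) - 1L,
    txEnd = GenomicRanges::end(genes)
  )
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Construct a read set
#'
#' Bundles mapped reads with the two normalization constants every
#' depth-aware computation needs: the mapped-read total (the
#' per-million denominator of fpkm and bedGraph scaling) and the reference
#' genome length (the denominator of the uniform Poisson background rate).
#'
#' @param reads GRanges of mapped reads (stranded).
#' @param total_mapped Number of mapped reads; defaults to `length(reads)`.
#' @param genome_length Total reference length in bp.
#' @return An object of class `ReadSet`.
#' @export
read_set <- function(reads, total_mapped = length(reads), genome_length) {
  stopifnot(is(reads, "GRanges"), genome_length > 0)
  if (total_mapped < 0) stop("total_mapped must be >= 0")
  structure(list(reads = reads,
                 total_mapped = as.numeric(total_mapped),
                 genome_length = as.numeric(genome_length)),
            class = "ReadSet")
}

#' @export
print.ReadSet <- function(x, ...) {
  cat(sprintf("ReadSet: %d reads stored, %.0f mapped, genome %.0f bp\n",
              length(x$reads), x$total_mapped, x$genome_length))
  invisible(x)
}

#' Merge intervals into maximal union intervals
#'
#' Strand is ignored (binding-site footprints are strandless). With
#' `bookended = TRUE` (the default, matching `bedtools merge`), touching
#' intervals (one ends exactly where the next starts) also merge.
#'
#' @param x GRanges.
#' @param bookended Merge bookended intervals too?
#' @return Sorted, strand-stripped GRanges of merged intervals.
#' @export
merge_intervals <- function(x, bookended = TRUE) {
  gr <- granges(x)
  GenomicRanges::strand(gr) <- "*"
  GenomicRanges::reduce(sort(gr),
                        min.gapwidth = if (bookended) 1L else 0L)
}

#' Distance to the nearest interval
#'
#' Edge-to-edge gap in bp between `query` and its nearest subject on the
#' same chromosome (0 if they overlap), ignoring strand. Ties are broken by
#' the leftmost subject start. When no subject shares the query's
#' chromosome the distance is `Inf` and the subject index is `NA`, so
#' downstream categorization can treat such queries as maximally distal.
#'
#' @param query A single-range GRanges.
#' @param subjects Non-empty GRanges.
#' @return A list with `distance` (bp, possibly `Inf`) and `subject` (index
#'   into `subjects`, or `NA`).
#' @export
closest_distance <- function(query, subjects) {
  stopifnot(length(query) == 1L)
  if (length(subjects) == 0L) stop("subjects must be non-empty")
  same <- which(as.character(GenomicRanges::seqnames(subjects)) ==
                as.character(GenomicRanges::seqnames(query)))
  if (!length(same)) return(list(distance = Inf, subject = NA_integer_))
  d <- GenomicRanges::distance(rep(granges(query), length(same)),
                               granges(subjects)[same], ignore.strand = TRUE)
  dmin <- min(d)
  cand <- same[d == dmin]
  best <- cand[which.min(GenomicRanges::start(subjects)[cand])]
  list(distance = as.numeric(dmin), subject = best)
}

#' Count reads overlapping a window
#'
#' A read counts if it overlaps the window by at least 1 bp (coverageBed
#' default). With `strand_specific = TRUE` only reads on the window's strand
#' count; an unstranded (`*`) window counts both strands regardless.
#'
#' @param windows GRanges of counting windows (vectorized).
#' @param reads A `ReadSet` or a GRanges of reads.
#' @param strand_specific Restrict to reads matching each window's strand?
#' @return Integer vector of counts, one per window.
#' @export
count_overlapping_reads <- function(windows, reads, strand_specific = TRUE) {
  rd <- if (is(reads, "ReadSet")) reads$reads else reads
  n <- GenomicRanges::countOverlaps(windows, rd, minoverlap = 1L,
                                    ignore.strand = TRUE)
  if (strand_specific) {
    ws <- as.character(GenomicRanges::strand(windows))
    stranded <- ws %in% c("+", "-")
    if (any(stranded)) {
      rs <- as.character(GenomicRanges::strand(rd))
      for (s in c("+", "-")) {
        sel <- which(ws == s)
        if (length(sel)) {
          n[sel] <- GenomicRanges::countOverlaps(
            windows[sel], rd[rs == s], minoverlap = 1L, ignore.strand = TRUE)
        }
      }
    }
  }
  as.integer(n)
}

#' Write depth-normalized strand-split coverage as bedGraph
#'
#' Per-base coverage is computed per strand, divided by the mapped-read
#' total in millions, and written as a 4-column bedGraph in which
#' minus-strand values carry a negative sign so both strands display in one
#' track.
#'
#' @param reads A `ReadSet`; `total_mapped` must be positive.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_bedgraph <- function(reads, path) {
  stopifnot(is(reads, "ReadSet"))
  if (reads$total_mapped <= 0) stop("total_mapped must be > 0")
  denom <- reads$total_mapped / 1e6
  out <- list()
  for (s in c("+", "-")) {
    sel <- reads$reads[as.character(GenomicRanges::strand(reads$reads)) == s]
    if (!length(sel)) next
    cov <- GenomicRanges::coverage(sel)
    for (chr in names(cov)) {
      r <- cov[[chr]]
      v <- S4Vectors::runValue(r)
      l <- S4Vectors::runLength(r)
      ends <- cumsum(l)
      starts <- ends - l  # 0-based bedGraph starts
      nz <- v > 0
      if (!any(nz)) next
      val <- v[nz] / denom
      if (s == "-") val <- -val
      out[[length(out) + 1L]] <- data.frame(
        chrom = chr, start = starts[nz], end = ends[nz], value = val)
    }
  }
  if (!length(out)) {
    file.create(path)
  } else {
    data.table::fwrite(data.table::rbindlist(out), path, sep = "\t",
                       col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
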