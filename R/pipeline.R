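#' Run the full analysis pipeline on a dataset
#'
#' Composes the stages end to end on an in-memory dataset (simulated or
#' loaded from a fixture directory): gene quantification over promoter and
#' body windows, differential-transcription calling between treated and
#' control wild type, pausing and divergence indices, consensus-site
#' construction from the peak experiments, the stranded eRNA analysis with
#' distance categorization, the TSS-distance histogram, and
#' binding-proximity enrichment of the called gene set. All parameter
#' defaults are the analysis constants used throughout the package (padj
#' 0.1, background 3%, activity alpha 0.01, consensus support 5, proximity
#' 25 kb).
#'
#' @param dataset Output of [simulate_dataset()] or [read_fixture()].
#' @param out_dir Optional directory; when given, every result table is
#'   written there as TSV along with a `manifest.json` echoing the
#'   parameters.
#' @param padj_threshold Adjusted-p cutoff for differential calling.
#' @param background_fraction Background fraction for activity calls.
#' @param activity_alpha Significance threshold for activity calls.
#' @param min_support Consensus-site support cutoff.
#' @param radius Proximity radius in bp for categorization and enrichment.
#' @param divergence_window Window for the divergence index, bp.
#' @return List of result tables: `quant`, `de`, `pausing`, `divergence`,
#'   `sites`, `stranded`, `erna`, `histogram`, `enrichment`.
#' @export
run_pipeline <- function(dataset, out_dir = NULL, padj_threshold = 0.1,
                         background_fraction = 0.03, activity_alpha = 0.01,
                         min_support = 5L, radius = 25000,
                         divergence_window = 1000L) {
  stopifnot(padj_threshold > 0, padj_threshold < 1,
            activity_alpha > 0, activity_alpha < 1)
  ann <- dataset$annotation
  readsets <- dataset$readsets
  conditions <- dataset$conditions

  quant <- quantify_genes(ann, readsets)
  cm <- count_matrix(quant)
  de <- call_differential(cm, conditions[colnames(cm)],
                          comparison = c("wt_ctl", "wt_trt"),
                          threshold = padj_threshold)
  wt_trt <- names(conditions)[conditions == "wt_trt"][1]
  q1 <- quant[quant$sample == wt_trt, ]
  pausing <- pausing_index(q1$promoter_count, q1$promoter_length,
                           q1$body_count, q1$body_length, gene = q1$gene)
  divergence <- divergence_index(ann, readsets[[wt_trt]],
                                 window = divergence_window)

  cons <- consensus_sites(dataset$peaks, min_support = min_support)
  targets <- de$gene[de$called]
  cons <- categorize_sites(cons, ann, targets, radius = radius)
  rec <- stranded_sites(cons, ann)
  erna <- erna_quantify(rec, readsets, background_fraction, activity_alpha,
                        comparisons = list(c(names(conditions)[conditions == "wt_ctl"][1],
                                             wt_trt)))
  histogram <- if (length(cons)) tss_distance_histogram(ann, cons) else NULL
  enrichment <- binding_enrichment(targets, ann, cons, radius = radius)

  res <- list(quant = quant, de = de, pausing = pausing,
              divergence = divergence,
              sites = as.data.frame(cons), stranded = as.data.frame(rec),
              erna = erna$records, erna_sites = erna$sites,
              erna_folds = erna$folds,
              histogram = histogram, enrichment = enrichment)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(res)) {
      x <- res[[nm]]
      if (is.data.frame(x))
        data.table::fwrite(x, file.path(out_dir, paste0(nm, ".tsv")),
                           sep = "\t")
    }
    manifest <- list(
      parameters = list(padj_threshold = padj_threshold,
                        background_fraction = background_fraction,
                        activity_alpha = activity_alpha,
                        min_support = min_support, radius = radius,
                        divergence_window = divergence_window),
      seed = dataset$config$seed,
      n_samples = length(readsets),
      package_version = as.character(utils::packageVersion("nascentr")))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  res
}
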