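# End-to-end discovery orchestrator: the sequence applied to a two-class
# cohort, from fold filtering through GA/kNN ranking to panel metrics and
# the composite score.

#' Run the discovery pipeline on a two-class cohort
#'
#' Applies, in order: sample alignment with the metadata and restriction
#' to the AIS and control classes; optional fold-change pre-filtering on
#' the linear-scale matrix (strict `>` at `config$fold_threshold`);
#' per-gene z-transformation; GA/kNN collection of a near-optimal solution
#' pool within the searched gene set; frequency ranking; leave-one-out
#' metrics of the top panel and the accuracy-versus-panel-size curve; and
#' the oriented composite score of the reported panel.
#'
#' @param expr Genes x samples linear-scale expression matrix.
#' @param metadata Metadata data.frame (see [read_metadata()]).
#' @param config A [run_config()].
#' @param fold_filter Apply the fold-change pre-filter before the search
#'   (set `FALSE` to search all genes, e.g. for matrices that are not on
#'   a linear intensity scale).
#' @param benchmark Also run [random_panel_benchmark()] against random
#'   panels from the genome-wide pool (and the fold-filtered pool when
#'   filtering was applied).
#' @return A list with `fold_table`, `searched_genes`, `pool`, `ranking`,
#'   `curve`, `panel` (top `config$panel_size_report` gene ids),
#'   `panel_metrics`, `composite`, and optionally `benchmark`.
#' @export
run_discovery_pipeline <- function(expr, metadata, config = run_config(),
                                   fold_filter = TRUE, benchmark = FALSE) {
  set.seed(config$seed)
  expr <- align_samples(expr, metadata)
  keep <- metadata$class_label %in% c("control", "AIS")
  expr <- expr[, keep, drop = FALSE]
  labels <- as.character(metadata$class_label[keep])

  fold_table <- NULL
  if (fold_filter) {
    fold_table <- compute_fold_changes(expr, labels)
    searched <- filter_by_fold_change(fold_table, config$fold_threshold)
    if (length(searched) <= config$ga$d)
      stop("fold filter retained too few genes (", length(searched),
           ") for chromosomes of length ", config$ga$d)
  } else {
    searched <- rownames(expr)
  }
  z <- z_transform(expr)
  searched <- intersect(searched, rownames(z))
  pool <- collect_near_optimal_pool(z, labels, config$ga,
                                    gene_pool = match(searched, rownames(z)))
  ranking <- rank_genes(pool)
  max_m <- min(config$top_n_eval, nrow(ranking))
  curve <- accuracy_by_panel_size(z, labels, ranking, max_m = max_m,
                                  k = config$k)
  panel <- ranking$gene_id[seq_len(min(config$panel_size_report, nrow(ranking)))]
  metrics <- loocv_metrics(z, labels, panel, k = config$k)
  composite <- orient_composite(fit_composite(z[panel, , drop = FALSE]), labels)

  out <- list(fold_table = fold_table, searched_genes = searched,
              pool = pool, ranking = ranking, curve = curve, panel = panel,
              panel_metrics = metrics, composite = composite)
  if (benchmark) {
    pools <- list(genome_wide = rownames(z))
    if (fold_filter && length(searched) > 50L) pools$fold_filtered <- searched
    out$benchmark <- random_panel_benchmark(
      z, labels, ranking, pools,
      sizes = unique(pmin(c(config$panel_size_report, 50L), max_m)),
      k = config$k)
  }
  out
}
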