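#' Run the full analysis pipeline
#'
#' Chains every stage on a count matrix + design + gene sets: detection
#' filter, size factors, biotype-stratified percentile filter, per-group NB
#' Wald differential expression with BH correction, direction calls,
#' concordance table, pathway net-expression scoring against the detected
#' universe, SOM clustering of pathway profiles, and dataset summaries.
#' When `out_dir` is given, all result tables are written as TSV, the SOM
#' model as JSON, and the active configuration is echoed as JSON.
#'
#' @param counts a [count_matrix()].
#' @param design a [group_design()].
#' @param gene_sets a `gene_set_collection`.
#' @param fdr BH FDR threshold for calls (default 1e-5).
#' @param percentile low-expression percentile in (0,1) (default 0.40).
#' @param norm `"size-factor"` (median-of-ratios, default) or
#'   `"total-count"` normalization for the percentile filter and DE stage.
#' @param min_pathway_genes minimum detected pathway size (default 20).
#' @param grid_rows,grid_cols SOM grid dimensions (default 4 x 4).
#' @param som_epochs SOM training epochs (default 100).
#' @param pseudocount for [moderated_log()].
#' @param shrink dispersion shrinkage weight.
#' @param reference_group reference for the concordance classification
#'   (default: first group of the design order).
#' @param seed integer seed controlling the SOM stage.
#' @param out_dir optional output directory (created if missing).
#' @param verbose log one line per stage to stderr.
#' @return a list with elements `filtered` (count_matrix), `filter_reports`,
#'   `size_factors`, `de` (`de_result`), `dirs` (`direction_matrix`),
#'   `concordance` (data.frame), `net` (`net_expression_matrix`), `som`
#'   (`som_model`), `assignment` (`som_assignment`), `deg` (`deg_summary`),
#'   `pca` (`pca_result` or NULL), `config` (list of active parameters).
#' @export
run_pipeline <- function(counts, design, gene_sets,
                         fdr = 1e-5, percentile = 0.40,
                         norm = c("size-factor", "total-count"),
                         min_pathway_genes = 20L,
                         grid_rows = 4L, grid_cols = 4L,
                         som_epochs = 100L,
                         pseudocount = 1, shrink = 0.5,
                         reference_group = design$group_order[1L],
                         seed = 1L, out_dir = NULL, verbose = TRUE) {
  norm <- match.arg(norm)
  stopifnot(inherits(counts, "count_matrix"),
            inherits(design, "group_design"))
  config <- list(fdr = fdr, percentile = percentile, norm = norm,
                 min_pathway_genes = min_pathway_genes,
                 grid = sprintf("%dx%d", grid_rows, grid_cols),
                 som_epochs = som_epochs, pseudocount = pseudocount,
                 shrink = shrink, reference_group = reference_group,
                 seed = seed)

  det <- detection_filter(counts, verbose = verbose)
  sf <- if (norm == "size-factor") estimate_size_factors(det$counts)
        else total_count_size_factors(det$counts)
  pf <- percentile_filter(det$counts, sf, q = percentile, verbose = verbose)
  de <- run_de(pf$counts, design, size_factors = sf, fdr = fdr,
               shrink = shrink, verbose = verbose)
  dirs <- call_directions(de)
  conc <- concordance_table(dirs, reference_group)
  universe <- detected_universe(counts)
  net <- net_expression_matrix(dirs, gene_sets, universe,
                               min_size = min_pathway_genes,
                               verbose = verbose)
  som <- train_som(net, grid = hex_grid(grid_rows, grid_cols),
                   epochs = som_epochs, seed = seed)
  assignment <- assign_bmu(som, net)
  deg <- deg_summary(dirs, de)
  deg_union <- rownames(dirs)[rowSums(dirs != 0L) >= 1L]
  pca <- NULL
  if (length(deg_union) >= 2L) {
    le <- moderated_log(pf$counts, sf, pseudocount = pseudocount)
    pca <- tryCatch(pca_degs(le[deg_union, , drop = FALSE],
                             verbose = verbose),
                    error = function(e) NULL)
  }

  res <- list(filtered = pf$counts,
              filter_reports = list(detection = det$report,
                                    percentile = pf$report),
              size_factors = sf, de = de, dirs = dirs,
              concordance = conc, net = net, som = som,
              assignment = assignment, deg = deg, pca = pca,
              config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

#' Write all pipeline result tables
#'
#' Emits `de_table.tsv`, `directions.tsv`, `concordance.tsv`,
#' `net_expression.tsv`, `som_assignment.tsv`, `som_model.json`,
#' `deg_summary.tsv`, `pca_scores.tsv` (if computed), `size_factors.tsv`,
#' and `config.json` into `out_dir`.
#'
#' @param res the list returned by [run_pipeline()].
#' @param out_dir output directory, created if needed.
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(out_dir, f)
  write_tsv_table(res$de$table, fp("de_table.tsv"))
  dirs_df <- data.frame(gene = rownames(res$dirs), unclass(res$dirs),
                        check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_table(dirs_df, fp("directions.tsv"))
  write_tsv_table(res$concordance, fp("concordance.tsv"))
  write_tsv_table(net_expression_table(res$net), fp("net_expression.tsv"))
  write_tsv_table(som_assignment_table(res$assignment),
                  fp("som_assignment.tsv"))
  write_som_model(res$som, fp("som_model.json"))
  write_tsv_table(res$deg$per_group, fp("deg_summary.tsv"))
  if (!is.null(res$pca)) {
    sc <- data.frame(sample = rownames(res$pca$scores), res$pca$scores,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv_table(sc, fp("pca_scores.tsv"))
  }
  write_tsv_table(data.frame(sample = names(res$size_factors),
                             size_factor = unname(res$size_factors),
                             stringsAsFactors = FALSE),
                  fp("size_factors.tsv"))
  jsonlite::write_json(res$config, fp("config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(out_dir)
}
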