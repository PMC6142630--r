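#' Run the full analysis pipeline
#'
#' QC filters, spike-in normalization, combination calling and tabulation,
#' HVG selection, optional tSNE, and diffusion pseudo-time with group
#' centroids and the complexity-progression statistic, in the order the
#' stages depend on each other. Pseudo-time is computed on one tissue's
#' cells (autopod by default: proximal cells order poorly along a temporal
#' frame), rooted at the cell nearest the centroid of the earliest
#' single-gene group.
#'
#' @param cm A raw [hox_counts()].
#' @param panel A [hox_panel()].
#' @param cfg A [pipeline_config()].
#' @param pseudotime_tissue Tissue whose cells are ordered (default
#'   `"autopod"`).
#' @param run_tsne Compute the tSNE embedding as well?
#' @return A list: `qc_cells`, `qc_genes` (reports), `counts` (filtered),
#'   `size_factors`, `norm`, `calls`, `combination_table`, `hvg`,
#'   `embedding` (or NULL), `diffusion`, `root`, `pseudotime`, `centroids`,
#'   `progression`.
#' @export
run_pipeline <- function(cm, panel = hox_panel(), cfg = pipeline_config(),
                         pseudotime_tissue = "autopod", run_tsne = FALSE) {
  qc_c <- filter_cells(cm, cfg)
  qc_g <- filter_genes(qc_c$counts, panel, cfg)
  filtered <- qc_g$counts

  sf <- spike_size_factors(filtered)
  norm <- normalize_counts(filtered, sf, length_correct = FALSE)

  calls <- call_combinations(norm, panel, cfg)
  combo_tab <- tabulate_combinations(calls, filtered$cell_meta, cfg)

  hvg <- decompose_variance(norm, cfg)
  hvg_genes <- hvg$gene_id[hvg$hvg]

  embedding <- if (run_tsne) {
    suppressWarnings(embed_tsne(norm, hvg_genes, cfg))
  }

  pt_cells <- filtered$cell_meta$cell_id[
    filtered$cell_meta$tissue == pseudotime_tissue]
  dr <- diffusion_map(norm, genes = hvg_genes, cells = pt_cells, cfg = cfg)
  root <- select_root_cell(dr, calls,
                           label = panel$posterior_d[length(panel$posterior_d)])
  pt <- dpt(dr, root)
  prog <- group_centroids_and_progression(dr, calls, pt, cfg)

  list(qc_cells = qc_c$report, qc_genes = qc_g$report, counts = filtered,
       size_factors = sf, norm = norm, calls = calls,
       combination_table = combo_tab, hvg = hvg, embedding = embedding,
       diffusion = dr, root = root, pseudotime = pt,
       centroids = prog$centroids, progression = prog$progression)
}

#' Rank cells by one gene against a gene-set median
#'
#' Generic metadata filter: ranks cells by the normalized expression of a
#' single gene (e.g. Xist) and by the median expression of a gene set (e.g.
#' top Y-chromosome genes), for flagging cells by derived metadata such as
#' embryo of origin. This is a ranking utility, not a validated
#' sex-assignment method.
#'
#' @param norm A [normalize_counts()] result.
#' @param gene Single gene id.
#' @param gene_set Character vector of gene ids.
#' @return A tibble per cell: `cell_id`, `gene_expr`, `gene_rank`,
#'   `set_median`, `set_rank`.
#' @export
rank_cells_by_gene <- function(norm, gene, gene_set) {
  stopifnot(inherits(norm, "hox_norm"))
  check_panel_present(rownames(norm$values), c(gene, gene_set))
  gx <- norm$values[gene, ]
  sm <- apply(norm$values[gene_set, , drop = FALSE], 2, stats::median)
  tibble::tibble(
    cell_id = colnames(norm$values),
    gene_expr = unname(gx),
    gene_rank = rank(-gx, ties.method = "average"),
    set_median = unname(sm),
    set_rank = rank(-sm, ties.method = "average")
  )
}
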