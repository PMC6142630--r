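#' Filter low-quality cells
#'
#' A cell is retained iff all three criteria hold, with the strict
#' inequalities of the published filters: total mapped reads (endogenous plus
#' spike-in) strictly greater than `min_mapped_reads`; number of genes with
#' count > 0 strictly greater than `min_genes_expressed`; fraction of reads
#' mapping to spike-ins strictly less than `max_spike_fraction`. Spike-in
#' reads count towards the mapped-read total (they are mapped reads).
#'
#' @param cm A [hox_counts()] object with a non-empty spike mask.
#' @param cfg A [pipeline_config()].
#' @return A list with `counts` (the retained cells) and `report`, a tibble
#'   with one row per input cell: `cell_id`, `total_reads`,
#'   `n_genes_expressed`, `spike_fraction`, the three per-criterion logicals,
#'   `pass`, and a semicolon-joined `fail_reason`.
#' @export
filter_cells <- function(cm, cfg = pipeline_config()) {
  stopifnot(inherits(cm, "hox_counts"))
  if (ncol(cm$values) == 0) stop("empty matrix: no cells", call. = FALSE)
  if (!any(cm$spike_mask)) {
    stop("spike-based QC requested but no spike-ins flagged", call. = FALSE)
  }
  v <- counts_matrix(cm)
  total <- colSums(v)
  n_expr <- colSums(v > 0)
  spike_frac <- colSums(v[cm$spike_mask, , drop = FALSE]) / total
  spike_frac[total == 0] <- NA_real_

  ok_reads <- total > cfg$min_mapped_reads
  ok_genes <- n_expr > cfg$min_genes_expressed
  ok_spike <- !is.na(spike_frac) & spike_frac < cfg$max_spike_fraction
  pass <- ok_reads & ok_genes & ok_spike

  reason <- purrr::pmap_chr(
    list(ok_reads, ok_genes, ok_spike),
    function(r, g, s) {
      why <- c(if (!r) "low_reads", if (!g) "few_genes", if (!s) "high_spike")
      if (length(why)) paste(why, collapse = ";") else ""
    }
  )
  report <- tibble::tibble(
    cell_id = colnames(v), total_reads = unname(total),
    n_genes_expressed = unname(n_expr),
    spike_fraction = unname(spike_frac), ok_reads = unname(ok_reads),
    ok_genes = unname(ok_genes), ok_spike = unname(ok_spike),
    pass = unname(pass), fail_reason = reason
  )
  if (!any(pass)) {
    stop("all cells fail QC; review thresholds (min_mapped_reads = ",
         cfg$min_mapped_reads, ", min_genes_expressed = ",
         cfg$min_genes_expressed, ", max_spike_fraction = ",
         cfg$max_spike_fraction, ")", call. = FALSE)
  }
  list(counts = subset_counts(cm, cells = colnames(v)[pass]), report = report)
}

#' Filter genes expressed at low levels
#'
#' A gene is retained iff it is present (raw count > 0) in at least
#' `gene_presence_fraction` of the cells of either tissue (inclusive, on the
#' real-valued fraction; denominators are the post-cell-filter per-tissue
#' cell counts). Hox-cluster genes are rescued regardless. Spike-ins are kept
#' unless their counts are all zero across the retained cells, in which case
#' they are dropped.
#'
#' @param cm A QC-passed [hox_counts()] with `tissue` labels for every cell.
#' @param panel A [hox_panel()]; its members plus any gene whose symbol
#'   matches `^Hox` are eligible for rescue.
#' @param cfg A [pipeline_config()].
#' @return A list with `counts` (the retained genes) and `report`, a tibble
#'   per gene: presence fraction per tissue, `retained`, and
#'   `retention_reason` in `presence` / `hox_rescue` / `spike` / `dropped`.
#' @export
filter_genes <- function(cm, panel = hox_panel(), cfg = pipeline_config()) {
  stopifnot(inherits(cm, "hox_counts"))
  tis <- cm$cell_meta$tissue
  tab <- table(tis)
  if (any(tab == 0) || length(tab) < 2) {
    stop("the either-tissue presence rule needs cells in both tissues; got: ",
         paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
         call. = FALSE)
  }
  v <- counts_matrix(cm)
  present <- v > 0
  frac_by_tissue <- sapply(names(tab), function(ts) {
    rowMeans(present[, tis == ts, drop = FALSE])
  })
  max_frac <- apply(frac_by_tissue, 1, max)
  passes_presence <- max_frac >= cfg$gene_presence_fraction

  symbols <- cm$gene_meta$symbol
  is_hox <- grepl("^Hox", symbols) | symbols %in%
    c(panel$posterior_d, panel$a_cluster)
  nonzero <- rowSums(v) > 0
  spike <- cm$spike_mask

  retained <- ifelse(spike, nonzero, passes_presence | is_hox)
  reason <- dplyr::case_when(
    spike & nonzero ~ "spike",
    !spike & passes_presence ~ "presence",
    !spike & is_hox ~ "hox_rescue",
    TRUE ~ "dropped"
  )
  report <- tibble::tibble(
    gene_id = rownames(v),
    symbol = symbols,
    spike = spike,
    max_presence_fraction = unname(max_frac),
    retained = unname(as.logical(retained)),
    retention_reason = reason
  )
  for (ts in names(tab)) {
    report[[paste0("presence_", ts)]] <- unname(frac_by_tissue[, ts])
  }
  list(counts = subset_counts(cm, genes = rownames(v)[retained]),
       report = report)
}
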