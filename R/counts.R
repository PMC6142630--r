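#' Construct a single-cell count container
#'
#' `hox_counts()` bundles an integer genes x cells count matrix with its cell
#' and gene metadata and a spike-in mask. It is the entry point of the
#' pipeline: QC, normalization and everything downstream consume it. Genes are
#' rows and cells are columns, matching the on-disk layout of single-cell
#' count tables; cells are the statistical units.
#'
#' @param values Integer matrix, genes x cells, counts >= 0. Dense or a
#'   `Matrix` sparse matrix; stored sparse when density < 0.5.
#' @param cell_meta Tibble with one row per cell: `cell_id`, `tissue`
#'   (`"autopod"` or `"zeugopod"`), `batch`, `embryo`. Missing `embryo` is
#'   tolerated; `batch` is required for every cell.
#' @param gene_meta Tibble with one row per gene: `gene_id`, `symbol`,
#'   `length_bp` (positive integer). Optional logical panel flag columns are
#'   carried along untouched.
#' @param spike_mask Logical per gene, `TRUE` for ERCC spike-ins. Defaults to
#'   gene ids matching the ERCC naming standard prefix `"ERCC-"`.
#' @return An object of class `hox_counts`.
#' @export
hox_counts <- function(values, cell_meta, gene_meta = NULL, spike_mask = NULL) {
  if (is.null(dim(values)) || length(dim(values)) != 2L) {
    stop("`values` must be a genes x cells matrix", call. = FALSE)
  }
  gene_ids <- rownames(values)
  cell_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(cell_ids)) {
    stop("`values` must carry gene ids as rownames and cell ids as colnames",
         call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(cell_ids)) {
    stop("duplicate cell ids: ",
         paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "),
         call. = FALSE)
  }
  v <- as.matrix(values)
  if (any(!is.finite(v))) stop("counts must be finite", call. = FALSE)
  if (any(v < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(v != round(v))) stop("counts must be integers", call. = FALSE)
  storage.mode(v) <- "double"  # integer-valued doubles; avoids int overflow on sums

  if (is.null(spike_mask)) spike_mask <- grepl("^ERCC-", gene_ids)
  stopifnot(length(spike_mask) == length(gene_ids))

  cell_meta <- tibble::as_tibble(cell_meta)
  if (!"cell_id" %in% names(cell_meta)) {
    stop("`cell_meta` needs a `cell_id` column", call. = FALSE)
  }
  missing_cells <- setdiff(cell_ids, cell_meta$cell_id)
  if (length(missing_cells)) {
    stop("cells missing from metadata: ",
         paste(missing_cells, collapse = ", "), call. = FALSE)
  }
  cell_meta <- cell_meta[match(cell_ids, cell_meta$cell_id), , drop = FALSE]
  if (!"batch" %in% names(cell_meta) || anyNA(cell_meta$batch)) {
    stop("every cell needs a batch label", call. = FALSE)
  }

  if (is.null(gene_meta)) {
    gene_meta <- tibble::tibble(gene_id = gene_ids, symbol = gene_ids,
                                length_bp = NA_integer_)
  } else {
    gene_meta <- tibble::as_tibble(gene_meta)
    if (!"gene_id" %in% names(gene_meta)) {
      stop("`gene_meta` needs a `gene_id` column", call. = FALSE)
    }
    gene_meta <- gene_meta[match(gene_ids, gene_meta$gene_id), , drop = FALSE]
    if (anyNA(gene_meta$gene_id)) {
      stop("gene_meta does not cover all genes in the matrix", call. = FALSE)
    }
    if (!"symbol" %in% names(gene_meta)) gene_meta$symbol <- gene_meta$gene_id
  }

  dens <- mean(v > 0)
  store <- if (dens < 0.5) Matrix::Matrix(v, sparse = TRUE) else v
  structure(
    list(values = store, cell_meta = cell_meta, gene_meta = gene_meta,
         spike_mask = as.logical(spike_mask)),
    class = "hox_counts"
  )
}

#' @export
print.hox_counts <- function(x, ...) {
  cat(sprintf("<hox_counts> %d genes x %d cells (%d spike-ins)\n",
              nrow(x$values), ncol(x$values), sum(x$spike_mask)))
  tab <- table(x$cell_meta$tissue)
  cat("  tissues:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "| batches:", length(unique(x$cell_meta$batch)), "\n")
  invisible(x)
}

#' @export
dim.hox_counts <- function(x) dim(x$values)

# dense numeric copy of the counts
counts_matrix <- function(cm) as.matrix(cm$values)

#' Subset a count container by gene and/or cell ids
#'
#' @param cm A [hox_counts()] object.
#' @param genes,cells Character vectors of ids to keep (`NULL` keeps all).
#' @return A `hox_counts` restricted to the requested rows/columns.
#' @export
subset_counts <- function(cm, genes = NULL, cells = NULL) {
  stopifnot(inherits(cm, "hox_counts"))
  g <- if (is.null(genes)) rownames(cm$values) else genes
  cl <- if (is.null(cells)) colnames(cm$values) else cells
  gi <- match(g, rownames(cm$values))
  ci <- match(cl, colnames(cm$values))
  if (anyNA(gi)) stop("unknown genes: ", paste(g[is.na(gi)], collapse = ", "))
  if (anyNA(ci)) stop("unknown cells: ", paste(cl[is.na(ci)], collapse = ", "))
  hox_counts(as.matrix(cm$values)[gi, ci, drop = FALSE],
             cell_meta = cm$cell_meta[ci, , drop = FALSE],
             gene_meta = cm$gene_meta[gi, , drop = FALSE],
             spike_mask = cm$spike_mask[gi])
}

#' Define the Hoxd panel used for combination calling
#'
#' The posterior HoxD panel: the five genes whose per-cell on/off
#' combinations the analysis calls, ordered along the cluster from Hoxd9 to
#' Hoxd13. The Hoxa paralogs are carried only for cumulative expression
#' plots, and the reporter (Gfp, knocked into Hoxd11) for correlation checks.
#'
#' @param posterior_d Ordered symbols of the posterior Hoxd genes.
#' @param a_cluster Ordered Hoxa symbols (cumulative plots only).
#' @param reporter Reporter gene symbol.
#' @return A list of class `hox_panel`.
#' @export
hox_panel <- function(posterior_d = c("Hoxd9", "Hoxd10", "Hoxd11", "Hoxd12", "Hoxd13"),
                      a_cluster = c("Hoxa9", "Hoxa10", "Hoxa11", "Hoxa13"),
                      reporter = "Gfp") {
  if (length(posterior_d) < 2) {
    stop("the posterior panel needs at least 2 genes", call. = FALSE)
  }
  structure(list(posterior_d = posterior_d, a_cluster = a_cluster,
                 reporter = reporter), class = "hox_panel")
}

# error if any panel gene is absent from the matrix
check_panel_present <- function(cm_or_rownames, panel_genes) {
  rn <- if (is.character(cm_or_rownames)) cm_or_rownames else rownames(cm_or_rownames$values)
  absent <- setdiff(panel_genes, rn)
  if (length(absent)) {
    stop("panel genes absent from matrix: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}
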