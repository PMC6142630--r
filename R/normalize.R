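#' Spike-in size factors with per-batch mean centering
#'
#' The raw factor of cell j is its spike-in count total divided by the mean
#' of that total over cells; factors are then mean-centered to their batch of
#' origin (divided by the mean raw factor of the cell's batch), so within
#' every batch the centered factors average exactly 1. Because spike-in input
#' is constant per cell, the factor estimates capture efficiency.
#'
#' @param cm A [hox_counts()] with spike-ins and batch labels.
#' @return A tibble with one row per cell: `cell_id`, `batch`, `spike_total`,
#'   `raw_factor`, `centered_factor`.
#' @export
spike_size_factors <- function(cm) {
  stopifnot(inherits(cm, "hox_counts"))
  if (!any(cm$spike_mask)) stop("no spike-ins in matrix", call. = FALSE)
  v <- counts_matrix(cm)
  spike_total <- colSums(v[cm$spike_mask, , drop = FALSE])
  zero <- spike_total == 0
  if (any(zero)) {
    stop("cells with zero spike-in total (exclude them or fail them in QC): ",
         paste(colnames(v)[zero], collapse = ", "), call. = FALSE)
  }
  raw <- spike_total / mean(spike_total)
  batch <- cm$cell_meta$batch
  batch_mean <- tapply(raw, batch, mean)
  centered <- raw / batch_mean[batch]
  tibble::tibble(cell_id = colnames(v), batch = batch,
                 spike_total = unname(spike_total), raw_factor = unname(raw),
                 centered_factor = unname(as.numeric(centered)))
}

#' Normalize counts by size factors, optionally per kilobase
#'
#' Each count is divided by its cell's centered size factor. With
#' `length_correct = TRUE`, endogenous genes are additionally divided by
#' their length in kilobases (spike-ins keep per-cell units; their nominal
#' "length" is not a transcript length).
#'
#' @param cm A [hox_counts()] object.
#' @param sf Size factors from [spike_size_factors()], computed on the same
#'   cells.
#' @param length_correct Divide endogenous genes by length/1000?
#' @return An object of class `hox_norm`: list with `values` (genes x cells
#'   non-negative reals), `unit` (`"per_cell"` or `"per_cell_per_kb"`),
#'   `spike_mask`, `cell_meta`, `gene_meta`, and `size_factors`.
#' @export
normalize_counts <- function(cm, sf = spike_size_factors(cm),
                             length_correct = FALSE) {
  stopifnot(inherits(cm, "hox_counts"))
  idx <- match(colnames(cm$values), sf$cell_id)
  if (anyNA(idx)) stop("size factors missing for some cells", call. = FALSE)
  fac <- sf$centered_factor[idx]
  v <- sweep(counts_matrix(cm), 2, fac, "/")
  unit <- "per_cell"
  if (length_correct) {
    len <- cm$gene_meta$length_bp
    need <- !cm$spike_mask
    if (anyNA(len[need])) {
      stop("length correction requested but length_bp missing for: ",
           paste(cm$gene_meta$gene_id[need & is.na(len)], collapse = ", "),
           call. = FALSE)
    }
    v[need, ] <- v[need, , drop = FALSE] / (len[need] / 1000)
    unit <- "per_cell_per_kb"
  }
  structure(
    list(values = v, unit = unit, spike_mask = cm$spike_mask,
         cell_meta = cm$cell_meta, gene_meta = cm$gene_meta,
         size_factors = sf, length_corrected = length_correct),
    class = "hox_norm"
  )
}

#' @export
print.hox_norm <- function(x, ...) {
  cat(sprintf("<hox_norm> %d genes x %d cells, unit = %s\n",
              nrow(x$values), ncol(x$values), x$unit))
  invisible(x)
}

#' @export
dim.hox_norm <- function(x) dim(x$values)

# log2(x + 1) of the normalized values, optionally restricted
log_expr <- function(norm, genes = NULL, cells = NULL) {
  v <- norm$values
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (!is.null(cells)) v <- v[, cells, drop = FALSE]
  log2(v + 1)
}
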