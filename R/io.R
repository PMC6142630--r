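#' Read a genes x cells count table
#'
#' Reads either a delimited table (TSV/CSV; header of cell ids, first column
#' of gene ids) or a MatrixMarket MTX triplet (with `<stem>.rows` /
#' `<stem>.cols` sidecar name files), joins per-cell metadata by cell id and
#' flags spike-ins by the ERCC id prefix. Deposited count tables sometimes
#' carry leading genomic-coordinate columns (chromosome/start/end) before the
#' per-cell columns; any column whose name is not found in the metadata and
#' that matches the usual coordinate names is dropped with a message.
#'
#' @param path Count table (`.tsv`/`.csv`/`.txt`) or MTX file (`.mtx`).
#' @param meta_path Delimited cell-metadata table with columns `cell_id`,
#'   `tissue`, `batch` (and optionally `embryo`).
#' @param gene_meta_path Optional gene-annotation table (`gene_id`, `symbol`,
#'   `length_bp`).
#' @param spike_ids Optional explicit spike-in ids, overriding the `"ERCC-"`
#'   prefix rule.
#' @return A [hox_counts()] object.
#' @export
read_counts <- function(path, meta_path, gene_meta_path = NULL,
                        spike_ids = NULL) {
  cell_meta <- read_delim_auto(meta_path)
  if (!"cell_id" %in% names(cell_meta)) {
    stop("cell metadata needs a `cell_id` column", call. = FALSE)
  }

  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    m <- Matrix::readMM(path)
    stem <- sub("\\.mtx$", "", path, ignore.case = TRUE)
    rows <- readLines(paste0(stem, ".rows"))
    cols <- readLines(paste0(stem, ".cols"))
    if (length(rows) != nrow(m) || length(cols) != ncol(m)) {
      stop("MTX sidecar name files do not match matrix dimensions",
           call. = FALSE)
    }
    v <- as.matrix(m)
    dimnames(v) <- list(rows, cols)
  } else {
    tab <- read_delim_auto(path)
    gene_ids <- as.character(tab[[1]])
    tab <- tab[, -1, drop = FALSE]
    # tolerate leading coordinate columns in deposited tables
    coord_like <- grepl("^(chr|chrom|chromosome|start|end|stop|strand)$",
                        names(tab), ignore.case = TRUE) &
      !(names(tab) %in% cell_meta$cell_id)
    if (any(coord_like)) {
      message("dropping ", sum(coord_like), " leading coordinate column(s): ",
              paste(names(tab)[coord_like], collapse = ", "))
      tab <- tab[, !coord_like, drop = FALSE]
    }
    v <- as.matrix(tab)
    if (!is.numeric(v)) stop("count table contains non-numeric entries",
                             call. = FALSE)
    rownames(v) <- gene_ids
  }

  if (any(is.na(v))) stop("count table contains missing values", call. = FALSE)
  if (any(v < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(v != round(v))) stop("counts must be integers", call. = FALSE)

  gene_meta <- if (!is.null(gene_meta_path)) read_delim_auto(gene_meta_path)
  spike_mask <- if (is.null(spike_ids)) NULL else rownames(v) %in% spike_ids
  hox_counts(v, cell_meta = cell_meta, gene_meta = gene_meta,
             spike_mask = spike_mask)
}

#' Write a count container to disk
#'
#' Writes the counts as a TSV (gene ids in the first column, cell ids as the
#' header) plus `<stem>_cells.tsv` and `<stem>_genes.tsv` metadata sidecars,
#' or as an MTX triplet when `path` ends in `.mtx`. `read_counts()` on the
#' result reproduces the integer values exactly.
#'
#' @param cm A [hox_counts()] object.
#' @param path Destination (`.tsv` or `.mtx`).
#' @return `path`, invisibly.
#' @export
write_counts <- function(cm, path) {
  stopifnot(inherits(cm, "hox_counts"))
  stem <- sub("\\.(tsv|mtx)$", "", path, ignore.case = TRUE)
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    Matrix::writeMM(Matrix::Matrix(as.matrix(cm$values), sparse = TRUE), path)
    writeLines(rownames(cm$values), paste0(stem, ".rows"))
    writeLines(colnames(cm$values), paste0(stem, ".cols"))
  } else {
    v <- as.matrix(cm$values)
    df <- data.frame(gene_id = rownames(v), v, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_table(cm$cell_meta, paste0(stem, "_cells.tsv"))
  write_table(cm$gene_meta, paste0(stem, "_genes.tsv"))
  invisible(path)
}

#' Write a tabular result deterministically
#'
#' Column order is preserved as given; floats are written at 6 significant
#' digits, so write -> read -> write is byte-identical.
#'
#' @param obj A data frame / tibble.
#' @param path Destination TSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(obj, path) {
  df <- as.data.frame(obj)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- signif(df[[j]], 6)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_delim_auto <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = sep,
                                      check.names = FALSE,
                                      stringsAsFactors = FALSE))
}
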