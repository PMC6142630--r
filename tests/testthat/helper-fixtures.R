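# Fixture builders shared across the suite. Everything is generated in code;
# no files ship with the tests.

# minimal count container: counts matrix with auto ids and one batch
make_counts <- function(values, tissue = NULL, batch = NULL,
                        gene_ids = NULL, cell_ids = NULL, spike_mask = NULL,
                        length_bp = NULL) {
  if (is.null(gene_ids)) {
    gene_ids <- rownames(values) %||% sprintf("g%03d", seq_len(nrow(values)))
  }
  if (is.null(cell_ids)) {
    cell_ids <- colnames(values) %||% sprintf("c%03d", seq_len(ncol(values)))
  }
  dimnames(values) <- list(gene_ids, cell_ids)
  if (is.null(tissue)) tissue <- rep("autopod", ncol(values))
  if (is.null(batch)) batch <- rep("b1", ncol(values))
  gm <- tibble::tibble(gene_id = gene_ids, symbol = gene_ids,
                       length_bp = length_bp %||% rep(1000L, nrow(values)))
  hox_counts(values,
             cell_meta = tibble::tibble(cell_id = cell_ids, tissue = tissue,
                                        batch = batch),
             gene_meta = gm, spike_mask = spike_mask)
}

# wrap a plain matrix as a normalized-expression object
make_norm <- function(values, spike_mask = NULL, tissue = NULL,
                      batch = NULL) {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("c%03d", seq_len(ncol(values)))
  }
  if (is.null(spike_mask)) spike_mask <- grepl("^ERCC-", rownames(values))
  if (is.null(tissue)) tissue <- rep("autopod", ncol(values))
  if (is.null(batch)) batch <- rep("b1", ncol(values))
  structure(
    list(values = values, unit = "per_cell", spike_mask = spike_mask,
         cell_meta = tibble::tibble(cell_id = colnames(values),
                                    tissue = tissue, batch = batch),
         gene_meta = tibble::tibble(gene_id = rownames(values),
                                    symbol = rownames(values),
                                    length_bp = 1000L),
         size_factors = NULL, length_corrected = FALSE),
    class = "hox_norm"
  )
}

# panel-expression matrix (5 panel genes x cells) as a hox_norm
make_panel_norm <- function(panel_values) {
  rownames(panel_values) <- c("Hoxd9", "Hoxd10", "Hoxd11", "Hoxd12", "Hoxd13")
  make_norm(panel_values)
}

# small synthetic parameter set: fast to draw, keeps the default structure
small_params <- function(...) {
  defaults <- list(n_cells = c(autopod = 60, zeugopod = 60),
                   n_target_genes = 20, n_background_genes = 60,
                   n_spikes = 15)
  do.call(synth_params, utils::modifyList(defaults, list(...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
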