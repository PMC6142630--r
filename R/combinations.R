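#' Call the per-cell Hoxd combination
#'
#' The study's central statistic: a panel gene is "on" in a cell iff its
#' normalized expression is at least `combo_min_expr` (default 5) AND at
#' least `combo_max_fraction` (default 5%) of the cell's most expressed
#' panel gene. Both criteria are inclusive (>=); the maximum in the relative
#' criterion runs over the posterior Hoxd panel only. A cell with no gene
#' passing gets the first-class empty label `"none"`. The label is the
#' "+"-joined on-set in panel order, so it is a pure function of the on-set.
#'
#' @param norm A [normalize_counts()] result (length correction off by
#'   default for calling, so the absolute threshold applies to per-cell
#'   units).
#' @param panel A [hox_panel()]; every member must be present in the matrix.
#' @param cfg A [pipeline_config()].
#' @param relative_on_raw Apply the 5% relative criterion to raw counts
#'   instead of normalized values (an alternative reading of "when count
#'   represented at least 5%"); requires `raw` when `TRUE`.
#' @param raw Optional [hox_counts()] supplying raw counts for
#'   `relative_on_raw`.
#' @return A tibble with one row per cell x panel gene: `cell_id`, `gene`,
#'   `expr`, `frac_of_max` (the two audit values), `on`; plus per-cell
#'   columns `label` and `n_on` repeated within cell.
#' @export
call_combinations <- function(norm, panel = hox_panel(),
                              cfg = pipeline_config(),
                              relative_on_raw = FALSE, raw = NULL) {
  stopifnot(inherits(norm, "hox_norm"))
  genes <- panel$posterior_d
  check_panel_present(rownames(norm$values), genes)
  ex <- norm$values[genes, , drop = FALSE]
  if (any(ex < 0)) stop("expression values must be non-negative")

  rel_base <- ex
  if (relative_on_raw) {
    if (is.null(raw)) stop("relative_on_raw = TRUE needs the raw counts")
    check_panel_present(raw, genes)
    rel_base <- counts_matrix(raw)[genes, colnames(ex), drop = FALSE]
  }
  mx <- apply(rel_base, 2, max)
  frac <- sweep(rel_base, 2, pmax(mx, .Machine$double.eps), "/")
  frac[, mx == 0] <- 0
  on <- ex >= cfg$combo_min_expr & frac >= cfg$combo_max_fraction

  labels <- apply(on, 2, function(o) {
    if (!any(o)) "none" else paste(genes[o], collapse = "+")
  })
  n_on_cell <- colSums(on)
  tibble::tibble(
    cell_id = rep(colnames(ex), each = length(genes)),
    gene = rep(genes, times = ncol(ex)),
    expr = as.vector(ex),
    frac_of_max = as.vector(frac),
    on = as.vector(on),
    label = rep(unname(labels), each = length(genes)),
    n_on = rep(unname(n_on_cell), each = length(genes))
  )
}

# one row per cell
combination_labels <- function(calls) {
  dplyr::distinct(calls, .data$cell_id, .data$label, .data$n_on)
}

#' Tabulate combination frequencies and flag main groups
#'
#' Counts cells per canonical combination label, overall and per tissue.
#' Main groups are the labels with strictly more than `main_group_min_cells`
#' cells (default 5). Because it is unresolved whether the published
#' combination count includes the empty combination, the distinct-label
#' count is reported both with and without `"none"` (attributes
#' `n_distinct_with_none` / `n_distinct_without_none`).
#'
#' @param calls Output of [call_combinations()].
#' @param cell_meta Per-cell metadata with `cell_id` and `tissue` (optional;
#'   omit for an unstratified table).
#' @param cfg A [pipeline_config()].
#' @return A tibble: `tissue` (`"all"` for the pooled stratum), `label`,
#'   `n_cells`, `frequency` (sums to 1 within stratum), `main_group`.
#' @export
tabulate_combinations <- function(calls, cell_meta = NULL,
                                  cfg = pipeline_config()) {
  lab <- combination_labels(calls)
  if (nrow(lab) == 0) stop("no cells to tabulate", call. = FALSE)
  if (!is.null(cell_meta)) {
    lab <- dplyr::left_join(lab,
                            dplyr::select(cell_meta, "cell_id", "tissue"),
                            by = "cell_id")
  } else {
    lab$tissue <- "all"
  }
  strata <- dplyr::bind_rows(lab, dplyr::mutate(lab, tissue = "all"))
  strata <- dplyr::distinct(strata)  # collapses when input already pooled
  out <- strata |>
    dplyr::count(.data$tissue, .data$label, name = "n_cells") |>
    dplyr::group_by(.data$tissue) |>
    dplyr::mutate(frequency = .data$n_cells / sum(.data$n_cells)) |>
    dplyr::ungroup() |>
    dplyr::mutate(main_group = .data$n_cells > cfg$main_group_min_cells) |>
    dplyr::arrange(.data$tissue, dplyr::desc(.data$n_cells), .data$label)
  attr(out, "n_distinct_with_none") <-
    length(unique(lab$label))
  attr(out, "n_distinct_without_none") <-
    length(setdiff(unique(lab$label), "none"))
  out
}

#' Per-cell cumulative panel expression
#'
#' Stacked per-cell contributions of the Hoxd (and optionally Hoxa) panel
#' genes: each gene's normalized value plus the panel total, so cells can be
#' ordered by total combinatorial output. Contributions sum to the total
#' exactly.
#'
#' @param norm A [normalize_counts()] result.
#' @param panel A [hox_panel()].
#' @param include_a Also include the Hoxa cluster genes that are present.
#' @return A tibble per cell x gene: `cell_id`, `gene`, `cluster`
#'   (`"HoxD"`/`"HoxA"`), `expr`, `panel_total` (per cell, over the HoxD
#'   panel).
#' @export
cumulative_panel_expression <- function(norm, panel = hox_panel(),
                                        include_a = FALSE) {
  stopifnot(inherits(norm, "hox_norm"))
  check_panel_present(rownames(norm$values), panel$posterior_d)
  genes <- panel$posterior_d
  cluster <- rep("HoxD", length(genes))
  if (include_a) {
    a_here <- intersect(panel$a_cluster, rownames(norm$values))
    genes <- c(genes, a_here)
    cluster <- c(cluster, rep("HoxA", length(a_here)))
  }
  ex <- norm$values[genes, , drop = FALSE]
  total <- unname(colSums(ex[cluster == "HoxD", , drop = FALSE]))
  tibble::tibble(
    cell_id = rep(colnames(ex), each = length(genes)),
    gene = rep(genes, times = ncol(ex)),
    cluster = rep(cluster, times = ncol(ex)),
    expr = as.vector(ex),
    panel_total = rep(total, each = length(genes))
  )
}
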