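#' Tidy a differential-expression result
#'
#' @param x A `hox_de` result from [moderated_two_group_test()].
#' @param ... Unused.
#' @return A tibble with one row per gene (broom convention: `term`,
#'   `estimate`, `statistic`, `p.value`, `p.adjusted`, `significant`).
#' @exportS3Method generics::tidy
tidy.hox_de <- function(x, ...) {
  tibble::tibble(term = x$gene_id, estimate = x$log2_fc, statistic = x$t,
                 p.value = x$p_value, p.adjusted = x$p_adjusted,
                 significant = x$significant)
}

#' One-row summary of a differential-expression result
#'
#' @param x A `hox_de` result.
#' @param ... Unused.
#' @return A one-row tibble: contrast, group sizes, fitted variance prior
#'   (`d0`, `s0_sq`), genes tested and significant.
#' @exportS3Method generics::glance
glance.hox_de <- function(x, ...) {
  tibble::tibble(contrast = attr(x, "contrast"),
                 n1 = attr(x, "n1"), n2 = attr(x, "n2"),
                 d0 = attr(x, "d0"), s0_sq = attr(x, "s0_sq"),
                 n_genes = nrow(x), n_significant = sum(x$significant))
}

#' Tidy a diffusion-map result
#'
#' @param x A `hox_diffusion` result from [diffusion_map()].
#' @param ... Unused.
#' @return A tibble per cell: `cell_id` plus one column per diffusion
#'   component.
#' @exportS3Method generics::tidy
tidy.hox_diffusion <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(x$components))
  out <- dplyr::bind_cols(tibble::tibble(cell_id = x$cell_ids), out)
  out
}

#' One-row summary of a diffusion-map result
#'
#' @param x A `hox_diffusion` result.
#' @param ... Unused.
#' @return A one-row tibble: cells embedded, eigenvalue 1, the spectral gap
#'   and retained components.
#' @exportS3Method generics::glance
glance.hox_diffusion <- function(x, ...) {
  tibble::tibble(n_cells = length(x$cell_ids),
                 lambda1 = x$eigenvalues[1],
                 lambda2 = x$eigenvalues[2],
                 spectral_gap = x$eigenvalues[1] - x$eigenvalues[2],
                 k_components = ncol(x$components))
}

#' Tidy a quadrant-gating result
#'
#' @param x A `hox_quadrants` result from [gate_quadrants()].
#' @param ... Unused.
#' @return The quadrant table as a tibble.
#' @exportS3Method generics::tidy
tidy.hox_quadrants <- function(x, ...) x$table
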