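#' Spearman correlation of every gene against the Hoxd panel
#'
#' Tie-corrected (average-rank) Spearman rho of each gene's normalized
#' expression against each posterior panel gene, over a chosen cell stratum;
#' p-values use the t approximation t = rho * sqrt((n-2)/(1-rho^2)), and BH
#' adjustment runs over all gene x panel tests jointly. Constant genes have
#' undefined rho and are recorded as missing.
#'
#' @param norm A [normalize_counts()] result.
#' @param panel A [hox_panel()].
#' @param cells Cell ids of the stratum (default: all cells).
#' @param genes Genes to test (default: all non-panel genes).
#' @return A tibble per gene x panel gene: `gene_id`, `panel_gene`, `rho`,
#'   `n`, `p_value`, `p_adjusted` (NA rows for constant genes).
#' @export
spearman_vs_panel <- function(norm, panel = hox_panel(), cells = NULL,
                              genes = NULL) {
  stopifnot(inherits(norm, "hox_norm"))
  if (is.null(cells)) cells <- colnames(norm$values)
  if (length(cells) < 3) stop("need at least 3 cells", call. = FALSE)
  check_panel_present(rownames(norm$values), panel$posterior_d)
  if (is.null(genes)) genes <- setdiff(rownames(norm$values), panel$posterior_d)

  gx <- t(norm$values[genes, cells, drop = FALSE])
  px <- t(norm$values[panel$posterior_d, cells, drop = FALSE])
  constant <- apply(gx, 2, function(x) length(unique(x)) == 1)
  rho <- suppressWarnings(stats::cor(gx, px, method = "spearman"))
  rho[constant, ] <- NA_real_
  n <- length(cells)
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(rho) >= 1] <- 0

  out <- tibble::tibble(
    gene_id = rep(genes, times = length(panel$posterior_d)),
    panel_gene = rep(panel$posterior_d, each = length(genes)),
    rho = as.vector(rho), n = n, p_value = as.vector(p)
  )
  out$p_adjusted <- NA_real_
  ok <- !is.na(out$p_value)
  out$p_adjusted[ok] <- bh_adjust(out$p_value[ok])
  out
}

#' Select genes covarying with the panel
#'
#' Genes whose correlation against at least one panel gene passes both an
#' effect-size floor and an FDR bound (defaults |rho| >= 0.3, BH FDR < 0.05;
#' the published gene list's exact thresholds are unstated, so these are
#' configuration, not constants).
#'
#' @param rho_table Output of [spearman_vs_panel()].
#' @param cfg A [pipeline_config()].
#' @return Character vector of selected gene ids.
#' @export
select_covarying <- function(rho_table, cfg = pipeline_config()) {
  hit <- rho_table |>
    dplyr::filter(!is.na(.data$rho),
                  abs(.data$rho) >= cfg$covary_min_rho,
                  .data$p_adjusted < cfg$covary_max_fdr)
  sort(unique(hit$gene_id))
}

#' Pairwise Spearman correlation matrix over a gene set
#'
#' @param norm A [normalize_counts()] result.
#' @param genes Gene ids.
#' @param cells Cell stratum (default all).
#' @return A list of class `hox_cor`: `rho` (symmetric, unit diagonal), `n`,
#'   `p_adjusted` (BH over the upper triangle), `cells`.
#' @export
correlation_matrix <- function(norm, genes, cells = NULL) {
  stopifnot(inherits(norm, "hox_norm"))
  if (is.null(cells)) cells <- colnames(norm$values)
  x <- t(norm$values[genes, cells, drop = FALSE])
  rho <- suppressWarnings(stats::cor(x, method = "spearman"))
  n <- length(cells)
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(rho) >= 1] <- 0
  ut <- upper.tri(p)
  padj <- p
  padj[ut] <- bh_adjust(p[ut])
  padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
  diag(padj) <- 0
  structure(list(rho = rho, n = n, p_adjusted = padj, cells = cells),
            class = "hox_cor")
}

#' Hierarchically cluster a correlation matrix
#'
#' Agglomerative clustering with distance 1 - rho (sign-coherent
#' co-expression: anti-correlated genes separate) and average linkage.
#' Genes are ordered lexicographically before clustering so ties break
#' deterministically regardless of input order.
#'
#' @param corr A [correlation_matrix()] result (no missing rho allowed).
#' @param linkage Agglomeration method for [stats::hclust()].
#' @return A list of class `hox_dendro`: `hclust` (the fit), `merges`
#'   (tibble: step, height), `leaf_order` (gene ids), `rho_ordered` (the
#'   matrix in leaf order), `linkage`, `distance`.
#' @export
cluster_correlations <- function(corr, linkage = "average") {
  stopifnot(inherits(corr, "hox_cor"))
  rho <- corr$rho
  if (any(is.na(rho))) {
    bad <- which(is.na(rho), arr.ind = TRUE)
    pairs <- unique(apply(bad, 1, function(i) {
      paste(sort(rownames(rho)[i]), collapse = "~")
    }))
    stop("missing correlations for pairs: ", paste(pairs, collapse = ", "),
         call. = FALSE)
  }
  ord <- order(rownames(rho))
  rho <- rho[ord, ord]
  d <- stats::as.dist(1 - rho)
  hc <- stats::hclust(d, method = linkage)
  leaf <- rownames(rho)[hc$order]
  structure(
    list(hclust = hc,
         merges = tibble::tibble(step = seq_along(hc$height),
                                 height = hc$height),
         leaf_order = leaf,
         rho_ordered = rho[leaf, leaf],
         linkage = linkage, distance = "1 - spearman rho"),
    class = "hox_dendro"
  )
}
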