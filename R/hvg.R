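#' Decompose gene variance into technical and biological parts
#'
#' Per-gene mean and variance of log2(normalized + 1); a local-regression
#' (loess) trend of variance on mean is fitted to the spike-in genes, whose
#' variability is purely technical because their input is constant. The
#' technical variance of an endogenous gene is the trend evaluated at its
#' mean (clamped to non-negative, direct-surface evaluation so means outside
#' the spike range are defined); biological variance is total minus
#' technical, floored at 0. Genes rank by biological variance, descending.
#'
#' @param norm A [normalize_counts()] result with >= 10 spike-ins of
#'   non-zero variance.
#' @param cfg A [pipeline_config()] (`hvg_trend_span`, `n_hvg`).
#' @param use_endogenous_trend Fall back to fitting the trend on endogenous
#'   genes (for matrices without usable spikes).
#' @return A tibble per endogenous gene: `gene_id`, `mean_log2`,
#'   `total_variance`, `technical_variance`, `biological_variance`, `rank`,
#'   `hvg` (`TRUE` for the top `n_hvg`).
#' @export
decompose_variance <- function(norm, cfg = pipeline_config(),
                               use_endogenous_trend = FALSE) {
  stopifnot(inherits(norm, "hox_norm"))
  lx <- log_expr(norm)
  mn <- rowMeans(lx)
  vr <- apply(lx, 1, stats::var)

  trend_on <- if (use_endogenous_trend) !norm$spike_mask else norm$spike_mask
  fit_idx <- trend_on & vr > 0
  if (!use_endogenous_trend && sum(fit_idx) < 10) {
    stop("fewer than 10 spike-ins with non-zero variance; consider ",
         "use_endogenous_trend = TRUE", call. = FALSE)
  }
  fit <- stats::loess(v ~ m,
                      data = data.frame(m = mn[fit_idx], v = vr[fit_idx]),
                      span = cfg$hvg_trend_span, degree = 1,
                      control = stats::loess.control(surface = "direct"))
  endo <- !norm$spike_mask
  tech <- pmax(stats::predict(fit, newdata = data.frame(m = mn[endo])), 0)
  bio <- pmax(vr[endo] - tech, 0)

  out <- tibble::tibble(
    gene_id = rownames(lx)[endo],
    mean_log2 = mn[endo],
    total_variance = vr[endo],
    technical_variance = tech,
    biological_variance = bio
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$biological_variance),
                        .data$gene_id)
  out$rank <- seq_len(nrow(out))
  out$hvg <- out$rank <= cfg$n_hvg
  out
}

#' tSNE embedding on the highly variable genes
#'
#' Runs tSNE on log2(normalized + 1) of the HVG set with the stated
#' parameters (2 dimensions, perplexity 30, 3000 iterations, seed 42 by
#' default). Perplexity is auto-reduced with a warning when there are fewer
#' than 3 x perplexity + 1 cells, unless `auto_reduce = FALSE`. Without PCA
#' pre-reduction by default (the matrices are small); set `tsne$pca = TRUE`
#' in the config for a 50-component pre-reduction on larger inputs.
#'
#' @param norm A [normalize_counts()] result.
#' @param hvg_genes Character vector of genes to embed on (e.g. the `hvg`
#'   rows of [decompose_variance()]).
#' @param cfg A [pipeline_config()]; the `tsne` sublist supplies `dims`,
#'   `perplexity`, `max_iter`, `seed`, `pca`, `theta`.
#' @param auto_reduce Auto-reduce perplexity for small matrices?
#' @return A tibble of class `hox_embed`: `cell_id`, `tsne1`, `tsne2`;
#'   attributes `params` and `hvg_genes`.
#' @export
embed_tsne <- function(norm, hvg_genes, cfg = pipeline_config(),
                       auto_reduce = TRUE) {
  stopifnot(inherits(norm, "hox_norm"))
  p <- cfg$tsne
  x <- t(log_expr(norm, genes = hvg_genes))
  n <- nrow(x)
  perplexity <- p$perplexity
  if (n - 1 < 3 * perplexity) {
    if (!auto_reduce) {
      stop("need more than 3 x perplexity cells (have ", n, ")",
           call. = FALSE)
    }
    perplexity <- max(2, floor((n - 1) / 3))
    warning("perplexity reduced to ", perplexity, " for ", n, " cells")
  }
  set.seed(p$seed)
  fit <- Rtsne::Rtsne(x, dims = p$dims, perplexity = perplexity,
                      max_iter = p$max_iter, theta = p$theta, pca = p$pca,
                      check_duplicates = FALSE,
                      initial_dims = if (isTRUE(p$pca)) 50 else ncol(x))
  out <- tibble::tibble(cell_id = rownames(x),
                        tsne1 = fit$Y[, 1], tsne2 = fit$Y[, 2])
  class(out) <- c("hox_embed", class(out))
  attr(out, "params") <- list(dims = p$dims, perplexity = perplexity,
                              max_iter = p$max_iter, seed = p$seed,
                              theta = p$theta, pca = p$pca)
  attr(out, "hvg_genes") <- hvg_genes
  out
}
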