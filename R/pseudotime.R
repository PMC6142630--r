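#' Diffusion map of cells
#'
#' Builds a cell-cell random-walk operator on log2(normalized + 1) Euclidean
#' distances: a Gaussian kernel K(i,j) = exp(-d^2 / (2 sigma_i sigma_j)) with
#' either a global bandwidth or the local bandwidth sigma_i = distance to the
#' knn-th neighbour (default knn = 10); density normalization
#' W = K / (rowsum_i * rowsum_j); row-normalized transition operator
#' P = D^-1 W. Eigenpairs come from the symmetric conjugate
#' D^-1/2 W D^-1/2, so the top eigenvalue is 1 with the stationary
#' eigenvector, and the diffusion components (DCs) are the non-stationary
#' right eigenvectors scaled by their eigenvalues. Distances between cells in
#' this representation reflect transition probability along many random-walk
#' paths, the metric appropriate to noisy differentiation data.
#'
#' @param norm A [normalize_counts()] result.
#' @param genes Genes to compute distances on (e.g. the HVG set).
#' @param cells Cells to embed (default all; >= 10).
#' @param cfg A [pipeline_config()]; `pseudotime$k_eigs` retained eigenpairs,
#'   `pseudotime$knn` local-bandwidth neighbour, `pseudotime$sigma`
#'   `"local"` or a positive number for a global bandwidth.
#' @return A list of class `hox_diffusion`: `eigenvalues` (lambda_1 = 1
#'   first), `components` (cells x k, DC1.. = eigenvectors 2.. scaled by
#'   eigenvalue), `psi` (unscaled right eigenvectors incl. stationary),
#'   `stationary` (measure pi), `cell_ids`, `P` (transition matrix),
#'   `params`.
#' @export
diffusion_map <- function(norm, genes = NULL, cells = NULL,
                          cfg = pipeline_config()) {
  stopifnot(inherits(norm, "hox_norm"))
  if (is.null(genes)) genes <- rownames(norm$values)
  if (is.null(cells)) cells <- colnames(norm$values)
  if (length(cells) < 10) stop("need at least 10 cells", call. = FALSE)
  x <- t(log_expr(norm, genes = genes, cells = cells))
  pst <- cfg$pseudotime
  d2 <- as.matrix(stats::dist(x))^2

  if (identical(pst$sigma, "local")) {
    knn <- min(pst$knn, nrow(x) - 1)
    sig <- apply(d2, 1, function(r) sqrt(sort(r)[knn + 1]))  # knn-th neighbour
    sig[sig == 0] <- min(sig[sig > 0])
    denom <- 2 * outer(sig, sig)
  } else {
    denom <- 2 * pst$sigma^2
  }
  K <- exp(-d2 / denom)
  q <- rowSums(K)
  W <- K / outer(q, q)                       # density normalization
  rs <- rowSums(W)
  off <- W - diag(diag(W))
  if (any(rowSums(off) < .Machine$double.eps)) {
    stop("kernel graph disconnected (a cell has no neighbours); ",
         "increase sigma or knn", call. = FALSE)
  }
  A <- W / sqrt(outer(rs, rs))               # symmetric conjugate of P
  eg <- eigen(A, symmetric = TRUE)
  k <- min(pst$k_eigs + 1, nrow(x))
  lambda <- eg$values[seq_len(k)]
  if (length(lambda) > 1 && lambda[2] > 1 - 1e-12) {
    stop("kernel graph disconnected (eigenvalue 1 is degenerate); ",
         "increase sigma or knn", call. = FALSE)
  }
  v <- eg$vectors[, seq_len(k), drop = FALSE]
  psi <- v / sqrt(rs)                        # right eigenvectors of P
  # deterministic sign: largest-magnitude entry positive
  for (j in seq_len(ncol(psi))) {
    i <- which.max(abs(psi[, j]))
    if (psi[i, j] < 0) {
      psi[, j] <- -psi[, j]
      v[, j] <- -v[, j]
    }
  }
  comps <- sweep(psi[, -1, drop = FALSE], 2, lambda[-1], "*")
  colnames(comps) <- paste0("DC", seq_len(ncol(comps)))
  rownames(comps) <- cells
  structure(
    list(eigenvalues = lambda, components = comps, psi = psi,
         stationary = rs / sum(rs), cell_ids = cells,
         P = W / rs, params = pst),
    class = "hox_diffusion"
  )
}

#' Diffusion pseudo-time from a root cell
#'
#' Accumulates transitions over all retained non-stationary eigenpairs,
#' M = sum_l lambda_l / (1 - lambda_l) psi_l psi_l^T, and defines the
#' pseudo-time of a cell as the Euclidean distance between its row of M and
#' the root's row, rescaled to [0, 1]. The root's pseudo-time is exactly 0.
#'
#' @param dr A [diffusion_map()] result.
#' @param root Root cell id.
#' @return A tibble: `cell_id`, `pseudotime` (in [0, 1], 0 at the root).
#' @export
dpt <- function(dr, root) {
  stopifnot(inherits(dr, "hox_diffusion"))
  if (!root %in% dr$cell_ids) stop("root cell not in map: ", root,
                                   call. = FALSE)
  lambda <- dr$eigenvalues
  if (sum(lambda > 1 - 1e-8) > 1) {
    stop("eigenvalue 1 has multiplicity > 1: kernel graph disconnected",
         call. = FALSE)
  }
  lam <- lambda[-1]
  psi <- dr$psi[, -1, drop = FALSE]
  scaled <- sweep(psi, 2, lam / (1 - lam), "*")
  M <- scaled %*% t(psi)                    # accumulated transition profile
  ri <- match(root, dr$cell_ids)
  delta <- sweep(M, 2, M[ri, ])
  d <- sqrt(rowSums(delta^2))
  rng <- max(d)
  tibble::tibble(cell_id = dr$cell_ids,
                 pseudotime = unname(if (rng > 0) d / rng else d))
}

#' Pick a root cell from the earliest combination group
#'
#' The cell nearest (in DC1/DC2) to the centroid of the single-gene group of
#' the panel's most readily activated gene (the `Hoxd13`-only group by
#' default), that group sitting at one extremity of the pseudo-time axis.
#' Falls back to the cell with extreme DC1 when the group is absent.
#'
#' @param dr A [diffusion_map()] result.
#' @param calls Output of [call_combinations()] covering the embedded cells.
#' @param label Combination label of the root group.
#' @return A cell id.
#' @export
select_root_cell <- function(dr, calls, label = "Hoxd13") {
  lab <- combination_labels(calls)
  members <- intersect(lab$cell_id[lab$label == label], dr$cell_ids)
  dc <- dr$components[, 1:2, drop = FALSE]
  if (length(members) == 0) {
    return(dr$cell_ids[which.max(abs(dc[, 1]))])
  }
  ctr <- colMeans(dc[members, , drop = FALSE])
  d <- sqrt(colSums((t(dc[members, , drop = FALSE]) - ctr)^2))
  members[which.min(d)]
}

#' Combination-group centroids and pseudo-time progression
#'
#' Centroid of every main combination group in (DC1, DC2) (arithmetic mean
#' of member cells), and a progression statistic: the Spearman correlation
#' between each cell's on-set size and its pseudo-time, with a permutation
#' p-value (on-set sizes permuted across cells, seeded). A positive
#' progression means combinatorial complexity increases along pseudo-time.
#'
#' @param dr A [diffusion_map()] result.
#' @param calls Output of [call_combinations()] covering the embedded cells.
#' @param pt Output of [dpt()].
#' @param cfg A [pipeline_config()] (`pseudotime$n_permutations`).
#' @param seed Seed for the permutation null.
#' @return A list: `centroids` (tibble: label, n_cells, DC1, DC2),
#'   `progression` (tibble: spearman_rho, p_permutation, n_cells; NA rho
#'   when on-set size is constant).
#' @export
group_centroids_and_progression <- function(dr, calls, pt,
                                            cfg = pipeline_config(),
                                            seed = cfg$seed) {
  stopifnot(inherits(dr, "hox_diffusion"))
  lab <- combination_labels(calls)
  lab <- lab[match(dr$cell_ids, lab$cell_id), ]
  if (anyNA(lab$cell_id)) {
    stop("combination calls do not cover the embedded cells", call. = FALSE)
  }
  dc <- dr$components[, 1:2, drop = FALSE]
  centroids <- tibble::tibble(cell_id = dr$cell_ids,
                              label = lab$label,
                              DC1 = dc[, 1], DC2 = dc[, 2]) |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(n_cells = dplyr::n(), DC1 = mean(.data$DC1),
                     DC2 = mean(.data$DC2), .groups = "drop")

  ptv <- pt$pseudotime[match(dr$cell_ids, pt$cell_id)]
  size <- lab$n_on
  if (length(unique(size)) == 1 || length(unique(ptv)) == 1) {
    prog <- tibble::tibble(spearman_rho = NA_real_, p_permutation = NA_real_,
                           n_cells = length(ptv))
  } else {
    rho <- stats::cor(size, ptv, method = "spearman")
    set.seed(seed)
    nperm <- cfg$pseudotime$n_permutations
    perm <- replicate(nperm,
                      stats::cor(sample(size), ptv, method = "spearman"))
    pval <- (1 + sum(perm >= rho)) / (nperm + 1)
    prog <- tibble::tibble(spearman_rho = rho, p_permutation = pval,
                           n_cells = length(ptv))
  }
  list(centroids = centroids, progression = prog)
}
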