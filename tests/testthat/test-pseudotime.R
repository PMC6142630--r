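# a 1-D chain of cells: two genes tracing a line, global bandwidth
chain_norm <- function(n = 50) {
  x <- seq(0, 8, length.out = n)
  v <- rbind(gene1 = 2^x - 1, gene2 = 2^(x / 2) - 1)  # log2(x+1) is linear
  colnames(v) <- sprintf("cell%02d", seq_len(n))
  make_norm(v)
}

chain_cfg <- pipeline_config(pseudotime = list(sigma = 0.5, k_eigs = 10))

test_that("the transition operator is row-stochastic with top eigenvalue 1", {
  norm <- chain_norm()
  dr <- diffusion_map(norm, cfg = chain_cfg)
  expect_equal(unname(rowSums(dr$P)), rep(1, 50), tolerance = 1e-10)
  expect_equal(dr$eigenvalues[1], 1, tolerance = 1e-8)
  expect_lt(dr$eigenvalues[2], 1)
  # stationary eigenvector is constant up to scaling
  expect_lt(diff(range(dr$psi[, 1])), 1e-8)
})

test_that("diffusion components are orthogonal under the stationary measure", {
  sim <- simulate_counts(small_params(seed = 81, low_quality_fraction = 0))
  norm <- normalize_counts(sim$counts)
  dr <- diffusion_map(norm)
  pi_w <- dr$stationary
  psi <- dr$psi
  gram <- t(psi) %*% (psi * pi_w)
  off <- gram - diag(diag(gram))
  expect_lt(max(abs(off)), 1e-6)
})

test_that("a 1-D chain is ordered by DC1 and by pseudo-time", {
  norm <- chain_norm()
  dr <- diffusion_map(norm, cfg = chain_cfg)
  pos <- seq_len(50)
  expect_gt(abs(cor(dr$components[, 1], pos, method = "spearman")), 0.99)

  pt <- dpt(dr, root = "cell01")
  expect_equal(pt$pseudotime[pt$cell_id == "cell01"], 0)
  expect_true(all(pt$pseudotime >= 0 & pt$pseudotime <= 1))
  expect_gt(cor(pt$pseudotime, pos, method = "spearman"), 0.99)
})

test_that("disconnected kernel graphs are reported", {
  # distinct points with a tiny global bandwidth: rows lose all neighbours
  v <- rbind(g1 = 2^(seq(1, 12)) - 1,
             g2 = 2^(seq(12, 1)) - 1)
  colnames(v) <- sprintf("c%02d", 1:12)
  norm <- make_norm(v)
  cfg <- pipeline_config(pseudotime = list(sigma = 1e-6))
  expect_error(diffusion_map(norm, cfg = cfg), "disconnected|neighbours")
})

test_that("centroids are member means and mirrored groups mirror exactly", {
  comps <- rbind(matrix(c(1, 2, 1, 3, 2, 2), 3, 2),
                 -matrix(c(1, 2, 1, 3, 2, 2), 3, 2))
  rownames(comps) <- sprintf("c%d", 1:6)
  colnames(comps) <- c("DC1", "DC2")
  dr <- structure(list(components = comps, cell_ids = rownames(comps),
                       eigenvalues = c(1, 0.5, 0.2),
                       psi = cbind(1, comps), stationary = rep(1 / 6, 6)),
                  class = "hox_diffusion")
  calls <- tibble::tibble(cell_id = rownames(comps), gene = "Hoxd13",
                          expr = 10, frac_of_max = 1, on = TRUE,
                          label = rep(c("A", "B"), each = 3),
                          n_on = rep(c(1, 2), each = 3))
  pt <- tibble::tibble(cell_id = rownames(comps),
                       pseudotime = c(0, .1, .2, .8, .9, 1))
  res <- group_centroids_and_progression(dr, calls, pt,
                                         pipeline_config(pseudotime =
                                                           list(n_permutations = 199)))
  ctr <- res$centroids
  expect_equal(ctr$DC1[ctr$label == "A"], mean(comps[1:3, 1]))
  expect_equal(ctr$DC1[ctr$label == "A"], -ctr$DC1[ctr$label == "B"])
  expect_equal(ctr$DC2[ctr$label == "A"], -ctr$DC2[ctr$label == "B"])
  expect_gt(res$progression$spearman_rho, 0)

  # single group: progression undefined, reported missing
  calls1 <- dplyr::mutate(calls, label = "A", n_on = 1)
  res1 <- group_centroids_and_progression(dr, calls1, pt,
                                          pipeline_config(pseudotime =
                                                            list(n_permutations = 199)))
  expect_true(is.na(res1$progression$spearman_rho))
})

test_that("pseudotime recovers the latent order of nested-activation cells", {
  sim <- simulate_counts(small_params(seed = 83))
  res <- run_pipeline(sim$counts, cfg = synth_qc_config(small_params()))
  tr <- sim$cell_truth[match(res$pseudotime$cell_id, sim$cell_truth$cell_id), ]
  expect_gte(cor(res$pseudotime$pseudotime, tr$t, method = "spearman"), 0.5)

  # root choice within the earliest group barely moves the ordering
  lab <- dplyr::distinct(res$calls, cell_id, label)
  d13_cells <- intersect(lab$cell_id[lab$label == "Hoxd13"],
                         res$diffusion$cell_ids)
  expect_gt(length(d13_cells), 1)
  pt_alt <- dpt(res$diffusion, root = setdiff(d13_cells, res$root)[1])
  expect_gt(cor(res$pseudotime$pseudotime, pt_alt$pseudotime,
                method = "spearman"), 0.95)
})

test_that("weakly coupled zeugopod cells progress worse than autopod cells", {
  sim <- simulate_counts(small_params(seed = 85))
  cfg <- synth_qc_config(small_params(),
                         pseudotime = list(n_permutations = 999))
  res_a <- run_pipeline(sim$counts, cfg = cfg, pseudotime_tissue = "autopod")
  res_z <- run_pipeline(sim$counts, cfg = cfg, pseudotime_tissue = "zeugopod")
  expect_gt(res_a$progression$spearman_rho, res_z$progression$spearman_rho)
})
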