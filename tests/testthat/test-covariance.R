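test_that("panel correlations match the tie-corrected rank formula", {
  # gene identical to Hoxd13 -> rho 1; hand tie-corrected case -> 0.8208
  pv <- matrix(0, 5, 5)
  pv[5, ] <- 1:5  # Hoxd13
  rownames(pv) <- c("Hoxd9", "Hoxd10", "Hoxd11", "Hoxd12", "Hoxd13")
  v <- rbind(pv,
             twin = 1:5,
             tied = c(5, 6, 7, 8, 7),
             flat = rep(3, 5))
  norm <- make_norm(v)
  out <- spearman_vs_panel(norm)
  d13 <- out[out$panel_gene == "Hoxd13", ]
  expect_equal(d13$rho[d13$gene_id == "twin"], 1)
  expect_equal(d13$p_value[d13$gene_id == "twin"], 0)

  # brute-force average-rank Pearson on the tied example
  rx <- rank(1:5); ry <- rank(c(5, 6, 7, 8, 7))
  hand <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(d13$rho[d13$gene_id == "tied"], hand)
  expect_equal(round(hand, 4), 0.8208)

  # constant gene: missing, excluded from selection
  expect_true(is.na(d13$rho[d13$gene_id == "flat"]))
  sel <- select_covarying(out, pipeline_config(covary_min_rho = 0.0001,
                                               covary_max_fdr = 0.9999))
  expect_false("flat" %in% sel)
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(3)
  pv <- matrix(rexp(5 * 30), 5, 30)
  rownames(pv) <- c("Hoxd9", "Hoxd10", "Hoxd11", "Hoxd12", "Hoxd13")
  g <- matrix(rexp(30), 1, 30, dimnames = list("gene", NULL))
  a <- spearman_vs_panel(make_norm(rbind(pv, g)))
  b <- spearman_vs_panel(make_norm(rbind(pv, gene = exp(g * 2))))
  expect_equal(a$rho, b$rho)
})

test_that("independent genes rarely exceed the 3/sqrt(n) null band", {
  set.seed(19)
  n <- 100
  pv <- matrix(rexp(5 * n), 5, n)
  rownames(pv) <- c("Hoxd9", "Hoxd10", "Hoxd11", "Hoxd12", "Hoxd13")
  g <- matrix(rexp(200 * n), 200, n,
              dimnames = list(sprintf("g%03d", 1:200), NULL))
  out <- spearman_vs_panel(make_norm(rbind(pv, g)))
  expect_gt(mean(abs(out$rho) < 3 / sqrt(n)), 0.95)
})

test_that("covarying-gene selection recovers a driven gene and honors no-op thresholds", {
  sim <- simulate_counts(small_params(seed = 41, low_quality_fraction = 0))
  norm <- normalize_counts(sim$counts)
  out <- spearman_vs_panel(norm)
  sel <- select_covarying(out, pipeline_config())
  # a target gene driven by the Hoxd11 module must be picked up
  driven <- sim$gene_truth$gene_id[sim$gene_truth$type == "target" &
                                     sim$gene_truth$module == "Hoxd11"]
  expect_gt(length(intersect(driven, sel)), 0.5 * length(driven))

  # rho = 0 and FDR = 1 selects every non-constant gene
  all_sel <- select_covarying(out, pipeline_config(
    covary_min_rho = 1e-12, covary_max_fdr = 0.999999))
  nonconst <- unique(out$gene_id[!is.na(out$rho)])
  expect_setequal(all_sel, nonconst)
})

test_that("clustering merges the tight pair first and is permutation-stable", {
  rho <- matrix(0.1, 3, 3, dimnames = list(c("a", "b", "c"),
                                           c("a", "b", "c")))
  diag(rho) <- 1
  rho["a", "b"] <- rho["b", "a"] <- 0.9
  corr <- structure(list(rho = rho, n = 10,
                         p_adjusted = matrix(0, 3, 3), cells = NULL),
                    class = "hox_cor")
  den <- cluster_correlations(corr)
  first <- den$hclust$merge[1, ]
  expect_setequal(rownames(rho)[-first], c("a", "b"))
  expect_equal(den$hclust$height[1], 1 - 0.9)

  # permuting the input order changes nothing after lexicographic ordering
  perm <- c(3, 1, 2)
  corr_p <- structure(list(rho = rho[perm, perm], n = 10,
                           p_adjusted = matrix(0, 3, 3), cells = NULL),
                      class = "hox_cor")
  den_p <- cluster_correlations(corr_p)
  expect_equal(den_p$hclust$height, den$hclust$height)
  expect_equal(den_p$leaf_order, den$leaf_order)
})

test_that("duplicated genes merge at height zero; missing rho is an error", {
  set.seed(4)
  v <- matrix(rexp(4 * 20), 4, 20,
              dimnames = list(c("a", "b", "dup1", "dup2"), NULL))
  v["dup2", ] <- v["dup1", ]
  corr <- correlation_matrix(make_norm(v), rownames(v))
  den <- cluster_correlations(corr)
  expect_equal(min(den$hclust$height), 0)
  first <- den$hclust$merge[1, ]
  expect_setequal(sort(rownames(corr$rho))[-first], c("dup1", "dup2"))

  corr$rho[1, 2] <- corr$rho[2, 1] <- NA
  expect_error(cluster_correlations(corr), "a~b")
})

test_that("panel genes cluster with their own target modules", {
  # full cell set, as in the supervised target-gene covariance heatmaps:
  # pooling both tissues decorrelates neighbouring modules (activation flips
  # are independent across panel genes) while within-module coupling remains
  sim <- simulate_counts(synth_params(seed = 61, low_quality_fraction = 0))
  norm <- normalize_counts(sim$counts)
  genes <- sim$gene_truth$gene_id[sim$gene_truth$type %in%
                                    c("panel", "target")]
  corr <- correlation_matrix(norm, genes)
  den <- cluster_correlations(corr)
  cut <- cutree(den$hclust, k = 5)
  truth <- sim$gene_truth$module[match(names(cut), sim$gene_truth$gene_id)]
  ari <- mclust::adjustedRandIndex(cut, truth)
  expect_gt(ari, 0.7)
})
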