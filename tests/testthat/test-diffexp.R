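test_that("BH adjustment matches the hand step-up and its dominance bounds", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.1, 1.5)), "0, 1")

  # independent step-up oracle on random vectors
  set.seed(5)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    n <- length(p)
    o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    expected <- pmin(adj, 1)[order(o)]
    got <- bh_adjust(p)
    expect_equal(got, expected)
    expect_true(all(got >= p & got <= 1))
  }
})

test_that("the unmoderated limit equals the pooled two-sample t by hand", {
  v <- rbind(g1 = c(2, 3, 2, 4, 4, 5, 6, 4))
  norm <- make_norm(v)
  res <- moderated_two_group_test(norm, paste0("c00", 1:4), paste0("c00", 5:8),
                                  prior = list(d0 = 0, s0_sq = 1))
  x <- log2(v[1, 1:4] + 1); y <- log2(v[1, 5:8] + 1)
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(res$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-12)
  expect_equal(res$df, 6)
  expect_equal(res$log2_fc, mean(x) - mean(y))
})

test_that("identical groups yield zero fold changes and no calls", {
  set.seed(2)
  v <- matrix(rpois(50 * 4, 30), 50, 4)
  v <- cbind(v, v)  # second group duplicates the first's values
  norm <- make_norm(v)
  cells <- colnames(norm$values)
  res <- moderated_two_group_test(norm, cells[1:4], cells[5:8])
  expect_true(all(res$log2_fc == 0))
  expect_false(any(res$significant))
})

test_that("moderated statistics agree with the limma cross-check", {
  set.seed(33)
  n1 <- 8; n2 <- 8
  v <- matrix(rnbinom(300 * (n1 + n2), mu = 50, size = 2), 300)
  v[1:20, 1:n1] <- v[1:20, 1:n1] * 8L  # some true signal
  norm <- make_norm(v)
  cells <- colnames(norm$values)
  res <- moderated_two_group_test(norm, cells[1:n1], cells[n1 + 1:n2])

  le <- log2(v + 1)
  design <- cbind(1, rep(c(1, 0), c(n1, n2)))
  fit <- limma::eBayes(limma::lmFit(le, design))
  expect_equal(attr(res, "d0"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(res, "s0_sq"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(res$t, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(res$p_value, unname(fit$p.value[, 2]), tolerance = 1e-8)
})

test_that("swapping group labels negates fold changes and keeps p-values", {
  set.seed(12)
  v <- matrix(rnbinom(100 * 10, mu = 20, size = 3), 100, 10)
  norm <- make_norm(v)
  g1 <- colnames(norm$values)[1:5]; g2 <- colnames(norm$values)[6:10]
  a <- moderated_two_group_test(norm, g1, g2)
  b <- moderated_two_group_test(norm, g2, g1)
  expect_equal(a$log2_fc, -b$log2_fc)
  expect_equal(a$t, -b$t)
  expect_equal(a$p_value, b$p_value)
})

test_that("posterior variances shrink between prior and gene variance", {
  set.seed(44)
  v <- matrix(rnbinom(200 * 12, mu = 30, size = 1), 200, 12)
  norm <- make_norm(v)
  g1 <- colnames(norm$values)[1:6]; g2 <- colnames(norm$values)[7:12]
  res <- moderated_two_group_test(norm, g1, g2)
  le <- log2(v + 1)
  s2 <- sapply(seq_len(nrow(le)), function(i) {
    (5 * var(le[i, 1:6]) + 5 * var(le[i, 7:12])) / 10
  })
  s0 <- attr(res, "s0_sq")
  s2_post <- ifelse(res$t != 0, (res$log2_fc / res$t)^2 / (1 / 6 + 1 / 6),
                    NA)
  ok <- !is.na(s2_post)
  expect_true(all(s2_post[ok] >= pmin(s0, s2[ok]) - 1e-12))
  expect_true(all(s2_post[ok] <= pmax(s0, s2[ok]) + 1e-12))
})

test_that("the global null keeps type-I error and BH calls in check", {
  set.seed(7)
  v <- matrix(rnbinom(2000 * 60, mu = 40, size = 2), 2000, 60)
  norm <- make_norm(v)
  g1 <- colnames(norm$values)[1:30]; g2 <- colnames(norm$values)[31:60]
  res <- moderated_two_group_test(norm, g1, g2)
  frac <- mean(res$p_value < 0.05)
  expect_lt(abs(frac - 0.05), 0.01)
  expect_equal(sum(res$significant), 0L)
})

test_that("group validation rejects small or overlapping groups", {
  v <- matrix(rpois(20, 5), 5, 4)
  norm <- make_norm(v)
  cells <- colnames(norm$values)
  expect_error(moderated_two_group_test(norm, cells[1], cells[2:4]),
               "at least 2")
  expect_error(moderated_two_group_test(norm, cells[1:2], cells[2:4]),
               "disjoint")
})

test_that("overlap counts equal brute-force set algebra", {
  mk <- function(sig, universe) {
    out <- tibble::tibble(gene_id = universe,
                          significant = universe %in% sig)
    class(out) <- c("hox_de", class(out))
    out
  }
  u <- letters[1:10]
  ov <- deg_overlap(list(A = mk(c("a", "b"), u), B = mk("c", u)))
  expect_equal(sum(ov$n_genes[ov$A & ov$B]), 0)
  ov2 <- deg_overlap(list(A = mk(c("a", "b", "c"), u),
                          B = mk(c("b", "c", "d"), u)))
  expect_equal(ov2$n_genes[ov2$A & ov2$B], 2L)

  set.seed(50)
  for (i in 1:100) {
    u <- sprintf("g%02d", 1:30)
    s1 <- sample(u, sample(0:20, 1)); s2 <- sample(u, sample(0:20, 1))
    s3 <- sample(u, sample(0:20, 1))
    ov <- deg_overlap(list(x = mk(s1, u), y = mk(s2, u), z = mk(s3, u)))
    both <- length(intersect(intersect(s1, s2), s3))
    got <- ov$n_genes[ov$x & ov$y & ov$z]
    expect_equal(if (length(got)) got else 0L, both)
    only_x <- length(setdiff(setdiff(s1, s2), s3))
    got_x <- ov$n_genes[ov$x & !ov$y & !ov$z]
    expect_equal(if (length(got_x)) got_x else 0L, only_x)
  }
  expect_error(deg_overlap(list(mk("a", u), mk("a", letters[1:5]))),
               "universe")
})
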