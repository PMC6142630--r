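test_that("the dual-threshold rule matches hand application", {
  # columns are cells; rows Hoxd9, d10, d11, d12, d13
  pv <- cbind(c1 = c(0, 4, 6, 0, 100),    # 6 passes both; 4 fails absolute
              c2 = c(0, 0, 8, 0, 200),    # 8 >= 5 but 8 < 0.05*200 = 10
              c3 = c(0, 0, 0, 0, 0))      # all zero -> none
  norm <- make_panel_norm(pv)
  calls <- call_combinations(norm)
  lab <- dplyr::distinct(calls, cell_id, label)
  expect_equal(lab$label, c("Hoxd11+Hoxd13", "Hoxd13", "none"))
  # audit columns record the criteria inputs
  c1 <- calls[calls$cell_id == "c1" & calls$gene == "Hoxd11", ]
  expect_equal(c1$expr, 6)
  expect_equal(c1$frac_of_max, 6 / 100)
})

test_that("calls equal a brute-force reapplication on random cells", {
  set.seed(99)
  n <- 1000
  pv <- matrix(rexp(5 * n, rate = 1 / 20), 5, n)
  pv[sample(length(pv), length(pv) / 3)] <- 0
  norm <- make_panel_norm(pv)
  cfg <- pipeline_config()
  calls <- call_combinations(norm, cfg = cfg)
  genes <- c("Hoxd9", "Hoxd10", "Hoxd11", "Hoxd12", "Hoxd13")
  brute <- vapply(seq_len(n), function(j) {
    x <- pv[, j]
    on <- x >= 5 & x >= 0.05 * max(x)
    if (!any(on)) "none" else paste(genes[on], collapse = "+")
  }, character(1))
  expect_equal(dplyr::distinct(calls, cell_id, label)$label, brute)
})

test_that("rescaling a cell leaves the relative criterion invariant", {
  set.seed(7)
  for (i in 1:50) {
    x <- round(rexp(5, 1 / 15), 2)
    lambda <- runif(1, 0.1, 10)
    n1 <- make_panel_norm(cbind(c1 = x))
    n2 <- make_panel_norm(cbind(c1 = lambda * x))
    on1 <- call_combinations(n1)$on
    on2 <- call_combinations(n2)$on
    # relative part unchanged; absolute part passes iff lambda*x >= 5
    rel <- x >= 0.05 * max(x) & max(x) > 0
    expect_equal(on1, rel & x >= 5)
    expect_equal(on2, rel & lambda * x >= 5)
  }
})

test_that("cell order never affects calls", {
  set.seed(15)
  pv <- matrix(rexp(5 * 40, 1 / 20), 5, 40,
               dimnames = list(NULL, sprintf("c%02d", 1:40)))
  norm <- make_panel_norm(pv)
  perm <- sample(40)
  norm_p <- make_panel_norm(pv[, perm])
  a <- dplyr::distinct(call_combinations(norm), cell_id, label)
  b <- dplyr::distinct(call_combinations(norm_p), cell_id, label)
  expect_equal(a$label[match(b$cell_id, a$cell_id)], b$label)
})

test_that("main groups need strictly more than the minimum cell count", {
  labels <- rep(c("Hoxd13", "Hoxd11+Hoxd13", "Hoxd10+Hoxd13", "none"),
                c(7, 6, 5, 2))
  n <- length(labels)
  calls <- tibble::tibble(cell_id = sprintf("c%02d", seq_len(n)),
                          gene = "Hoxd13", expr = 10, frac_of_max = 1,
                          on = TRUE, label = labels,
                          n_on = 1)
  tab <- tabulate_combinations(calls, cfg = pipeline_config())
  expect_equal(sum(tab$main_group), 2L)
  expect_equal(tab$frequency[tab$label == "Hoxd13"], 7 / 20)
  expect_equal(sum(tab$frequency), 1)

  one <- tabulate_combinations(calls[calls$label == "Hoxd13", ])
  expect_equal(one$frequency, 1)
  expect_equal(attr(tab, "n_distinct_with_none"), 4L)
  expect_equal(attr(tab, "n_distinct_without_none"), 3L)
})

test_that("recovered combination frequencies match generator truth", {
  p <- small_params(epsilon = 0, zeugopod_epsilon = 0, seed = 23,
                    low_quality_fraction = 0)
  sim <- simulate_counts(p)
  norm <- normalize_counts(sim$counts)
  calls <- call_combinations(norm)
  tab <- tabulate_combinations(calls, sim$counts$cell_meta)
  tab_a <- tab[tab$tissue == "autopod", ]

  genes <- c("Hoxd9", "Hoxd10", "Hoxd11", "Hoxd12", "Hoxd13")
  tr <- sim$cell_truth[sim$cell_truth$tissue == "autopod", ]
  states <- as.matrix(tr[paste0("on_", genes)])
  truth_lab <- apply(states, 1, function(o) {
    if (!any(o)) "none" else paste(genes[o], collapse = "+")
  })
  truth_freq <- table(truth_lab) / length(truth_lab)
  n <- length(truth_lab)
  for (lb in names(truth_freq)) {
    f <- truth_freq[[lb]]
    obs <- tab_a$frequency[tab_a$label == lb]
    obs <- if (length(obs)) obs else 0
    se <- sqrt(f * (1 - f) / n)
    expect_lt(abs(obs - f), 3 * max(se, 1e-3))
  }
})

test_that("cumulative panel expression conserves totals and collinear order", {
  sim <- simulate_counts(small_params(epsilon = 0, zeugopod_epsilon = 0,
                                      seed = 27, low_quality_fraction = 0))
  norm <- normalize_counts(sim$counts)
  cum <- cumulative_panel_expression(norm, include_a = TRUE)
  sums <- cum |>
    dplyr::filter(cluster == "HoxD") |>
    dplyr::group_by(cell_id, panel_total) |>
    dplyr::summarise(s = sum(expr), .groups = "drop")
  expect_equal(sums$s, sums$panel_total)

  means <- cum |>
    dplyr::filter(cluster == "HoxD") |>
    dplyr::group_by(gene) |>
    dplyr::summarise(m = mean(expr), .groups = "drop")
  m <- means$m[match(c("Hoxd13", "Hoxd12", "Hoxd11", "Hoxd10", "Hoxd9"),
                     means$gene)]
  expect_true(all(diff(m) < 0))

  single <- cumulative_panel_expression(norm, hox_panel(
    posterior_d = c("Hoxd13", "Hoxd12")))
  tot <- single |>
    dplyr::group_by(cell_id) |>
    dplyr::summarise(s = sum(expr), t = panel_total[1], .groups = "drop")
  expect_equal(tot$s, tot$t)
})

test_that("absent panel genes are reported by name", {
  norm <- make_norm(matrix(1, 2, 2,
                           dimnames = list(c("Hoxd13", "Shh"), NULL)))
  expect_error(call_combinations(norm), "Hoxd9")
})
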