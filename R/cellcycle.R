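#' Read marker pairs for cell-cycle scoring
#'
#' Three-column TSV: `phase` (G1 / S / G2M), `gene_hi`, `gene_lo`. Duplicate
#' pairs within a phase are rejected.
#'
#' @param path TSV path.
#' @return A tibble of class `marker_pairs`.
#' @export
read_marker_pairs <- function(path) {
  tab <- read_delim_auto(path)
  marker_pairs(tab)
}

#' @rdname read_marker_pairs
#' @param pairs A data frame with columns `phase`, `gene_hi`, `gene_lo`.
#' @export
marker_pairs <- function(pairs) {
  pairs <- tibble::as_tibble(pairs)
  stopifnot(all(c("phase", "gene_hi", "gene_lo") %in% names(pairs)))
  key <- paste(pairs$phase, pairs$gene_hi, pairs$gene_lo)
  if (anyDuplicated(key)) {
    stop("duplicate marker pairs: ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  class(pairs) <- c("marker_pairs", class(pairs))
  pairs
}

#' Score cell-cycle phase from marker pairs
#'
#' For each phase, the score of a cell is the fraction of informative pairs
#' (both genes present in the matrix and not tied in that cell) with
#' expr(gene_hi) > expr(gene_lo). Pair comparisons are rank-based, so scores
#' are invariant to any monotone transform of expression. Phase assignment:
#' G1 if the G1 score is >= 0.5 and exceeds the G2M score; G2M if the G2M
#' score is >= 0.5 and exceeds the G1 score; otherwise S. A cell with no
#' informative pair for a phase has a missing score and no assigned phase.
#'
#' @param norm A [normalize_counts()] result (raw or normalized values give
#'   identical scores within a cell).
#' @param pairs A [marker_pairs()] table.
#' @return A tibble per cell: `cell_id`, `score_G1`, `score_S`, `score_G2M`,
#'   `n_informative_G1/S/G2M`, `phase` (NA when unassigned).
#' @export
score_cycle <- function(norm, pairs) {
  stopifnot(inherits(norm, "hox_norm"), inherits(pairs, "marker_pairs"))
  v <- norm$values
  phases <- c("G1", "S", "G2M")
  res <- lapply(phases, function(ph) {
    pp <- pairs[pairs$phase == ph, ]
    pp <- pp[pp$gene_hi %in% rownames(v) & pp$gene_lo %in% rownames(v), ]
    if (nrow(pp) == 0) {
      return(list(score = rep(NA_real_, ncol(v)),
                  n_inf = rep(0L, ncol(v))))
    }
    hi <- v[pp$gene_hi, , drop = FALSE]
    lo <- v[pp$gene_lo, , drop = FALSE]
    informative <- hi != lo
    wins <- hi > lo
    n_inf <- colSums(informative)
    score <- ifelse(n_inf > 0, colSums(wins & informative) / n_inf, NA_real_)
    list(score = unname(score), n_inf = unname(as.integer(n_inf)))
  })
  names(res) <- phases
  out <- tibble::tibble(cell_id = colnames(v))
  for (ph in phases) {
    out[[paste0("score_", ph)]] <- res[[ph]]$score
    out[[paste0("n_informative_", ph)]] <- res[[ph]]$n_inf
  }
  g1 <- out$score_G1; g2m <- out$score_G2M
  phase <- dplyr::case_when(
    is.na(g1) | is.na(g2m) | is.na(out$score_S) ~ NA_character_,
    g1 >= 0.5 & g1 > g2m ~ "G1",
    g2m >= 0.5 & g2m > g1 ~ "G2M",
    TRUE ~ "S"
  )
  out$phase <- phase
  out
}

#' Phase composition per combination group, with homogeneity test
#'
#' Cross-tabulates assigned phases against combination groups and tests
#' homogeneity with a chi-square test, switching to Fisher's exact test when
#' any expected count falls below 5. With a single group only proportions
#' are returned.
#'
#' @param scores Output of [score_cycle()].
#' @param calls Output of [call_combinations()].
#' @return A list: `composition` (tibble: label, phase, n_cells,
#'   proportion), `test` (tibble: method, statistic, p_value; NULL for a
#'   single group).
#' @export
phase_by_group <- function(scores, calls) {
  lab <- combination_labels(calls)
  df <- dplyr::inner_join(scores, lab, by = "cell_id")
  df <- df[!is.na(df$phase), ]
  comp <- df |>
    dplyr::count(.data$label, .data$phase, name = "n_cells") |>
    dplyr::group_by(.data$label) |>
    dplyr::mutate(proportion = .data$n_cells / sum(.data$n_cells)) |>
    dplyr::ungroup()
  if (length(unique(df$label)) < 2) {
    return(list(composition = comp, test = NULL))
  }
  tab <- table(df$label, df$phase)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    ft <- stats::fisher.test(tab, simulate.p.value = nrow(tab) * ncol(tab) > 10,
                             B = 10000)
    test <- tibble::tibble(method = "fisher", statistic = NA_real_,
                           p_value = ft$p.value)
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab))
    test <- tibble::tibble(method = "chi-square",
                           statistic = unname(ct$statistic),
                           p_value = ct$p.value)
  }
  list(composition = comp, test = test)
}
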